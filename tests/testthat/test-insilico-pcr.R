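plant_at <- function(genome, oligo, pos0) {   # pos0 is 0-based
  substr(genome, pos0 + 1, pos0 + nchar(oligo)) <- oligo
  genome
}
rc <- function(x) paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]),
                        collapse = "")

test_that("planted sites are found on the correct strands", {
  set.seed(71)
  primer <- "GGTCGAGCTTGGGATCGTAG"
  g <- random_dna_str(1000, gc = 0.3)
  g <- plant_at(g, primer, 100)
  g <- plant_at(g, rc(primer), 700)
  sites <- find_binding_sites(primer, g, max_mismatch = 0)
  expect_identical(nrow(sites), 2L)
  plus <- sites[sites$strand == "+", ]
  expect_identical(plus$start, 100L)
  expect_identical(plus$end, 120L)
  expect_identical(plus$mismatches, 0L)
  minus <- sites[sites$strand == "-", ]
  expect_identical(minus$start, 700L)
})

test_that("3'-anchor mismatches disqualify a site; internal ones do not", {
  set.seed(72)
  primer <- "TCATCACCCAAGCCAACCAG"
  g <- random_dna_str(600, gc = 0.3)
  internal <- primer
  substr(internal, 5, 5) <- if (substr(primer, 5, 5) == "A") "C" else "A"
  terminal <- primer
  substr(terminal, 20, 20) <- if (substr(primer, 20, 20) == "G") "T" else "G"
  g <- plant_at(g, internal, 50)
  g <- plant_at(g, terminal, 300)
  sites <- find_binding_sites(primer, g, max_mismatch = 2)
  expect_identical(sites$start, 50L)
  expect_identical(sites$mismatches, 1L)
})

test_that("binding-site search equals the exhaustive position scan", {
  set.seed(73)
  for (rep in 1:8) {
    g <- random_dna_str(3000, gc = runif(1, 0.3, 0.7))
    primer <- random_dna_str(18)
    # plant some near-matches to exercise the mismatch logic
    g <- plant_at(g, primer, 40)
    mut <- primer; substr(mut, 7, 7) <- "A"
    g <- plant_at(g, mut, 900)
    g <- plant_at(g, rc(primer), 2000)
    got <- find_binding_sites(primer, g, max_mismatch = 2, anchor3_len = 3)
    want <- binding_oracle(primer, g, 2, 3)
    expect_identical(got$start, want$start, info = paste("rep", rep))
    expect_identical(got$strand, want$strand)
    expect_identical(got$mismatches, want$mismatches)
  }
  # N never matches a primer base
  gN <- paste0(strrep("AT", 30), "GGTCGAGCTTGGGNTCGTAG", strrep("TA", 30))
  expect_identical(nrow(find_binding_sites("GGTCGAGCTTGGGATCGTAG", gN,
                                           max_mismatch = 0)), 0L)
  expect_identical(nrow(find_binding_sites("GGTCGAGCTTGGGATCGTAG", gN,
                                           max_mismatch = 1)), 1L)
})

test_that("amplicons arise from convergent site pairs within range", {
  set.seed(74)
  fwd <- "TCATCACCCAAGCCAACCAG"; rev <- "TCATGGTCGATCCGTCCTCT"
  g <- random_dna_str(6000, gc = 0.3)
  g <- plant_at(g, fwd, 1000)
  g <- plant_at(g, rc(rev), 1380)            # product 1000..1400 = 400 bp
  amp <- predict_amplicons(list(forward = fwd, reverse = rev), g)
  expect_identical(nrow(amp), 1L)
  expect_identical(amp$length_bp, 400L)
  expect_identical(amp$start, 1000L)
  expect_identical(amp$end, 1400L)
  expect_identical(nchar(amp$sequence), 400L)
  # amplicon slice re-matches both primers under the site rule
  expect_identical(substr(amp$sequence, 1, 20), fwd)
  expect_identical(substr(amp$sequence, 381, 400), rc(rev))

  # convergent but 5 kb apart at max 2000: no product
  g2 <- random_dna_str(6000, gc = 0.3)
  g2 <- plant_at(g2, fwd, 100)
  g2 <- plant_at(g2, rc(rev), 5100)
  expect_identical(nrow(predict_amplicons(list(forward = fwd, reverse = rev),
                                          g2)), 0L)

  # two forward sites + one reverse site in range: two amplicons
  g3 <- random_dna_str(6000, gc = 0.3)
  g3 <- plant_at(g3, fwd, 100)
  g3 <- plant_at(g3, fwd, 600)
  g3 <- plant_at(g3, rc(rev), 1200)
  amp3 <- predict_amplicons(list(forward = fwd, reverse = rev), g3)
  expect_identical(nrow(amp3), 2L)
  expect_setequal(amp3$length_bp, c(1120L, 620L))
})

test_that("reverse-complementing the genome preserves amplicon lengths", {
  set.seed(75)
  fwd <- "GTTCATCGCCCTTGAGGTAG"; rev <- "GTTCCTTGCGAATGCGGG"
  g <- random_dna_str(4000, gc = 0.3)
  g <- plant_at(g, fwd, 500)
  g <- plant_at(g, rc(rev), 900)
  a1 <- predict_amplicons(list(forward = fwd, reverse = rev), g)
  a2 <- predict_amplicons(list(forward = fwd, reverse = rev), rc(g))
  expect_identical(nrow(a1), nrow(a2))
  expect_identical(sort(a1$length_bp), sort(a2$length_bp))
  expect_false(identical(a1$fwd_strand, a2$fwd_strand))
})

test_that("specificity check flags only comparably long off-target products", {
  pt <- generate_primer_target(seed = 42)
  crit <- primer_criteria(tm_range_c = c(46, 56))
  tab <- design_primer_pairs(pt$gene, crit)
  pair <- list(forward = tab$forward[1], reverse = tab$reverse[1],
               amplicon_len = tab$amplicon_len[1])
  tgt <- genome_record("target", paste0(strrep("AT", 150), pt$gene,
                                        strrep("TA", 150)), role = "focal")
  verdicts <- vapply(c("none", "comparable_product", "long_product",
                       "single_site"), function(spec) {
    panel <- generate_offtarget_panel(pair, 2, spec, 6000, seed = 7)
    specificity_check(pair, tgt, panel$genomes)$verdict
  }, "")
  expect_identical(unname(verdicts),
                   c("specific", "nonspecific", "specific", "specific"))
  # a product at 5x the target length is not "comparably long" at f = 0.25
  L <- pair$amplicon_len
  set.seed(76)
  g5 <- random_dna_str(12000, gc = 0)
  g5 <- plant_at(g5, pair$forward, 1000)
  g5 <- plant_at(g5, rc(pair$reverse), 1000 + 5 * L - nchar(pair$reverse))
  rep5 <- specificity_check(pair, tgt, list(genome_record("x5", g5)),
                            max_product_bp = 5000)
  expect_identical(nrow(rep5$offtarget_amplicons$x5), 1L)
  expect_identical(rep5$offtarget_amplicons$x5$length_bp, 5L * L)
  expect_false(rep5$mispriming_flags[["x5"]])
  expect_error(specificity_check(pair, genome_record("bare", strrep("AT", 500)),
                                 list()), "no target product")
})
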