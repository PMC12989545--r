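test_that("GC content matches character counting, including assay primers", {
  expect_equal(gc_content("ATAT"), 0.0)
  expect_equal(gc_content("GGTCGAGCTTGGGATCGTAG"), 60.0)   # 12 of 20
  expect_equal(round(gc_content("GTTCCTTGCGAATGCGGG"), 1), 61.1)  # 11 of 18
  expect_error(gc_content("ACGU"), "non-ACGT")
  expect_error(gc_content(""), "non-empty")
  pr <- shipped_primers()
  for (s in pr$sequence)
    expect_equal(gc_content(s), gc_oracle(s))
})

test_that("self-complementarity equals the exhaustive window enumeration", {
  expect_identical(self_complementarity("AAAA"), 0L)
  expect_identical(self_complementarity("ACGT"), 4L)        # palindrome
  expect_identical(self_complementarity("GGTCGAGCTTGGGATCGTAG"), 4L)
  expect_error(self_complementarity("ACG"), "shorter than 4")
  pr <- shipped_primers()
  for (s in pr$sequence) {
    expect_identical(self_complementarity(s, "any"), selfcomp_oracle(s, "any"))
    expect_identical(self_complementarity(s, "end3"),
                     selfcomp_oracle(s, "end3"))
  }
  set.seed(52)
  for (rep in 1:60) {
    s <- random_dna_str(sample(18:24, 1))
    expect_identical(self_complementarity(s, "any"),
                     selfcomp_oracle(s, "any"), info = s)
    expect_identical(self_complementarity(s, "end3"),
                     selfcomp_oracle(s, "end3"), info = s)
  }
})

test_that("nearest-neighbor Tm matches the frozen reference value", {
  # reference value computed with an independent implementation of the
  # unified nearest-neighbor table (Bio.SeqUtils.MeltingTemp, DNA_NN3,
  # 16.6*log10[Na+] salt term, 125 nM effective duplex concentration)
  expect_equal(primer_tm("GGTCGAGCTTGGGATCGTAG"), 50.8746, tolerance = 1e-3)
})

test_that("Tm model symmetries: duplex reverse complement and salt term", {
  set.seed(61)
  for (rep in 1:10) {
    s <- random_dna_str(20)
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                collapse = "")
    expect_equal(primer_tm(s), primer_tm(rc), tolerance = 1e-9)
  }
  s <- "GGTCGAGCTTGGGATCGTAG"
  expect_equal(primer_tm(s, na_mM = 100) - primer_tm(s, na_mM = 50),
               16.6 * log10(2), tolerance = 1e-9)
  expect_error(primer_tm("ACGTACGT"), "10-40")
})

test_that("primer pair design recovers a planted clean site pair", {
  pt <- generate_primer_target(gene_len_bp = 600, product_len_bp = 400,
                               seed = 42)
  crit <- primer_criteria(tm_range_c = c(46, 56))
  tab <- design_primer_pairs(pt$gene, crit, max_pairs = 10000)
  expect_gt(nrow(tab), 0)
  tr <- pt$truth
  # the exact planted pair is present and criterion-compliant
  hit <- tab[tab$forward == tr$forward & tab$reverse == tr$reverse &
             tab$amplicon_start == tr$forward_start &
             tab$amplicon_end == tr$reverse_end, ]
  expect_identical(nrow(hit), 1L)
  expect_equal(hit$amplicon_len, tr$product_len_bp)
  # the top-ranked pair recovers the planted windows (the A/T background
  # admits only windows overlapping the planted sites)
  top <- tab[1, ]
  overlap <- function(a1, a2, b1, b2) max(0, min(a2, b2) - max(a1, b1))
  expect_gte(overlap(top$amplicon_start,
                     top$amplicon_start + nchar(top$forward),
                     tr$forward_start, tr$forward_end), 10)
  expect_gte(overlap(top$amplicon_end - nchar(top$reverse), top$amplicon_end,
                     tr$reverse_start, tr$reverse_end), 10)
})

test_that("every returned pair satisfies every criterion", {
  pt <- generate_primer_target(seed = 7)
  crit <- primer_criteria(tm_range_c = c(46, 56))
  tab <- design_primer_pairs(pt$gene, crit)
  expect_gt(nrow(tab), 0)
  for (i in seq_len(nrow(tab))) {
    for (s in c(tab$forward[i], tab$reverse[i])) {
      expect_gte(round(gc_content(s), 1), crit$gc_min_pct)
      expect_lte(round(gc_content(s), 1), crit$gc_max_pct)
      expect_lte(self_complementarity(s, "any"), crit$selfcomp_max)
      expect_gte(primer_tm(s), crit$tm_range_c[1])
      expect_lte(primer_tm(s), crit$tm_range_c[2])
    }
    expect_lte(abs(tab$fwd_tm_c[i] - tab$rev_tm_c[i]),
               crit$max_pair_tm_diff_c)
    expect_gte(tab$amplicon_len[i], crit$min_amplicon_bp)
    # reverse primer is the reverse complement of its target window
    win <- substr(pt$gene, tab$amplicon_end[i] - nchar(tab$reverse[i]) + 1,
                  tab$amplicon_end[i])
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", win), "")[[1]]),
                collapse = "")
    expect_identical(tab$reverse[i], rc)
  }
})

test_that("design is deterministic and degenerate targets yield reasons", {
  pt <- generate_primer_target(seed = 9)
  crit <- primer_criteria(tm_range_c = c(46, 56))
  expect_identical(design_primer_pairs(pt$gene, crit),
                   design_primer_pairs(pt$gene, crit))
  short <- design_primer_pairs(strrep("ACGT", 50), primer_criteria())
  expect_identical(nrow(short), 0L)
  expect_identical(attr(short, "reason"), "target_too_short")
  at <- design_primer_pairs(strrep("AT", 400), primer_criteria())
  expect_identical(nrow(at), 0L)   # GC criterion unsatisfiable
})
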