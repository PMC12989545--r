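test_that("generators are pure functions of parameters and seed", {
  pg1 <- generate_pangenome(2, 10, 0.9, 3, seed = 5)
  pg2 <- generate_pangenome(2, 10, 0.9, 3, seed = 5)
  expect_identical(pg1, pg2)
  pg3 <- generate_pangenome(2, 10, 0.9, 3, seed = 6)
  expect_false(identical(pg1$proteins, pg3$proteins))

  pt1 <- generate_primer_target(seed = 4)
  expect_identical(pt1, generate_primer_target(seed = 4))

  qd1 <- generate_qpcr_dataset(crops = "wheat", seed = 8)
  expect_identical(qd1, generate_qpcr_dataset(crops = "wheat", seed = 8))

  set.seed(1); ref <- random_dna_str(5000)
  expect_identical(plant_insertions(ref, 2, c(100, 200), seed = 3),
                   plant_insertions(ref, 2, c(100, 200), seed = 3))
  # the generator does not perturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_pangenome(1, 3, 0.9, 1, seed = 1))
  expect_identical(runif(1), before)
})

test_that("pangenome truth table matches its construction", {
  pg <- generate_pangenome(4, 50, 0.95, 5, seed = 42)
  expect_length(pg$truth$planted_singleton_ids, 5)
  expect_true(all(grepl("^focal\\|sing", pg$truth$planted_singleton_ids)))
  strains <- table(vapply(pg$proteins, `[[`, "", "strain"))
  expect_identical(unname(strains[["focal"]]), 55L)
  expect_true(all(strains[grep("bg", names(strains))] == 50L))
  # nucleotide genes exist for every planted singleton, in the GC band
  expect_setequal(names(pg$focal_genes_nt), pg$truth$planted_singleton_ids)
  gcs <- vapply(pg$focal_genes_nt, gc_content, 0)
  expect_true(all(gcs > 35 & gcs < 65))
})

test_that("core families sit near the requested cross-strain identity", {
  pg <- generate_pangenome(3, 12, 0.95, 2, c(300, 900), seed = 17)
  ids <- vapply(pg$proteins, `[[`, "", "id")
  for (fam in sprintf("core_%03d", c(1, 5, 9))) {
    copies <- pg$proteins[grepl(fam, ids)]
    for (i in 2:length(copies)) {
      al <- align_pair(copies[[1]]$sequence, copies[[i]]$sequence)
      expect_gte(al$identity, 0.93)
      expect_lte(al$identity, 0.98)
    }
  }
})

test_that("qPCR generator hits the requested positive rate at the extremes", {
  qd1 <- generate_qpcr_dataset(true_positive_rate = 1.0, ct_sd = 1.5,
                               tm_sd = 0.05, seed = 11)
  calls <- call_samples(qd1$observations,
                        c(xoxF = 90.3, copG = 84.6, ubik = 93.2))
  treated <- calls[calls$group == "treated", ]
  dr <- detection_rates(treated)
  expect_true(all(dr$rate_pct == 100.0))
  controls <- calls[calls$group == "control", ]
  expect_true(all(detection_rates(controls)$rate_pct == 0.0))

  qd0 <- generate_qpcr_dataset(true_positive_rate = 0.0, seed = 12)
  calls0 <- call_samples(qd0$observations,
                         c(xoxF = 90.3, copG = 84.6, ubik = 93.2))
  expect_true(all(detection_rates(calls0)$rate_pct == 0.0))
})

test_that("negative models produce the matching reason codes", {
  ctl <- c(xoxF = 90.3, copG = 84.6, ubik = 93.2)
  late <- generate_qpcr_dataset(crops = "pea", true_positive_rate = 0,
                                negative_model = "late_ct", seed = 14)
  calls <- call_samples(late$observations, ctl)
  expect_true(all(!is.na(calls$ct)))          # amplification does occur
  late_wells <- calls$ct > 30
  expect_true(mean(late_wells) > 0.95)        # N(35, 2) rarely dips under 30
  expect_true(all(grepl("ct_above_threshold", calls$reasons[late_wells])))
  expect_true(all(!calls$positive[late_wells]))
  off <- generate_qpcr_dataset(crops = "pea", true_positive_rate = 0,
                               negative_model = "offpeak_tm", seed = 15)
  calls2 <- call_samples(off$observations, ctl)
  expect_true(all(!calls2$positive))
  expect_true(all(grepl("tm_mismatch", calls2$reasons)))
})

test_that("plant_insertions records exact intervals and handles edge cases", {
  set.seed(2); ref <- random_dna_str(10000)
  pi <- plant_insertions(ref, 4, c(200, 800), seed = 6)
  tr <- pi$truth$insertions
  expect_identical(nrow(tr), 4L)
  expect_true(all(tr$end > tr$start))
  expect_true(all(tr$start[-1] >= tr$end[-4]))   # disjoint, sorted
  expect_identical(nchar(pi$query$sequence),
                   nchar(ref) + sum(tr$end - tr$start))
  # the inserted slices are exactly the planted sequences' coordinates:
  # removing them reconstitutes the reference
  q <- pi$query$sequence
  for (i in 4:1) q <- paste0(substr(q, 1, tr$start[i]),
                             substr(q, tr$end[i] + 1, nchar(q)))
  expect_identical(q, ref)

  p0 <- plant_insertions(ref, 0, seed = 6)
  expect_identical(p0$query$sequence, ref)
  expect_error(plant_insertions(random_dna_str(500), 5, c(100, 100),
                                seed = 1), "cannot place")
})

test_that("offtarget panel truth matches in-silico PCR behaviour", {
  pt <- generate_primer_target(seed = 42)
  crit <- primer_criteria(tm_range_c = c(46, 56))
  tab <- design_primer_pairs(pt$gene, crit)
  pair <- list(forward = tab$forward[1], reverse = tab$reverse[1],
               amplicon_len = tab$amplicon_len[1])
  panel <- generate_offtarget_panel(pair, 3, "comparable_product",
                                    genome_len_bp = 6000, seed = 9)
  for (i in 1:3) {
    tr <- panel$truth$per_genome[[i]]
    amp <- predict_amplicons(pair, panel$genomes[[i]])
    expect_identical(amp$length_bp, tr$expected_product_bp)
    expect_identical(amp$start, tr$fwd_site)
  }
  single <- generate_offtarget_panel(pair, 1, "single_site",
                                     genome_len_bp = 6000, seed = 10)
  sites <- find_binding_sites(pair$forward, single$genomes[[1]])
  expect_gte(nrow(sites), 1)
  expect_identical(nrow(predict_amplicons(pair, single$genomes[[1]])), 0L)
})
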