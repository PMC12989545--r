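make_prot <- function(id, seq, strain = "s1", product = "MFS transporter")
  protein_record(id, seq, strain = strain, product = product)

test_that("identical proteins cluster together; dissimilar ones do not", {
  set.seed(21)
  s <- random_aa_str(100)
  cl <- cluster_proteins(list(make_prot("a", s), make_prot("b", s, "s2")))
  expect_length(cl, 1)
  expect_setequal(cl[[1]]$members, c("a", "b"))
  expect_setequal(cl[[1]]$strains_present, c("s1", "s2"))

  # ~50% point-mutated copy stays below the 0.8 identity threshold
  ch <- strsplit(s, "")[[1]]
  pos <- sample(100, 50)
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  for (p in pos) ch[p] <- sample(setdiff(aa, ch[p]), 1)
  s2 <- paste(ch, collapse = "")
  cl2 <- cluster_proteins(list(make_prot("a", s), make_prot("b", s2, "s2")))
  expect_length(cl2, 2)
  expect_true(all(lengths(lapply(cl2, `[[`, "members")) == 1))
  expect_error(cluster_proteins(list()), "no proteins")
})

test_that("clustering partitions the input and is prefilter-invariant", {
  pg <- generate_pangenome(3, 15, 0.9, 4, c(150, 600), seed = 77)
  cl <- cluster_proteins(pg$proteins)
  members <- unlist(lapply(cl, `[[`, "members"))
  expect_identical(sort(members),
                   sort(vapply(pg$proteins, `[[`, "", "id")))
  expect_identical(anyDuplicated(members), 0L)

  cl_nofilter <- cluster_proteins(pg$proteins, use_prefilter = FALSE)
  canon <- function(cls) {
    key <- lapply(cls, function(c) sort(c$members))
    key[order(vapply(key, `[[`, "", 1))]
  }
  expect_identical(canon(cl), canon(cl_nofilter))
})

test_that("planted focal-only genes are recovered as singletons", {
  pg <- generate_pangenome(4, 50, 0.95, 5, seed = 42)
  cl <- cluster_proteins(pg$proteins)
  # every core family forms one multi-strain cluster
  core_cl <- Filter(function(c) any(grepl("core", c$members)), cl)
  expect_length(core_cl, 50)
  expect_true(all(vapply(core_cl, function(c)
    length(c$strains_present) == 5, TRUE)))
  singles <- find_singletons(cl, "focal")
  expect_identical(singles, pg$truth$planted_singleton_ids)
  expect_error(find_singletons(cl, "not_a_strain"), "absent")
})

test_that("singleton ranking follows homolog count, identity, then id", {
  set.seed(31)
  seqs <- replicate(4, random_aa_str(90))
  prots <- lapply(seq_along(seqs), function(i)
    make_prot(paste0("c", i), seqs[i], "focal"))
  # panel holds an exact copy of c3 only
  panel <- list(make_prot("bg1", seqs[3], "bg"),
                make_prot("bg2", random_aa_str(90), "bg"))
  cands <- refine_by_background(paste0("c", 1:4), prots, panel)
  df <- as.data.frame(cands)
  expect_identical(df$id[4], "c3")           # its homolog pushes it last
  expect_identical(df$homolog_count[4], 1L)
  expect_equal(df$best_identity[4], 1.0)
  expect_identical(df$id[1:3], c("c1", "c2", "c4"))  # lexicographic among ties
  expect_true(all(df$homolog_count[1:3] == 0L))
  expect_true(all(df$best_identity[1:3] == 0))

  # empty panel: all counts zero, ids lexicographic
  cands0 <- refine_by_background(paste0("c", c(3, 1, 4, 2)), prots, list())
  expect_identical(as.data.frame(cands0)$id, paste0("c", 1:4))
})

test_that("ranking is invariant under input permutation", {
  pg <- generate_pangenome(2, 8, 0.9, 4, c(300, 900), seed = 13)
  ids <- pg$truth$planted_singleton_ids
  panel <- Filter(function(p) p$strain != "focal", pg$proteins)
  r1 <- as.data.frame(refine_by_background(ids, pg$proteins, panel))
  set.seed(1)
  r2 <- as.data.frame(refine_by_background(sample(ids), pg$proteins,
                                           rev(panel)))
  expect_identical(r1$id, r2$id)
})

test_that("length/annotation filter drops short and hypothetical genes", {
  set.seed(41)
  cfg <- screen_config()
  # 23 candidates, 16 strictly shorter than 300 bp -> 7 retained
  lens <- c(rep(150L, 16), 300L, 301L, rep(600L, 5))
  prots <- lapply(seq_along(lens), function(i)
    protein_record(sprintf("g%02d", i), random_aa_str(lens[i] %/% 3 - 1),
                   strain = "focal", coding_length_bp = lens[i],
                   product = "ABC transporter permease"))
  cands <- refine_by_background(vapply(prots, `[[`, "", "id"), prots, list())
  filt <- filter_candidates(cands, cfg)
  expect_length(filt$retained, 7)
  expect_identical(sort(unique(filt$dropped$reason)), "too_short")
  # boundary: exactly 300 bp is retained ("shorter than 300" is strict)
  expect_true("g17" %in% as.data.frame(filt$retained)$id)

  hyp <- protein_record("h1", random_aa_str(150), strain = "focal",
                        coding_length_bp = 453)
  c2 <- refine_by_background("h1", list(hyp), list())
  f2 <- filter_candidates(c2, cfg)
  expect_length(f2$retained, 0)
  expect_identical(f2$dropped$reason, "hypothetical")
  # and retained when the filter is disabled
  cfg_keep <- screen_config(exclude_hypothetical = FALSE)
  f3 <- filter_candidates(refine_by_background("h1", list(hyp), list(),
                                               cfg_keep), cfg_keep)
  expect_length(f3$retained, 1)
})
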