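## Deterministic generators producing pipeline inputs with planted ground
## truth: a desk-scale pan-proteome with focal-only genes, off-target genomes
## with primer-site decoys, qPCR runs with Gaussian Ct/Tm noise, and a
## reference genome with planted insertions. Every generator is a pure
## function of (parameters, seed).

## point substitutions only (no indels), so identity audits are exact under
## (near-)ungapped comparison
mutate_protein <- function(seq, divergence) {
  L <- nchar(seq)
  nmut <- round(divergence * L)
  if (nmut == 0L) return(seq)
  ch <- seq_chars(seq)
  pos <- sample.int(L, nmut)
  for (p in pos) ch[p] <- sample(setdiff(AA20, ch[p]), 1L)
  paste(ch, collapse = "")
}

## GC-biased back-translation: picks codons stochastically, weighted toward
## the target GC fraction
.CODONS <- list(
  A = c("GCT","GCC","GCA","GCG"), R = c("CGT","CGC","CGA","CGG","AGA","AGG"),
  N = c("AAT","AAC"), D = c("GAT","GAC"), C = c("TGT","TGC"),
  Q = c("CAA","CAG"), E = c("GAA","GAG"), G = c("GGT","GGC","GGA","GGG"),
  H = c("CAT","CAC"), I = c("ATT","ATC","ATA"),
  L = c("TTA","TTG","CTT","CTC","CTA","CTG"), K = c("AAA","AAG"),
  M = "ATG", F = c("TTT","TTC"), P = c("CCT","CCC","CCA","CCG"),
  S = c("TCT","TCC","TCA","TCG","AGT","AGC"), T = c("ACT","ACC","ACA","ACG"),
  W = "TGG", Y = c("TAT","TAC"), V = c("GTT","GTC","GTA","GTG"))

back_translate <- function(protein, gc_target = 0.5) {
  ch <- seq_chars(protein)
  codons <- vapply(ch, function(a) {
    cs <- .CODONS[[a]]
    if (length(cs) == 1L) return(cs)
    gcs <- vapply(cs, function(c3)
      sum(seq_chars(c3) %in% c("G", "C")) / 3, 0)
    w <- exp(-8 * abs(gcs - gc_target))
    sample(cs, 1L, prob = w)
  }, "")
  paste(c(codons, "TGA"), collapse = "")
}

.PRODUCT_VOCAB <- c(
  "ribbon-helix-helix domain-containing protein",
  "accessory factor family protein", "ABC transporter permease",
  "methanol dehydrogenase subunit", "TonB-dependent receptor",
  "two-component sensor histidine kinase", "MFS transporter",
  "polysaccharide export protein", "flagellar hook-length control protein",
  "GNAT family N-acetyltransferase")

#' Generate a desk-scale pan-proteome with planted focal-only genes
#'
#' Core protein families are generated once and point-mutated per strain so
#' that cross-strain copies sit near `core_identity`; `n_planted_singletons`
#' random genes are present only in the focal strain. Gene lengths are drawn
#' uniformly from `gene_len_range_bp` (so, at the defaults, some planted genes
#' fall below the 300-bp filter). Nucleotide coding sequences for the focal
#' genes are emitted by GC-biased back-translation for downstream primer
#' design.
#'
#' @param n_background number of background strains (>= 1).
#' @param n_core number of core protein families shared by all strains.
#' @param core_identity target cross-strain identity of core families.
#' @param n_planted_singletons focal-only genes to plant.
#' @param gene_len_range_bp uniform gene-length range in bp.
#' @param gc_range GC range of the back-translated focal coding sequences.
#' @param seed RNG seed.
#' @param focal_strain label of the focal strain.
#' @return list: `proteins` (all strains), `focal_genes_nt` (named character),
#'   `focal_strain`, `truth` (planted singleton ids, parameters, seed).
#' @export
generate_pangenome <- function(n_background = 4L, n_core = 50L,
                               core_identity = 0.95,
                               n_planted_singletons = 5L,
                               gene_len_range_bp = c(150L, 1200L),
                               gc_range = c(0.40, 0.60), seed = 42L,
                               focal_strain = "focal") {
  stopifnot(n_background >= 1L, core_identity > 0.5, core_identity <= 1)
  if (gene_len_range_bp[1] < 90L)
    stop("gene_len_range_bp too short to encode a protein", call. = FALSE)
  with_seed(seed, {
    strains <- c(focal_strain, sprintf("bg%02d", seq_len(n_background)))
    div <- (1 - core_identity) / 2   # per-copy divergence from the family base
    draw_len_bp <- function() {
      bp <- sample(gene_len_range_bp[1]:gene_len_range_bp[2], 1L)
      3L * max(30L, bp %/% 3L)       # whole codons, incl. stop
    }
    proteins <- list()
    for (fam in seq_len(n_core)) {
      bp <- draw_len_bp()
      base <- random_protein(bp %/% 3L - 1L)
      prod <- sample(.PRODUCT_VOCAB, 1L)
      for (s in strains) {
        id <- sprintf("%s|core_%03d", s, fam)
        proteins[[id]] <- protein_record(
          id, mutate_protein(base, div), strain = s,
          coding_length_bp = bp, product = prod)
      }
    }
    planted <- character(n_planted_singletons)
    focal_nt <- character(0)
    for (g in seq_len(n_planted_singletons)) {
      bp <- draw_len_bp()
      id <- sprintf("%s|sing_%02d", focal_strain, g)
      prot <- random_protein(bp %/% 3L - 1L)
      proteins[[id]] <- protein_record(
        id, prot, strain = focal_strain, coding_length_bp = bp,
        product = sample(.PRODUCT_VOCAB, 1L))
      planted[g] <- id
      focal_nt[id] <- back_translate(prot, runif(1, gc_range[1], gc_range[2]))
    }
    list(proteins = proteins, focal_genes_nt = focal_nt,
         focal_strain = focal_strain,
         truth = list(planted_singleton_ids = sort(planted),
                      params = list(n_background = n_background,
                                    n_core = n_core,
                                    core_identity = core_identity,
                                    n_planted_singletons = n_planted_singletons,
                                    gene_len_range_bp = gene_len_range_bp,
                                    gc_range = gc_range),
                      seed = seed))
  })
}

#' Write a generated pan-proteome to disk
#'
#' One amino-acid FASTA per strain, a focal nucleotide gene FASTA, a TSV
#' annotation table and the truth table as JSON.
#'
#' @param pg output of [generate_pangenome()].
#' @param dir output directory (created).
#' @return invisible vector of written paths.
#' @export
write_pangenome <- function(pg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  strains <- unique(vapply(pg$proteins, `[[`, "", "strain"))
  paths <- character(0)
  for (s in strains) {
    ps <- Filter(function(p) p$strain == s, pg$proteins)
    f <- file.path(dir, paste0(s, ".faa"))
    seqs <- setNames(vapply(ps, `[[`, "", "sequence"),
                     paste(vapply(ps, `[[`, "", "id"),
                           vapply(ps, `[[`, "", "product")))
    Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), f, width = 60)
    paths <- c(paths, f)
  }
  fnt <- file.path(dir, "focal_genes.fna")
  write_fasta(pg$focal_genes_nt, fnt)
  ann <- data.frame(
    seqid = vapply(pg$proteins, `[[`, "", "strain"),
    feature_id = vapply(pg$proteins, `[[`, "", "id"),
    start = 1L,
    end = vapply(pg$proteins, `[[`, 0L, "coding_length_bp"),
    strand = "+",
    product = vapply(pg$proteins, `[[`, "", "product"),
    stringsAsFactors = FALSE)
  fann <- file.path(dir, "annotations.tsv")
  write_tsv_report(ann, fann)
  ftr <- file.path(dir, "truth.json")
  jsonlite::write_json(pg$truth, ftr, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, fnt, fann, ftr))
}

#' Generate off-target genomes with planted primer-site decoys
#'
#' @param pair list with `forward`/`reverse` primer sequences and
#'   `amplicon_len` (target product length).
#' @param n_genomes genomes to generate.
#' @param decoy_spec `"none"`, `"comparable_product"` (convergent sites giving
#'   a product within +/-10 percent of the target's), `"long_product"`
#'   (convergent sites, product about 1.6x the target, outside the
#'   comparable band at the default 25 percent), or `"single_site"` (a lone
#'   forward site, no product).
#' @param genome_len_bp genome length (> 2x the target amplicon).
#' @param gc background GC fraction.
#' @param seed RNG seed.
#' @return list: `genomes` (list of [genome_record()]s, role `"offtarget"`),
#'   `truth` (per genome: decoy type, planted coordinates, expected product
#'   length or NA).
#' @export
generate_offtarget_panel <- function(pair, n_genomes = 3L,
                                     decoy_spec = c("none",
                                                    "comparable_product",
                                                    "long_product",
                                                    "single_site"),
                                     genome_len_bp = 6000L, gc = 0.5,
                                     seed = 42L) {
  decoy_spec <- match.arg(decoy_spec)
  pair <- as.list(pair)
  L <- as.integer(pair$amplicon_len)
  if (genome_len_bp <= 2L * L)
    stop("genome_len_bp must exceed twice the target amplicon length",
         call. = FALSE)
  with_seed(seed, {
    genomes <- vector("list", n_genomes)
    truth <- vector("list", n_genomes)
    for (g in seq_len(n_genomes)) {
      id <- sprintf("offtarget_%02d", g)
      seq <- random_dna(genome_len_bp, gc)
      product <- NA_integer_; fwd_at <- NA_integer_; rev_at <- NA_integer_
      if (decoy_spec != "none") {
        product <- switch(decoy_spec,
          comparable_product = as.integer(round(L * runif(1, 0.92, 1.08))),
          long_product = as.integer(round(L * 1.6)),
          single_site = NA_integer_)
        fwd_at <- sample.int(genome_len_bp - max(product, L, na.rm = TRUE) -
                               nchar(pair$forward) - 1L, 1L)
        substr(seq, fwd_at + 1L, fwd_at + nchar(pair$forward)) <-
          pair$forward
        if (!is.na(product)) {
          rc <- revcomp(pair$reverse)
          rev_at <- fwd_at + product - nchar(pair$reverse)
          substr(seq, rev_at + 1L, rev_at + nchar(rc)) <- rc
        }
      }
      genomes[[g]] <- genome_record(id, seq, role = "offtarget")
      truth[[g]] <- list(genome_id = id, decoy = decoy_spec,
                         fwd_site = fwd_at, rev_site = rev_at,
                         expected_product_bp = product)
    }
    list(genomes = genomes,
         truth = list(per_genome = truth, seed = seed,
                      params = list(decoy_spec = decoy_spec,
                                    genome_len_bp = genome_len_bp, gc = gc)))
  })
}

#' Generate a target gene with a designed-in clean primer site pair
#'
#' Plants two GC-balanced, weakly self-complementary primer windows (forward
#' site and reverse-complemented reverse site) a fixed product length apart in
#' an A/T-only background, so the planted windows are the only fully
#' criterion-compliant primer sites on the gene. Planted primers are rejection
#' sampled to GC within `primer_gc`, self-complementarity at most 2, Tm within
#' `tm_band` and pair Tm difference at most `pair_tm_tol`.
#'
#' @param gene_len_bp target gene length.
#' @param product_len_bp planted amplicon length (forward 5' to reverse 5').
#' @param primer_len planted primer length.
#' @param primer_gc GC bounds (fractions) of the planted primers.
#' @param tm_band Tm band in degC for the planted primers.
#' @param pair_tm_tol maximum planted-pair Tm difference in degC.
#' @param seed RNG seed.
#' @return list: `gene` (ACGT string), `truth` (planted primers, their window
#'   coordinates 0-based half-open, product length, parameters, seed).
#' @export
generate_primer_target <- function(gene_len_bp = 600L, product_len_bp = 400L,
                                   primer_len = 20L,
                                   primer_gc = c(0.45, 0.55),
                                   tm_band = c(47, 55), pair_tm_tol = 0.1,
                                   seed = 42L) {
  stopifnot(product_len_bp > 2L * primer_len,
            gene_len_bp >= product_len_bp + 20L)
  with_seed(seed, {
    draw_primer <- function(tm_target = NULL) {
      for (try in 1:20000) {
        s <- random_dna(primer_len, 0.5)
        gcf <- gc_content(s) / 100
        if (gcf < primer_gc[1] || gcf > primer_gc[2]) next
        if (self_complementarity(s, "any") > 2L) next
        tm <- primer_tm(s)
        if (tm < tm_band[1] || tm > tm_band[2]) next
        if (!is.null(tm_target) && abs(tm - tm_target) > pair_tm_tol) next
        return(s)
      }
      stop("could not sample a planted primer under the constraints",
           call. = FALSE)
    }
    fwd <- draw_primer()
    rev <- draw_primer(tm_target = primer_tm(fwd))
    gene <- random_dna(gene_len_bp, gc = 0)   # A/T background
    slack <- gene_len_bp - product_len_bp
    fpos <- sample.int(slack - 10L, 1L) + 5L  # 0-based forward window start
    substr(gene, fpos + 1L, fpos + primer_len) <- fwd
    rpos <- fpos + product_len_bp - primer_len
    substr(gene, rpos + 1L, rpos + primer_len) <- revcomp(rev)
    list(gene = gene,
         truth = list(forward = fwd, reverse = rev,
                      forward_start = fpos, forward_end = fpos + primer_len,
                      reverse_start = rpos, reverse_end = rpos + primer_len,
                      product_len_bp = product_len_bp,
                      params = list(gene_len_bp = gene_len_bp,
                                    primer_len = primer_len,
                                    primer_gc = primer_gc, tm_band = tm_band,
                                    pair_tm_tol = pair_tm_tol),
                      seed = seed))
  })
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= lo | x > hi)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic qPCR colonization dataset
#'
#' Emulates a plant-colonization trial: per crop x timepoint, `n_per_group`
#' inoculated ("treated") and `n_per_group` non-inoculated ("control")
#' samples. Treated samples are colonized with probability
#' `true_positive_rate`; colonized wells draw Ct from a truncated
#' `N(ct_mu, ct_sd)` on (0, 40] and Tm from `N(control_tm, tm_sd)` per assay.
#' Non-colonized wells follow `negative_model`: `"absent"` (no
#' amplification), `"late_ct"` (Ct ~ N(35, 2), correct Tm), or `"offpeak_tm"`
#' (good Ct, Tm shifted by at least 1.5 degC). Controls never carry the
#' organism.
#'
#' @param crops,timepoints grouping labels.
#' @param n_per_group samples per (crop, timepoint, group).
#' @param true_positive_rate colonization probability of treated samples.
#' @param assays assay names; each sample is measured in every assay.
#' @param control_tm named vector of per-assay positive-control Tm (degC).
#' @param ct_mu,ct_sd,tm_sd positive-well noise model.
#' @param negative_model behaviour of non-colonized wells.
#' @param seed RNG seed.
#' @return list: `observations` (data frame sample/assay/crop/timepoint_days/
#'   group/ct/tm_c), `truth` (per-sample colonization status, parameters,
#'   seed).
#' @export
generate_qpcr_dataset <- function(crops = c("wheat", "corn", "oilseed_rape",
                                            "pea", "tomato"),
                                  timepoints = c(14L, 28L),
                                  n_per_group = 6L,
                                  true_positive_rate = 0.8,
                                  assays = c("xoxF", "copG", "ubik"),
                                  control_tm = c(xoxF = 90.3, copG = 84.6,
                                                 ubik = 93.2),
                                  ct_mu = 22, ct_sd = 3, tm_sd = 0.15,
                                  negative_model = c("absent", "late_ct",
                                                     "offpeak_tm"),
                                  seed = 42L) {
  negative_model <- match.arg(negative_model)
  stopifnot(true_positive_rate >= 0, true_positive_rate <= 1,
            all(assays %in% names(control_tm)))
  with_seed(seed, {
    rows <- list(); truth_rows <- list()
    sid <- 0L
    for (crop in crops) for (tp in timepoints)
      for (grp in c("treated", "control")) {
        for (r in seq_len(n_per_group)) {
          sid <- sid + 1L
          sample_id <- sprintf("S%04d", sid)
          colonized <- grp == "treated" &&
            runif(1) < true_positive_rate
          truth_rows[[sid]] <- data.frame(
            sample = sample_id, crop = crop, timepoint_days = tp,
            group = grp, colonized = colonized, stringsAsFactors = FALSE)
          for (a in assays) {
            if (colonized) {
              ct <- rtrunc_norm(1, ct_mu, ct_sd, 0, 40)
              tm <- rnorm(1, control_tm[[a]], tm_sd)
            } else {
              neg <- switch(negative_model,
                absent = list(ct = NA_real_, tm = NA_real_),
                late_ct = list(ct = rtrunc_norm(1, 35, 2, 0, 40),
                               tm = rnorm(1, control_tm[[a]], tm_sd)),
                offpeak_tm = list(ct = rtrunc_norm(1, ct_mu, ct_sd, 0, 40),
                                  tm = control_tm[[a]] +
                                    sample(c(-1, 1), 1) *
                                    (1.5 + abs(rnorm(1, 0, 0.3)))))
              ct <- neg$ct; tm <- neg$tm
            }
            rows[[length(rows) + 1L]] <- data.frame(
              sample = sample_id, assay = a, crop = crop,
              timepoint_days = tp, group = grp,
              ct = ct, tm_c = tm, stringsAsFactors = FALSE)
          }
        }
      }
    list(observations = do.call(rbind, rows),
         truth = list(samples = do.call(rbind, truth_rows),
                      params = list(true_positive_rate = true_positive_rate,
                                    negative_model = negative_model,
                                    control_tm = as.list(control_tm)),
                      seed = seed))
  })
}

#' Plant random insertions into a reference genome
#'
#' Inserts random-sequence stretches at uniform, non-overlapping positions
#' (minimum 200 bp apart and away from the ends so recovered regions stay
#' distinct) and records the exact query-coordinate intervals.
#'
#' @param reference [genome_record()] or ACGTN string.
#' @param n_insertions insertions to plant (0 returns the reference
#'   unchanged).
#' @param len_range_bp uniform insertion-length range.
#' @param gc GC fraction of inserted sequence.
#' @param seed RNG seed.
#' @param min_gap_bp minimum distance between insertion points.
#' @return list: `query` ([genome_record()]), `truth` (0-based half-open
#'   query intervals, parameters, seed).
#' @export
plant_insertions <- function(reference, n_insertions, len_range_bp = c(200L,
                             800L), gc = 0.5, seed = 42L, min_gap_bp = 200L) {
  rseq <- if (inherits(reference, "genome_record")) reference$sequence
          else toupper(reference)
  rid <- if (inherits(reference, "genome_record")) reference$id else "query"
  n <- nchar(rseq)
  if (n_insertions > 0 &&
      (n_insertions + 1L) * min_gap_bp >= n)
    stop("cannot place ", n_insertions, " insertions ", min_gap_bp,
         " bp apart in a ", n, " bp reference", call. = FALSE)
  with_seed(seed, {
    pos <- integer(0)
    tries <- 0L
    while (length(pos) < n_insertions) {
      cand <- sample.int(n - 2L * min_gap_bp, 1L) + min_gap_bp
      if (all(abs(cand - pos) >= min_gap_bp)) pos <- c(pos, cand)
      tries <- tries + 1L
      if (tries > 10000L)
        stop("failed to place non-overlapping insertions", call. = FALSE)
    }
    pos <- sort(pos)
    lens <- if (n_insertions > 0)
      sample(len_range_bp[1]:len_range_bp[2], n_insertions, replace = TRUE)
    else integer(0)
    pieces <- character(0); cursor <- 0L
    intervals <- data.frame(start = integer(0), end = integer(0))
    offset <- 0L
    for (k in seq_len(n_insertions)) {
      pieces <- c(pieces, substr(rseq, cursor + 1L, pos[k]),
                  random_dna(lens[k], gc))
      qstart <- pos[k] + offset
      intervals <- rbind(intervals,
                         data.frame(start = qstart, end = qstart + lens[k]))
      offset <- offset + lens[k]
      cursor <- pos[k]
    }
    pieces <- c(pieces, substr(rseq, cursor + 1L, n))
    qseq <- paste(pieces, collapse = "")
    list(query = genome_record(paste0(rid, "_resequenced"), qseq),
         truth = list(insertions = intervals,
                      params = list(n_insertions = n_insertions,
                                    len_range_bp = len_range_bp, gc = gc),
                      seed = seed))
  })
}
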