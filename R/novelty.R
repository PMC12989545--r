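## Novel-region scan between two assemblies of the same strain: shared-k-mer
## seeds extended ungapped with an X-drop rule; query intervals covered by a
## significant alignment (Karlin-Altschul e-value under +1/-2 scoring) are
## conserved, and maximal uncovered intervals of at least min_region_bp are
## reported as novel.

#' Novelty-scan configuration
#'
#' @param seed_k seed k-mer length (>= 11).
#' @param evalue_max alignments at or below this e-value mark conserved
#'   sequence.
#' @param min_region_bp shortest reported novel region.
#' @param xdrop stop extension once the score drops this far below its
#'   running maximum.
#' @param lambda,K Karlin-Altschul parameters for match +1 / mismatch -2.
#' @param max_seed_hits cap on reference positions explored per seed k-mer
#'   (guards against low-complexity repeats).
#' @return object of class `novelty_config`.
#' @export
novelty_config <- function(seed_k = 15L, evalue_max = 1e-10,
                           min_region_bp = 10L, xdrop = 20,
                           lambda = 1.28, K = 0.46, max_seed_hits = 50L) {
  stopifnot(seed_k >= 11L, min_region_bp >= 1L, xdrop > 0, evalue_max > 0)
  structure(list(seed_k = as.integer(seed_k), evalue_max = evalue_max,
                 min_region_bp = as.integer(min_region_bp), xdrop = xdrop,
                 lambda = lambda, K = K,
                 max_seed_hits = as.integer(max_seed_hits)),
            class = "novelty_config")
}

## ungapped X-drop extension of an exact seed; returns per-direction extension
## lengths (at the running-score maximum) and the total score
xdrop_extend <- function(qv, rv, qs, qe, rs, re, xdrop) {
  ext <- function(qidx, ridx) {
    n <- min(length(qidx), length(ridx))
    if (n == 0L) return(list(len = 0L, score = 0))
    sc <- cumsum(ifelse(qv[qidx[1:n]] == rv[ridx[1:n]], 1, -2))
    run <- cummax(sc)
    stop_at <- which(run - sc > xdrop)[1]
    if (!is.na(stop_at)) { sc <- sc[1:stop_at]; }
    b <- which.max(sc)
    if (sc[b] <= 0) list(len = 0L, score = 0) else list(len = b, score = sc[b])
  }
  nq <- length(qv); nr <- length(rv)
  right <- ext(if (qe < nq) (qe + 1L):nq else integer(0),
               if (re < nr) (re + 1L):nr else integer(0))
  left  <- ext(if (qs > 1L) (qs - 1L):1L else integer(0),
               if (rs > 1L) (rs - 1L):1L else integer(0))
  list(q_start = qs - left$len, q_end = qe + right$len,
       score = (qe - qs + 1L) + left$score + right$score)
}

#' Find regions of a query assembly absent from a reference assembly
#'
#' Both strands of the reference are indexed at `seed_k`; seeds are extended
#' ungapped (match +1, mismatch -2) under the X-drop rule, and extensions
#' significant at `E = K*m*n*exp(-lambda*S) <= evalue_max` mark their query
#' span as conserved. Maximal uncovered query intervals of at least
#' `min_region_bp` are returned, annotated with overlapping features (>= 1 bp
#' overlap). Coordinates are linear; circular replicons should be rotated to
#' a common start beforehand.
#'
#' @param query,reference [genome_record()]s or ACGTN strings.
#' @param config a [novelty_config()].
#' @return data frame of class `novel_regions`: `query_id`, `start`, `end`
#'   (0-based half-open), `length_bp`, `feature_ids` (";"-joined).
#' @export
find_novel_regions <- function(query, reference, config = novelty_config()) {
  qrec <- if (inherits(query, "genome_record")) query
          else genome_record("query", query)
  rseq <- if (inherits(reference, "genome_record")) reference$sequence
          else toupper(reference)
  k <- config$seed_k
  qseq <- qrec$sequence
  nq <- nchar(qseq); nr <- nchar(rseq)
  if (nq < k || nr < k)
    stop("both genomes must be at least seed_k long", call. = FALSE)
  qv <- seq_chars(qseq)
  strands <- list(`+` = seq_chars(rseq), `-` = seq_chars(revcomp(rseq)))

  qmers <- substring(qseq, 1:(nq - k + 1L), k:nq)
  idx <- lapply(strands, function(rv) {
    rmers <- paste0(substring(paste(rv, collapse = ""),
                              1:(nr - k + 1L), k:nr))
    split(seq_along(rmers), rmers)
  })

  covered <- IRanges::IRanges()
  cov_end <- 0L
  i <- 1L
  while (i <= nq - k + 1L) {
    if (i + k - 1L <= cov_end) { i <- i + 1L; next }
    if (grepl("N", qmers[i], fixed = TRUE)) { i <- i + 1L; next }
    hit_any <- FALSE
    for (strand in names(strands)) {
      rpos <- idx[[strand]][[qmers[i]]]
      if (is.null(rpos)) next
      if (length(rpos) > config$max_seed_hits)
        rpos <- rpos[seq_len(config$max_seed_hits)]
      rv <- strands[[strand]]
      for (rp in rpos) {
        al <- xdrop_extend(qv, rv, i, i + k - 1L, rp, rp + k - 1L,
                           config$xdrop)
        ev <- config$K * nq * nr * exp(-config$lambda * al$score)
        if (ev <= config$evalue_max) {
          covered <- c(covered, IRanges::IRanges(al$q_start, al$q_end))
          cov_end <- max(cov_end, al$q_end)
          hit_any <- TRUE
        }
      }
      if (hit_any) break
    }
    i <- if (hit_any) max(i + 1L, cov_end - k + 2L) else i + 1L
  }

  covered <- IRanges::reduce(covered)
  gaps <- IRanges::gaps(covered, start = 1L, end = nq)
  gaps <- gaps[IRanges::width(gaps) >= config$min_region_bp]
  if (length(gaps) == 0L) {
    out <- data.frame(query_id = character(0), start = integer(0),
                      end = integer(0), length_bp = integer(0),
                      feature_ids = character(0), stringsAsFactors = FALSE)
  } else {
    starts <- IRanges::start(gaps) - 1L   # to 0-based half-open
    ends <- IRanges::end(gaps)
    feats <- vapply(seq_along(gaps), function(g) {
      ov <- vapply(qrec$features, function(f)
        f$start < ends[g] && f$end > starts[g], TRUE)
      paste(vapply(qrec$features[ov], `[[`, "", "id"), collapse = ";")
    }, "")
    out <- data.frame(query_id = qrec$id, start = starts, end = ends,
                      length_bp = ends - starts, feature_ids = feats,
                      stringsAsFactors = FALSE)
  }
  class(out) <- c("novel_regions", "data.frame")
  out
}

#' Summarize novel regions
#'
#' Feature counts use >= 1 bp interval overlap; a feature overlapping several
#' regions is counted once. tRNA features are recognized by their product
#' containing "tRNA".
#'
#' @param regions output of [find_novel_regions()].
#' @param features list of [feature_record()]s on the query (defaults to the
#'   ids already annotated on `regions`).
#' @return list: `n_regions`, `total_bp`, `n_genes` (protein-coding),
#'   `n_trna`.
#' @export
summarize_novelty <- function(regions, features = list()) {
  ov_ids <- unique(unlist(strsplit(regions$feature_ids[
    nzchar(regions$feature_ids)], ";", fixed = TRUE)))
  if (length(features)) {
    byid <- setNames(features, vapply(features, `[[`, "", "id"))
    ov <- byid[intersect(ov_ids, names(byid))]
    trna <- vapply(ov, function(f) grepl("tRNA", f$product), TRUE)
    n_trna <- sum(trna); n_genes <- sum(!trna)
  } else {
    n_trna <- NA_integer_; n_genes <- length(ov_ids)
  }
  list(n_regions = nrow(regions), total_bp = sum(regions$length_bp),
       n_genes = n_genes, n_trna = n_trna)
}
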