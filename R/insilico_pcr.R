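## In-silico PCR: primer binding-site search under a mismatch-count model with
## an exact 3'-anchor, amplicon prediction from convergent site pairs, and the
## mispriming (comparably-long off-target product) specificity check.

#' Find primer binding sites on a genome
#'
#' Scans both strands for ungapped windows with at most `max_mismatch`
#' mismatches overall and zero mismatches in the 3'-terminal `anchor3_len`
#' bases (the polymerase extension anchor). `N` in the genome never matches a
#' primer base.
#'
#' @param primer ACGT string, 5'->3'.
#' @param genome [genome_record()] or ACGTN string.
#' @param max_mismatch maximum total mismatches per site.
#' @param anchor3_len length of the mismatch-free 3' anchor.
#' @return data frame: `genome_id`, `start`, `end` (0-based half-open on the
#'   plus strand), `strand`, `mismatches`.
#' @export
find_binding_sites <- function(primer, genome, max_mismatch = 2L,
                               anchor3_len = 3L) {
  assert_acgt(primer, "primer")
  gid <- if (inherits(genome, "genome_record")) genome$id else "genome"
  gseq <- if (inherits(genome, "genome_record")) genome$sequence
          else toupper(genome)
  empty <- data.frame(genome_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE)
  L <- nchar(primer)
  if (L > nchar(gseq)) return(empty)
  subj <- Biostrings::DNAString(gseq)

  scan_strand <- function(pat, strand) {
    hits <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj,
                                     max.mismatch = max_mismatch)
    if (length(hits) == 0L) return(empty)
    st <- Biostrings::start(hits); en <- Biostrings::end(hits)
    pc <- seq_chars(pat)
    keep <- logical(length(st)); mm <- integer(length(st))
    for (h in seq_along(st)) {
      wc <- seq_chars(substr(gseq, st[h], en[h]))
      bad <- wc != pc
      mm[h] <- sum(bad)
      # 3' end of the primer sits at the window's right end on +, left on -
      anchor <- if (strand == "+") (L - anchor3_len + 1L):L
                else 1L:anchor3_len
      keep[h] <- mm[h] <= max_mismatch && !any(bad[anchor])
    }
    if (!any(keep)) return(empty)
    data.frame(genome_id = gid, start = st[keep] - 1L, end = en[keep],
               strand = strand, mismatches = mm[keep],
               stringsAsFactors = FALSE)
  }
  out <- rbind(scan_strand(primer, "+"), scan_strand(revcomp(primer), "-"))
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Predict PCR products of a primer pair on a genome
#'
#' Pairs every plus-strand site of one primer with every minus-strand site of
#' the other (both orientations) whose 5' ends converge within
#' `max_product_bp`. Product length is measured 5' end to 5' end, inclusive of
#' both primers.
#'
#' @param pair list with `forward` and `reverse` ACGT strings (a row of the
#'   [design_primer_pairs()] table works).
#' @param genome [genome_record()] or ACGTN string.
#' @param max_product_bp longest product considered amplifiable.
#' @param max_mismatch,anchor3_len site-search stringency, see
#'   [find_binding_sites()].
#' @return data frame: `genome_id`, `start`, `end`, `length_bp`,
#'   `fwd_strand`, `fwd_mismatches`, `rev_mismatches`, `sequence`.
#' @export
predict_amplicons <- function(pair, genome, max_product_bp = 2000L,
                              max_mismatch = 2L, anchor3_len = 3L) {
  pair <- as.list(pair)
  gid <- if (inherits(genome, "genome_record")) genome$id else "genome"
  gseq <- if (inherits(genome, "genome_record")) genome$sequence
          else toupper(genome)
  fs <- find_binding_sites(pair$forward, genome, max_mismatch, anchor3_len)
  rs <- find_binding_sites(pair$reverse, genome, max_mismatch, anchor3_len)
  rows <- list()
  pair_up <- function(plus, minus, orient) {
    for (i in seq_len(nrow(plus))) {
      for (j in seq_len(nrow(minus))) {
        len <- minus$end[j] - plus$start[i]
        if (plus$start[i] < minus$end[j] && len <= max_product_bp &&
            len >= max(nchar(pair$forward), nchar(pair$reverse))) {
          rows[[length(rows) + 1L]] <<- data.frame(
            genome_id = gid, start = plus$start[i], end = minus$end[j],
            length_bp = len, fwd_strand = orient,
            fwd_mismatches = if (orient == "+") plus$mismatches[i]
                             else minus$mismatches[j],
            rev_mismatches = if (orient == "+") minus$mismatches[j]
                             else plus$mismatches[i],
            sequence = substr(gseq, plus$start[i] + 1L, minus$end[j]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  pair_up(fs[fs$strand == "+", ], rs[rs$strand == "-", ], "+")
  pair_up(rs[rs$strand == "+", ], fs[fs$strand == "-", ], "-")
  if (!length(rows))
    return(data.frame(genome_id = character(0), start = integer(0),
                      end = integer(0), length_bp = integer(0),
                      fwd_strand = character(0), fwd_mismatches = integer(0),
                      rev_mismatches = integer(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mispriming specificity check against off-target genomes
#'
#' An off-target genome is flagged when it yields any product whose length is
#' "comparably long": within `(1 - f) * L` to `(1 + f) * L` of the target
#' product length `L` (shortest target product when several are predicted).
#' The verdict is `"specific"` iff no off-target genome is flagged.
#'
#' @param pair list with `forward`/`reverse` primer sequences.
#' @param target_genome [genome_record()] expected to amplify.
#' @param offtarget_genomes list of [genome_record()]s.
#' @param comparable_fraction half-width `f` of the comparable-length band.
#' @param max_product_bp,max_mismatch,anchor3_len see [predict_amplicons()].
#' @return object of class `specificity_report`.
#' @export
specificity_check <- function(pair, target_genome, offtarget_genomes,
                              comparable_fraction = 0.25,
                              max_product_bp = 2000L, max_mismatch = 2L,
                              anchor3_len = 3L) {
  tgt <- predict_amplicons(pair, target_genome, max_product_bp,
                           max_mismatch, anchor3_len)
  if (nrow(tgt) == 0L)
    stop("no target product: primer pair does not amplify the target genome",
         call. = FALSE)
  L <- min(tgt$length_bp)
  band <- c((1 - comparable_fraction) * L, (1 + comparable_fraction) * L)
  ids <- vapply(offtarget_genomes, function(g)
    if (inherits(g, "genome_record")) g$id else "genome", "")
  offt <- setNames(vector("list", length(offtarget_genomes)), ids)
  flags <- setNames(logical(length(offtarget_genomes)), ids)
  for (k in seq_along(offtarget_genomes)) {
    amp <- predict_amplicons(pair, offtarget_genomes[[k]], max_product_bp,
                             max_mismatch, anchor3_len)
    offt[[k]] <- amp
    flags[k] <- nrow(amp) > 0L &&
      any(amp$length_bp >= band[1] & amp$length_bp <= band[2])
  }
  structure(list(target_amplicons = tgt, offtarget_amplicons = offt,
                 mispriming_flags = flags, target_length = L,
                 comparable_fraction = comparable_fraction,
                 verdict = if (any(flags)) "nonspecific" else "specific"),
            class = "specificity_report")
}

#' @export
print.specificity_report <- function(x, ...) {
  cat("<specificity_report> verdict:", x$verdict, "\n")
  cat("  target product:", x$target_length, "bp (",
      nrow(x$target_amplicons), "site pair(s) )\n")
  for (id in names(x$mispriming_flags))
    cat("  off-target", id, ":",
        if (x$mispriming_flags[[id]]) "MISPRIMING" else "clean", "\n")
  invisible(x)
}
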