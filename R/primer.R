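## Primer enumeration and scoring under the marker-assay quality criteria:
## amplicon length > 300 bp, primer GC between 40 and 60 percent,
## self-complementarity score between 0 and 4, plus Tm constraints that make
## the pair usable in a single real-time PCR program.

#' Primer-pair quality criteria
#'
#' Defaults encode the marker-assay rules: amplicon strictly longer than
#' 300 bp (`min_amplicon_bp = 301`), GC between 40 and 60 percent (inclusive),
#' self-complementarity at most 4, primer length 18-24 nt, Tm 57-63 degC and
#' at most 2 degC between the two primers of a pair.
#'
#' @param min_amplicon_bp minimum product length in bp (inclusive).
#' @param gc_min_pct,gc_max_pct GC bounds in percent (inclusive).
#' @param selfcomp_max maximum self-complementarity score.
#' @param primer_len_range integer vector `c(min, max)` primer length.
#' @param tm_range_c numeric `c(min, max)` primer Tm in degC.
#' @param max_pair_tm_diff_c maximum |Tm_f - Tm_r| in degC.
#' @return object of class `primer_criteria`.
#' @export
primer_criteria <- function(min_amplicon_bp = 301L, gc_min_pct = 40,
                            gc_max_pct = 60, selfcomp_max = 4L,
                            primer_len_range = c(18L, 24L),
                            tm_range_c = c(57, 63),
                            max_pair_tm_diff_c = 2.0) {
  stopifnot(gc_min_pct < gc_max_pct, min_amplicon_bp > 0,
            primer_len_range[1] <= primer_len_range[2], selfcomp_max >= 0)
  structure(list(min_amplicon_bp = as.integer(min_amplicon_bp),
                 gc_min_pct = gc_min_pct, gc_max_pct = gc_max_pct,
                 selfcomp_max = selfcomp_max,
                 primer_len_range = as.integer(primer_len_range),
                 tm_range_c = tm_range_c,
                 max_pair_tm_diff_c = max_pair_tm_diff_c),
            class = "primer_criteria")
}

#' GC content in percent
#'
#' @param seq ACGT string.
#' @return `100 * (#G + #C) / length`, unrounded.
#' @export
gc_content <- function(seq) {
  assert_acgt(seq, "primer sequence")
  ch <- seq_chars(seq)
  100 * sum(ch == "G" | ch == "C") / length(ch)
}

#' Self-complementarity score of an oligo
#'
#' The maximum, over all ungapped antiparallel alignments of the sequence
#' against itself (equivalently all offsets of the sequence against its
#' reverse complement), of the best-scoring contiguous window scored +1 per
#' Watson-Crick pair and -1 per non-pair. Mode `"end3"` restricts windows to
#' those covering the 3'-terminal base. Scores are floored at 0.
#'
#' @param seq ACGT string, length >= 4.
#' @param mode `"any"` (whole-oligo dimer propensity) or `"end3"`
#'   (extension-prone 3' dimer).
#' @return integer score.
#' @export
self_complementarity <- function(seq, mode = c("any", "end3")) {
  mode <- match.arg(mode)
  assert_acgt(seq, "primer sequence")
  L <- nchar(seq)
  if (L < 4L) stop("sequence shorter than 4 nt", call. = FALSE)
  s <- seq_chars(seq)
  r <- seq_chars(revcomp(seq))   # r[k] complements s[L + 1 - k]
  best <- 0L
  for (shift in (1L - L):(L - 1L)) {
    i <- max(1L, 1L - shift):min(L, L - shift)
    if (mode == "end3") {
      if (shift > 0L) next       # column i = L only exists for shift <= 0
      v <- ifelse(s[i] == r[i + shift], 1L, -1L)
      # best window forced to end at the 3'-terminal column (i = L, last)
      best <- max(best, max(rev(cumsum(rev(v)))))
    } else {
      v <- ifelse(s[i] == r[i + shift], 1L, -1L)
      run <- 0L
      for (x in v) {             # Kadane
        run <- max(0L, run + x)
        if (run > best) best <- run
      }
    }
  }
  best
}

## SantaLucia (1998) unified nearest-neighbor parameters.
## dH in kcal/mol, dS in cal/(mol K), per 5'->3' dinucleotide step.
.NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
            CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
            TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
            CC = -8.0)
.NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
            TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
            CC = -19.9)

#' Oligo melting temperature (nearest-neighbor model)
#'
#' SantaLucia (1998) unified nearest-neighbor dH/dS with terminal initiation
#' terms; `Tm = dH / (dS + R * ln(C/4)) - 273.15 + 16.6 * log10([Na+])`
#' with `R = 1.9872` cal/(mol K), `C` the oligo concentration and `[Na+]` in
#' mol/L.
#'
#' @param seq ACGT string, 10-40 nt.
#' @param na_mM monovalent cation concentration in mM.
#' @param oligo_nM oligo concentration in nM.
#' @return Tm in degC.
#' @export
primer_tm <- function(seq, na_mM = 50, oligo_nM = 500) {
  assert_acgt(seq, "primer sequence")
  L <- nchar(seq)
  if (L < 10L || L > 40L)
    stop("primer_tm is defined for 10-40 nt oligos, got ", L, call. = FALSE)
  steps <- substring(seq, 1:(L - 1L), 2:L)
  dh <- sum(.NN_DH[steps])
  ds <- sum(.NN_DS[steps])
  for (term in c(substr(seq, 1L, 1L), substr(seq, L, L))) {
    if (term %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else                       { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  R <- 1.9872
  C <- oligo_nM * 1e-9
  dh * 1000 / (ds + R * log(C / 4)) - 273.15 + 16.6 * log10(na_mM / 1000)
}

#' Score a single primer
#'
#' @param sequence ACGT string, 5'->3'.
#' @param na_mM,oligo_nM Tm conditions.
#' @return object of class `primer` with `gc_pct` (1 decimal), `tm_c`,
#'   `selfcomp_any`, `selfcomp_3p`.
#' @export
primer <- function(sequence, na_mM = 50, oligo_nM = 500) {
  structure(list(sequence = sequence,
                 gc_pct = round(gc_content(sequence), 1),
                 tm_c = primer_tm(sequence, na_mM, oligo_nM),
                 selfcomp_any = self_complementarity(sequence, "any"),
                 selfcomp_3p = self_complementarity(sequence, "end3")),
            class = "primer")
}

primer_passes <- function(p, criteria) {
  p$gc_pct >= criteria$gc_min_pct && p$gc_pct <= criteria$gc_max_pct &&
    p$selfcomp_any <= criteria$selfcomp_max &&
    p$tm_c >= criteria$tm_range_c[1] && p$tm_c <= criteria$tm_range_c[2]
}

empty_pair_table <- function(reason = NULL) {
  out <- data.frame(forward = character(0), reverse = character(0),
                    fwd_gc_pct = numeric(0), rev_gc_pct = numeric(0),
                    fwd_tm_c = numeric(0), rev_tm_c = numeric(0),
                    fwd_selfcomp = integer(0), rev_selfcomp = integer(0),
                    amplicon_start = integer(0), amplicon_end = integer(0),
                    amplicon_len = integer(0), rank = integer(0),
                    stringsAsFactors = FALSE)
  attr(out, "reason") <- reason
  out
}

#' Enumerate and rank primer pairs on a target sequence
#'
#' Every window in the primer length range is scored; windows passing the
#' per-primer criteria (GC, self-complementarity, Tm) are combined into
#' convergent pairs with the forward site strictly upstream of (and not
#' overlapping) the reverse site and amplicon length at least
#' `min_amplicon_bp`. Pairs additionally satisfy the pair Tm-difference bound
#' and are ranked by (|dTm|, combined self-complementarity, distance of mean
#' GC from 50), ties broken by coordinates. The reverse primer is reported
#' 5'->3' on the minus strand.
#'
#' @param target [genome_record()] or ACGT string.
#' @param criteria a [primer_criteria()].
#' @param na_mM,oligo_nM Tm conditions.
#' @param max_pairs cap on the returned table.
#' @return data frame of ranked pairs (possibly empty, with a `reason`
#'   attribute when the target is unusable); coordinates 0-based half-open on
#'   the target.
#' @export
design_primer_pairs <- function(target, criteria = primer_criteria(),
                                na_mM = 50, oligo_nM = 500,
                                max_pairs = 100L) {
  seq <- if (inherits(target, "genome_record")) target$sequence else target
  n <- nchar(seq)
  if (n < criteria$min_amplicon_bp)
    return(empty_pair_table("target_too_short"))

  lens <- criteria$primer_len_range[1]:criteria$primer_len_range[2]
  wins <- list()
  for (L in lens) {
    starts <- 0:(n - L)                      # 0-based
    ws <- substring(seq, starts + 1L, starts + L)
    ok <- !grepl("[^ACGT]", ws)
    for (idx in which(ok)) {
      p <- primer(ws[idx], na_mM, oligo_nM)
      if (primer_passes(p, criteria))
        wins[[length(wins) + 1L]] <-
          list(start = starts[idx], end = starts[idx] + L, p = p)
    }
  }
  if (!length(wins)) return(empty_pair_table("no_valid_primer_window"))

  starts <- vapply(wins, `[[`, 0L, "start")
  ends <- vapply(wins, `[[`, 0L, "end")
  tms <- vapply(wins, function(w) w$p$tm_c, 0)
  rows <- list()
  for (i in seq_along(wins)) {           # forward window
    for (j in seq_along(wins)) {         # reverse window
      alen <- ends[j] - starts[i]
      if (alen < criteria$min_amplicon_bp || ends[i] > starts[j]) next
      dtm <- abs(tms[i] - tms[j])
      if (dtm > criteria$max_pair_tm_diff_c) next
      f <- wins[[i]]$p
      rp <- primer(revcomp(wins[[j]]$p$sequence), na_mM, oligo_nM)
      if (!primer_passes(rp, criteria)) next
      rows[[length(rows) + 1L]] <- data.frame(
        forward = f$sequence, reverse = rp$sequence,
        fwd_gc_pct = f$gc_pct, rev_gc_pct = rp$gc_pct,
        fwd_tm_c = f$tm_c, rev_tm_c = rp$tm_c,
        fwd_selfcomp = f$selfcomp_any, rev_selfcomp = rp$selfcomp_any,
        amplicon_start = starts[i], amplicon_end = ends[j],
        amplicon_len = alen, rank = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_pair_table("no_valid_pair"))
  out <- do.call(rbind, rows)
  key_dtm <- abs(out$fwd_tm_c - out$rev_tm_c)
  key_sc <- out$fwd_selfcomp + out$rev_selfcomp
  key_gc <- abs((out$fwd_gc_pct + out$rev_gc_pct) / 2 - 50)
  ord <- order(key_dtm, key_sc, key_gc, out$amplicon_start, out$amplicon_end)
  out <- out[ord, , drop = FALSE]
  if (nrow(out) > max_pairs) out <- out[seq_len(max_pairs), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
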