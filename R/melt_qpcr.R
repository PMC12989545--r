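## Melt-curve prediction and the qPCR positivity rule: an amplicon-level Tm
## model, a derivative melt curve simulated on the instrument grid (72-95 degC
## in 0.5 degC steps, hence a 0.5 degC measurement uncertainty), the
## Ct <= 30 & |dTm| <= 0.5 decision, and detection-rate tabulation.

#' Melt-program configuration
#'
#' @param temp_start_c,temp_end_c melt ramp bounds in degC.
#' @param temp_step_c instrument grid increment in degC.
#' @param na_mM monovalent salt for the amplicon Tm model.
#' @return object of class `melt_config`.
#' @export
melt_config <- function(temp_start_c = 72.0, temp_end_c = 95.0,
                        temp_step_c = 0.5, na_mM = 50) {
  stopifnot(temp_start_c < temp_end_c, temp_step_c > 0)
  structure(list(temp_start_c = temp_start_c, temp_end_c = temp_end_c,
                 temp_step_c = temp_step_c, na_mM = na_mM),
            class = "melt_config")
}

#' Predicted melting temperature of a long amplicon
#'
#' Empirical long-duplex formula
#' `Tm = 81.5 + 16.6*log10([Na+]) + 0.41*GC% - 675/length` (valid from about
#' 50 bp). Predicted values are comparable between amplicons under the same
#' model but are not instrument-calibrated; classification therefore always
#' works on Tm differences to a positive control, never on absolute Tm.
#'
#' @param seq amplicon sequence (ACGTN; GC% is computed over ACGT).
#' @param na_mM monovalent cation concentration in mM.
#' @return Tm in degC.
#' @export
amplicon_melt_tm <- function(seq, na_mM = 50) {
  if (nchar(seq) < 50L)
    stop("amplicon Tm formula needs length >= 50 bp, got ", nchar(seq),
         call. = FALSE)
  ch <- seq_chars(toupper(seq))
  acgt <- ch[ch %in% c("A", "C", "G", "T")]
  gc_pct <- 100 * sum(acgt %in% c("G", "C")) / length(acgt)
  81.5 + 16.6 * log10(na_mM / 1000) + 0.41 * gc_pct - 675 / nchar(seq)
}

#' Simulate a derivative melt curve on the instrument grid
#'
#' Fluorescence is modeled as the sum over amplicons of
#' `abundance * sigmoid((Tm - T) / w)` with helicity width `w = 1` degC; the
#' reported signal is `-dF/dT` evaluated on the grid `temp_start .. temp_end`
#' at `temp_step` (the final grid point is clamped to `temp_end` when the step
#' does not divide the range). Peaks are the per-component argmax of the
#' connected grid regions above half the global maximum.
#'
#' @param amplicons data frame with `sequence` and optional `abundance`, a
#'   character vector of sequences, or a list of such.
#' @param config a [melt_config()].
#' @param noise_sd Gaussian noise SD added to `-dF/dT`.
#' @param seed RNG seed for the noise (ignored when `noise_sd = 0`).
#' @param width_c sigmoid helicity width in degC.
#' @return object of class `melt_curve`: `temperature`, `dfdt`,
#'   `peaks_c` (peak temperatures), `tm_predicted` (per amplicon).
#' @export
simulate_melt_curve <- function(amplicons, config = melt_config(),
                                noise_sd = 0, seed = NULL, width_c = 1.0) {
  if (is.character(amplicons))
    amplicons <- data.frame(sequence = amplicons, abundance = 1,
                            stringsAsFactors = FALSE)
  if (!is.data.frame(amplicons)) amplicons <- as.data.frame(amplicons)
  if (nrow(amplicons) == 0L) stop("need at least one amplicon", call. = FALSE)
  if (is.null(amplicons$abundance)) amplicons$abundance <- 1

  grid <- seq(config$temp_start_c, config$temp_end_c, by = config$temp_step_c)
  if (grid[length(grid)] < config$temp_end_c)
    grid <- c(grid, config$temp_end_c)

  tms <- vapply(amplicons$sequence, amplicon_melt_tm, 0,
                na_mM = config$na_mM, USE.NAMES = FALSE)
  dfdt <- numeric(length(grid))
  for (k in seq_len(nrow(amplicons))) {
    p <- plogis((tms[k] - grid) / width_c)
    dfdt <- dfdt + amplicons$abundance[k] / width_c * p * (1 - p)
  }
  if (noise_sd > 0) {
    dfdt <- if (is.null(seed)) dfdt + rnorm(length(grid), 0, noise_sd)
            else with_seed(seed, dfdt + rnorm(length(grid), 0, noise_sd))
  }
  half <- max(dfdt) / 2
  above <- dfdt > half
  peaks <- numeric(0)
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    i <- starts[k]:ends[k]
    peaks <- c(peaks, grid[i[which.max(dfdt[i])]])
  }
  structure(list(temperature = grid, dfdt = dfdt, peaks_c = peaks,
                 tm_predicted = tms), class = "melt_curve")
}

#' @export
plot.melt_curve <- function(x, ...) {
  graphics::plot(x$temperature, x$dfdt, type = "l",
                 xlab = "Temperature (°C)", ylab = "-dF/dT", ...)
  graphics::abline(v = x$peaks_c, lty = 2, col = "grey40")
  invisible(x)
}

#' One qPCR well observation
#'
#' @param sample,assay identifiers.
#' @param ct cycle threshold, `NA` for no amplification; must lie in (0, 40]
#'   when present (40-cycle program).
#' @param tm_c observed melt peak in degC, `NA` when absent.
#' @param crop,timepoint_days,group experimental grouping fields.
#' @return one-row data frame of class `qpcr_observation`.
#' @export
qpcr_observation <- function(sample, assay, ct = NA_real_, tm_c = NA_real_,
                             crop = NA_character_,
                             timepoint_days = NA_integer_,
                             group = NA_character_) {
  if (!is.na(ct) && (ct <= 0 || ct > 40))
    stop("ct must lie in (0, 40], got ", ct, call. = FALSE)
  structure(data.frame(sample = sample, assay = assay, ct = ct, tm_c = tm_c,
                       crop = crop, timepoint_days = timepoint_days,
                       group = group, stringsAsFactors = FALSE),
            class = c("qpcr_observation", "data.frame"))
}

#' Positivity call for qPCR observations
#'
#' A well is positive iff amplification occurred (Ct present), `Ct <= ct_max`
#' and the observed melt Tm lies within `tm_tol_c` of the positive-control
#' Tm; both thresholds are inclusive. Reason codes for negatives:
#' `no_amplification`, `ct_above_threshold`, `tm_mismatch`.
#'
#' @param obs data frame with columns `ct` and `tm_c` (`NA` = absent); extra
#'   columns are carried through.
#' @param control_tm_c positive-control melt Tm in degC. Either a single
#'   value or a named vector indexed by `obs$assay`.
#' @param ct_max Ct positivity threshold (inclusive).
#' @param tm_tol_c maximum |Tm - control Tm| (inclusive).
#' @return `obs` with added columns `positive` (logical) and `reasons`
#'   (";"-joined codes, empty when positive).
#' @export
call_samples <- function(obs, control_tm_c, ct_max = 30, tm_tol_c = 0.5) {
  if (!all(c("ct", "tm_c") %in% names(obs)))
    stop("observations need 'ct' and 'tm_c' columns", call. = FALSE)
  ctl <- if (length(control_tm_c) > 1L || !is.null(names(control_tm_c))) {
    if (is.null(obs$assay)) stop("per-assay control Tm needs an 'assay' column",
                                 call. = FALSE)
    unname(control_tm_c[obs$assay])
  } else rep(control_tm_c, nrow(obs))
  if (anyNA(ctl)) stop("missing control Tm for some assay", call. = FALSE)
  n <- nrow(obs)
  reasons <- character(n)
  no_amp <- is.na(obs$ct)
  ct_high <- !no_amp & obs$ct > ct_max
  tm_bad <- !no_amp & (is.na(obs$tm_c) | abs(obs$tm_c - ctl) > tm_tol_c)
  for (i in seq_len(n)) {
    r <- c(if (no_amp[i]) "no_amplification",
           if (ct_high[i]) "ct_above_threshold",
           if (tm_bad[i]) "tm_mismatch")
    reasons[i] <- paste(r, collapse = ";")
  }
  obs$positive <- !nzchar(reasons)
  obs$reasons <- reasons
  obs
}

#' Single-observation positivity call
#'
#' @inheritParams call_samples
#' @param obs a [qpcr_observation()] or any one-row data frame/list with `ct`
#'   and `tm_c`.
#' @return list of class `qpcr_call`: `observation`, `positive`, `reasons`
#'   (character vector, empty when positive).
#' @export
call_sample <- function(obs, control_tm_c, ct_max = 30, tm_tol_c = 0.5) {
  df <- as.data.frame(as.list(obs)[c("ct", "tm_c",
                                     intersect("assay", names(obs)))],
                      stringsAsFactors = FALSE)
  out <- call_samples(df, control_tm_c, ct_max, tm_tol_c)
  structure(list(observation = obs, positive = out$positive[1],
                 reasons = if (nzchar(out$reasons[1]))
                   strsplit(out$reasons[1], ";", fixed = TRUE)[[1]]
                 else character(0)),
            class = "qpcr_call")
}

#' @export
print.qpcr_call <- function(x, ...) {
  cat("<qpcr_call>", if (x$positive) "POSITIVE"
      else paste("negative:", paste(x$reasons, collapse = ", ")), "\n")
  invisible(x)
}

#' Detection rates per group
#'
#' Percent positive per group at 1 decimal. When `complete = TRUE` the table
#' covers the full crossing of observed (or supplied) group levels; cells
#' without observations carry `NA` rate and are rendered `"ND"` (no data) by
#' [format_detection_rates()].
#'
#' @param calls output of [call_samples()].
#' @param group_by grouping column names present in `calls`.
#' @param complete include empty cells of the level crossing.
#' @param levels optional named list of level vectors overriding the observed
#'   ones.
#' @return data frame: group columns, `n`, `positive`, `rate_pct`.
#' @export
detection_rates <- function(calls,
                            group_by = c("crop", "timepoint_days", "assay"),
                            complete = TRUE, levels = NULL) {
  miss <- setdiff(group_by, names(calls))
  if (length(miss)) stop("missing grouping column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(calls) == 0L) stop("no calls to tabulate", call. = FALSE)
  agg <- aggregate(calls$positive, by = calls[group_by],
                   FUN = function(v) c(n = length(v), pos = sum(v)))
  tab <- data.frame(agg[group_by],
                    n = agg$x[, "n"], positive = agg$x[, "pos"],
                    stringsAsFactors = FALSE)
  if (complete) {
    lv <- lapply(setNames(group_by, group_by), function(g)
      (levels[[g]] %||% sort(unique(calls[[g]]))))
    full <- expand.grid(lv, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    tab <- merge(full, tab, by = group_by, all.x = TRUE, sort = FALSE)
    tab$n[is.na(tab$n)] <- 0L
  }
  tab$rate_pct <- ifelse(tab$n > 0, round(100 * tab$positive / tab$n, 1),
                         NA_real_)
  tab <- tab[do.call(order, tab[group_by]), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Render a detection-rate table with "ND" for empty cells
#'
#' @param rates output of [detection_rates()].
#' @return data frame with `rate_pct` as character, `"ND"` where no data.
#' @export
format_detection_rates <- function(rates) {
  rates$rate_pct <- ifelse(is.na(rates$rate_pct), "ND",
                           formatC(rates$rate_pct, digits = 1, format = "f"))
  rates$positive <- ifelse(is.na(rates$positive), 0L, rates$positive)
  rates
}

#' Sample-level colonization verdict
#'
#' A sample counts as colonized when at least `min_assays_positive` of its
#' assays are positive (default 1: OR over assays).
#'
#' @param calls output of [call_samples()] with a `sample` column.
#' @param min_assays_positive assays required positive.
#' @return data frame `sample`, `n_assays`, `n_positive`, `colonized`.
#' @export
colonization_verdict <- function(calls, min_assays_positive = 1L) {
  agg <- aggregate(calls$positive, by = list(sample = calls$sample),
                   FUN = function(v) c(n = length(v), pos = sum(v)))
  out <- data.frame(sample = agg$sample, n_assays = agg$x[, "n"],
                    n_positive = agg$x[, "pos"], stringsAsFactors = FALSE)
  out$colonized <- out$n_positive >= min_assays_positive
  out[order(out$sample), , drop = FALSE]
}
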