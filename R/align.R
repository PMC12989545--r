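## Protein-protein local alignment used by the clustering and background
## refinement steps. Smith-Waterman with affine gaps is delegated to
## Biostrings; identity/coverage bookkeeping and Karlin-Altschul significance
## live here.

.align_env <- new.env(parent = emptyenv())

blosum62_x0 <- function() {
  if (is.null(.align_env$mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    m["X", ] <- 0L   # X is fully ambiguous: neutral against everything
    m[, "X"] <- 0L
    .align_env$mat <- m
  }
  .align_env$mat
}

#' Local pairwise protein alignment (BLOSUM62, affine gaps 11/1)
#'
#' Smith-Waterman local alignment under BLOSUM62 with gap open 11 and gap
#' extend 1 (a gap of length L costs 11 + L). `X` scores 0 against every
#' residue. Identity is matches over alignment columns (gap columns count);
#' coverage of a sequence is the aligned span divided by its full length.
#'
#' @param a,b amino-acid strings or [protein_record()]s.
#' @return list with `identity`, `coverage_a`, `coverage_b`, `score`.
#' @export
align_pair <- function(a, b) {
  if (inherits(a, "protein_record")) a <- a$sequence
  if (inherits(b, "protein_record")) b <- b$sequence
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = blosum62_x0(), gapOpening = 11, gapExtension = 1)
  w <- Biostrings::nchar(pa)
  if (w == 0L)
    return(list(identity = 0, coverage_a = 0, coverage_b = 0, score = 0))
  pr <- methods::slot(Biostrings::pattern(pa), "range")
  sr <- methods::slot(Biostrings::subject(pa), "range")
  list(identity   = Biostrings::nmatch(pa) / w,
       coverage_a = IRanges::width(pr) / nchar(a),
       coverage_b = IRanges::width(sr) / nchar(b),
       score      = Biostrings::score(pa))
}

#' Karlin-Altschul e-value of an ungapped-statistics alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with the published ungapped BLOSUM62
#' constants as defaults.
#'
#' @param score alignment score `S`.
#' @param m query length (residues).
#' @param n search-space size (total panel residues).
#' @param lambda,K Karlin-Altschul parameters.
#' @return e-value (vectorized over `score`).
#' @export
ka_evalue <- function(score, m, n, lambda = 0.3176, K = 0.134) {
  if (m <= 0 || n <= 0) stop("m and n must be positive", call. = FALSE)
  K * m * n * exp(-lambda * score)
}
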