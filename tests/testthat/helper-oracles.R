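# Independent brute-force oracles used to cross-check the fast
# implementations. These deliberately share no code with the package paths
# they verify.

# exhaustive (offset, window) enumeration of antiparallel self-alignment;
# +1 per Watson-Crick pair, -1 per non-pair, best contiguous window
selfcomp_oracle <- function(seq, mode = "any") {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  s <- strsplit(seq, "")[[1]]
  L <- length(s)
  best <- 0L
  for (shift in (1 - L):(L - 1)) {
    # column at index i pairs s[i] with s[j], j = L + 1 - i - shift
    is <- seq_len(L)
    js <- L + 1L - is - shift
    ok <- js >= 1L & js <= L
    is <- is[ok]; js <- js[ok]
    if (!length(is)) next
    v <- ifelse(comp[s[is]] == s[js], 1L, -1L)
    n <- length(v)
    cs <- c(0L, cumsum(v))
    # every window sum a..b as a matrix; rows = b, cols = a, keep b >= a
    w <- outer(cs[-1L], cs[-(n + 1L)], `-`)
    keep <- row(w) >= col(w)
    if (mode == "end3") {
      cpos <- match(L, is)
      if (is.na(cpos)) next
      keep <- keep & row(w) >= cpos & col(w) <= cpos
    }
    m <- suppressWarnings(max(w[keep]))
    if (is.finite(m) && m > best) best <- m
  }
  best
}

gc_oracle <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  100 * (sum(s == "G") + sum(s == "C")) / length(s)
}

# position-by-position binding-site scan on both strands
binding_oracle <- function(primer, genome, max_mismatch = 2, anchor3 = 3) {
  revcomp_chr <- function(x)
    paste(rev(chartr("ACGTN", "TGCAN", strsplit(x, "")[[1]])), collapse = "")
  g <- strsplit(toupper(genome), "")[[1]]
  scan <- function(pat, strand) {
    p <- strsplit(pat, "")[[1]]
    L <- length(p)
    out <- NULL
    for (pos in seq_len(length(g) - L + 1L)) {
      w <- g[pos:(pos + L - 1L)]
      bad <- w != p
      anchor <- if (strand == "+") (L - anchor3 + 1L):L else 1L:anchor3
      if (sum(bad) <= max_mismatch && !any(bad[anchor]))
        out <- rbind(out, data.frame(start = pos - 1L, end = pos + L - 1L,
                                     strand = strand, mismatches = sum(bad)))
    }
    out
  }
  res <- rbind(scan(primer, "+"), scan(revcomp_chr(primer), "-"))
  if (is.null(res)) data.frame(start = integer(0), end = integer(0),
                               strand = character(0),
                               mismatches = integer(0))
  else res[order(res$start, res$strand), , drop = FALSE]
}

# Gotoh local alignment DP (affine gap of length g costs 11 + g), returning
# the optimal score; quadratic, no heuristics
sw_oracle_score <- function(a, b, mat = NULL) {
  if (is.null(mat)) {
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    mat <- e$BLOSUM62; mat["X", ] <- 0L; mat[, "X"] <- 0L
  }
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  open <- 12; ext <- 1   # first gap base 12, each further base 1
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[av[i - 1], bv[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

random_dna_str <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

random_aa_str <- function(n) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# the three marker-assay primer pairs shipped with the package
shipped_primers <- function() {
  path <- system.file("extdata", "gobio_primers.tsv", package = "strainmark")
  read.delim(path, stringsAsFactors = FALSE)
}
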