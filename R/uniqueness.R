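## Singleton screening: greedy identity/coverage clustering of a pan-proteome,
## extraction of focal-strain singletons, refinement against a background
## panel under Karlin-Altschul significance, and the length/annotation filter.

#' Screening configuration
#'
#' @param cluster_identity minimum pairwise identity to join a cluster.
#' @param cluster_coverage minimum aligned coverage, enforced on BOTH
#'   sequences.
#' @param background_evalue_max e-value at or below which a background panel
#'   protein counts as a homolog.
#' @param min_gene_length_bp genes strictly shorter than this are dropped.
#' @param exclude_hypothetical drop candidates whose product is hypothetical.
#' @param max_candidates cap on the ranked candidate list.
#' @return object of class `screen_config`.
#' @export
screen_config <- function(cluster_identity = 0.80, cluster_coverage = 0.80,
                          background_evalue_max = 1e-3,
                          min_gene_length_bp = 300L,
                          exclude_hypothetical = TRUE,
                          max_candidates = 25L) {
  stopifnot(cluster_identity > 0, cluster_identity <= 1,
            cluster_coverage > 0, cluster_coverage <= 1,
            background_evalue_max > 0, min_gene_length_bp > 0,
            max_candidates >= 1)
  structure(list(cluster_identity = cluster_identity,
                 cluster_coverage = cluster_coverage,
                 background_evalue_max = background_evalue_max,
                 min_gene_length_bp = as.integer(min_gene_length_bp),
                 exclude_hypothetical = isTRUE(exclude_hypothetical),
                 max_candidates = as.integer(max_candidates)),
            class = "screen_config")
}

protein_kmers <- function(seq, k = 5L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

#' Greedy incremental protein clustering
#'
#' CD-HIT-style: proteins are sorted by length descending (ties broken by id)
#' and each joins the first existing representative it matches at
#' `cluster_identity` identity and `cluster_coverage` coverage on both
#' sequences, otherwise it founds a new cluster. A shared-5-mer prefilter can
#' skip representative comparisons; it is an accelerator only and on package
#' fixtures yields the identical partition.
#'
#' @param proteins list of [protein_record()]s with unique ids.
#' @param config a [screen_config()].
#' @param use_prefilter skip representatives sharing no 5-mer with the query.
#' @return list of clusters, each `list(representative, members,
#'   strains_present)`; the clusters partition the input.
#' @export
cluster_proteins <- function(proteins, config = screen_config(),
                             use_prefilter = TRUE) {
  if (length(proteins) == 0L) stop("no proteins to cluster", call. = FALSE)
  ids <- vapply(proteins, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate protein id: '", ids[duplicated(ids)][1], "'",
         call. = FALSE)
  names(proteins) <- ids
  lens <- vapply(proteins, function(p) nchar(p$sequence), 0L)
  ord <- order(-lens, ids)
  proteins <- proteins[ord]

  reps <- list()        # representative protein records, founding order
  rep_kmers <- list()
  assign_to <- integer(length(proteins))
  for (i in seq_along(proteins)) {
    p <- proteins[[i]]
    pk <- protein_kmers(p$sequence)
    cand <- seq_along(reps)
    if (use_prefilter && length(cand) && length(pk))
      cand <- cand[vapply(rep_kmers[cand], function(rk)
        length(rk) == 0L || any(pk %in% rk), TRUE)]
    hit <- 0L
    if (length(cand)) {
      # one vectorized alignment call against all candidate representatives
      rep_seqs <- vapply(reps[cand], `[[`, "", "sequence")
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(rep_seqs), Biostrings::AAString(p$sequence),
        type = "local", substitutionMatrix = blosum62_x0(),
        gapOpening = 11, gapExtension = 1)
      w <- Biostrings::nchar(pa)
      ident <- ifelse(w > 0, Biostrings::nmatch(pa) / w, 0)
      cov_rep <- IRanges::width(methods::slot(Biostrings::pattern(pa),
                                              "range")) / nchar(rep_seqs)
      cov_p <- IRanges::width(methods::slot(Biostrings::subject(pa),
                                            "range")) / nchar(p$sequence)
      ok <- ident >= config$cluster_identity &
        cov_p >= config$cluster_coverage & cov_rep >= config$cluster_coverage
      if (any(ok)) hit <- cand[which(ok)[1]]   # first in founding order
    }
    if (hit == 0L) {
      reps[[length(reps) + 1L]] <- p
      rep_kmers[[length(reps)]] <- pk
      hit <- length(reps)
    }
    assign_to[i] <- hit
  }

  lapply(seq_along(reps), function(j) {
    memb <- proteins[assign_to == j]
    list(representative = reps[[j]]$id,
         members = vapply(memb, `[[`, "", "id"),
         strains_present = sort(unique(vapply(memb, `[[`, "", "strain"))))
  })
}

#' Focal-strain singletons from a clustering
#'
#' A singleton is a cluster containing exactly one protein, and that protein
#' belongs to the focal strain.
#'
#' @param clusters output of [cluster_proteins()].
#' @param focal_strain strain label.
#' @return character vector of protein ids (sorted).
#' @export
find_singletons <- function(clusters, focal_strain) {
  strains <- unique(unlist(lapply(clusters, `[[`, "strains_present")))
  if (!focal_strain %in% strains)
    stop("focal strain '", focal_strain, "' absent from clustering",
         call. = FALSE)
  ids <- unlist(lapply(clusters, function(cl) {
    if (length(cl$members) == 1L &&
        identical(cl$strains_present, focal_strain)) cl$members
    else character(0)
  }))
  sort(unname(ids))
}

#' Construct a marker candidate
#' @keywords internal
marker_candidate <- function(protein, homolog_count, best_identity, config) {
  stopifnot(homolog_count >= 0)
  if (homolog_count == 0L) best_identity <- 0
  structure(list(protein = protein,
                 homolog_count = as.integer(homolog_count),
                 best_identity = best_identity,
                 passes_length =
                   protein$coding_length_bp >= config$min_gene_length_bp,
                 passes_annotation =
                   !(config$exclude_hypothetical && protein$is_hypothetical),
                 rank_score = NA_real_),
            class = "marker_candidate")
}

#' Refine singletons against a background panel
#'
#' A background protein is a homolog of a candidate when their local alignment
#' score reaches significance `E <= background_evalue_max`, with
#' `E = K*m*n*exp(-lambda*S)` under ungapped BLOSUM62 constants
#' (`lambda = 0.3176`, `K = 0.134`), `m` the candidate length and `n` the
#' total residue count of the panel. Candidates are ranked ascending by
#' (homolog count, best identity, id).
#'
#' @param singleton_ids candidate protein ids.
#' @param proteins list of [protein_record()]s containing the candidates.
#' @param background_panel list of [protein_record()]s (may be empty).
#' @param config a [screen_config()].
#' @return list of `marker_candidate`s, ranked; `rank_score` is the 1-based
#'   rank.
#' @export
refine_by_background <- function(singleton_ids, proteins, background_panel,
                                 config = screen_config()) {
  names(proteins) <- vapply(proteins, `[[`, "", "id")
  miss <- setdiff(singleton_ids, names(proteins))
  if (length(miss))
    stop("unknown candidate id: '", miss[1], "'", call. = FALSE)
  n_panel <- sum(vapply(background_panel,
                        function(p) nchar(p$sequence), 0L))
  panel_seqs <- vapply(background_panel, `[[`, "", "sequence")
  cands <- lapply(singleton_ids, function(id) {
    p <- proteins[[id]]
    hc <- 0L; best <- 0
    if (n_panel > 0L) {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(panel_seqs), Biostrings::AAString(p$sequence),
        type = "local", substitutionMatrix = blosum62_x0(),
        gapOpening = 11, gapExtension = 1)
      ev <- ka_evalue(Biostrings::score(pa), m = nchar(p$sequence),
                      n = n_panel)
      is_hom <- ev <= config$background_evalue_max
      hc <- sum(is_hom)
      if (hc > 0L) {
        w <- Biostrings::nchar(pa)
        ident <- ifelse(w > 0, Biostrings::nmatch(pa) / w, 0)
        best <- max(ident[is_hom])
      }
    }
    marker_candidate(p, hc, best, config)
  })
  ord <- order(vapply(cands, `[[`, 0L, "homolog_count"),
               vapply(cands, `[[`, 0, "best_identity"),
               vapply(cands, function(x) x$protein$id, ""))
  cands <- cands[ord]
  for (i in seq_along(cands)) cands[[i]]$rank_score <- i
  class(cands) <- "marker_candidates"
  cands
}

#' Length and annotation filter for marker candidates
#'
#' Drops candidates whose gene is strictly shorter than
#' `min_gene_length_bp` (reason `"too_short"`) and, when configured,
#' candidates annotated as hypothetical (reason `"hypothetical"`). The
#' retained list is truncated to `max_candidates`.
#'
#' @param candidates output of [refine_by_background()].
#' @param config a [screen_config()].
#' @return list with `retained` (marker candidates) and `dropped`
#'   (data frame id/reason).
#' @export
filter_candidates <- function(candidates, config = screen_config()) {
  keep <- logical(length(candidates))
  drop_id <- character(0); drop_reason <- character(0)
  for (i in seq_along(candidates)) {
    cc <- candidates[[i]]
    reasons <- c(if (!cc$passes_length) "too_short",
                 if (!cc$passes_annotation) "hypothetical")
    if (length(reasons)) {
      drop_id <- c(drop_id, cc$protein$id)
      drop_reason <- c(drop_reason, paste(reasons, collapse = ";"))
    } else keep[i] <- TRUE
  }
  retained <- candidates[keep]
  if (length(retained) > config$max_candidates)
    retained <- retained[seq_len(config$max_candidates)]
  class(retained) <- "marker_candidates"
  list(retained = retained,
       dropped = data.frame(id = drop_id, reason = drop_reason,
                            stringsAsFactors = FALSE))
}

#' @export
as.data.frame.marker_candidates <- function(x, ...) {
  if (length(x) == 0L)
    return(data.frame(id = character(0), strain = character(0),
                      length_bp = integer(0), product = character(0),
                      homolog_count = integer(0), best_identity = numeric(0),
                      passes_length = logical(0),
                      passes_annotation = logical(0), rank = integer(0)))
  data.frame(
    id = vapply(x, function(c) c$protein$id, ""),
    strain = vapply(x, function(c) c$protein$strain, ""),
    length_bp = vapply(x, function(c) c$protein$coding_length_bp, 0L),
    product = vapply(x, function(c) c$protein$product, ""),
    homolog_count = vapply(x, `[[`, 0L, "homolog_count"),
    best_identity = vapply(x, `[[`, 0, "best_identity"),
    passes_length = vapply(x, `[[`, TRUE, "passes_length"),
    passes_annotation = vapply(x, `[[`, TRUE, "passes_annotation"),
    rank = vapply(x, function(c) as.integer(c$rank_score), 0L),
    stringsAsFactors = FALSE)
}

#' @export
print.marker_candidates <- function(x, ...) {
  cat("<marker_candidates>", length(x), "candidates\n")
  if (length(x)) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}
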