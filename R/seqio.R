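## Domain record types and readers/writers for the formats the pipeline
## touches. Internal coordinates are 0-based half-open everywhere; conversion
## to/from 1-based inclusive happens only at the GFF3 boundary.

#' Terms that mark a protein product description as uninformative
#'
#' Case-insensitive substrings; a product matching any of them flags the
#' protein as "hypothetical" for the annotation filter.
#' @export
HYPOTHETICAL_TERMS <- c("hypothetical protein", "uncharacterized protein",
                        "domain of unknown function", "DUF")

#' Is a product description "hypothetical"?
#'
#' @param product character vector of product descriptions.
#' @param terms term list matched case-insensitively as substrings.
#' @return logical vector.
#' @export
is_hypothetical_product <- function(product, terms = HYPOTHETICAL_TERMS) {
  if (length(product) == 0L) return(logical(0))
  product[is.na(product)] <- "hypothetical protein"
  hit <- rep(FALSE, length(product))
  for (t in terms) hit <- hit | grepl(t, product, ignore.case = TRUE)
  hit
}

#' Construct a genome record
#'
#' A named nucleotide sequence with optional feature annotations; the
#' substrate for in-silico PCR and the novelty scan. Non-ACGT IUPAC codes are
#' collapsed to `N` (with a warning) so that they can never match a primer
#' base.
#'
#' @param id sequence label.
#' @param sequence nucleotide string (any case; IUPAC codes allowed on input).
#' @param features list of [feature_record()]s falling within the sequence.
#' @param source_strain strain label, defaults to `id`.
#' @param role one of `"focal"`, `"background"`, `"offtarget"`.
#' @return object of class `genome_record`.
#' @export
genome_record <- function(id, sequence, features = list(),
                          source_strain = id, role = "background") {
  stopifnot(is.character(id), nzchar(id))
  if (!nzchar(sequence)) stop("sequence must be non-empty for '", id, "'",
                              call. = FALSE)
  sequence <- toupper(sequence)
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0L) {
    if (grepl("[^ACGTURYSWKMBDHVN]", sequence))
      stop("illegal nucleotide at position ",
           regexpr("[^ACGTURYSWKMBDHVN]", sequence), " in '", id, "'",
           call. = FALSE)
    warning("non-ACGT IUPAC codes in '", id, "' collapsed to N",
            call. = FALSE)
    sequence <- gsub("[URYSWKMBDHV]", "N", sequence)
  }
  role <- match.arg(role, c("focal", "background", "offtarget"))
  n <- nchar(sequence)
  for (f in features)
    if (f$start < 0L || f$end > n)
      stop("feature '", f$id, "' outside [0, ", n, ")", call. = FALSE)
  structure(list(id = id, sequence = sequence, features = features,
                 source_strain = source_strain, role = role),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record>", x$id, "|", nchar(x$sequence), "bp |",
      length(x$features), "features | strain", x$source_strain,
      "| role", x$role, "\n")
  invisible(x)
}

#' Construct a feature record (0-based half-open coordinates)
#'
#' @param id locus tag.
#' @param start,end 0-based half-open interval, `0 <= start < end`.
#' @param strand `"+"` or `"-"`.
#' @param product free-text description; `NA`/missing defaults to
#'   `"hypothetical protein"`.
#' @return object of class `feature_record` with derived `length_bp`.
#' @export
feature_record <- function(id, start, end, strand, product = NA_character_) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop("feature '", id, "': need 0 <= start < end, got [", start, ", ",
         end, ")", call. = FALSE)
  if (!strand %in% c("+", "-"))
    stop("feature '", id, "': strand must be '+' or '-', got '", strand, "'",
         call. = FALSE)
  if (is.na(product) || !nzchar(product)) product <- "hypothetical protein"
  structure(list(id = id, start = start, end = end, strand = strand,
                 product = product, length_bp = end - start),
            class = "feature_record")
}

#' Construct a protein record
#'
#' @param id protein/locus id.
#' @param sequence amino-acid string over the 20-letter alphabet plus X
#'   (ambiguity codes B/Z/J/U/O are collapsed to X with a warning).
#' @param strain source strain label.
#' @param coding_length_bp length of the coding gene in bp; defaults to
#'   `3 * nchar(sequence) + 3` (stop codon included).
#' @param product product description (drives the "hypothetical" flag).
#' @param hypothetical_terms term list for [is_hypothetical_product()].
#' @return object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, strain = NA_character_,
                           coding_length_bp = NULL,
                           product = "hypothetical protein",
                           hypothetical_terms = HYPOTHETICAL_TERMS) {
  if (!nzchar(sequence)) stop("empty protein sequence for '", id, "'",
                              call. = FALSE)
  sequence <- toupper(sequence)
  if (grepl("[BZJUO]", sequence)) {
    warning("ambiguous amino-acid codes in '", id, "' collapsed to X",
            call. = FALSE)
    sequence <- gsub("[BZJUO]", "X", sequence)
  }
  bad <- regexpr(paste0("[^", paste(AA20, collapse = ""), "X]"), sequence)
  if (bad > 0L)
    stop("illegal amino acid at position ", bad, " in '", id, "'",
         call. = FALSE)
  if (is.null(coding_length_bp)) coding_length_bp <- 3L * nchar(sequence) + 3L
  if (coding_length_bp < 3L * nchar(sequence))
    stop("coding_length_bp of '", id, "' shorter than 3x protein length",
         call. = FALSE)
  structure(list(id = id, sequence = sequence, strain = strain,
                 coding_length_bp = as.integer(coding_length_bp),
                 product = product,
                 is_hypothetical = is_hypothetical_product(product,
                                                           hypothetical_terms)),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record>", x$id, "|", nchar(x$sequence), "aa | strain",
      x$strain, "|", x$product, "\n")
  invisible(x)
}

fasta_ids <- function(set) {
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id: '", dup[1], "'", call. = FALSE)
  ids
}

#' Read a FASTA file into genome or protein records
#'
#' Headers are truncated at the first whitespace to form the record id; the
#' remainder (if any) is kept as the product description for proteins.
#' Sequences are uppercased and alphabet-validated; record order is preserved.
#'
#' @param path FASTA file (plain or gzipped).
#' @param alphabet `"nt"` for [genome_record()]s, `"aa"` for
#'   [protein_record()]s.
#' @param strain strain label attached to every record (default: `NA` for aa,
#'   the record id for nt).
#' @param role genome role for nt records.
#' @return list of records, named by id.
#' @export
read_fasta <- function(path, alphabet = c("nt", "aa"), strain = NULL,
                       role = "background") {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- fasta_ids(set)
  desc <- trimws(sub("^\\S+\\s*", "", names(set)))
  seqs <- unname(as.character(set))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    out[[i]] <- if (alphabet == "nt") {
      genome_record(ids[i], seqs[i],
                    source_strain = strain %||% ids[i], role = role)
    } else {
      protein_record(ids[i], seqs[i], strain = strain %||% NA_character_,
                     product = if (nzchar(desc[i])) desc[i]
                               else "hypothetical protein")
    }
  }
  names(out) <- ids
  out
}

#' Write records to FASTA
#'
#' @param records list of genome/protein records, or a named character vector.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (is.list(records))
    records <- setNames(vapply(records, `[[`, "", "sequence"),
                        vapply(records, `[[`, "", "id"))
  set <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

parse_gff_attr <- function(attr, key) {
  m <- regmatches(attr, regexpr(paste0("(^|;)\\s*", key, "=[^;]*"), attr))
  if (!length(m)) return(NA_character_)
  URLdecode(sub(paste0("^.*", key, "="), "", m))
}

#' Read feature annotations (GFF3 or TSV) into feature records
#'
#' Both dialects use 1-based inclusive coordinates on disk; they are converted
#' to the internal 0-based half-open convention here. The TSV dialect has a
#' header with columns `seqid, feature_id, start, end, strand, product`.
#' GFF3 feature ids come from the `ID` or `locus_tag` attribute and products
#' from the `product` attribute.
#'
#' @param path annotation file.
#' @param dialect `"gff3"` or `"tsv"`.
#' @return named list: seqid -> list of [feature_record()]s.
#' @export
read_annotations <- function(path, dialect = c("gff3", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "gff3") {
    ln <- readLines(path)
    ln <- ln[!grepl("^#", ln) & nzchar(ln)]
    if (!length(ln)) return(list())
    fld <- strsplit(ln, "\t", fixed = TRUE)
    if (any(lengths(fld) != 9L))
      stop("malformed GFF3 line (need 9 tab-separated columns)",
           call. = FALSE)
    df <- as.data.frame(do.call(rbind, fld), stringsAsFactors = FALSE)
    names(df) <- c("seqid", "source", "type", "start", "end", "score",
                   "strand", "phase", "attributes")
    df$feature_id <- vapply(df$attributes, function(a) {
      id <- parse_gff_attr(a, "ID")
      if (is.na(id)) id <- parse_gff_attr(a, "locus_tag")
      id
    }, "")
    df$product <- vapply(df$attributes, parse_gff_attr, "", key = "product")
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
    need <- c("seqid", "feature_id", "start", "end", "strand")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("TSV annotations missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    if (!"product" %in% names(df)) df$product <- NA_character_
  }
  start1 <- as.integer(df$start); end1 <- as.integer(df$end)
  if (any(is.na(start1)) || any(is.na(end1)))
    stop("non-integer coordinates in ", path, call. = FALSE)
  if (any(start1 > end1))
    stop("start > end for feature '",
         df$feature_id[which(start1 > end1)[1]], "'", call. = FALSE)
  out <- list()
  for (i in seq_len(nrow(df))) {
    fr <- feature_record(df$feature_id[i], start1[i] - 1L, end1[i],
                         df$strand[i], df$product[i])
    out[[df$seqid[i]]] <- c(out[[df$seqid[i]]], list(fr))
  }
  out
}

#' Write feature records as GFF3 (1-based inclusive on disk)
#'
#' @param features named list seqid -> list of feature records.
#' @param path output file.
#' @export
write_gff3 <- function(features, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (seqid in names(features)) {
    for (f in features[[seqid]]) {
      attr <- paste0("ID=", f$id, ";product=",
                     URLencode(f$product, reserved = FALSE))
      writeLines(paste(seqid, "strainmark", "gene", f$start + 1L, f$end,
                       ".", f$strand, ".", attr, sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Write a deterministic TSV report
#'
#' Columns keep their input order; non-integer numeric columns are serialized
#' with 4 decimals. List columns are rejected.
#'
#' @param rows data frame.
#' @param path output file.
#' @export
write_tsv_report <- function(rows, path) {
  if (!is.data.frame(rows)) stop("rows must be a data frame", call. = FALSE)
  for (j in seq_along(rows)) {
    if (!is.atomic(rows[[j]]))
      stop("column '", names(rows)[j], "' is not atomic", call. = FALSE)
    if (is.double(rows[[j]])) rows[[j]] <- fmt_num(rows[[j]])
  }
  ok <- tryCatch({
    write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write: ", path, call. = FALSE)
  invisible(path)
}

#' Write regions as 3-column BED (0-based half-open)
#'
#' @param regions data frame with columns `chrom`/`query_id`, `start`, `end`,
#'   or a list of novel-region records.
#' @param path output file.
#' @export
write_bed <- function(regions, path) {
  if (is.list(regions) && !is.data.frame(regions))
    regions <- data.frame(
      chrom = vapply(regions, `[[`, "", "query_id"),
      start = vapply(regions, function(r) r$start, 0L),
      end   = vapply(regions, function(r) r$end, 0L))
  if (!"chrom" %in% names(regions) && "query_id" %in% names(regions))
    names(regions)[names(regions) == "query_id"] <- "chrom"
  con <- file(path, "w"); on.exit(close(con))
  writeLines("#chrom\tstart\tend", con)
  if (nrow(regions))
    writeLines(paste(regions$chrom, regions$start, regions$end, sep = "\t"),
               con)
  invisible(path)
}
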