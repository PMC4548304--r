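#' Construct an alignment object
#'
#' An `msa` object is an ordered set of identified, equal-length gapped
#' sequences: the container every distance computation in this package
#' starts from.
#'
#' @param ids character vector of unique, whitespace-free sequence ids.
#' @param seqs character vector of aligned sequences (equal lengths,
#'   uppercased on storage).
#' @param descriptions optional free-text descriptions (default empty).
#' @return An object of class `msa` with elements `ids`, `descriptions`,
#'   `seqs`, `n` (number of sequences) and `width` (alignment columns).
#' @export
msa <- function(ids, seqs, descriptions = character(length(ids))) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs))
    stop("ids and seqs must have the same length")
  if (any(!nzchar(ids)) || any(grepl("\\s", ids)))
    stop("sequence ids must be non-empty and contain no whitespace")
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ", ids[duplicated(ids)][1L])
  if (any(!nzchar(seqs)))
    stop("empty sequence for id: ", ids[!nzchar(seqs)][1L])
  w <- nchar(seqs)
  if (any(w != w[1L])) {
    bad <- ids[which(w != w[1L])[1L]]
    stop("unaligned input: sequence '", bad, "' has length ", w[w != w[1L]][1L],
         ", expected ", w[1L])
  }
  structure(
    list(ids = ids, descriptions = as.character(descriptions), seqs = seqs,
         n = length(ids), width = w[1L]),
    class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("Multiple sequence alignment:", x$n, "sequences x", x$width,
      "columns\n")
  show <- utils::head(seq_len(x$n), 6L)
  for (i in show) {
    s <- x$seqs[i]
    if (nchar(s) > 50) s <- paste0(substr(s, 1, 50), "...")
    cat(sprintf("  %-20s %s\n", x$ids[i], s))
  }
  if (x$n > 6L) cat("  ... and", x$n - 6L, "more\n")
  invisible(x)
}

# Parse a FASTA file into (ids, descriptions, seqs); shared by the aligned
# and unaligned readers.
read_fasta_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e)
                    stop("cannot parse FASTA file '", path, "': ",
                         conditionMessage(e)))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descriptions <- ifelse(grepl("\\s", headers),
                         sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ", ids[duplicated(ids)][1L])
  list(ids = ids, descriptions = descriptions,
       seqs = toupper(as.character(set)))
}

#' Read a multiple sequence alignment from FASTA
#'
#' All records must have the same length. Residues are uppercased; any
#' character not in `gap_chars` is kept as a residue (the parser is
#' permissive about alphabets).
#'
#' @param path path to a FASTA alignment.
#' @param gap_chars characters treated as gaps (default `-` and the
#'   Pfam-style `.`).
#' @return An [msa] object.
#' @export
read_alignment <- function(path, gap_chars = c("-", ".")) {
  rec <- read_fasta_records(path)
  if (length(rec$ids) < 2L)
    stop("an alignment needs at least 2 sequences, got ", length(rec$ids))
  aln <- msa(rec$ids, rec$seqs, rec$descriptions)
  attr(aln, "gap_chars") <- gap_chars
  aln
}

#' Read unaligned sequences from FASTA
#'
#' Records may have different lengths; gap characters are stripped so
#' downstream similarity searches see plain residues.
#'
#' @inheritParams read_alignment
#' @return A data.frame with columns `id`, `description`, `seq`, in file
#'   order.
#' @export
read_unaligned <- function(path, gap_chars = c("-", ".")) {
  rec <- read_fasta_records(path)
  seqs <- rec$seqs
  for (g in gap_chars) seqs <- gsub(g, "", seqs, fixed = TRUE)
  data.frame(id = rec$ids, description = rec$descriptions,
             seq = seqs, stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param ids,seqs parallel character vectors.
#' @param path output path.
#' @param descriptions optional descriptions appended to the header lines.
#' @export
write_fasta <- function(ids, seqs, path,
                        descriptions = character(length(ids))) {
  headers <- ifelse(nzchar(descriptions), paste(ids, descriptions), ids)
  set <- Biostrings::BStringSet(as.character(seqs))
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path, format = "fasta")
  invisible(path)
}

#' Read a square Phylip distance matrix
#'
#' Relaxed dialect: the first non-blank line holds the sequence count N;
#' each following non-blank line holds a whitespace-terminated label (any
#' length) and N numeric fields. Lower-triangular Phylip is rejected.
#'
#' @param path path to the matrix file.
#' @param tol tolerance for the symmetry and zero-diagonal checks.
#' @return A list with `labels` (character) and `values` (numeric N x N
#'   matrix, dimnames set to the labels).
#' @export
read_phylip_distmat <- function(path, tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty distance matrix file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L)
    stop("first line must be the sequence count, got: '", lines[1L], "'")
  body <- lines[-1L]
  if (length(body) != n)
    stop("expected ", n, " matrix rows, found ", length(body))
  toks <- strsplit(trimws(body), "\\s+")
  nf <- lengths(toks) - 1L
  if (all(nf == seq_len(n) - 1L) && n > 1L)
    stop("lower-triangular Phylip matrices are not supported; ",
         "provide the full square matrix")
  if (any(nf != n))
    stop("row ", which(nf != n)[1L], " has ", nf[nf != n][1L],
         " numeric fields, expected ", n)
  labels <- vapply(toks, `[[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(toks, function(t) as.numeric(t[-1L]), numeric(n)))
  if (anyNA(vals)) {
    bad <- which(colSums(is.na(vals)) > 0)[1L]
    stop("non-numeric distance field in row ", bad, " ('", labels[bad], "')")
  }
  m <- t(matrix(vals, nrow = n))
  if (max(abs(diag(m))) > tol)
    stop("distance matrix diagonal is not zero (max |diag| = ",
         format(max(abs(diag(m)))), ")")
  if (max(abs(m - t(m))) > tol)
    stop("distance matrix is asymmetric (max |S - t(S)| = ",
         format(max(abs(m - t(m)))), ")")
  dimnames(m) <- list(labels, labels)
  list(labels = labels, values = m)
}

#' Write a square Phylip distance matrix
#'
#' @param values square numeric matrix.
#' @param labels row labels; defaults to the matrix rownames.
#' @param path output path.
#' @export
write_phylip_distmat <- function(values, path,
                                 labels = rownames(values)) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (is.null(labels)) labels <- paste0("seq", seq_len(n))
  rows <- vapply(seq_len(n), function(i)
    paste(labels[i], paste(sprintf("%.10g", values[i, ]), collapse = " ")),
    character(1))
  writeLines(c(as.character(n), rows), path)
  invisible(path)
}

#' Write the outlier report and the core / outlier FASTA partition
#'
#' The report is tab-separated with header
#' `sequence_id  raw_score  outlier_score  is_outlier`; the two FASTA
#' files partition the input alignment into non-flagged (core) and
#' flagged (outlier) records, preserving input order.
#'
#' @param fit an [msa_outliers][detect_outliers] object.
#' @param alignment the [msa] the fit was computed from, or `NULL` when
#'   the input was a pre-computed distance matrix (FASTA outputs are then
#'   skipped).
#' @param out_report,out_core,out_outliers output paths; `out_core` /
#'   `out_outliers` may be `NULL` to skip.
#' @export
write_outputs <- function(fit, alignment, out_report,
                          out_core = NULL, out_outliers = NULL) {
  stopifnot(inherits(fit, "msa_outliers"))
  if (!is.null(out_report)) {
    df <- data.frame(sequence_id = fit$ids,
                     raw_score = sprintf("%.10g", fit$raw_scores),
                     outlier_score = sprintf("%.10g", fit$outlier_scores),
                     is_outlier = fit$flags)
    ok <- tryCatch({
      write.table(df, out_report, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      TRUE
    }, error = function(e) stop("cannot write report to '", out_report,
                                "': ", conditionMessage(e)))
  }
  if (!is.null(alignment)) {
    stopifnot(inherits(alignment, "msa"))
    if (!identical(alignment$ids, fit$ids))
      stop("alignment ids do not match the fitted report")
    if (!is.null(out_core))
      write_fasta(alignment$ids[!fit$flags], alignment$seqs[!fit$flags],
                  out_core, alignment$descriptions[!fit$flags])
    if (!is.null(out_outliers))
      write_fasta(alignment$ids[fit$flags], alignment$seqs[fit$flags],
                  out_outliers, alignment$descriptions[fit$flags])
  }
  invisible(NULL)
}
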