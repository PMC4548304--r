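#' All-vs-all pairwise similarity via an external protein search tool
#'
#' Builds a temporary protein database from the input sequences, searches
#' every sequence against it with an NCBI-BLAST-compatible `blastp` at
#' default parameters (tabular output requested explicitly so parsing is
#' version-stable), and keeps the best bit score per unordered pair
#' (maximum over HSPs and over the two query/subject directions).
#' Self-hits are excluded; a pair with no reported hit scores 0.
#'
#' @param records data.frame with columns `id` and `seq` (see
#'   [read_unaligned()]).
#' @param blast_exe path to the `blastp` executable; `makeblastdb` is
#'   expected alongside it.
#' @param workdir directory for temporary files.
#' @return A data.frame with columns `id1`, `id2`, `bitscore`, one row per
#'   unordered pair with a reported hit.
#' @export
all_vs_all_similarity <- function(records, blast_exe = "blastp",
                                  workdir = tempfile("blastwork")) {
  if (nrow(records) < 2L) stop("need at least 2 sequences")
  exe <- Sys.which(blast_exe)
  if (!nzchar(exe))
    stop("protein search tool '", blast_exe, "' not found; install ",
         "NCBI BLAST+ or point --blast-exe / blast_exe at blastp")
  mkdb <- file.path(dirname(exe), "makeblastdb")
  if (!file.exists(mkdb)) mkdb <- Sys.which("makeblastdb")
  if (!nzchar(mkdb) || !file.exists(mkdb))
    stop("makeblastdb not found next to '", exe, "'")
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(workdir, "input.fasta")
  write_fasta(records$id, records$seq, fa)
  db <- file.path(workdir, "db")
  out <- file.path(workdir, "hits.tsv")
  run <- function(cmd, args) {
    res <- suppressWarnings(system2(cmd, args, stdout = TRUE,
                                    stderr = TRUE))
    status <- attr(res, "status")
    if (!is.null(status) && status != 0)
      stop("search tool failed (exit ", status, "): ",
           paste(res, collapse = " | "))
    res
  }
  run(mkdb, c("-in", fa, "-dbtype", "prot", "-out", db))
  run(exe, c("-query", fa, "-db", db,
             "-outfmt", shQuote("6 qseqid sseqid bitscore"),
             "-out", out))
  hits <- if (file.size(out) > 0)
    read.table(out, sep = "\t", stringsAsFactors = FALSE,
               col.names = c("q", "s", "bits"))
  else data.frame(q = character(), s = character(), bits = numeric())
  hits <- hits[hits$q != hits$s, , drop = FALSE]
  if (nrow(hits) == 0L)
    return(data.frame(id1 = character(), id2 = character(),
                      bitscore = numeric()))
  a <- pmin(hits$q, hits$s)
  b <- pmax(hits$q, hits$s)
  best <- aggregate(hits$bits, by = list(id1 = a, id2 = b), FUN = max)
  data.frame(id1 = best$id1, id2 = best$id2, bitscore = best$x,
             stringsAsFactors = FALSE)
}

#' Total pairwise similarity per sequence
#'
#' Sums the pair bit scores over every pair containing each sequence; a
#' sequence sharing little similarity with the rest of the set gets an
#' anomalously LOW total, which the classifier treats as the suspicious
#' tail for similarity-kind scores.
#'
#' @param table pair table from [all_vs_all_similarity()] (columns `id1`,
#'   `id2`, `bitscore`).
#' @param ids ordered sequence ids; pairs must only mention these.
#' @return Named numeric vector of totals in the order of `ids`.
#' @export
similarity_scores <- function(table, ids) {
  scores <- structure(numeric(length(ids)), names = ids)
  if (nrow(table) > 0L) {
    unknown <- setdiff(unique(c(table$id1, table$id2)), ids)
    if (length(unknown) > 0L)
      stop("similarity table mentions unknown id: ", unknown[1L])
    for (k in seq_len(nrow(table))) {
      scores[table$id1[k]] <- scores[table$id1[k]] + table$bitscore[k]
      scores[table$id2[k]] <- scores[table$id2[k]] + table$bitscore[k]
    }
  }
  scores
}

#' Detect outliers in unaligned sequences
#'
#' The unaligned-mode pipeline: all-vs-all similarity search, per-sequence
#' bit-score totals, bootstrap normalisation, and flagging of sequences
#' with anomalously low totals. Less sensitive than the aligned gap-based
#' mode; bootstrap is the only supported normalisation here.
#'
#' @inheritParams all_vs_all_similarity
#' @inheritParams detect_outliers
#' @return An `msa_outliers` object with `kind = "similarity"`.
#' @export
detect_outliers_unaligned <- function(records, threshold = 2,
                                      tail = c("upper", "lower", "both"),
                                      replicates = 1000L, rng_seed = 2015L,
                                      blast_exe = "blastp") {
  tab <- all_vs_all_similarity(records, blast_exe)
  raw <- similarity_scores(tab, records$id)
  fit <- score_outliers(raw, kind = "similarity", norm = "bootstrap",
                        threshold = threshold, tail = match.arg(tail),
                        replicates = replicates, rng_seed = rng_seed,
                        metric = "bitscore", mode = "unaligned")
  fit$call <- match.call()
  fit
}
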