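#' Guess the kind of an input file
#'
#' A leading integer line means a square Phylip distance matrix; a FASTA
#' file whose records share one length and contain gap characters is
#' treated as an alignment; any other FASTA is treated as unaligned. The
#' heuristic can misfire on gap-free alignments (which are valid
#' alignments with no gap signal), so callers can override it.
#'
#' @param path input file.
#' @param gap_chars gap characters used for the alignment check.
#' @return `"distmat"`, `"msa"` or `"unaligned"`.
#' @export
detect_input_kind <- function(path, gap_chars = c("-", ".")) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[nzchar(trimws(first))]
  if (length(first) == 0L) stop("empty input file: ", path)
  if (grepl("^\\s*\\d+\\s*$", first[1L])) return("distmat")
  rec <- read_fasta_records(path)
  w <- nchar(rec$seqs)
  has_gaps <- any(vapply(gap_chars, function(g)
    any(grepl(g, rec$seqs, fixed = TRUE)), logical(1)))
  if (length(rec$seqs) >= 2L && all(w == w[1L]) && has_gaps)
    "msa"
  else "unaligned"
}

#' Run the full outlier-detection pipeline on a file
#'
#' End-to-end front end used by the command-line script: detects (or is
#' told) the input kind, computes raw scores by the appropriate route,
#' normalises and classifies, and writes the report plus the core /
#' outlier FASTA partition (sequence inputs only; a distance matrix input
#' yields the report alone). An alignment with no gap signal (gap-free,
#' or all gap patterns identical) is reported as having no detectable
#' outliers rather than treated as an error — the method has no power
#' there.
#'
#' @param input input file path.
#' @param type `"auto"` (default), `"msa"`, `"unaligned"` or `"distmat"`.
#' @param out_report,out_core,out_outliers output paths (`NULL` skips).
#' @param blast_exe protein search executable for unaligned input.
#' @param verbose print progress information.
#' @inheritParams detect_outliers
#' @return The fitted `msa_outliers` object, invisibly.
#' @export
run_pipeline <- function(input, type = c("auto", "msa", "unaligned",
                                         "distmat"),
                         metric = "linear", mode = c("full", "mbed"),
                         norm = c("bootstrap", "iqr"), threshold = 2,
                         tail = c("upper", "lower", "both"),
                         replicates = 1000L, n_seeds = "auto",
                         rng_seed = 2015L, gap_chars = c("-", "."),
                         out_report = "outlier_report.tsv",
                         out_core = "core_sequences.fasta",
                         out_outliers = "outlier_sequences.fasta",
                         blast_exe = "blastp", verbose = TRUE) {
  type <- match.arg(type)
  mode <- match.arg(mode)
  norm <- match.arg(norm)
  tail <- match.arg(tail)
  say <- function(...) if (verbose) message(...)
  if (type == "auto") {
    type <- detect_input_kind(input, gap_chars)
    say("detected input kind: ", type)
  }
  alignment <- NULL
  if (type == "msa") {
    alignment <- read_alignment(input, gap_chars)
    say("alignment: N = ", alignment$n, ", L = ", alignment$width,
        "; metric = ", metric, ", mode = ", mode)
    mask <- gap_mask(alignment, gap_chars)
    no_signal <- all(apply(mask, 2L, function(col)
      all(col == col[1L])))
    if (no_signal) {
      say("no gap signal (all gap patterns identical); ",
          "no outliers detectable by this method")
      raw <- structure(numeric(alignment$n), names = alignment$ids)
      fit <- structure(
        list(ids = alignment$ids, raw_scores = unname(raw),
             outlier_scores = numeric(alignment$n),
             flags = rep(FALSE, alignment$n), threshold = threshold,
             tail = tail, kind = "distance",
             stats = structure(list(method = norm, note = "no gap signal"),
                               class = "norm_stats_degenerate"),
             metric = metric, mode = mode, n = alignment$n),
        class = "msa_outliers")
      write_outputs(fit, alignment, out_report, out_core, out_outliers)
      return(invisible(fit))
    }
    if (mode == "full" && alignment$n > 1000)
      say("note: N > 1000; the seed approximation (mode = \"mbed\") ",
          "is much faster at this scale")
    fit <- detect_outliers(alignment, metric = metric, mode = mode,
                           norm = norm, threshold = threshold, tail = tail,
                           replicates = replicates, n_seeds = n_seeds,
                           rng_seed = rng_seed, gap_chars = gap_chars)
  } else if (type == "distmat") {
    dm <- read_phylip_distmat(input)
    say("distance matrix: N = ", length(dm$labels))
    if (mode == "mbed")
      stop("seed (mbed) mode needs sequences; a pre-computed distance ",
           "matrix is analysed in full mode")
    fit <- detect_outliers(dm, norm = norm, threshold = threshold,
                           tail = tail, replicates = replicates,
                           rng_seed = rng_seed)
    say("note: core/outlier FASTA outputs are skipped for distance-",
        "matrix input")
    out_core <- NULL
    out_outliers <- NULL
  } else {
    records <- read_unaligned(input, gap_chars)
    say("unaligned sequences: N = ", nrow(records))
    if (norm == "iqr")
      stop("unaligned similarity mode supports bootstrap normalisation ",
           "only")
    fit <- detect_outliers_unaligned(records, threshold = threshold,
                                     tail = tail, replicates = replicates,
                                     rng_seed = rng_seed,
                                     blast_exe = blast_exe)
  }
  if (type == "unaligned") {
    # write partition by hand: records are not an equal-length msa
    if (!is.null(out_report)) {
      df <- data.frame(sequence_id = fit$ids,
                       raw_score = sprintf("%.10g", fit$raw_scores),
                       outlier_score = sprintf("%.10g", fit$outlier_scores),
                       is_outlier = fit$flags)
      write.table(df, out_report, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    if (!is.null(out_core))
      write_fasta(fit$ids[!fit$flags], records$seq[!fit$flags], out_core)
    if (!is.null(out_outliers))
      write_fasta(fit$ids[fit$flags], records$seq[fit$flags], out_outliers)
  } else {
    write_outputs(fit, alignment, out_report, out_core, out_outliers)
  }
  if (verbose) {
    s <- fit$stats
    if (identical(s$method, "bootstrap"))
      say(sprintf("stats: mean = %.6g, sd = %.6g (B = %d)",
                  s$mean, s$sd, s$replicates))
    else if (identical(s$method, "iqr"))
      say(sprintf("stats: Q1 = %.6g, Q3 = %.6g, r = %.6g",
                  s$q1, s$q3, s$iqr))
  }
  say("flagged ", sum(fit$flags), " of ", fit$n,
      " sequences at threshold ", threshold)
  invisible(fit)
}

#' @export
print.norm_stats_degenerate <- function(x, ...) {
  cat("  normalisation skipped:", x$note, "\n")
  invisible(x)
}
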