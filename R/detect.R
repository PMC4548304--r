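#' Detect outlier sequences in a multiple sequence alignment
#'
#' The main fitting function. Converts the alignment to a binary gap mask,
#' computes per-sequence mean gap distances (full pairwise matrix, or the
#' log(N)-seed approximation for large alignments), normalises them by
#' bootstrap or interquartile range, and flags sequences whose normalised
#' score exceeds the threshold. Also accepts a pre-computed square
#' distance matrix (a numeric matrix or the list returned by
#' [read_phylip_distmat()]), in which case `metric`/`mode` are ignored and
#' the matrix is used as-is (seed mode needs sequences, so it is an error
#' there).
#'
#' @param x an [msa] alignment, a square numeric distance matrix, or a
#'   `read_phylip_distmat()` result.
#' @param metric gap metric: `"linear"` (default), `"affine"` or
#'   `"cumulative"`.
#' @param mode `"full"` pairwise matrix or `"mbed"` seed approximation.
#' @param norm `"bootstrap"` (default) or `"iqr"`.
#' @param threshold flag threshold T (default 2).
#' @param tail which tail(s) count as outlying; default `"upper"`.
#' @param replicates bootstrap replicate count B.
#' @param n_seeds seed count for `mode = "mbed"`, or `"auto"`.
#' @param rng_seed integer seed for seed selection and bootstrapping.
#' @param gap_chars characters treated as gaps.
#' @return An object of class `msa_outliers`: a list with per-sequence
#'   `ids`, `raw_scores` (mean gap distance), signed `outlier_scores`,
#'   logical `flags`, plus `threshold`, `tail`, `stats` (the normalisation
#'   statistics used), `metric`, `mode` and `n`. Methods: `print`,
#'   `summary`, `plot`, `as.data.frame`.
#' @examples
#' aln <- make_family(family_model(n_core = 40, length = 60,
#'                                 n_blocks = 3, rng_seed = 1))
#' fit <- detect_outliers(aln, rng_seed = 1)
#' summary(fit)
#' @export
detect_outliers <- function(x, metric = c("linear", "affine", "cumulative"),
                            mode = c("full", "mbed"),
                            norm = c("bootstrap", "iqr"),
                            threshold = 2,
                            tail = c("upper", "lower", "both"),
                            replicates = 1000L, n_seeds = "auto",
                            rng_seed = 2015L, gap_chars = c("-", ".")) {
  mode <- match.arg(mode)
  if (inherits(x, "msa")) {
    metric <- match.arg(metric)
    mask <- gap_mask(x, gap_chars)
    raw <- if (mode == "full") mean_scores(gap_dist_matrix(mask, metric))
           else mbed_means(mask, metric, n_seeds, rng_seed)
  } else {
    if (is.list(x) && !is.null(x$values)) x <- x$values
    if (!is.matrix(x) || nrow(x) != ncol(x))
      stop("x must be an 'msa' alignment or a square distance matrix")
    if (mode == "mbed")
      stop("seed (mbed) mode needs sequences or a full matrix; ",
           "a pre-computed distance matrix is analysed in full mode")
    metric <- "precomputed"
    raw <- mean_scores(x)
  }
  fit <- score_outliers(raw, ids = names(raw), kind = "distance",
                        norm = norm, threshold = threshold, tail = tail,
                        replicates = replicates, rng_seed = rng_seed,
                        metric = metric, mode = mode)
  fit$call <- match.call()
  fit
}

#' @export
print.msa_outliers <- function(x, ...) {
  cat("Gap-based outlier detection\n")
  if (!is.na(x$metric))
    cat(sprintf("  metric: %s, mode: %s\n", x$metric, x$mode))
  cat(sprintf("  sequences: %d, kind: %s\n", x$n, x$kind))
  print(x$stats)
  cat(sprintf("  threshold: %g (%s tail), flagged: %d\n",
              x$threshold, x$tail, sum(x$flags)))
  invisible(x)
}

#' @method summary msa_outliers
#' @export
summary.msa_outliers <- function(object, ...) {
  print(object)
  if (any(object$flags)) {
    cat("\nFlagged sequences (most outlying first):\n")
    o <- order(-abs(object$outlier_scores))
    o <- o[object$flags[o]]
    df <- data.frame(sequence_id = object$ids[o],
                     raw_score = round(object$raw_scores[o], 4),
                     outlier_score = round(object$outlier_scores[o], 4))
    print(df, row.names = FALSE)
  } else {
    cat("\nNo sequences flagged.\n")
  }
  invisible(object)
}

#' @method as.data.frame msa_outliers
#' @export
as.data.frame.msa_outliers <- function(x, ...) {
  data.frame(sequence_id = x$ids, raw_score = x$raw_scores,
              outlier_score = x$outlier_scores, is_outlier = x$flags,
              stringsAsFactors = FALSE)
}

#' Histogram of normalised outlier scores
#'
#' Distribution of the signed outlier scores with the decision
#' threshold(s) marked; flagged sequences fall beyond the dashed line(s).
#'
#' @param x an `msa_outliers` object.
#' @param ... passed to [graphics::hist()].
#' @method plot msa_outliers
#' @export
plot.msa_outliers <- function(x, ...) {
  graphics::hist(x$outlier_scores, breaks = "FD",
                 main = "Normalised outlier scores",
                 xlab = "outlier score", ...)
  s <- if (x$kind == "similarity") -1 else 1
  if (x$tail %in% c("upper", "both"))
    graphics::abline(v = s * x$threshold, lty = 2, col = "red")
  if (x$tail %in% c("lower", "both"))
    graphics::abline(v = -s * x$threshold, lty = 2, col = "red")
  invisible(x)
}
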