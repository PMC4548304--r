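#' Bootstrap estimates of the score mean and standard deviation
#'
#' Draws `replicates` pseudo-replicates of size N with replacement from
#' the raw score vector; the estimated mean is the mean of the replicate
#' means and the estimated standard deviation is the mean of the replicate
#' sample standard deviations (divisor N-1). These robust estimates centre
#' and scale the scores before thresholding.
#'
#' @param scores numeric vector of per-sequence raw scores (length >= 2).
#' @param replicates number of pseudo-replicates B (default 1000).
#' @param rng_seed integer seed for the resampling.
#' @param resampler optional function(n) returning n resampling indices,
#'   replacing the default `sample.int(n, n, replace = TRUE)`; intended
#'   for deterministic testing.
#' @return A `norm_stats` list with `method = "bootstrap"`, `mean`, `sd`,
#'   `replicates` and `rng_seed`.
#' @export
bootstrap_stats <- function(scores, replicates = 1000L, rng_seed = 2015L,
                            resampler = NULL) {
  n <- length(scores)
  if (n < 2L) stop("need at least 2 scores")
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L)
    stop("replicates must be a positive integer")
  draw <- function() {
    if (is.null(resampler)) sample.int(n, n, replace = TRUE)
    else resampler(n)
  }
  res <- with_seed(rng_seed, {
    idx <- matrix(0L, n, replicates)
    for (b in seq_len(replicates)) idx[, b] <- draw()
    vals <- matrix(scores[idx], n, replicates)
    c(mean(colMeans(vals)),
      mean(apply(vals, 2L, sd)))
  })
  structure(list(method = "bootstrap", mean = res[1L], sd = res[2L],
                 replicates = replicates, rng_seed = rng_seed),
            class = "norm_stats")
}

#' Interquartile-range statistics of the score vector
#'
#' Computes the first and third quartiles of the sorted scores by linear
#' interpolation at ranks 0.25(N-1) and 0.75(N-1) (the standard type-7
#' estimator; configurable) and their difference r = Q3 - Q1. Degenerate
#' inputs with r = 0 — many identical scores — are an error because the
#' downstream score divides by r; bootstrap normalisation is the robust
#' choice there.
#'
#' @param scores numeric vector of per-sequence raw scores (length >= 4).
#' @param qtype quantile estimator type passed to [stats::quantile()].
#' @return A `norm_stats` list with `method = "iqr"`, `q1`, `q3`, `iqr`.
#' @export
iqr_stats <- function(scores, qtype = 7L) {
  if (length(scores) < 4L)
    stop("need at least 4 scores for quartile estimation")
  q <- unname(quantile(scores, c(0.25, 0.75), type = qtype, names = FALSE))
  r <- q[2L] - q[1L]
  if (r <= 0)
    stop("interquartile range is 0 (many identical scores); ",
         "use bootstrap normalisation instead")
  structure(list(method = "iqr", q1 = q[1L], q3 = q[2L], iqr = r),
            class = "norm_stats")
}

#' @export
print.norm_stats <- function(x, ...) {
  if (x$method == "bootstrap")
    cat(sprintf("bootstrap normalisation: mean = %.4g, sd = %.4g (B = %d)\n",
                x$mean, x$sd, x$replicates))
  else
    cat(sprintf("IQR normalisation: Q1 = %.4g, Q3 = %.4g, r = %.4g\n",
                x$q1, x$q3, x$iqr))
  invisible(x)
}

#' Normalise raw scores into outlier scores
#'
#' Bootstrap: the z-like score (D - mean)/sd, signed, upper tail positive.
#' IQR: (D - Q3)/r above the third quartile, (D - Q1)/r below the first
#' (negative; its magnitude (Q1 - D)/r is the lower-tail excess), and
#' exactly 0 strictly inside (Q1, Q3). In both methods a sequence beyond
#' the upper tail carries a positive score and one beyond the lower tail a
#' negative score.
#'
#' @param scores raw score vector.
#' @param stats a `norm_stats` object from [bootstrap_stats()] or
#'   [iqr_stats()].
#' @return Numeric vector of signed normalised scores.
#' @export
normalise_scores <- function(scores, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  if (stats$method == "bootstrap") {
    if (stats$sd <= 0)
      stop("estimated standard deviation is 0 (all scores identical); ",
           "no finite outlier scores exist - inspect the input")
    (scores - stats$mean) / stats$sd
  } else {
    out <- numeric(length(scores))
    up <- scores > stats$q3
    lo <- scores < stats$q1
    out[up] <- (scores[up] - stats$q3) / stats$iqr
    out[lo] <- (scores[lo] - stats$q1) / stats$iqr
    out
  }
}

#' Classify sequences from normalised scores
#'
#' A sequence is flagged when its normalised score exceeds the threshold
#' on the active tail: `upper` flags score > T, `lower` flags -score > T,
#' `both` flags |score| > T. Distance inputs use the upper tail by default
#' (an aberrant sequence is unusually FAR from the rest); similarity
#' inputs (unaligned mode) have the sign flipped first, because there an
#' anomalously LOW total similarity is suspicious.
#'
#' @param outlier_scores signed normalised scores from
#'   [normalise_scores()].
#' @param threshold non-negative threshold T (default 2; 2-10 is the
#'   useful range, lower = more sensitive).
#' @param tail `"upper"`, `"lower"` or `"both"`.
#' @param kind `"distance"` or `"similarity"`.
#' @return Logical vector of flags.
#' @export
classify_outliers <- function(outlier_scores, threshold = 2,
                              tail = c("upper", "lower", "both"),
                              kind = c("distance", "similarity")) {
  tail <- match.arg(tail)
  kind <- match.arg(kind)
  if (threshold < 0) stop("threshold must be non-negative")
  s <- if (kind == "similarity") -outlier_scores else outlier_scores
  switch(tail,
         upper = s > threshold,
         lower = -s > threshold,
         both  = abs(s) > threshold)
}

#' Score and classify a raw score vector
#'
#' The normalisation + classification back end shared by the aligned,
#' distance-matrix and unaligned front ends: estimates centring statistics
#' (bootstrap or IQR), converts raw scores into normalised outlier scores
#' and flags those beyond the threshold.
#'
#' @param raw_scores named numeric vector of per-sequence raw scores
#'   (mean gap distances, or total similarity in unaligned mode).
#' @param ids sequence ids; defaults to the names of `raw_scores`.
#' @param kind `"distance"` or `"similarity"`.
#' @param norm `"bootstrap"` or `"iqr"`.
#' @param threshold,tail see [classify_outliers()].
#' @param replicates,rng_seed bootstrap parameters (see
#'   [bootstrap_stats()]).
#' @param metric,mode metadata recorded on the result (set by the aligned
#'   front end).
#' @return An object of class `msa_outliers`; see [detect_outliers()].
#' @export
score_outliers <- function(raw_scores, ids = NULL,
                           kind = c("distance", "similarity"),
                           norm = c("bootstrap", "iqr"),
                           threshold = 2, tail = c("upper", "lower", "both"),
                           replicates = 1000L, rng_seed = 2015L,
                           metric = NA_character_, mode = NA_character_) {
  kind <- match.arg(kind)
  norm <- match.arg(norm)
  tail <- match.arg(tail)
  if (is.null(ids)) ids <- names(raw_scores)
  raw_scores <- as.numeric(raw_scores)
  n <- length(raw_scores)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  if (length(ids) != n) stop("ids and raw_scores lengths differ")
  if (norm == "iqr" && kind == "similarity")
    stop("unaligned similarity mode supports bootstrap normalisation only")
  stats <- switch(norm,
                  bootstrap = bootstrap_stats(raw_scores, replicates,
                                              rng_seed),
                  iqr = iqr_stats(raw_scores))
  outlier_scores <- normalise_scores(raw_scores, stats)
  flags <- classify_outliers(outlier_scores, threshold, tail, kind)
  structure(
    list(ids = as.character(ids), raw_scores = raw_scores,
         outlier_scores = outlier_scores, flags = flags,
         threshold = threshold, tail = tail, kind = kind, stats = stats,
         metric = metric, mode = mode, n = n),
    class = "msa_outliers")
}
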