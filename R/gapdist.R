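METRICS <- c(linear = 1L, affine = 2L, cumulative = 3L)

metric_code <- function(metric) {
  metric <- match.arg(metric, names(METRICS))
  METRICS[[metric]]
}

#' Binary gap mask of an alignment
#'
#' Recodes an alignment into a binary N x L matrix with 1 at gap columns
#' and 0 at residue columns. All distance metrics in this package operate
#' on this mask only; residue identity never enters the computation.
#'
#' @param alignment an [msa] object.
#' @param gap_chars characters counted as gaps.
#' @return Integer matrix of 0/1 with rownames set to the sequence ids.
#' @export
gap_mask <- function(alignment, gap_chars = c("-", ".")) {
  stopifnot(inherits(alignment, "msa"))
  chars <- strsplit(alignment$seqs, "", fixed = TRUE)
  m <- t(vapply(chars, function(x) as.integer(x %in% gap_chars),
                integer(alignment$width)))
  # single-column alignments: vapply returns a vector, keep matrix shape
  if (alignment$width == 1L) m <- matrix(m, ncol = 1L)
  rownames(m) <- alignment$ids
  m
}

check_pair <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) != length(b))
    stop("mask rows have different lengths (", length(a), " vs ",
         length(b), ")")
  if (!all(a %in% c(0L, 1L)) || !all(b %in% c(0L, 1L)))
    stop("mask rows must be binary (0 = residue, 1 = gap)")
  list(a = a, b = b)
}

#' Pairwise gap distances between two mask rows
#'
#' Three metrics over the column-wise agreement of two binary gap masks:
#' \describe{
#'   \item{linear}{each disagreeing column scores 1 (Hamming distance on
#'     the masks); insensitive to how disagreements group into runs.}
#'   \item{affine}{a disagreeing column scores 3 when the previous column
#'     agreed (a mismatch opening; column 1 always opens) and 1 when it
#'     also disagreed (extension) — short gaps weigh relatively more.}
#'   \item{cumulative}{a disagreeing column scores 1 plus the previous
#'     column's score (0 on agreement), so a run of k disagreements
#'     contributes k(k+1)/2 — long gaps weigh progressively more.}
#' }
#'
#' @param a,b binary vectors of equal length (1 = gap).
#' @return Non-negative numeric distance.
#' @export
pair_linear <- function(a, b) {
  p <- check_pair(a, b)
  pair_dist_cpp(p$a, p$b, 1L)
}

#' @rdname pair_linear
#' @export
pair_affine <- function(a, b) {
  p <- check_pair(a, b)
  pair_dist_cpp(p$a, p$b, 2L)
}

#' @rdname pair_linear
#' @export
pair_cumulative <- function(a, b) {
  p <- check_pair(a, b)
  pair_dist_cpp(p$a, p$b, 3L)
}

#' Full pairwise gap-distance matrix
#'
#' Evaluates the chosen metric on every unordered pair of mask rows:
#' exactly N(N-1)/2 pair evaluations (recorded in the `n_pair_evals`
#' attribute), symmetric with zero diagonal.
#'
#' @param mask binary gap mask (rows = sequences), from [gap_mask()].
#' @param metric `"linear"`, `"affine"` or `"cumulative"`.
#' @return N x N numeric matrix with attributes `metric`, `mode = "full"`
#'   and `n_pair_evals`.
#' @export
gap_dist_matrix <- function(mask, metric = c("linear", "affine",
                                             "cumulative")) {
  code <- metric_code(metric)
  mask <- as.matrix(mask)
  n <- nrow(mask)
  if (n < 2L) stop("need at least 2 sequences for a distance matrix")
  storage.mode(mask) <- "integer"
  m <- full_dist_cpp(as.vector(t(mask)), n, ncol(mask), code)
  dimnames(m) <- list(rownames(mask), rownames(mask))
  structure(m, metric = names(METRICS)[code], mode = "full",
            n_pair_evals = n * (n - 1) / 2)
}

#' Per-sequence mean distance from a full matrix
#'
#' The mean of each row over the other N-1 sequences. Dividing by the
#' contributing-pair count (rather than summing) keeps scores on the same
#' scale across alignment sizes and across full / seed modes; the
#' downstream normalisations are scale-invariant, so classification is
#' unaffected.
#'
#' @param matrix full-mode distance matrix from [gap_dist_matrix()] or
#'   [read_phylip_distmat()].
#' @return Named numeric vector of length N.
#' @export
mean_scores <- function(matrix) {
  matrix <- as.matrix(matrix)
  n <- nrow(matrix)
  if (n < 2L || ncol(matrix) != n)
    stop("need a square matrix with at least 2 sequences")
  structure(rowSums(matrix) / (n - 1), names = rownames(matrix))
}

#' Default seed count for the log(N)-seed approximation
#'
#' `max(5, ceiling(log2(N)))`, capped at N. The logarithmic base follows
#' the Clustal Omega embedding lineage; the floor of 5 keeps small inputs
#' stable.
#'
#' @param n number of sequences.
#' @export
mbed_seed_count <- function(n) {
  min(n, max(5L, as.integer(ceiling(log2(n)))))
}

#' Approximate per-sequence mean distances from random seeds
#'
#' Instead of the O(N^2) full matrix, picks M seed sequences uniformly at
#' random and computes only the M x N seed-to-all distances (at most M*N
#' pair evaluations), giving O(N log N) work at the default M. Each
#' sequence's score is its mean distance to the seeds; a seed's own zero
#' self-distance is excluded from its mean (over M-1 seeds) so seeds are
#' not biased toward the core.
#'
#' @inheritParams gap_dist_matrix
#' @param n_seeds number of seeds M, or `"auto"` for [mbed_seed_count()].
#' @param rng_seed integer seed driving the random seed selection
#'   (fixed default so repeated runs are reproducible).
#' @return Named numeric vector of length N with attributes `seeds`
#'   (chosen row indices), `mode = "mbed"`, `metric` and `n_pair_evals`.
#' @export
mbed_means <- function(mask, metric = c("linear", "affine", "cumulative"),
                       n_seeds = "auto", rng_seed = 2015L) {
  code <- metric_code(metric)
  mask <- as.matrix(mask)
  n <- nrow(mask)
  if (n < 2L) stop("need at least 2 sequences")
  if (identical(n_seeds, "auto")) n_seeds <- mbed_seed_count(n)
  n_seeds <- as.integer(n_seeds)
  if (is.na(n_seeds) || n_seeds < 1L || n_seeds > n)
    stop("n_seeds must be between 1 and N = ", n)
  if (n_seeds == 1L)
    stop("n_seeds = 1 leaves the seed itself with no distances; use >= 2")
  seeds <- sort(with_seed(rng_seed, sample.int(n, n_seeds)))
  storage.mode(mask) <- "integer"
  sm <- seed_dist_cpp(as.vector(t(mask)), n, ncol(mask), seeds - 1L, code)
  denom <- rep(n_seeds, n)
  denom[seeds] <- n_seeds - 1L  # self-distance excluded
  scores <- colSums(sm) / denom
  structure(scores, names = rownames(mask), seeds = seeds, mode = "mbed",
            metric = names(METRICS)[code],
            n_pair_evals = n_seeds * n - n_seeds)
}
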