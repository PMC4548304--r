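AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Describe a synthetic family's gap architecture
#'
#' A family model specifies the shared gap architecture of a simulated
#' protein family: alignment length, a set of column intervals where gap
#' blocks may occur, the per-sequence probability that each block is
#' present, and a jitter that shifts block boundaries by a few columns per
#' sequence. When `gap_blocks` is not given, `n_blocks` non-overlapping
#' blocks (widths 4-12 columns) are drawn from the model seed.
#'
#' @param n_core number of core sequences to generate.
#' @param length alignment length L (columns).
#' @param gap_blocks list of `c(start, end)` 1-based column intervals, or
#'   `NULL` to draw them.
#' @param n_blocks number of blocks to draw when `gap_blocks` is `NULL`.
#' @param gap_prob per-sequence probability that each block is gapped.
#' @param jitter maximum per-sequence shift of block boundaries (columns).
#' @param frag_prob probability that a sequence is a fragment, i.e. is
#'   truncated at one terminus and padded with a terminal gap run (large
#'   family alignments typically contain such partial sequences).
#' @param frag_max maximum truncated fraction of the alignment length.
#' @param rng_seed integer seed; the model is fully reproducible from it.
#' @param columns restrict drawn blocks to these columns (used to build
#'   families with disjoint architectures); must be a contiguous range.
#' @return A `family_model` list.
#' @export
family_model <- function(n_core, length, gap_blocks = NULL, n_blocks = 10L,
                         gap_prob = 0.3, jitter = 2L, frag_prob = 0,
                         frag_max = 0.3, rng_seed = 1L,
                         columns = seq_len(length)) {
  if (length < 1L || n_core < 2L)
    stop("degenerate model: need length >= 1 and n_core >= 2")
  if (gap_prob < 0 || gap_prob > 1) stop("gap_prob must be in [0, 1]")
  if (frag_prob < 0 || frag_prob > 1) stop("frag_prob must be in [0, 1]")
  if (is.null(gap_blocks)) {
    gap_blocks <- with_seed(rng_seed * 7L + 3L,
                            draw_blocks(n_blocks, columns))
  }
  for (b in gap_blocks)
    if (length(b) != 2L || b[1L] < 1L || b[2L] > length || b[1L] > b[2L])
      stop("gap blocks must be c(start, end) intervals within 1..length")
  structure(list(n_core = as.integer(n_core), length = as.integer(length),
                 gap_blocks = gap_blocks, gap_prob = gap_prob,
                 jitter = as.integer(jitter), frag_prob = frag_prob,
                 frag_max = frag_max, rng_seed = as.integer(rng_seed)),
            class = "family_model")
}

# Place n non-overlapping blocks (nominal widths 4-12, shrunk evenly if
# the region is tight) inside a contiguous column range, separating them
# with random non-negative spacers plus a 1-column buffer.
draw_blocks <- function(n, columns) {
  lo <- min(columns); hi <- max(columns)
  C <- hi - lo + 1L
  if (n < 1L) return(list())
  if (4L * n + (n - 1L) > C)
    stop("cannot place ", n, " gap blocks in ", C, " columns")
  w <- sample(4:12, n, replace = TRUE)
  limit <- C - (n - 1L)
  if (sum(w) > limit) {
    w <- pmax(4L, as.integer(floor(w * limit / sum(w))))
    while (sum(w) > limit) w[which.max(w)] <- w[which.max(w)] - 1L
  }
  slack <- C - sum(w) - (n - 1L)
  # distribute the slack over the n+1 inter-block spacers
  cuts <- sort(sample.int(slack + n, n))  # stars and bars
  spacers <- diff(c(0L, cuts)) - 1L
  starts <- lo + cumsum(spacers) + c(0L, cumsum(w[-n] + 1L))
  lapply(seq_len(n), function(i) c(starts[i], starts[i] + w[i] - 1L))
}

#' Generate a synthetic family alignment
#'
#' Simulates `n_core` aligned sequences sharing the model's gap
#' architecture: residue columns are uniform random amino acids, and each
#' gap block is present in a given sequence with probability `gap_prob`,
#' with its boundaries shifted by up to `jitter` columns. With probability
#' `frag_prob` a sequence is a fragment: one terminus is replaced by a gap
#' run covering up to `frag_max` of the columns. Residue content is
#' deliberately unrealistic — the detector is gap-only, so only the gap
#' architecture matters for aligned-mode behaviour.
#'
#' @param model a [family_model()].
#' @param prefix id prefix for the generated sequences.
#' @return An [msa] of `n_core` sequences, reproducible from the model
#'   seed.
#' @export
make_family <- function(model, prefix = "core") {
  stopifnot(inherits(model, "family_model"))
  with_seed(model$rng_seed, {
    L <- model$length
    n <- model$n_core
    chars <- matrix(sample(AA, n * L, replace = TRUE), n, L)
    for (i in seq_len(n)) {
      for (b in model$gap_blocks) {
        if (runif(1) > model$gap_prob) next
        sh <- if (model$jitter > 0)
          sample(seq(-model$jitter, model$jitter), 1L) else 0L
        lo <- max(1L, b[1L] + sh)
        hi <- min(L, b[2L] + sh)
        if (lo <= hi) chars[i, lo:hi] <- "-"
      }
      if (model$frag_prob > 0 && runif(1) < model$frag_prob) {
        k <- sample.int(max(1L, as.integer(model$frag_max * L)), 1L)
        if (runif(1) < 0.5) chars[i, seq_len(k)] <- "-"
        else chars[i, (L - k + 1L):L] <- "-"
      }
    }
    msa(sprintf("%s%04d", prefix, seq_len(n)),
        apply(chars, 1L, paste, collapse = ""))
  })
}

ungapped_lengths <- function(aln, gap_chars = c("-", ".")) {
  aln$width - rowSums(gap_mask(aln, gap_chars))
}

#' Seed a family alignment with outlier sequences
#'
#' Draws `k` sequences from a second family model — typically one with a
#' disjoint gap-block layout, emulating sequences from an unrelated family
#' — appends them to the core alignment and shuffles the row order. The
#' injected outliers must have mean ungapped length within
#' `length_tolerance` of the core mean (default 10%), mirroring the
#' common benchmarking practice of length-matching outliers so that crude
#' length effects do not dominate detection.
#'
#' @param family an [msa] of core sequences (from [make_family()]).
#' @param k number of outliers to inject.
#' @param outlier_model [family_model()] the outliers are drawn from; its
#'   `length` must equal the family alignment width.
#' @param length_tolerance allowed relative deviation of the outliers'
#'   mean ungapped length.
#' @param rng_seed seed for the row shuffle.
#' @return A list with `alignment` (the seeded [msa]) and `labels`
#'   (logical, `TRUE` at injected outliers).
#' @export
inject_outliers <- function(family, k, outlier_model,
                            length_tolerance = 0.10, rng_seed = 1L) {
  stopifnot(inherits(family, "msa"))
  k <- as.integer(k)
  if (k == 0L) {
    return(list(alignment = family, labels = rep(FALSE, family$n)))
  }
  stopifnot(inherits(outlier_model, "family_model"))
  if (outlier_model$length != family$width)
    stop("outlier model length must match the family alignment width")
  om <- outlier_model
  om$n_core <- max(2L, k)
  out <- make_family(om, prefix = "outl")
  keep <- seq_len(k)
  core_len <- mean(ungapped_lengths(family))
  out_len <- mean(ungapped_lengths(out)[keep])
  if (abs(out_len - core_len) > length_tolerance * core_len)
    stop(sprintf(paste0("outlier mean ungapped length %.1f deviates more ",
                        "than %.0f%% from the core mean %.1f"),
                 out_len, 100 * length_tolerance, core_len))
  ids <- c(family$ids, out$ids[keep])
  seqs <- c(family$seqs, out$seqs[keep])
  labels <- c(rep(FALSE, family$n), rep(TRUE, k))
  ord <- with_seed(rng_seed, sample.int(length(ids)))
  list(alignment = msa(ids[ord], seqs[ord]), labels = labels[ord])
}

#' ROC curve and trapezoidal AUC from scores and labels
#'
#' Sweeps the decision threshold over every observed score, computes the
#' true/false positive rates, and integrates the ROC curve by the
#' trapezoidal rule. Higher scores must indicate outliers.
#'
#' @param scores numeric scores (e.g. normalised outlier scores).
#' @param labels logical, `TRUE` = real outlier.
#' @return A list with `curve` (data.frame threshold/TPR/FPR) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("labels must contain both classes")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(curve = data.frame(threshold = thr, TPR = tpr, FPR = fpr),
       auc = auc)
}

#' Benchmark the detector on seeded synthetic datasets
#'
#' Generates `n_datasets` core families seeded with `k` outliers each,
#' runs the full aligned-mode detector on every dataset, sweeps the
#' classification threshold, and tabulates TPR, FPR, precision and recall
#' (pooled over datasets) plus the per-dataset trapezoidal AUC of the
#' normalised scores.
#'
#' @param family_model,outlier_model [family_model()]s for core and
#'   outlier sequences; dataset i uses `rng_seed + i - 1` offsets so every
#'   dataset is distinct but reproducible.
#' @param k outliers per dataset.
#' @param n_datasets number of independent datasets.
#' @param thresholds thresholds to sweep for the rate table.
#' @param metric,mode,norm,replicates,tail detector configuration (see
#'   [detect_outliers()]).
#' @param rng_seed base seed.
#' @return A list with `rates` (data.frame: threshold, TPR, FPR,
#'   precision, recall), `auc` (mean over datasets) and `auc_per_dataset`.
#' @export
benchmark_run <- function(family_model, outlier_model, k = 5L,
                          n_datasets = 1L, thresholds = seq(0, 10, 0.5),
                          metric = "linear", mode = "full",
                          norm = "bootstrap", replicates = 1000L,
                          tail = "upper", rng_seed = 1L) {
  scores <- list(); labels <- list(); aucs <- numeric(n_datasets)
  for (d in seq_len(n_datasets)) {
    fm <- family_model; fm$rng_seed <- family_model$rng_seed + d - 1L
    om <- outlier_model; om$rng_seed <- outlier_model$rng_seed + d - 1L
    ds <- inject_outliers(make_family(fm), k, om,
                          rng_seed = rng_seed + d - 1L)
    fit <- detect_outliers(ds$alignment, metric = metric, mode = mode,
                           norm = norm, replicates = replicates,
                           tail = tail, rng_seed = rng_seed + d - 1L)
    scores[[d]] <- fit$outlier_scores
    labels[[d]] <- ds$labels
    aucs[d] <- roc_auc(fit$outlier_scores, ds$labels)$auc
  }
  sc <- unlist(scores); lb <- unlist(labels)
  rates <- do.call(rbind, lapply(thresholds, function(t) {
    flag <- sc > t
    tp <- sum(flag & lb); fp <- sum(flag & !lb); fn <- sum(!flag & lb)
    data.frame(threshold = t,
               TPR = tp / sum(lb), FPR = fp / sum(!lb),
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = tp / (tp + fn))
  }))
  list(rates = rates, auc = mean(aucs), auc_per_dataset = aucs)
}
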