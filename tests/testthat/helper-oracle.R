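# Independent single-pass reference implementations of the three gap
# metrics, written directly from their column-walk definitions. These are
# deliberately plain R loops, sharing no code with the package kernels.

ref_linear <- function(a, b) {
  s <- 0
  for (l in seq_along(a)) if (a[l] != b[l]) s <- s + 1
  s
}

ref_affine <- function(a, b) {
  s <- 0
  for (l in seq_along(a)) {
    if (a[l] != b[l]) {
      opened <- if (l == 1) TRUE else a[l - 1] == b[l - 1]
      s <- s + if (opened) 3 else 1
    }
  }
  s
}

ref_cumulative <- function(a, b) {
  s <- 0
  C <- 0
  for (l in seq_along(a)) {
    C <- if (a[l] != b[l]) 1 + C else 0
    s <- s + C
  }
  s
}

# Random binary mask pairs of a common random length in [1, max_len].
random_mask_pair <- function(max_len = 200, p = 0.3) {
  L <- sample.int(max_len, 1L)
  list(a = rbinom(L, 1L, p), b = rbinom(L, 1L, p))
}

# Small alignment built in code, used across seqio/pipeline tests.
toy_alignment <- function() {
  msa(ids = c("s1", "s2", "s3", "s4", "s5"),
      seqs = c("ACDEF-GHIK",
               "ACDEF-GHIK",
               "AC--FWGHIK",
               "ACDEF-GHIK",
               "----------"))
}

write_toy_fasta <- function(path, ids, seqs) {
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

# Standard different-clan benchmark pair: a consensus gap architecture in
# the first half of the columns, outliers with a disjoint architecture in
# the second half. Block count scales with length to keep the density
# comparable across scales.
diffclan_models <- function(n_core = 495, L = 300, rng_seed = 1) {
  half <- seq_len(L %/% 2)
  nb <- max(3L, L %/% 30L)
  fam <- family_model(n_core, L, n_blocks = nb, gap_prob = 0.8,
                      jitter = 2, rng_seed = rng_seed, columns = half)
  # same block widths relocated to the disjoint half: the outliers are
  # length-matched to the family by construction
  out_blocks <- lapply(fam$gap_blocks, function(b) b + L %/% 2)
  list(family = fam,
       outlier = family_model(5, L, gap_blocks = out_blocks,
                              gap_prob = 0.8, jitter = 2,
                              rng_seed = rng_seed + 100L))
}

# Canonical large fragment-rich family: sparse optional gap blocks plus a
# fragment fraction, emulating the composition of big full alignments
# where the seed approximation is actually used.
large_family_model <- function(n_core = 500, L = 300, rng_seed = 1) {
  family_model(n_core, L, n_blocks = 10, gap_prob = 0.2, jitter = 2,
               frag_prob = 0.2, frag_max = 0.3, rng_seed = rng_seed)
}
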