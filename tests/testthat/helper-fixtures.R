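# Small-grid configuration used throughout the unit tests: a 10^3 grid keeps
# every stage fast while exercising all mask compartments.
small_config <- function(...) {
  args <- utils::modifyList(
    list(grid_shape = c(10L, 10L, 10L), n_per_group = 3L, n_volumes = 60L),
    list(...))
  do.call(sim_config, args)
}

# A bold_run filled with the given t x v matrix over an all-true (or given)
# mask on a small grid.
bold_from_series <- function(mat, dims = NULL, tr_s = 2, filtered = FALSE,
                             mask = NULL) {
  n_vox <- ncol(mat)
  if (is.null(dims)) {
    side <- ceiling(n_vox^(1 / 3))
    dims <- c(side, side, max(1L, ceiling(n_vox / side^2)))
    while (prod(dims) < n_vox) dims[3] <- dims[3] + 1L
  }
  if (is.null(mask)) {
    mask <- array(FALSE, dims)
    mask[seq_len(n_vox)] <- TRUE
  }
  flat <- matrix(0, prod(dims), nrow(mat))
  flat[as.vector(mask), ] <- t(mat)
  dim(flat) <- c(dims, nrow(mat))
  bold_run(flat, tr_s = tr_s, voxel_size_mm = 3, filtered = filtered)
}

# Sinusoid sampled at TR on an exact DFT bin.
on_bin_sinusoid <- function(n_t, tr_s, freq_hz, amplitude = 1, phase = 0) {
  amplitude * sin(2 * pi * freq_hz * (0:(n_t - 1)) * tr_s + phase)
}

# Independent oracle for Kendall's W: mean pairwise Spearman identity,
# W = ((m - 1) * mean_rho + 1) / m.
kendalls_w_oracle <- function(series_set) {
  m <- nrow(series_set)
  ranks <- t(apply(series_set, 1L, rank))
  pairs <- utils::combn(m, 2L)
  rho <- apply(pairs, 2L, function(ij)
    stats::cor(ranks[ij[1], ], ranks[ij[2], ]))
  ((m - 1) * mean(rho) + 1) / m
}

# Gaussian two-class feature cohort with a mean shift on the first
# `n_informative` features; labels +1/-1.
gaussian_features <- function(n_per_group, n_features, shift = 0,
                              n_informative = n_features) {
  x <- matrix(stats::rnorm(2 * n_per_group * n_features), 2 * n_per_group)
  labels <- rep(c(1L, -1L), each = n_per_group)
  if (shift != 0 && n_informative > 0)
    x[labels == 1, seq_len(n_informative)] <-
      x[labels == 1, seq_len(n_informative)] + shift
  list(x = x, labels = labels)
}

dice <- function(a, b) {
  if (!any(a) || !any(b)) return(0)
  2 * sum(a & b) / (sum(a) + sum(b))
}
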