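#' Kendall's coefficient of concordance
#'
#' Agreement of `m` time series ("judges") ranking `n` time points
#' ("objects"):
#' `W = (12 * sum(R_t^2) - 3 m^2 n (n+1)^2) / (m^2 (n^3 - n))`,
#' where `R_t` is the cross-series sum of within-series ranks at time `t`.
#' Ties receive average ranks and no tie-correction factor is applied
#' (continuous-valued series make ties measure-zero). A constant series
#' contributes average ranks; if *all* series are constant the statistic is
#' degenerate and 0 is returned with a warning.
#'
#' @param series_set numeric matrix, `m` series in rows, `n` time points in
#'   columns (`m >= 2`, `n >= 2`).
#' @return scalar concordance in `[0, 1]`.
#' @export
kendalls_w <- function(series_set) {
  m <- nrow(series_set)
  n <- ncol(series_set)
  if (is.null(m) || m < 2L || n < 2L)
    stop("need at least 2 series and 2 time points")
  if (!all(is.finite(series_set))) stop("series must be finite")
  if (all(apply(series_set, 1L, function(x) max(x) == min(x)))) {
    warning("all series are constant; concordance undefined, returning 0")
    return(0)
  }
  ranks <- t(apply(series_set, 1L, rank))
  r_t <- colSums(ranks)
  w <- (12 * sum(r_t^2) - 3 * m^2 * n * (n + 1)^2) / (m^2 * (n^3 - n))
  min(max(w, 0), 1)
}

# 3D neighbourhood offsets: 7 = faces, 19 = faces + edges, 27 = full cube.
neighbourhood_offsets <- function(neighbourhood) {
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d2 <- rowSums(offs^2)
  keep <- switch(as.character(neighbourhood),
                 "7" = d2 <= 1, "19" = d2 <= 2, "27" = rep(TRUE, 27L),
                 stop("neighbourhood must be 7, 19 or 27"))
  offs[keep, , drop = FALSE]
}

shift3 <- function(arr, off) {
  d <- dim(arr)
  out <- array(0, dim = d)
  src <- dst <- vector("list", length(d))
  for (a in 1:3) {
    src[[a]] <- max(1L, 1L - off[a]):min(d[a], d[a] - off[a])
    dst[[a]] <- src[[a]] + off[a]
  }
  for (a in seq_along(d)[-(1:3)]) src[[a]] <- dst[[a]] <- seq_len(d[a])
  out[dst[[1]], dst[[2]], dst[[3]], ] <- arr[src[[1]], src[[2]], src[[3]], ]
  out
}

#' Regional homogeneity map
#'
#' Kendall's coefficient of concordance between each in-mask voxel's
#' bandpass-filtered time series and those of its spatial neighbours (up to
#' 26 for the full-cube neighbourhood). At mask and grid edges the available
#' in-mask neighbours are used (`m < 27`) so the map keeps the mask's full
#' support; voxels with fewer than 2 usable series get 0.
#'
#' The computation is vectorized: within-voxel temporal ranks are summed
#' over shifted copies of the rank field, and the concordance formula is
#' evaluated per voxel with its local judge count. It agrees exactly with
#' [kendalls_w()] applied voxel by voxel.
#'
#' @param bold a bandpass-filtered [bold_run()].
#' @param mask logical 3D analysis mask.
#' @param neighbourhood 7, 19 or 27 (voxel plus faces / edges / corners).
#' @return a raw-state [parameter_map()] of kind `"reho"`.
#' @export
reho_map <- function(bold, mask, neighbourhood = 27L) {
  assert_filtered(bold, "regional homogeneity")
  check_mask(mask, grid_dim(bold))
  d <- grid_dim(bold)
  n_t <- n_volumes(bold)
  y <- bold_matrix(bold, mask)
  ranks <- apply(y, 2L, rank)

  flat <- matrix(0, prod(d), n_t)
  flat[as.vector(mask), ] <- t(ranks)
  rank_field <- array(flat, dim = c(d, n_t))
  mask_field <- array(as.numeric(mask), dim = c(d, 1L))

  offs <- neighbourhood_offsets(neighbourhood)
  rank_sum <- array(0, dim = c(d, n_t))
  m_count <- array(0, dim = c(d, 1L))
  for (i in seq_len(nrow(offs))) {
    rank_sum <- rank_sum + shift3(rank_field, offs[i, ])
    m_count <- m_count + shift3(mask_field, offs[i, ])
  }
  m <- as.vector(m_count)
  dim(rank_sum) <- c(prod(d), n_t)
  ss <- rowSums(rank_sum^2)
  w <- (12 * ss - 3 * m^2 * n_t * (n_t + 1)^2) /
    (m^2 * (n_t^3 - n_t))
  w[m < 2 | !as.vector(mask)] <- 0
  w <- pmin(pmax(w, 0), 1)
  parameter_map(array(w, dim = d), "reho", "raw", mask,
                provenance = list(neighbourhood = neighbourhood))
}
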