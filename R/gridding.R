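#' Inverse-distance-weighted regridding
#'
#' Interpolates a field from one regular grid onto another using the k
#' nearest non-missing source cell centres with weights d^(-power). A
#' destination centre coinciding with a source centre (distance below 1e-9
#' degrees) takes that source value exactly. Typical use is moving coarse
#' (0.25 degree) satellite columns onto the fine (0.05 degree) modelling
#' grid.
#'
#' @param src Numeric matrix of source values (`NA` = missing), dimensions
#'   `src_grid$nrows x src_grid$ncols`.
#' @param src_grid,dst_grid `grid_spec` objects.
#' @param power IDW exponent (default 2).
#' @param k Number of nearest neighbours (default 4).
#' @param haversine Use great-circle distances in km instead of Euclidean
#'   degrees. Default `FALSE`; on the small synthetic domains the two are
#'   nearly proportional.
#' @return Numeric matrix on `dst_grid` with no missing values.
#' @export
idw_regrid <- function(src, src_grid, dst_grid, power = 2, k = 4,
                       haversine = FALSE) {
  stopifnot(is.matrix(src),
            nrow(src) == src_grid$nrows, ncol(src) == src_grid$ncols)
  plan <- idw_plan(src_grid, dst_grid, obs_mask = !is.na(src),
                   power = power, k = k, haversine = haversine)
  matrix(idw_apply(plan, src[!is.na(src)]),
         dst_grid$nrows, dst_grid$ncols)
}

# Precompute neighbour indices and weights for repeated regridding of
# fields sharing one missingness pattern. obs_mask marks usable source
# cells (column-major over the source matrix).
idw_plan <- function(src_grid, dst_grid, obs_mask = NULL, power = 2, k = 4,
                     haversine = FALSE) {
  src_xy <- grid_centres(src_grid)
  if (is.null(obs_mask)) obs_mask <- rep(TRUE, nrow(src_xy))
  obs_idx <- which(as.vector(obs_mask))
  if (length(obs_idx) == 0L)
    stop("all source cells missing: field cannot be regridded")
  sx <- src_xy[obs_idx, , drop = FALSE]
  dx <- grid_centres(dst_grid)
  k <- min(k, nrow(sx))
  nd <- nrow(dx)
  nb <- matrix(0L, nd, k)
  wt <- matrix(0, nd, k)
  chunk <- max(1L, as.integer(5e6 / nrow(sx)))
  for (s in seq(1L, nd, by = chunk)) {
    e <- min(s + chunk - 1L, nd)
    if (haversine) {
      d2 <- hav_dist(dx[s:e, 1], dx[s:e, 2], sx[, 1], sx[, 2])
    } else {
      d2 <- sqrt(outer(dx[s:e, 1], sx[, 1], "-")^2 +
                 outer(dx[s:e, 2], sx[, 2], "-")^2)
    }
    for (r in seq_len(e - s + 1L)) {
      d <- d2[r, ]
      hit <- which(d < 1e-9)
      if (length(hit)) {                    # exact colocation rule
        nb[s + r - 1L, ] <- c(hit[1L], rep(hit[1L], k - 1L))
        wt[s + r - 1L, ] <- c(1, rep(0, k - 1L))
      } else {
        o <- order(d)[seq_len(k)]
        w <- d[o]^(-power)
        nb[s + r - 1L, ] <- o
        wt[s + r - 1L, ] <- w / sum(w)
      }
    }
  }
  list(nb = nb, wt = wt, n_obs = length(obs_idx), obs_idx = obs_idx,
       dst_dim = c(dst_grid$nrows, dst_grid$ncols))
}

idw_apply <- function(plan, obs_values) {
  stopifnot(length(obs_values) == plan$n_obs)
  v <- matrix(obs_values[plan$nb], nrow(plan$nb), ncol(plan$nb))
  rowSums(v * plan$wt)
}

hav_dist <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  p1 <- outer(lat1 * rad, rep(1, length(lat2)))
  p2 <- outer(rep(1, length(lat1)), lat2 * rad)
  dlk <- outer(lat1 * rad, lat2 * rad, "-")
  dln <- outer(lon1 * rad, lon2 * rad, "-")
  a <- sin(dlk / 2)^2 + cos(p1) * cos(p2) * sin(dln / 2)^2
  6371 * 2 * asin(pmin(1, sqrt(a)))
}

#' Aggregate a fine grid to coarse blocks
#'
#' Each coarse cell is the mean of its `factor x factor` fine children,
#' ignoring missing values; a block with no valid child is missing. This is
#' the forward operator relating the fine truth field to coarse satellite
#' pixels in the synthetic world.
#'
#' @param fine Numeric matrix (`NA` = missing).
#' @param factor Integer block size; must divide both dimensions.
#' @return Matrix with dimensions `dim(fine) / factor`.
#' @export
block_aggregate <- function(fine, factor) {
  stopifnot(is.matrix(fine))
  factor <- as.integer(factor)
  if (nrow(fine) %% factor != 0L || ncol(fine) %% factor != 0L)
    stop("block factor ", factor, " does not divide field dimensions ",
         nrow(fine), " x ", ncol(fine))
  nr <- nrow(fine) %/% factor; nc <- ncol(fine) %/% factor
  gi <- rep(rep(seq_len(nr), each = factor), times = ncol(fine))
  gj <- rep(seq_len(nc), each = factor * nrow(fine))
  grp <- gi + (gj - 1L) * nr
  v <- as.vector(fine)
  ok <- !is.na(v)
  s <- rowsum(ifelse(ok, v, 0), grp, reorder = TRUE)
  n <- rowsum(as.numeric(ok), grp, reorder = TRUE)
  out <- s / n
  out[n == 0] <- NA_real_
  matrix(out, nr, nc)
}

# Separable Gaussian smoothing of a matrix (reflective normalisation at the
# borders): used by the synthetic world to turn white noise into smooth
# autocorrelated fields.
smooth_field <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  kern <- function(n) {
    d <- outer(seq_len(n), seq_len(n), "-")
    k <- exp(-d^2 / (2 * sigma^2))
    k / rowSums(k)
  }
  kern(nrow(mat)) %*% mat %*% t(kern(ncol(mat)))
}
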