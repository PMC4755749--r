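# Optional volumetric stage: render synthetic confocal-like intensity
# stacks from spot positions and re-detect spots from volumes.

#' Render a 3D intensity volume from kinetochore spots
#'
#' Sum of anisotropic Gaussian blobs at the spot positions, sampled on a
#' regular voxel grid. Voxel `(i, j, k)` (1-based) has its centre at
#' `origin + (c(i, j, k) - 0.5) * voxel_size_um`, i.e. voxel centres sit at
#' half-integer world offsets from the origin. Optionally adds Poisson
#' shot noise scaled by `photons_per_unit`.
#'
#' @param spots data.frame with `x_um`, `y_um`, `z_um` (and optionally
#'   `intensity`), or a numeric matrix with 3 columns. May have zero rows.
#' @param voxel_size_um voxel edge lengths (x, y, z) in um.
#' @param psf_sigma_um Gaussian blob s.d. per axis in um.
#' @param origin world coordinates of the grid corner; computed from the
#'   spot bounding box with `margin_um` padding when NULL.
#' @param dim_vox grid dimensions; derived from the bounding box when NULL.
#' @param margin_um padding used when deriving origin/dimensions.
#' @param photons_per_unit if > 0, intensities are scaled by this factor
#'   and Poisson noise is applied.
#' @return object of class `meioarch_volume`: list with `intensity` (3D
#'   array), `voxel_size_um`, `origin`.
#' @export
render_volume <- function(spots, voxel_size_um = c(0.1, 0.1, 0.25),
                          psf_sigma_um = c(0.12, 0.12, 0.30),
                          origin = NULL, dim_vox = NULL, margin_um = 1.0,
                          photons_per_unit = 0) {
  if (is.data.frame(spots)) {
    pos <- as.matrix(spots[, c("x_um", "y_um", "z_um")])
    intensity <- if ("intensity" %in% names(spots)) spots$intensity
      else rep(1, nrow(pos))
  } else {
    pos <- as.matrix(spots)
    intensity <- rep(1, nrow(pos))
  }
  if (ncol(pos) != 3L) ma_stop("render_volume: spots need 3 coordinates")
  n <- nrow(pos)
  if (is.null(origin)) {
    origin <- if (n) apply(pos, 2, min) - margin_um else c(0, 0, 0)
  }
  if (is.null(dim_vox)) {
    upper <- if (n) apply(pos, 2, max) + margin_um else origin + 2 * margin_um
    dim_vox <- pmax(3L, ceiling((upper - origin) / voxel_size_um))
  }
  if (n) {
    rel <- sweep(sweep(pos, 2, origin), 2, voxel_size_um, "/") + 0.5
    if (any(rel < 1) || any(rel > matrix(dim_vox, n, 3, byrow = TRUE)))
      ma_stop(paste("render_volume: spots outside grid at rows",
                    paste(which(rowSums(rel < 1 | rel >
                      matrix(dim_vox, n, 3, byrow = TRUE)) > 0),
                      collapse = ", ")))
  }
  vol <- array(0, dim = dim_vox)
  half <- ceiling(4 * psf_sigma_um / voxel_size_um)
  ax_centers <- lapply(1:3, function(a)
    origin[a] + (seq_len(dim_vox[a]) - 0.5) * voxel_size_um[a])
  for (i in seq_len(n)) {
    ctr_vox <- (pos[i, ] - origin) / voxel_size_um + 0.5
    lo <- pmax(1L, floor(ctr_vox - half))
    hi <- pmin(dim_vox, ceiling(ctr_vox + half))
    gx <- exp(-((ax_centers[[1]][lo[1]:hi[1]] - pos[i, 1])^2) /
                (2 * psf_sigma_um[1]^2))
    gy <- exp(-((ax_centers[[2]][lo[2]:hi[2]] - pos[i, 2])^2) /
                (2 * psf_sigma_um[2]^2))
    gz <- exp(-((ax_centers[[3]][lo[3]:hi[3]] - pos[i, 3])^2) /
                (2 * psf_sigma_um[3]^2))
    blob <- intensity[i] * outer(outer(gx, gy), gz)
    vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] + blob
  }
  if (photons_per_unit > 0) {
    vol <- array(stats::rpois(length(vol), vol * photons_per_unit) /
                   photons_per_unit, dim = dim_vox)
  }
  structure(list(intensity = vol, voxel_size_um = voxel_size_um,
                 origin = origin), class = "meioarch_volume")
}

# Separable Gaussian smoothing with zero padding.
gauss_smooth3 <- function(vol, sigma_vox) {
  d <- dim(vol)
  for (a in 1:3) {
    s <- sigma_vox[a]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2)); k <- k / sum(k)
    vol <- apply_along <- {
      perm <- switch(a, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
      v <- aperm(vol, perm)
      dv <- dim(v)
      m <- matrix(v, nrow = dv[1])
      padded <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
      sm <- matrix(0, nrow(m), ncol(m))
      for (t in seq_along(k))
        sm <- sm + k[t] * padded[t:(t + nrow(m) - 1L), , drop = FALSE]
      aperm(array(sm, dv), order(perm))
    }
  }
  vol
}

#' Detect spots in a 3D intensity volume
#'
#' Gaussian smoothing, 26-connected local maxima above an intensity
#' threshold, then sub-voxel refinement by the intensity-weighted centroid
#' of the raw volume in a fixed window around each maximum. Centres are
#' returned in world coordinates (um).
#'
#' @param volume a `meioarch_volume` from [render_volume()], or a 3D array
#'   (then `voxel_size_um` and `origin` are required).
#' @param smoothing_sigma_um Gaussian smoothing s.d. per axis (um).
#' @param min_intensity detection threshold on the smoothed volume.
#' @param voxel_size_um,origin grid metadata when `volume` is a bare array.
#' @param window_vox half-width (voxels) of the centroid window.
#' @return data.frame with `x_um`, `y_um`, `z_um`, `intensity` (smoothed
#'   peak value); zero rows when nothing exceeds the threshold.
#' @export
detect_spots <- function(volume, smoothing_sigma_um = c(0.08, 0.08, 0.16),
                         min_intensity = 0.1, voxel_size_um = NULL,
                         origin = NULL, window_vox = 2L) {
  if (inherits(volume, "meioarch_volume")) {
    vol <- volume$intensity
    voxel_size_um <- volume$voxel_size_um
    origin <- volume$origin
  } else {
    vol <- volume
    if (is.null(voxel_size_um) || is.null(origin))
      ma_stop("detect_spots: voxel size and origin metadata required")
  }
  d <- dim(vol)
  if (length(d) != 3L) ma_stop("detect_spots: need a 3D volume")
  sm <- gauss_smooth3(vol, smoothing_sigma_um / voxel_size_um)

  # local maxima: pad with -Inf and compare against all 26 neighbours
  pad <- array(-Inf, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- sm
  is_max <- array(TRUE, d)
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    nb <- pad[(2:(d[1] + 1)) + di, (2:(d[2] + 1)) + dj, (2:(d[3] + 1)) + dk]
    is_max <- is_max & (sm >= nb)
  }
  cand <- which(is_max & sm > min_intensity, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                      intensity = numeric(0)))
  # collapse plateau ties: keep one candidate per connected 1-voxel cluster
  ord <- order(-sm[cand])
  cand <- cand[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      later <- (i + 1):nrow(cand)
      close <- abs(cand[later, 1] - cand[i, 1]) <= 1 &
        abs(cand[later, 2] - cand[i, 2]) <= 1 &
        abs(cand[later, 3] - cand[i, 3]) <= 1
      keep[later][close] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]

  out <- matrix(NA_real_, nrow(cand), 3)
  for (i in seq_len(nrow(cand))) {
    c0 <- cand[i, ]
    lo <- pmax(1L, c0 - window_vox); hi <- pmin(d, c0 + window_vox)
    sub <- vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    wsum <- sum(sub)
    idx <- list(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3])
    ctr <- vapply(1:3, function(a) {
      marg <- apply(sub, a, sum)
      sum(idx[[a]] * marg) / wsum
    }, numeric(1))
    out[i, ] <- origin + (ctr - 0.5) * voxel_size_um
  }
  data.frame(x_um = out[, 1], y_um = out[, 2], z_um = out[, 3],
             intensity = sm[cand])
}
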