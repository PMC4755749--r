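# 3D geometry primitives shared by every analysis stage.
# All coordinates are in micrometres, all angles in degrees.

#' Signal a validation error
#'
#' Errors of class `meioarch_validation_error` map to exit code 2 in the
#' command-line interface; `meioarch_infeasible_error` (infeasible generator
#' parameter combinations) maps to exit code 3.
#'
#' @param msg message
#' @param class error class
#' @keywords internal
ma_stop <- function(msg, class = "meioarch_validation_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Construct a 3D point
#'
#' @param x,y,z coordinates in micrometres; must be finite.
#' @return named numeric vector of length 3.
#' @examples
#' pt3(1, 2, 3)
#' @export
pt3 <- function(x, y, z) {
  p <- c(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  if (!all(is.finite(p))) ma_stop("pt3: coordinates must be finite")
  p
}

#' Euclidean distance between two 3D points
#'
#' Distances between kinetochore centres are plain Euclidean norms of the
#' centre coordinates (the Pythagorean theorem in three dimensions).
#'
#' @param p,q numeric vectors of length 3 (micrometres).
#' @return distance in micrometres.
#' @examples
#' dist3(c(0, 0, 0), c(3, 4, 0)) # 5
#' @export
dist3 <- function(p, q) {
  if (length(p) != 3L || length(q) != 3L) ma_stop("dist3: points must have length 3")
  if (!all(is.finite(p)) || !all(is.finite(q))) ma_stop("dist3: non-finite input")
  sqrt(sum((p - q)^2))
}

#' Normalize a vector to unit length
#' @param v numeric length-3 vector.
#' @keywords internal
unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (!is.finite(n) || n == 0) ma_stop("unit3: zero or non-finite vector")
  v / n
}

#' Angle between two undirected axes
#'
#' Returns the acute angle between the lines spanned by `u` and `v`,
#' in degrees within \[0, 90\]. The result is invariant to the sign of
#' either direction vector, which is the correct notion for pair axes,
#' bivalent axes and the spindle axis (none of which carries a polarity).
#'
#' @param u,v non-zero direction vectors of length 3.
#' @return angle in degrees in \[0, 90\].
#' @examples
#' axis_angle(c(1, 0, 0), c(0, 1, 0)) # 90
#' axis_angle(c(1, 0, 0), c(-1, 0, 0)) # 0
#' @export
axis_angle <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (!is.finite(nu) || !is.finite(nv) || nu == 0 || nv == 0)
    ma_stop("axis_angle: zero or non-finite direction")
  ca <- abs(sum(u * v)) / (nu * nv)
  ca <- min(1, max(-1, ca))
  acos(ca) * 180 / pi
}

# Row-wise variant used by the classifiers: u is an n x 3 matrix, v a single
# axis. NA rows propagate NA angles.
axis_angle_rows <- function(u, v) {
  nv <- sqrt(sum(v^2))
  nu <- sqrt(rowSums(u^2))
  ca <- abs(as.vector(u %*% v)) / (nu * nv)
  ca <- pmin(1, pmax(-1, ca))
  acos(ca) * 180 / pi
}

#' Group spots of one bivalent into sister pairs
#'
#' Within a bivalent, the two most proximal kinetochores are defined as a
#' sister pair; the remaining two spots form the second pair. Spots that were
#' detected as a single merged signal (sub-resolution sisters) are taken as
#' complete one-spot pairs directly. When two candidate closest pairs tie in
#' distance (within 1e-9 um) the pair with the lexicographically smallest
#' tuple of spot ids is chosen, which makes the assignment deterministic.
#'
#' @param spots data.frame with columns `spot_id`, `x_um`, `y_um`, `z_um`,
#'   `radius_um`, `merged` (logical) and optionally `homolog_id`; all rows
#'   must belong to a single bivalent. Two unmerged spots are treated as one
#'   pair (the univalent case).
#' @return data.frame with one row per pair: member spot ids, `n_spots`,
#'   `distance_um` (0 for one-spot pairs), unit pair-axis components
#'   (`ax`,`ay`,`az`; NA for one-spot pairs), pair centroid (`cx`,`cy`,`cz`)
#'   and mean radius.
#' @export
assign_sister_pairs <- function(spots) {
  if (nrow(spots) == 0L) ma_stop("assign_sister_pairs: no spots")
  xyz <- as.matrix(spots[, c("x_um", "y_um", "z_um")])
  if (!all(is.finite(xyz))) ma_stop("assign_sister_pairs: non-finite coordinates")
  merged <- if ("merged" %in% names(spots)) isTRUE_vec(spots$merged) else rep(FALSE, nrow(spots))

  pairs <- list()
  add_pair <- function(idx) {
    n <- length(idx)
    if (n == 1L) {
      pairs[[length(pairs) + 1L]] <<- list(
        spot_id_1 = spots$spot_id[idx], spot_id_2 = NA_character_,
        n_spots = 1L, distance_um = 0,
        ax = NA_real_, ay = NA_real_, az = NA_real_,
        cx = xyz[idx, 1], cy = xyz[idx, 2], cz = xyz[idx, 3],
        radius_um = spots$radius_um[idx])
    } else {
      d <- sqrt(sum((xyz[idx[1], ] - xyz[idx[2], ])^2))
      axv <- if (d > 0) (xyz[idx[2], ] - xyz[idx[1], ]) / d else c(NA_real_, NA_real_, NA_real_)
      ctr <- colMeans(xyz[idx, , drop = FALSE])
      ids <- sort(spots$spot_id[idx])
      pairs[[length(pairs) + 1L]] <<- list(
        spot_id_1 = ids[1], spot_id_2 = ids[2],
        n_spots = 2L, distance_um = d,
        ax = axv[1], ay = axv[2], az = axv[3],
        cx = ctr[1], cy = ctr[2], cz = ctr[3],
        radius_um = mean(spots$radius_um[idx]))
    }
  }

  for (i in which(merged)) add_pair(i)
  rest <- which(!merged)
  if (length(rest) %% 2L != 0L)
    ma_stop("assign_sister_pairs: odd number of unmerged spots")
  if (length(rest) > 4L)
    ma_stop("assign_sister_pairs: more than 4 unmerged spots in one bivalent")
  if (length(rest) == 2L) {
    add_pair(rest)
  } else if (length(rest) == 4L) {
    cand <- utils::combn(rest, 2L)
    dd <- apply(cand, 2L, function(ij) sqrt(sum((xyz[ij[1], ] - xyz[ij[2], ])^2)))
    best <- which(dd <= min(dd) + 1e-9)
    if (length(best) > 1L) {
      keys <- vapply(best, function(k) {
        paste(sort(spots$spot_id[cand[, k]]), collapse = "\r")
      }, character(1))
      best <- best[order(keys)][1L]
    }
    first <- cand[, best[1L]]
    second <- setdiff(rest, first)
    add_pair(first)
    add_pair(second)
  }
  do.call(rbind, lapply(pairs, function(p) as.data.frame(p, stringsAsFactors = FALSE)))
}

# treat NA as FALSE
isTRUE_vec <- function(x) !is.na(x) & x

# Rotate unit vector v by `deg` degrees within the plane spanned by v and w
# (w need not be orthogonal to v). Used by the generator to jitter axes.
rotate_towards <- function(v, w, deg) {
  v <- unit3(v)
  w_perp <- w - sum(w * v) * v
  n <- sqrt(sum(w_perp^2))
  if (n < 1e-12) return(v)
  w_perp <- w_perp / n
  th <- deg * pi / 180
  unit3(cos(th) * v + sin(th) * w_perp)
}

# Any unit vector orthogonal to v.
perp_unit <- function(v) {
  v <- unit3(v)
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit3(ref - sum(ref * v) * v)
}
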