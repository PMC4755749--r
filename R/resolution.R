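# Optical-resolution model: sub-resolution spot merging and the four-way
# sister-kinetochore configuration classifier.

#' Anisotropic optical-resolution model
#'
#' Confocal stacks resolve structure much better laterally than axially, so
#' whether two sister kinetochores are detected as one or two spots depends
#' on the direction of their separation. Two spots merge into a single
#' detection when their displacement `(dx, dy, dz)` lies inside the
#' resolution ellipsoid, i.e. when
#' `(dx/m_l)^2 + (dy/m_l)^2 + (dz/m_a)^2 < 1`
#' with `m_l` the lateral and `m_a` the axial merge distance.
#'
#' Defaults follow the acquisition sampling of high-resolution kinetochore
#' stacks (300 nm lateral, 650 nm axial).
#'
#' @param merge_distance_lateral lateral merge distance in um (> 0).
#' @param merge_distance_axial axial (z) merge distance in um (> 0).
#' @param overlap_factor fraction of the summed spot radii below which two
#'   resolved spots are called `overlapping` rather than `distinct`;
#'   dimensionless in (0, 1).
#' @return object of class `resolution_model`.
#' @export
resolution_model <- function(merge_distance_lateral = 0.30,
                             merge_distance_axial = 0.65,
                             overlap_factor = 0.6) {
  if (merge_distance_lateral <= 0 || merge_distance_axial <= 0)
    ma_stop("resolution_model: merge distances must be > 0")
  if (overlap_factor <= 0 || overlap_factor >= 1)
    ma_stop("resolution_model: overlap_factor must be in (0, 1)")
  structure(list(merge_distance_lateral = merge_distance_lateral,
                 merge_distance_axial = merge_distance_axial,
                 overlap_factor = overlap_factor),
            class = "resolution_model")
}

# Squared ellipsoidal merge norm; < 1 means the displacement is unresolved.
merge_norm2 <- function(dx, dy, dz, model) {
  (dx / model$merge_distance_lateral)^2 +
    (dy / model$merge_distance_lateral)^2 +
    (dz / model$merge_distance_axial)^2
}

#' Collapse sub-resolution spots into merged detections
#'
#' Emulates what a spot detector sees: within each bivalent, pairs of spots
#' whose separation falls inside the resolution ellipsoid are iteratively
#' replaced (closest first) by a single merged detection at their
#' intensity-weighted midpoint. Merging is restricted to spots sharing
#' `oocyte_id` and `bivalent_id`; the generator keeps distinct bivalents
#' farther apart than the resolution limit, so cross-bivalent merging never
#' arises in practice.
#'
#' @param spots data.frame with columns `oocyte_id`, `spot_id`,
#'   `bivalent_id`, `homolog_id`, `x_um`, `y_um`, `z_um`, `radius_um`,
#'   `merged`.
#' @param model a [resolution_model()].
#' @return data.frame of detected spots; merged detections carry
#'   `merged = TRUE`, a combined id and the majority homolog label (NA when
#'   the members disagree).
#' @export
apply_resolution <- function(spots, model = resolution_model()) {
  if (nrow(spots) == 0L) return(spots)
  key <- paste(spots$oocyte_id, spots$bivalent_id, sep = "\r")
  out <- lapply(split(seq_len(nrow(spots)), key), function(idx) {
    g <- spots[idx, , drop = FALSE]
    repeat {
      n <- nrow(g)
      if (n < 2L) break
      best <- NULL; best_norm <- 1
      for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
        nn <- merge_norm2(g$x_um[i] - g$x_um[j], g$y_um[i] - g$y_um[j],
                          g$z_um[i] - g$z_um[j], model)
        if (nn < best_norm) { best_norm <- nn; best <- c(i, j) }
      }
      if (is.null(best)) break
      i <- best[1]; j <- best[2]
      w <- g$radius_um[c(i, j)]^3          # intensity ~ volume
      w <- w / sum(w)
      d <- sqrt((g$x_um[i] - g$x_um[j])^2 + (g$y_um[i] - g$y_um[j])^2 +
                  (g$z_um[i] - g$z_um[j])^2)
      m <- g[i, , drop = FALSE]
      m$x_um <- w[1] * g$x_um[i] + w[2] * g$x_um[j]
      m$y_um <- w[1] * g$y_um[i] + w[2] * g$y_um[j]
      m$z_um <- w[1] * g$z_um[i] + w[2] * g$z_um[j]
      m$radius_um <- max(g$radius_um[c(i, j)]) + d / 2
      m$merged <- TRUE
      m$spot_id <- paste(sort(g$spot_id[c(i, j)]), collapse = "+")
      hi <- g$homolog_id[c(i, j)]
      m$homolog_id <- if (length(unique(hi)) == 1L) hi[1] else NA_integer_
      g <- rbind(m, g[-c(i, j), , drop = FALSE])
    }
    g
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$oocyte_id, res$bivalent_id, res$spot_id), , drop = FALSE]
}

CONFIG_LEVELS <- c("indistinguishable", "overlapping", "distinct", "separated")

#' Classify a sister-pair configuration
#'
#' One detected spot is `indistinguishable` (its separation is recorded as
#' 0 um). With two detected spots of radii `r1`, `r2` at centre distance
#' `d`: `d < f * (r1 + r2)` is `overlapping` (markedly stretched single
#' signal), `f * (r1 + r2) <= d <= r1 + r2` is `distinct` (touching but
#' discrete), and `d > r1 + r2` is `separated` (non-touching), where `f` is
#' the model's `overlap_factor`. All arguments are vectorized.
#'
#' @param n_spots 1 or 2 detected spots per pair.
#' @param distance_um centre-to-centre distance in um (ignored for 1 spot).
#' @param r1,r2 spot radii in um.
#' @param model a [resolution_model()].
#' @return character vector of categories.
#' @export
classify_configuration <- function(n_spots, distance_um, r1, r2,
                                   model = resolution_model()) {
  if (any(n_spots > 2L)) ma_stop("classify_configuration: more than 2 spots in a pair")
  touch <- r1 + r2
  lo <- model$overlap_factor * touch
  out <- ifelse(n_spots == 1L, "indistinguishable",
         ifelse(distance_um < lo, "overlapping",
         ifelse(distance_um <= touch, "distinct", "separated")))
  out
}

#' Is a configuration category "split" (two discrete spots)?
#'
#' Two-discrete-spot categories are `distinct` and `separated`; the
#' `overlapping` category is a single stretched signal and does not count
#' as split. The split definition feeds the headline two-discrete-spot
#' fractions and is fixed here package-wide.
#'
#' @param category character vector of configuration categories.
#' @return logical vector.
#' @export
is_split <- function(category) {
  bad <- setdiff(unique(category[!is.na(category)]), CONFIG_LEVELS)
  if (length(bad)) ma_stop(paste("is_split: unknown category", bad[1]))
  category %in% c("distinct", "separated")
}

#' Angular thresholds for rotation, twist and biorientation calls
#'
#' The source observations describe orientations qualitatively
#' ("perpendicular to the spindle axis", a homolog rotation of "about 70
#' degrees"); operational cutoffs are required to make the calls
#' reproducible. Axes within `parallel_max` of a reference are treated as
#' parallel, axes beyond `perpendicular_min` as perpendicular, and the band
#' in between is an explicit ambiguity zone rather than a forced call.
#'
#' @param parallel_max max angle (deg) to count as parallel; default 30.
#' @param perpendicular_min min angle (deg) to count as perpendicular;
#'   default 60.
#' @param twist_min min inter-pair-axis angle (deg) for a twisted call;
#'   default 50, below the ~70 degree homolog rotation seen in twisted
#'   bivalents.
#' @return object of class `angle_thresholds`.
#' @export
angle_thresholds <- function(parallel_max = 30, perpendicular_min = 60,
                             twist_min = 50) {
  if (!(parallel_max > 0 && parallel_max < perpendicular_min &&
        perpendicular_min <= 90))
    ma_stop("angle_thresholds: need 0 < parallel_max < perpendicular_min <= 90")
  if (!(twist_min > parallel_max && twist_min <= 90))
    ma_stop("angle_thresholds: twist_min must lie in (parallel_max, 90]")
  structure(list(parallel_max = parallel_max,
                 perpendicular_min = perpendicular_min,
                 twist_min = twist_min),
            class = "angle_thresholds")
}
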