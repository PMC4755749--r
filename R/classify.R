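# Classification of kinetochore-microtubule attachment, bivalent rotation,
# twist, arm cohesion / univalents, and anaphase segregation outcomes.

#' Classify the k-fiber topology of one sister pair
#'
#' Counts the discrete cold-stable fibre bundles contacting either sister of
#' a pair and types multi-fibre attachments: two bundles that share a trunk
#' before branching are type `C`; two separate bundles running in parallel
#' to the same pole-endpoint neighbourhood are type `A`; separate bundles
#' from distant locations on the spindle (including opposite poles) are type
#' `B`.
#'
#' @param fibers data.frame of fibre records for one pair, with columns
#'   `contact` (`end_on`/`lateral`), `pole_index` (0/1), start and end
#'   coordinates `start_x_um`..`end_z_um` and `trunk_group` (shared id for
#'   branches of one trunk, else NA).
#' @param thresholds an [angle_thresholds()]; `parallel_max` bounds the
#'   inter-fibre angle for type `A`.
#' @param neighborhood_radius um; max pole-endpoint spread for type `A`.
#' @return list with `n_fibers` and `fiber_type` in
#'   `c("A","B","C","single","none")`.
#' @export
classify_fiber_topology <- function(fibers, thresholds = angle_thresholds(),
                                    neighborhood_radius = 2.0) {
  n <- if (is.null(fibers)) 0L else nrow(fibers)
  if (n == 0L) return(list(n_fibers = 0L, fiber_type = "none"))
  if (n == 1L) return(list(n_fibers = 1L, fiber_type = "single"))
  tg <- fibers$trunk_group
  if (all(!is.na(tg)) && length(unique(tg)) == 1L)
    return(list(n_fibers = n, fiber_type = "C"))
  ends <- as.matrix(fibers[, c("end_x_um", "end_y_um", "end_z_um")])
  starts <- as.matrix(fibers[, c("start_x_um", "start_y_um", "start_z_um")])
  same_pole <- length(unique(fibers$pole_index)) == 1L
  spread <- max(stats::dist(ends))
  dirs <- ends - starts
  max_ang <- 0
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n))
    max_ang <- max(max_ang, axis_angle(dirs[i, ], dirs[j, ]))
  if (same_pole && spread <= neighborhood_radius &&
      max_ang <= thresholds$parallel_max)
    list(n_fibers = n, fiber_type = "A")
  else
    list(n_fibers = n, fiber_type = "B")
}

#' Classify the kinetochore-microtubule attachment mode of one pair
#'
#' Only end-on fibres reaching opposite spindle poles qualify a pair as
#' merotelic; a pair with any lateral (side-wall) contact that is not
#' merotelic by end-on fibres is reported as lateral, which folds
#' lateral-merotelic contacts into the lateral group. End-on fibres to a
#' single pole are amphitelic; no fibres means unattached.
#'
#' @param fibers data.frame of fibre records for one pair (see
#'   [classify_fiber_topology()]); may be NULL or empty.
#' @return one of `"amphitelic"`, `"merotelic"`, `"lateral"`,
#'   `"unattached"`.
#' @export
classify_attachment_mode <- function(fibers) {
  n <- if (is.null(fibers)) 0L else nrow(fibers)
  if (n == 0L) return("unattached")
  endon_poles <- unique(fibers$pole_index[fibers$contact == "end_on"])
  if (length(endon_poles) >= 2L) return("merotelic")
  if (any(fibers$contact == "lateral")) return("lateral")
  if (length(endon_poles) == 1L) return("amphitelic")
  "unattached"
}

#' Score bivalent rotation relative to the spindle axis
#'
#' The bivalent axis is the line joining the two sister-pair centroids. With
#' `beta` the bivalent-axis/spindle-axis angle and `pi1`, `pi2` the
#' pair-axis/spindle-axis angles, a bivalent is `fully_inverted` when it
#' lies perpendicular to the spindle with both pairs of sisters facing
#' opposite poles (`beta >= perpendicular_min`, both `pi <= parallel_max`),
#' `half_inverted` when exactly one pair faces opposite poles
#' (`pi <= parallel_max`) while the other faces a single pole
#' (`pi >= perpendicular_min`), `in_axis` when aligned with the spindle with
#' both pairs facing single poles, and `ambiguous` otherwise. When one pair
#' is an unresolved single spot its axis is undefined; the call is then made
#' from the bivalent axis plus the remaining pair and flagged low
#' confidence.
#'
#' @param pair1,pair2 lists with elements `axis` (unit vector or NA) and
#'   `centroid` (length-3 numeric).
#' @param spindle_axis unit direction of the spindle pole-to-pole axis.
#' @param thresholds an [angle_thresholds()].
#' @return list: `label`, `bivalent_axis_deg`, `pair_axis_deg` (length 2,
#'   NA when undefined), `low_confidence`.
#' @export
score_rotation <- function(pair1, pair2, spindle_axis,
                           thresholds = angle_thresholds()) {
  b <- pair2$centroid - pair1$centroid
  if (sqrt(sum(b^2)) < 1e-9)
    ma_stop("score_rotation: coincident pair centroids, bivalent axis undefined")
  beta <- axis_angle(b, spindle_axis)
  p <- c(
    if (all(is.finite(pair1$axis))) axis_angle(pair1$axis, spindle_axis) else NA_real_,
    if (all(is.finite(pair2$axis))) axis_angle(pair2$axis, spindle_axis) else NA_real_
  )
  pm <- thresholds$parallel_max; qm <- thresholds$perpendicular_min
  n_def <- sum(!is.na(p))
  low <- n_def < 2L
  label <- "ambiguous"
  if (n_def == 2L) {
    if (beta >= qm && all(p <= pm)) label <- "fully_inverted"
    else if (sum(p <= pm) == 1L && sum(p >= qm) == 1L) label <- "half_inverted"
    else if (beta <= pm && all(p >= qm)) label <- "in_axis"
  } else if (n_def == 1L) {
    pk <- p[!is.na(p)]
    if (beta <= pm && pk >= qm) label <- "in_axis"
    else if (beta >= qm && pk <= pm) label <- "fully_inverted"
  }
  list(label = label, bivalent_axis_deg = beta, pair_axis_deg = p,
       low_confidence = low)
}

#' Score bivalent twist from the two sister-pair axes
#'
#' A twisted bivalent has one homolog rotated by roughly 70 degrees about
#' the bivalent axis, so its two pair axes sit perpendicular to each other
#' instead of in parallel. The pair-axis angle can only be measured when
#' both pairs are resolved into two discrete spots, so bivalents with an
#' indistinguishable or overlapping pair are `not_scorable`.
#'
#' @param axis1,axis2 pair-axis unit vectors (NA when undefined).
#' @param both_split logical; TRUE when both pairs are in a split
#'   (distinct/separated) configuration.
#' @param thresholds an [angle_thresholds()]; `twisted` needs an angle of at
#'   least `twist_min`, `undistorted` at most `parallel_max`; the band in
#'   between is recorded as undistorted with `ambiguous = TRUE`.
#' @return list: `label` (`twisted`/`undistorted`/`not_scorable`),
#'   `angle_deg`, `ambiguous`.
#' @export
score_twist <- function(axis1, axis2, both_split,
                        thresholds = angle_thresholds()) {
  if (!isTRUE(both_split) || !all(is.finite(axis1)) || !all(is.finite(axis2)))
    return(list(label = "not_scorable", angle_deg = NA_real_, ambiguous = FALSE))
  tau <- axis_angle(axis1, axis2)
  if (tau >= thresholds$twist_min)
    list(label = "twisted", angle_deg = tau, ambiguous = FALSE)
  else if (tau <= thresholds$parallel_max)
    list(label = "undistorted", angle_deg = tau, ambiguous = FALSE)
  else
    list(label = "undistorted", angle_deg = tau, ambiguous = TRUE)
}

#' Detect the arm-cohesion state of a bivalent from its chromatin envelopes
#'
#' The surface gap between the two homolog chromatin masses is
#' `g = |c1 - c2| - (e1 + e2)` (centroid distance minus summed extents).
#' Touching or overlapping chromatin (`g <= 0`) is `intact`; a positive gap
#' up to `max_gap` with the unit still held together is `weak_gap` (weakly
#' associated homologs under shared tension); separations beyond `max_gap`
#' indicate a fully disintegrated bivalent, i.e. two univalents.
#'
#' @param centroid1,centroid2 chromatin centroids (length-3, um).
#' @param extent1,extent2 chromatin half-extents along the bivalent axis
#'   (um).
#' @param max_gap largest gap (um) compatible with a still-associated
#'   bivalent; default 3.2, the largest gap observed between homologs that
#'   remained under shared tension.
#' @return list: `state` (`intact`/`weak_gap`/`disintegrated`), `gap_um`.
#' @export
detect_cohesion_state <- function(centroid1, extent1, centroid2, extent2,
                                  max_gap = 3.2) {
  g <- dist3(centroid1, centroid2) - (extent1 + extent2)
  if (g <= 0) list(state = "intact", gap_um = 0)
  else if (g <= max_gap) list(state = "weak_gap", gap_um = g)
  else list(state = "disintegrated", gap_um = g)
}

#' Check whole-oocyte chromosome accounting
#'
#' A meiosis-I human oocyte carries 46 chromosomes, so twice the number of
#' bivalents plus the number of univalents must equal 46 and the number of
#' segregation units must lie in 23..46. Oocytes with more than 23 units
#' necessarily contain univalents.
#'
#' @param n_bivalents,n_univalents unit counts.
#' @param n_chromosomes expected chromosome count; default 46.
#' @return list: `n_units`, `n_chromosomes`, `has_univalents`.
#' @export
check_chromosome_accounting <- function(n_bivalents, n_univalents,
                                        n_chromosomes = 46L) {
  total <- 2L * n_bivalents + n_univalents
  if (total != n_chromosomes)
    ma_stop(sprintf(
      "chromosome accounting failed: 2*%d bivalents + %d univalents = %d chromosomes, expected %d",
      n_bivalents, n_univalents, total, n_chromosomes))
  n_units <- n_bivalents + n_univalents
  if (n_units < n_chromosomes / 2 || n_units > n_chromosomes)
    ma_stop(sprintf("unit count %d outside [%d, %d]", n_units,
                    as.integer(n_chromosomes / 2), n_chromosomes))
  list(n_units = n_units, n_chromosomes = total,
       has_univalents = n_units > n_chromosomes / 2)
}

#' Score biorientation of a univalent
#'
#' A univalent is bioriented when its sister kinetochores face opposite
#' spindle poles: the pair axis lies within `parallel_max` of the spindle
#' axis (boundary inclusive) and end-on fibres reach both poles. An
#' unresolved (merged) pair cannot be scored and returns FALSE with a
#' low-confidence flag.
#'
#' @param pair_axis unit pair-axis vector or NA.
#' @param spindle_axis unit spindle axis.
#' @param fibers fibre records for the univalent's pair (may be empty).
#' @param thresholds an [angle_thresholds()].
#' @return list: `bioriented` (logical), `low_confidence`.
#' @export
univalent_biorientation <- function(pair_axis, spindle_axis, fibers,
                                    thresholds = angle_thresholds()) {
  if (!all(is.finite(pair_axis)))
    return(list(bioriented = FALSE, low_confidence = TRUE))
  ang <- axis_angle(pair_axis, spindle_axis)
  n <- if (is.null(fibers)) 0L else nrow(fibers)
  poles <- if (n > 0L) unique(fibers$pole_index[fibers$contact == "end_on"]) else integer(0)
  list(bioriented = ang <= thresholds$parallel_max && length(poles) >= 2L,
       low_confidence = FALSE)
}

#' Predict the anaphase-I segregation outcome of a bivalent
#'
#' Deterministic outcome table. An in-axis bivalent disjoins normally (one
#' chromosome to each pole). An inverted (half or fully rotated) bivalent
#' with centromeric cohesion intact in both sister pairs is pulled from both
#' sides and lags; with cohesion compromised in one pair it disintegrates
#' into one univalent plus two sister chromatids; with cohesion compromised
#' in both pairs it disintegrates into four individual chromatids, leaving
#' two non-sister chromatids of different parental origin in the egg
#' (reverse segregation). Each chromosome product counts two chromatids, so
#' products always total four chromatids.
#'
#' @param orientation `"in_axis"`, `"half_inverted"` or `"fully_inverted"`.
#' @param cohesion_states length-2 character, each `"intact"` or
#'   `"compromised"` (one entry per sister pair).
#' @return list: `orientation`, `centromeric_cohesion`,
#'   `predicted_products` (multiset of `"chromosome"`/`"chromatid"`),
#'   `predicted_event`.
#' @export
predict_segregation_outcome <- function(orientation, cohesion_states) {
  ok_orient <- c("in_axis", "half_inverted", "fully_inverted")
  if (!(length(orientation) == 1L && orientation %in% ok_orient))
    ma_stop("predict_segregation_outcome: unknown orientation")
  if (length(cohesion_states) != 2L ||
      !all(cohesion_states %in% c("intact", "compromised")))
    ma_stop("predict_segregation_outcome: cohesion_states must be two of intact/compromised")
  n_comp <- sum(cohesion_states == "compromised")
  if (orientation == "in_axis") {
    event <- "normal_disjunction"
    products <- c("chromosome", "chromosome")
  } else if (n_comp == 0L) {
    event <- "lagging"
    products <- c("chromosome", "chromosome")
  } else if (n_comp == 1L) {
    event <- "univalent_plus_chromatids"
    products <- c("chromosome", "chromatid", "chromatid")
  } else {
    event <- "reverse_segregation"
    products <- c("chromatid", "chromatid", "chromatid", "chromatid")
  }
  list(orientation = orientation, centromeric_cohesion = cohesion_states,
       predicted_products = products, predicted_event = event)
}

#' Count chromatids in a predicted product multiset
#' @param products character vector of `"chromosome"`/`"chromatid"`.
#' @return integer chromatid count (a chromosome carries two chromatids).
#' @export
count_chromatids <- function(products) {
  sum(ifelse(products == "chromosome", 2L, 1L))
}

# ---------------------------------------------------------------------------
# Cohort-level orchestration

spindle_geom <- function(srow) {
  p0 <- c(srow$pole0_x_um, srow$pole0_y_um, srow$pole0_z_um)
  p1 <- c(srow$pole1_x_um, srow$pole1_y_um, srow$pole1_z_um)
  if (all(p0 == p1)) ma_stop("spindle poles coincide")
  list(pole0 = p0, pole1 = p1, axis = unit3(p1 - p0),
       length = dist3(p0, p1), center = (p0 + p1) / 2)
}

#' Classify every unit of a simulated or imported cohort
#'
#' Runs the full per-oocyte analysis on detected spots: sister-pair
#' assignment, configuration classification, pole-proximity exclusion,
#' fibre topology and attachment mode, bivalent rotation and twist,
#' arm-cohesion state, univalent identification with 46-chromosome
#' accounting, and univalent biorientation.
#'
#' @param cohort a `meioarch_cohort` (see [simulate_cohort()]) or a list
#'   with elements `spots`, `fibers`, `chromatin`, `spindles`.
#' @param thresholds an [angle_thresholds()].
#' @param resolution a [resolution_model()] (used for configuration
#'   boundaries).
#' @param at_pole_fraction bivalents whose nearest pair centroid lies within
#'   this fraction of the spindle length from a pole are flagged `at_pole`
#'   and excluded from configuration statistics (they are not under
#'   tension); default 0.1.
#' @param max_gap see [detect_cohesion_state()].
#' @param neighborhood_radius see [classify_fiber_topology()].
#' @param proximal_max_um univalent partners closer than this are annotated
#'   `proximal`, otherwise `distal`; default 8.5.
#' @return list of data.frames: `pairs`, `bivalents`, `univalents`,
#'   `oocytes` (accounting per oocyte).
#' @export
classify_cohort <- function(cohort, thresholds = angle_thresholds(),
                            resolution = resolution_model(),
                            at_pole_fraction = 0.1, max_gap = 3.2,
                            neighborhood_radius = 2.0,
                            proximal_max_um = 8.5) {
  spots <- cohort$spots; fibers <- cohort$fibers
  chrom <- cohort$chromatin; spindles <- cohort$spindles
  if (!is.null(fibers) && nrow(fibers) > 0L) {
    unknown <- setdiff(fibers$spot_id, spots$spot_id)
    if (length(unknown))
      ma_stop(paste("fiber references unknown kinetochore:", unknown[1]))
  }
  pair_rows <- list(); biv_rows <- list(); uni_rows <- list(); oo_rows <- list()
  for (oid in unique(spots$oocyte_id)) {
    so <- spots[spots$oocyte_id == oid, , drop = FALSE]
    fo <- if (is.null(fibers)) NULL else fibers[fibers$oocyte_id == oid, , drop = FALSE]
    co <- if (is.null(chrom)) NULL else chrom[chrom$oocyte_id == oid, , drop = FALSE]
    srow <- spindles[spindles$oocyte_id == oid, , drop = FALSE]
    if (nrow(srow) != 1L) ma_stop(paste("missing spindle for oocyte", oid))
    sp <- spindle_geom(srow)
    fib_by_spot <- if (!is.null(fo) && nrow(fo) > 0L)
      split(seq_len(nrow(fo)), fo$spot_id) else list()

    biv_ids <- unique(so$bivalent_id)
    n_disint <- 0L
    for (bid in biv_ids) {
      sb <- so[so$bivalent_id == bid, , drop = FALSE]
      prs <- assign_sister_pairs(sb)
      np <- nrow(prs)
      # per-pair member radii for configuration boundaries
      r1 <- numeric(np); r2 <- numeric(np); hom <- integer(np)
      member_ids <- vector("list", np)
      for (k in seq_len(np)) {
        ids <- c(prs$spot_id_1[k], prs$spot_id_2[k])
        ids <- ids[!is.na(ids)]
        member_ids[[k]] <- ids
        rr <- sb$radius_um[match(ids, sb$spot_id)]
        r1[k] <- rr[1]; r2[k] <- if (length(rr) > 1L) rr[2] else rr[1]
        hh <- unique(sb$homolog_id[match(ids, sb$spot_id)])
        hom[k] <- if (length(hh) == 1L && !is.na(hh)) hh else NA_integer_
      }
      config <- classify_configuration(prs$n_spots, prs$distance_um, r1, r2,
                                       resolution)
      split_flag <- is_split(config)

      ctr <- as.matrix(prs[, c("cx", "cy", "cz")])
      d_pole <- pmin(sqrt(rowSums(sweep(ctr, 2, sp$pole0)^2)),
                     sqrt(rowSums(sweep(ctr, 2, sp$pole1)^2)))
      at_pole <- any(d_pole <= at_pole_fraction * sp$length)

      # cohesion from chromatin envelopes (when available)
      coh <- list(state = NA_character_, gap_um = NA_real_)
      cb <- if (!is.null(co)) co[co$bivalent_id == bid, , drop = FALSE] else NULL
      if (!is.null(cb) && nrow(cb) == 2L) {
        cb <- cb[order(cb$homolog_id), , drop = FALSE]
        coh <- detect_cohesion_state(
          c(cb$cx_um[1], cb$cy_um[1], cb$cz_um[1]), cb$extent_um[1],
          c(cb$cx_um[2], cb$cy_um[2], cb$cz_um[2]), cb$extent_um[2],
          max_gap = max_gap)
      }
      disint <- identical(coh$state, "disintegrated")
      if (disint) n_disint <- n_disint + 1L
      unit_type <- if (disint) "univalent" else "bivalent"

      # per-pair fibre classification
      n_fib <- integer(np); ftype <- character(np); mode <- character(np)
      pair_fibs <- vector("list", np)
      for (k in seq_len(np)) {
        ridx <- unlist(fib_by_spot[member_ids[[k]]], use.names = FALSE)
        pf <- if (length(ridx)) fo[ridx, , drop = FALSE] else NULL
        pair_fibs[[k]] <- pf
        topo <- classify_fiber_topology(pf, thresholds, neighborhood_radius)
        n_fib[k] <- topo$n_fibers; ftype[k] <- topo$fiber_type
        mode[k] <- classify_attachment_mode(pf)
      }

      axes <- as.matrix(prs[, c("ax", "ay", "az")])
      pair_ids <- paste0(bid, ".", seq_len(np))
      pax_deg <- vapply(seq_len(np), function(k) {
        if (all(is.finite(axes[k, ]))) axis_angle(axes[k, ], sp$axis) else NA_real_
      }, numeric(1))

      # bivalent-level scores (only meaningful with two pairs)
      rot <- list(label = NA_character_, bivalent_axis_deg = NA_real_,
                  pair_axis_deg = c(NA_real_, NA_real_), low_confidence = NA)
      twi <- list(label = NA_character_, angle_deg = NA_real_, ambiguous = FALSE)
      if (np == 2L && !disint && !at_pole) {
        rot <- score_rotation(
          list(axis = axes[1, ], centroid = ctr[1, ]),
          list(axis = axes[2, ], centroid = ctr[2, ]),
          sp$axis, thresholds)
        twi <- score_twist(axes[1, ], axes[2, ], all(split_flag), thresholds)
      }

      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        oocyte_id = oid, bivalent_id = bid, pair_id = pair_ids,
        homolog_id = hom,
        spot_id_1 = prs$spot_id_1, spot_id_2 = prs$spot_id_2,
        n_spots = prs$n_spots, distance_um = prs$distance_um,
        report_distance_um = ifelse(config %in% c("indistinguishable", "overlapping"),
                                    0, prs$distance_um),
        configuration = config, split = split_flag,
        unit_type = unit_type, excluded_at_pole = at_pole,
        cx = ctr[, 1], cy = ctr[, 2], cz = ctr[, 3],
        ax = axes[, 1], ay = axes[, 2], az = axes[, 3],
        pair_axis_spindle_deg = pax_deg,
        n_fibers = n_fib, fiber_type = ftype, attach_mode = mode,
        stringsAsFactors = FALSE)

      biv_rows[[length(biv_rows) + 1L]] <- data.frame(
        oocyte_id = oid, bivalent_id = bid, at_pole = at_pole,
        cohesion_state = coh$state, gap_um = coh$gap_um,
        unit_type = unit_type,
        rotation = rot$label,
        rotation_low_confidence = rot$low_confidence,
        bivalent_axis_deg = rot$bivalent_axis_deg,
        pair1_axis_deg = rot$pair_axis_deg[1],
        pair2_axis_deg = rot$pair_axis_deg[2],
        twist = twi$label, twist_angle_deg = twi$angle_deg,
        twist_ambiguous = twi$ambiguous,
        stringsAsFactors = FALSE)

      if (disint && np == 2L) {
        part_dist <- dist3(ctr[1, ], ctr[2, ])
        for (k in seq_len(np)) {
          bo <- univalent_biorientation(axes[k, ], sp$axis, pair_fibs[[k]],
                                        thresholds)
          uni_rows[[length(uni_rows) + 1L]] <- data.frame(
            oocyte_id = oid,
            univalent_id = paste0(bid, ".U", k),
            origin_bivalent_id = bid, pair_id = pair_ids[k],
            homolog_id = hom[k],
            position = if (part_dist <= proximal_max_um) "proximal" else "distal",
            bioriented = bo$bioriented,
            low_confidence = bo$low_confidence,
            stringsAsFactors = FALSE)
        }
      }
    }
    n_biv <- length(biv_ids) - n_disint
    n_uni <- 2L * n_disint
    acct <- check_chromosome_accounting(n_biv, n_uni)
    oo_rows[[length(oo_rows) + 1L]] <- data.frame(
      oocyte_id = oid, donor_age = srow$donor_age, stage = srow$stage,
      cold_treated = srow$cold_treated,
      n_bivalents = n_biv, n_univalents = n_uni,
      n_units = acct$n_units, n_chromosomes = acct$n_chromosomes,
      has_univalents = acct$has_univalents,
      n_spots_detected = nrow(so),
      stringsAsFactors = FALSE)
  }
  list(pairs = do.call(rbind, pair_rows),
       bivalents = do.call(rbind, biv_rows),
       univalents = if (length(uni_rows)) do.call(rbind, uni_rows) else
         data.frame(oocyte_id = character(0), univalent_id = character(0),
                    origin_bivalent_id = character(0), pair_id = character(0),
                    homolog_id = integer(0), position = character(0),
                    bioriented = logical(0), low_confidence = logical(0),
                    stringsAsFactors = FALSE),
       oocytes = do.call(rbind, oo_rows))
}

#' Identify univalents in one classified oocyte
#'
#' Convenience wrapper around the accounting check: takes the classified
#' tables of a single oocyte, verifies that twice the bivalent count plus
#' the univalent count equals 46, and returns the univalent records together
#' with the accounting report. Raises a validation error naming the
#' discrepancy when the accounting fails.
#'
#' @param classified result of [classify_cohort()], restricted to or
#'   containing the oocyte.
#' @param oocyte_id id of the oocyte to report on.
#' @return list: `univalents` (data.frame), `accounting` (list with
#'   `n_units`, `n_chromosomes`, `has_univalents`).
#' @export
identify_univalents <- function(classified, oocyte_id) {
  oo <- classified$oocytes[classified$oocytes$oocyte_id == oocyte_id, , drop = FALSE]
  if (nrow(oo) != 1L) ma_stop(paste("unknown oocyte", oocyte_id))
  acct <- check_chromosome_accounting(oo$n_bivalents, oo$n_univalents)
  uni <- classified$univalents[classified$univalents$oocyte_id == oocyte_id, ,
                               drop = FALSE]
  list(univalents = uni, accounting = acct)
}
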