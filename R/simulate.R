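# Seeded generator of synthetic meiosis-I spindle cohorts. Geometry is
# constructed so that, under the profile's resolution model, the sampled
# ground-truth labels are entailed by the spot/fibre/chromatin coordinates:
# a noise-free pipeline recovers every label exactly, and the default
# localization noise is small relative to the category margins. Sister
# separations are kept strictly below the inter-homolog centroid distance
# (validated in the profile), so closest-pair assignment is unambiguous.

derive_oocyte_seed <- function(profile_seed, index) {
  ((as.numeric(profile_seed) %% 2147483647) * 10007 + index * 7919) %%
    2147483629 + 1
}

runif_ball <- function(r) {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2)) * r * stats::runif(1)^(1 / 3)
}

# n points in a disc of radius R with a pairwise spacing floor, in 2D plate
# coordinates. Dart throwing; the default packing (23 in radius 5.5 with
# floor 1.5) always succeeds quickly.
place_on_plate <- function(n, radius, min_spacing, max_tries = 20000L) {
  pts <- matrix(NA_real_, n, 2)
  k <- 0L
  for (i in seq_len(max_tries)) {
    cand <- stats::runif(2, -radius, radius)
    if (sum(cand^2) > radius^2) next
    if (k > 0L) {
      dd <- sqrt(rowSums(sweep(pts[seq_len(k), , drop = FALSE], 2, cand)^2))
      if (any(dd < min_spacing)) next
    }
    k <- k + 1L
    pts[k, ] <- cand
    if (k == n) return(pts)
  }
  ma_stop("place_on_plate: could not satisfy the spacing floor",
          class = "meioarch_infeasible_error")
}

# In-plane perpendicular direction at angle phi (deg): cos(phi)*u + sin(phi)*w,
# where u is the in-imaging-plane perpendicular and w the optical (z) axis.
perp_axis <- function(u, w, phi_deg) {
  th <- phi_deg * pi / 180
  cos(th) * u + sin(th) * w
}

# simple growing row collector for homogeneous records
new_collector <- function(template, n_guess) {
  env <- new.env(parent = emptyenv())
  env$cols <- lapply(template, function(x) rep(x, n_guess))
  env$n <- 0L
  env$cap <- n_guess
  env
}
collect_row <- function(env, ...) {
  row <- list(...)
  if (env$n == env$cap) {
    env$cols <- lapply(env$cols, function(x) c(x, x))  # double capacity
    env$cap <- env$cap * 2L
  }
  env$n <- env$n + 1L
  i <- env$n
  for (nm in names(row)) env$cols[[nm]][i] <- row[[nm]]
  invisible(env)
}
collector_df <- function(env) {
  as.data.frame(lapply(env$cols, function(x) x[seq_len(env$n)]),
                stringsAsFactors = FALSE)
}

#' Simulate one meiosis-I oocyte
#'
#' Builds a bipolar spindle with its axis parallel to the imaging plane
#' (poles `spindle_length_um` apart), places 23 bivalent slots on the
#' metaphase plate with a lateral spacing floor, samples per-bivalent
#' disintegration, cohesion, rotation and twist states and per-pair
#' configuration, separation, attachment mode and fibre topology from the
#' profile, lays out kinetochore spots, chromatin envelopes and straight
#' k-fibre segments that entail those labels, applies Gaussian localization
#' noise and the optical-resolution merge, and returns the detected tables
#' together with a ground-truth table mirroring every classifier output.
#'
#' Geometric feasibility constraints are part of the stated world: twisted
#' bivalents rotate one pair axis ~70 degrees out of the imaging plane, so
#' that pair must be in the separated category to clear the (poorer) axial
#' resolution; half-inverted bivalents carry distinct-category pairs and
#' fully-inverted bivalents cap separated distances at 1.4 um so that
#' sister separations stay below cross-homolog spot distances.
#'
#' @param profile a [cohort_profile()].
#' @param seed integer seed for this oocyte.
#' @param oocyte_id identifier.
#' @return list of data.frames: `spots` (detected), `truth_spots`
#'   (noise-free ground truth positions), `fibers`, `chromatin`, `spindles`
#'   (one row), `truth_pairs`, `truth_bivalents`.
#' @export
simulate_oocyte <- function(profile, seed, oocyte_id = "O1") {
  set.seed(as.integer(seed %% 2147483647))
  pr <- profile
  age <- stats::runif(1, pr$age_range[1], pr$age_range[2])

  theta <- stats::runif(1, 0, 2 * pi)
  s <- c(cos(theta), sin(theta), 0)          # spindle axis, in imaging plane
  u <- c(-sin(theta), cos(theta), 0)         # in-plane perpendicular
  w <- c(0, 0, 1)                            # optical axis
  L <- pr$spindle_length_um
  pole0 <- -L / 2 * s
  pole1 <- L / 2 * s

  nb <- pr$n_bivalents
  plate <- place_on_plate(nb, pr$plate_radius_um, pr$min_spacing_um)
  t_ax <- stats::runif(nb, -pr$axial_jitter_um, pr$axial_jitter_um)

  mix <- pr$config_mixture[CONFIG_LEVELS]
  split_mix <- mix[c("distinct", "separated")]
  split_mix <- split_mix / sum(split_mix)
  sep_cap_inv <- min(1.4, pr$sep_bands$separated$max)
  stratum_of <- function(cat) if (cat %in% c("indistinguishable", "overlapping"))
    "unified" else cat

  ns <- 4L * nb
  sp <- list(x = numeric(ns), y = numeric(ns), z = numeric(ns),
             biv = character(ns), hom = integer(ns), sis = integer(ns))
  ch <- list(biv = character(2L * nb), hom = integer(2L * nb),
             cx = numeric(2L * nb), cy = numeric(2L * nb),
             cz = numeric(2L * nb), ext = numeric(2L * nb))
  tp <- new_collector(list(
    bivalent_id = "", homolog_id = 0L, unit_type = "", configuration = "",
    sep_um = 0, at_pole = FALSE, attach_mode = "", attach_eligible = FALSE,
    expected_attach_mode = "", expected_fiber_type = "",
    expected_n_fibers = 0L, univ_bioriented = NA,
    univ_position = NA_character_), 2L * nb)
  tb <- new_collector(list(
    bivalent_id = "", rotation = "", at_pole = FALSE, cohesion_state = "",
    gap_um = 0, twisted = NA, expected_rotation = NA_character_,
    expected_twist = NA_character_), nb)
  freq <- new_collector(list(biv = "", hom = 0L, topo = "", pole_face = 0L),
                        2L * nb)

  isp <- 0L
  for (j in seq_len(nb)) {
    bid <- sprintf("B%02d", j)
    disint <- stats::runif(1) < pr$p_disintegrate
    at_pole <- !disint && stats::runif(1) < pr$p_at_pole
    rot <- "in_axis"
    if (!disint && !at_pole) {
      rv <- stats::runif(1)
      rot <- if (rv < pr$p_fully_inverted) "fully_inverted"
      else if (rv < pr$p_fully_inverted + pr$p_half_inverted) "half_inverted"
      else "in_axis"
    }
    cats <- if (rot == "half_inverted") {
      c("distinct", "distinct")
    } else if (disint || rot == "fully_inverted") {
      sample(names(split_mix), 2L, replace = TRUE, prob = split_mix)
    } else {
      sample(CONFIG_LEVELS, 2L, replace = TRUE, prob = mix)
    }
    twisted <- NA
    if (!disint && !at_pole && rot == "in_axis" && all(is_split(cats))) {
      twisted <- stats::runif(1) < pr$p_twisted_given_split
      if (twisted) cats[2] <- "separated"  # out-of-plane pair must clear
    }                                      # the axial resolution limit
    d <- c(sample_sep(pr, cats[1], 1L), sample_sep(pr, cats[2], 1L))
    if (rot == "fully_inverted")
      d <- pmin(d, stats::runif(2, pr$sep_bands$separated$offset, sep_cap_inv))

    ex <- stats::runif(2, pr$extent_range[1], pr$extent_range[2])
    gap <- 0
    if (disint) {
      coh <- "disintegrated"
      prox <- stats::runif(1) < pr$p_proximal
      rng <- if (prox) pr$disint_gap_proximal else pr$disint_gap_distal
      gap <- stats::runif(1, rng[1], rng[2])
      cdist <- sum(ex) + gap
    } else if (stats::runif(1) < pr$p_weak_gap) {
      coh <- "weak_gap"
      gap <- sample_gap(pr, 1L)
      cdist <- sum(ex) + gap
    } else {
      coh <- "intact"
      cdist <- stats::runif(1, pr$intact_fill[1], pr$intact_fill[2]) * sum(ex)
    }

    # bivalent axis and centre position
    P <- t_ax[j] * s + plate[j, 1] * u + plate[j, 2] * w
    if (at_pole) {
      sgn <- sample(c(-1, 1), 1L)
      P <- sgn * (L / 2 - 0.9) * s + 0.4 * perp_axis(u, w, stats::runif(1, 0, 360))
    }
    if (disint) P <- t_ax[j] * 0.2 * s + 0.35 * (plate[j, 1] * u + plate[j, 2] * w)
    jit <- stats::runif(1, 0, pr$axis_jitter_deg)
    phi_b <- stats::runif(1, 0, 360)
    if (rot == "fully_inverted") {
      b_dir <- rotate_towards(perp_axis(u, w, phi_b), s, jit)
    } else if (rot == "half_inverted") {
      q <- perp_axis(u, w, phi_b)
      ang <- (45 + stats::runif(1, -5, 5)) * pi / 180
      b_dir <- unit3(cos(ang) * q + sin(ang) * s)
    } else if (disint) {
      b_dir <- perp_axis(u, w, phi_b)
    } else {
      b_dir <- rotate_towards(s, perp_axis(u, w, phi_b), jit)
    }
    pc <- rbind(P - cdist / 2 * b_dir, P + cdist / 2 * b_dir)

    # pair axes
    half_idx <- if (rot == "half_inverted") sample(1:2, 1L) else 0L
    bio <- c(NA, NA)
    axes <- matrix(NA_real_, 2, 3)
    phi1 <- stats::runif(1, -pr$inplane_tilt_deg, pr$inplane_tilt_deg)
    for (h in 1:2) {
      if (disint) {
        bio[h] <- stats::runif(1) < pr$p_univalent_bioriented
        axes[h, ] <- if (bio[h])
          rotate_towards(s, perp_axis(u, w, stats::runif(1, 0, 360)),
                         stats::runif(1, 0, pr$axis_jitter_deg))
        else perp_axis(u, w, stats::runif(1, -pr$inplane_tilt_deg,
                                          pr$inplane_tilt_deg))
      } else if (rot == "fully_inverted" || h == half_idx) {
        axes[h, ] <- rotate_towards(s, perp_axis(u, w, stats::runif(1, 0, 360)),
                                    stats::runif(1, 0, pr$axis_jitter_deg))
      } else if (isTRUE(twisted) && h == 2L) {
        dphi <- sample(c(-1, 1), 1L) *
          (pr$twist_angle_deg + stats::runif(1, -pr$twist_jitter_deg,
                                             pr$twist_jitter_deg))
        axes[h, ] <- perp_axis(u, w, phi1 + dphi)
      } else if (h == 1L) {
        axes[h, ] <- perp_axis(u, w, phi1)
      } else {
        dphi <- max(-12, min(12, stats::rnorm(1, 0, pr$untwist_sd_deg)))
        axes[h, ] <- perp_axis(u, w, phi1 + dphi)
      }
    }

    # spots and chromatin
    for (h in 1:2) {
      off <- d[h] / 2 * axes[h, ]
      for (sis in 1:2) {
        p_s <- pc[h, ] + (if (sis == 1L) -off else off)
        isp <- isp + 1L
        sp$x[isp] <- p_s[1]; sp$y[isp] <- p_s[2]; sp$z[isp] <- p_s[3]
        sp$biv[isp] <- bid; sp$hom[isp] <- h; sp$sis[isp] <- sis
      }
      k <- 2L * (j - 1L) + h
      ch$biv[k] <- bid; ch$hom[k] <- h
      ch$cx[k] <- pc[h, 1]; ch$cy[k] <- pc[h, 2]; ch$cz[k] <- pc[h, 3]
      ch$ext[k] <- ex[h]
    }

    # attachment sampling; fibres are attached to detected spots later
    split_h <- is_split(cats)
    for (h in 1:2) {
      pole_face <- if (sum(b_dir * s) >= 0) h - 1L else 2L - h
      inverted_pair <- rot == "fully_inverted" || h == half_idx
      if (disint) {
        mode <- "univalent"; exp_mode <- if (bio[h]) "merotelic" else "amphitelic"
        topo <- if (bio[h]) "opposite" else "A_same"
        exp_type <- if (bio[h]) "B" else "A"; exp_n <- 2L
      } else if (inverted_pair) {
        mode <- "bioriented"; exp_mode <- "merotelic"
        topo <- "opposite"; exp_type <- "B"; exp_n <- 2L
      } else {
        stratum <- stratum_of(cats[h])
        rv <- stats::runif(1)
        m <- pr$merotelic_given_config[[stratum]]
        if (rv < m) {
          mode <- exp_mode <- "merotelic"; topo <- "opposite"
          exp_type <- "B"; exp_n <- 2L
        } else if (rv < m + pr$lateral_rate) {
          mode <- exp_mode <- "lateral"; topo <- "lateral"
          exp_type <- "B"; exp_n <- 2L
        } else if (rv < m + pr$lateral_rate + pr$unattached_rate) {
          mode <- exp_mode <- "unattached"; topo <- "none"
          exp_type <- "none"; exp_n <- 0L
        } else {
          mode <- exp_mode <- "amphitelic"
          if (stats::runif(1) < amphi_two_fiber_rate(pr, stratum)) {
            if (stats::runif(1) < pr$p_typeA) {
              topo <- "A_same"; exp_type <- "A"
            } else {
              topo <- "B_same"; exp_type <- "B"
            }
            exp_n <- 2L
          } else if (stats::runif(1) < 0.5) {
            topo <- "C"; exp_type <- "C"; exp_n <- 2L
          } else {
            topo <- "single"; exp_type <- "single"; exp_n <- 1L
          }
        }
      }
      collect_row(freq, biv = bid, hom = h, topo = topo,
                  pole_face = pole_face)
      collect_row(tp, bivalent_id = bid, homolog_id = h,
                  unit_type = if (disint) "univalent" else "bivalent",
                  configuration = cats[h], sep_um = d[h], at_pole = at_pole,
                  attach_mode = mode,
                  attach_eligible = !disint && !inverted_pair,
                  expected_attach_mode = exp_mode,
                  expected_fiber_type = exp_type,
                  expected_n_fibers = exp_n,
                  univ_bioriented = bio[h],
                  univ_position = if (disint) {
                    if (gap + sum(ex) <= 8.5) "proximal" else "distal"
                  } else NA_character_)
    }

    n_def <- sum(cats != "indistinguishable")
    exp_rot <- if (at_pole || disint) NA_character_
      else if (rot != "in_axis") rot
      else if (n_def >= 1L) "in_axis" else "ambiguous"
    exp_twist <- if (at_pole || disint || rot != "in_axis") NA_character_
      else if (all(split_h)) { if (isTRUE(twisted)) "twisted" else "undistorted" }
      else "not_scorable"
    collect_row(tb, bivalent_id = bid, rotation = rot, at_pole = at_pole,
                cohesion_state = coh,
                gap_um = if (coh == "intact") 0 else gap,
                twisted = twisted, expected_rotation = exp_rot,
                expected_twist = exp_twist)
  }

  truth_spots <- data.frame(
    oocyte_id = oocyte_id, bivalent_id = sp$biv, homolog_id = sp$hom,
    spot_id = sprintf("%s.%s.%d.%d", oocyte_id, sp$biv, sp$hom, sp$sis),
    x_um = sp$x, y_um = sp$y, z_um = sp$z,
    radius_um = pr$radius_um, merged = FALSE, stringsAsFactors = FALSE)
  spots <- truth_spots
  if (any(pr$noise_sigma_um > 0)) {
    n <- nrow(spots)
    spots$x_um <- spots$x_um + stats::rnorm(n, 0, pr$noise_sigma_um[1])
    spots$y_um <- spots$y_um + stats::rnorm(n, 0, pr$noise_sigma_um[2])
    spots$z_um <- spots$z_um + stats::rnorm(n, 0, pr$noise_sigma_um[3])
  }
  spots <- apply_resolution(spots, pr$resolution)

  # fibres reference detected spots
  freq_df <- collector_df(freq)
  det_key <- paste(spots$bivalent_id, spots$homolog_id)
  fb <- new_collector(list(spot = "", pole_index = 0L,
                           sx = 0, sy = 0, sz = 0, ex = 0, ey = 0, ez = 0,
                           contact = "", trunk = NA_character_,
                           biv = "", hom = 0L), 4L * nb)
  poles <- list(pole0, pole1)
  for (i in seq_len(nrow(freq_df))) {
    topo <- freq_df$topo[i]
    if (topo == "none") next
    idx <- which(det_key == paste(freq_df$biv[i], freq_df$hom[i]))
    if (!length(idx)) next
    idx <- idx[order(spots$spot_id[idx])]
    starts <- cbind(spots$x_um[idx], spots$y_um[idx], spots$z_um[idx])
    sid <- spots$spot_id[idx]
    two <- if (length(idx) == 2L) c(1L, 2L) else c(1L, 1L)
    pf <- freq_df$pole_face[i]
    pole <- poles[[pf + 1L]]
    other <- poles[[2L - pf]]
    add_f <- function(k, pidx, end, contact, trunk) {
      collect_row(fb, spot = sid[k], pole_index = pidx,
                  sx = starts[k, 1], sy = starts[k, 2], sz = starts[k, 3],
                  ex = end[1], ey = end[2], ez = end[3],
                  contact = contact, trunk = trunk,
                  biv = freq_df$biv[i], hom = freq_df$hom[i])
    }
    if (topo == "single") {
      add_f(1L, pf, pole + runif_ball(1.0), "end_on", NA_character_)
    } else if (topo == "A_same") {
      anchor <- pole + runif_ball(1.0)
      add_f(two[1], pf, anchor + runif_ball(0.3), "end_on", NA_character_)
      add_f(two[2], pf, anchor + runif_ball(0.3), "end_on", NA_character_)
    } else if (topo == "B_same") {
      q <- perp_axis(u, w, stats::runif(1, 0, 360))
      add_f(two[1], pf, pole + 2.2 * q, "end_on", NA_character_)
      add_f(two[2], pf, pole - 2.2 * q, "end_on", NA_character_)
    } else if (topo == "C") {
      anchor <- pole + runif_ball(0.8)
      tg <- sprintf("%s.%s.%d.T", oocyte_id, freq_df$biv[i], freq_df$hom[i])
      add_f(two[1], pf, anchor + runif_ball(0.15), "end_on", tg)
      add_f(two[2], pf, anchor + runif_ball(0.15), "end_on", tg)
    } else if (topo == "opposite") {
      add_f(two[1], pf, pole + runif_ball(1.0), "end_on", NA_character_)
      add_f(two[2], 1L - pf, other + runif_ball(1.0), "end_on", NA_character_)
    } else if (topo == "lateral") {
      add_f(two[1], pf, pole + runif_ball(1.0), "end_on", NA_character_)
      add_f(two[2], 1L - pf, other + runif_ball(1.5), "lateral", NA_character_)
    }
  }
  fb_df <- collector_df(fb)
  fibers <- if (nrow(fb_df)) data.frame(
    oocyte_id = oocyte_id,
    fiber_id = sprintf("%s.F%04d", oocyte_id, seq_len(nrow(fb_df))),
    spot_id = fb_df$spot, bivalent_id = fb_df$biv, homolog_id = fb_df$hom,
    pole_index = fb_df$pole_index,
    start_x_um = fb_df$sx, start_y_um = fb_df$sy, start_z_um = fb_df$sz,
    end_x_um = fb_df$ex, end_y_um = fb_df$ey, end_z_um = fb_df$ez,
    contact = fb_df$contact, trunk_group = fb_df$trunk,
    stringsAsFactors = FALSE) else NULL

  chromatin <- data.frame(
    oocyte_id = oocyte_id, bivalent_id = ch$biv, homolog_id = ch$hom,
    cx_um = ch$cx, cy_um = ch$cy, cz_um = ch$cz, extent_um = ch$ext,
    stringsAsFactors = FALSE)
  tp_df <- collector_df(tp); tp_df <- cbind(oocyte_id = oocyte_id, tp_df)
  tb_df <- collector_df(tb); tb_df <- cbind(oocyte_id = oocyte_id, tb_df)

  spindles <- data.frame(
    oocyte_id = oocyte_id, donor_age = age, stage = pr$stage,
    cold_treated = pr$cold_treated,
    pole0_x_um = pole0[1], pole0_y_um = pole0[2], pole0_z_um = pole0[3],
    pole1_x_um = pole1[1], pole1_y_um = pole1[2], pole1_z_um = pole1[3],
    stringsAsFactors = FALSE)

  list(spots = spots, truth_spots = truth_spots, fibers = fibers,
       chromatin = chromatin, spindles = spindles,
       truth_pairs = tp_df, truth_bivalents = tb_df)
}

#' Simulate a cohort of oocytes
#'
#' Per-oocyte seeds are derived deterministically from the profile seed, so
#' identical profiles produce byte-identical cohorts.
#'
#' @param profile a [cohort_profile()].
#' @param n_oocytes optional override of `profile$n_oocytes`.
#' @return object of class `meioarch_cohort`: a list of data.frames
#'   (`spots`, `truth_spots`, `fibers`, `chromatin`, `spindles`,
#'   `truth_pairs`, `truth_bivalents`) with the profile attached.
#' @export
simulate_cohort <- function(profile, n_oocytes = NULL) {
  n <- if (is.null(n_oocytes)) profile$n_oocytes else as.integer(n_oocytes)
  if (is.na(n) || n < 1L) ma_stop("simulate_cohort: n_oocytes must be >= 1")
  width <- max(3L, nchar(as.character(n)))
  oos <- lapply(seq_len(n), function(i) {
    simulate_oocyte(profile, derive_oocyte_seed(profile$seed, i),
                    sprintf("O%0*d", width, i))
  })
  bind <- function(f) {
    parts <- Filter(Negate(is.null), lapply(oos, `[[`, f))
    if (length(parts)) do.call(rbind, parts) else NULL
  }
  out <- list(spots = bind("spots"), truth_spots = bind("truth_spots"),
              fibers = bind("fibers"), chromatin = bind("chromatin"),
              spindles = bind("spindles"), truth_pairs = bind("truth_pairs"),
              truth_bivalents = bind("truth_bivalents"))
  for (f in names(out)) if (!is.null(out[[f]])) rownames(out[[f]]) <- NULL
  structure(c(out, list(profile = profile)), class = "meioarch_cohort")
}

#' @export
print.meioarch_cohort <- function(x, ...) {
  nm <- if (!is.null(x$profile)) x$profile$name else "(imported)"
  cat("<meioarch_cohort>", nm, "\n")
  cat(sprintf("  %d oocytes, %d detected spots, %d fibre records\n",
              nrow(x$spindles), nrow(x$spots),
              if (is.null(x$fibers)) 0L else nrow(x$fibers)))
  invisible(x)
}

#' Simulate a live-imaging (time-lapse) cohort
#'
#' Per-oocyte records of meiotic progression relative to nuclear envelope
#' breakdown (NEBD): chromosome congression time (mean 16.3 h, s.d. 2.3 h),
#' anaphase onset (congression plus a gamma-distributed delay; onset is
#' timed 10 min before the first chromosome separation), the number of
#' misaligned chromosomes at onset with its derived severity (0 none, 1-3
#' mild, >3 severe), a lagging-chromosome flag, and whether the oocyte
#' progressed into anaphase (Bernoulli per severity stratum; the severe
#' stratum progresses with probability 0.92 by default).
#'
#' @param n_records number of oocytes.
#' @param seed integer seed.
#' @param params time-lapse parameter list; default
#'   `cohort_profile()$timelapse`.
#' @return data.frame with one row per oocyte.
#' @export
simulate_timelapse_cohort <- function(n_records, seed = 1L, params = NULL) {
  if (n_records < 1L) ma_stop("simulate_timelapse_cohort: n_records must be >= 1")
  if (is.null(params)) params <- default_timelapse()
  set.seed(as.integer(seed %% 2147483647))
  sev <- sample(names(params$severity_mixture), n_records, replace = TRUE,
                prob = params$severity_mixture)
  n_mis <- ifelse(sev == "none", 0L,
           ifelse(sev == "mild", sample(1:3, n_records, replace = TRUE),
                  sample(4:8, n_records, replace = TRUE)))
  sev <- severity_from_misaligned(n_mis)   # derived, keeps the invariant
  cong <- stats::rnorm(n_records, params$congression_mean_h,
                       params$congression_sd_h)
  cong <- pmax(cong, 6)
  onset <- cong + stats::rgamma(n_records, shape = params$onset_delay_shape,
                                rate = params$onset_delay_rate)
  progressed <- stats::runif(n_records) < params$progression[sev]
  lagging <- progressed & (stats::runif(n_records) < params$lagging[sev])
  data.frame(
    oocyte_id = sprintf("T%05d", seq_len(n_records)),
    t_nebd_h = 0,
    t_congression_h = cong,
    t_anaphase_onset_h = ifelse(progressed, onset, NA_real_),
    n_misaligned = n_mis, severity = sev,
    lagging = lagging, progressed = progressed,
    stringsAsFactors = FALSE)
}
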