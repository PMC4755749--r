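# Cohort profiles: every generator parameter for one donor age group, with
# feasibility validation against the optical-resolution model.

#' Construct a cohort-generator profile
#'
#' A profile is the complete stated world for one simulated age group: the
#' sister-pair configuration mixture, per-category separation-distance
#' samplers, configuration-conditional attachment rates, rotation / twist /
#' cohesion-loss probabilities, the localization-noise and optical
#' resolution model, and the seed. The packaged baselines
#' ([baseline_profile()]) encode the empirical rates of the study this
#' package emulates; `cohort_profile()` lets tests and users restate any of
#' them.
#'
#' Distance samplers are uniform on a band strictly inside the geometric
#' interval that entails the sampled category under the resolution model
#' (the `separated` category uses a truncated gamma above the touching
#' threshold, bounded by `max_separation`). Infeasible combinations (e.g. a
#' band that crosses a category boundary, or attachment rates that cannot
#' reproduce the requested marginal two-fibre rate) raise an error of class
#' `meioarch_infeasible_error`.
#'
#' @param name profile label.
#' @param n_oocytes number of oocytes to simulate.
#' @param seed integer seed; per-oocyte seeds are derived deterministically.
#' @param age_range donor ages are drawn uniformly from this range (years).
#' @param stage `"MI"` or `"MII"`.
#' @param cold_treated logical; cold treatment preserves k-fibres and is
#'   required before attachment modes can be reported.
#' @param config_mixture named probabilities over
#'   `indistinguishable`/`overlapping`/`distinct`/`separated`; must sum
#'   to 1.
#' @param sep_bands named list of per-category separation samplers; each a
#'   list with `min`,`max` (uniform) or `offset`,`shape`,`rate`,`max`
#'   (truncated gamma, `separated` only). NULL picks defaults from the
#'   resolution model and spot radius.
#' @param merotelic_given_config named probabilities of a merotelic
#'   attachment given the configuration stratum
#'   (`unified`/`distinct`/`separated`); `unified` pools the
#'   indistinguishable and overlapping categories.
#' @param lateral_rate,unattached_rate attachment-mode probabilities shared
#'   across strata; amphitelic takes the remainder.
#' @param p_two_fibers marginal probability that an attached pair shows two
#'   discrete k-fibres; the amphitelic-conditional rate is calibrated from
#'   it per stratum.
#' @param p_typeA probability that a two-fibre amphitelic attachment is
#'   type A (parallel fibres) rather than type B.
#' @param p_fully_inverted,p_half_inverted per-bivalent rotation
#'   probabilities.
#' @param p_twisted_given_split probability that a bivalent with both pairs
#'   split is twisted (~70 degree homolog rotation).
#' @param p_weak_gap per-bivalent probability of weakened arm cohesion (a
#'   gap between homologs while still under shared tension).
#' @param p_disintegrate per-bivalent probability of precocious
#'   disintegration into two univalents.
#' @param p_univalent_bioriented probability a univalent biorients.
#' @param p_proximal probability the two partner univalents sit proximally.
#' @param p_at_pole probability a bivalent sits at a spindle pole (excluded
#'   from tension-dependent statistics).
#' @param gap_sampler truncated-gamma sampler for weak-cohesion gaps (um);
#'   default offset 0.1, shape 1.5, rate 2, max 3.2.
#' @param radius_um nominal kinetochore spot radius.
#' @param max_separation largest sister separation (um); default 1.7.
#' @param noise_sigma_um localization noise s.d. per world axis (x, y
#'   lateral; z axial).
#' @param resolution a [resolution_model()].
#' @param thresholds an [angle_thresholds()].
#' @param spindle_length_um,plate_radius_um,min_spacing_um,axial_jitter_um
#'   spindle geometry: pole separation, metaphase-plate radius, lateral
#'   spacing floor between bivalents, axial jitter of plate positions.
#' @param extent_range,intact_fill chromatin half-extent range (um) and the
#'   fraction of the summed extents occupied by an intact bivalent's
#'   centroid separation.
#' @param disint_gap_proximal,disint_gap_distal surface-gap ranges (um)
#'   between partner univalents.
#' @param axis_jitter_deg,inplane_tilt_deg,twist_angle_deg,twist_jitter_deg,untwist_sd_deg
#'   angular jitters: axis placement jitter, max in-plane tilt of pair
#'   axes, the twist rotation and its jitter, and the s.d. of the residual
#'   inter-pair angle in untwisted bivalents.
#' @param n_bivalents bivalent slots per oocyte (23 for human meiosis I).
#' @param timelapse list of time-lapse parameters (severity mixture,
#'   per-severity progression and lagging probabilities, congression time
#'   mean/s.d. and anaphase-onset delay shape/rate).
#' @return object of class `cohort_profile`.
#' @export
cohort_profile <- function(name = "custom",
                           n_oocytes = 23L,
                           seed = 1L,
                           age_range = c(23, 29),
                           stage = "MI",
                           cold_treated = TRUE,
                           config_mixture = c(indistinguishable = 0.25,
                                              overlapping = 0.15,
                                              distinct = 0.30,
                                              separated = 0.30),
                           sep_bands = NULL,
                           merotelic_given_config = c(unified = 0.12,
                                                      distinct = 0.17,
                                                      separated = 0.28),
                           lateral_rate = 0.12,
                           unattached_rate = 0.01,
                           p_two_fibers = 0.90,
                           p_typeA = 0.85,
                           p_fully_inverted = 0.015,
                           p_half_inverted = 0.015,
                           p_twisted_given_split = 0.20,
                           p_weak_gap = 0.10,
                           p_disintegrate = 0.012,
                           p_univalent_bioriented = 0.95,
                           p_proximal = 0.5,
                           p_at_pole = 0.007,
                           gap_sampler = list(offset = 0.1, shape = 1.5,
                                              rate = 2, max = 3.2),
                           radius_um = 0.40,
                           max_separation = 1.7,
                           noise_sigma_um = c(0.012, 0.012, 0.025),
                           resolution = resolution_model(),
                           thresholds = angle_thresholds(),
                           spindle_length_um = 12,
                           plate_radius_um = 5.5,
                           min_spacing_um = 1.5,
                           axial_jitter_um = 1.5,
                           extent_range = c(1.1, 1.3),
                           intact_fill = c(0.88, 0.98),
                           disint_gap_proximal = c(4.2, 5.2),
                           disint_gap_distal = c(7.5, 9.0),
                           axis_jitter_deg = 5,
                           inplane_tilt_deg = 15,
                           twist_angle_deg = 70,
                           twist_jitter_deg = 5,
                           untwist_sd_deg = 5,
                           n_bivalents = 23L,
                           timelapse = NULL) {
  if (is.null(sep_bands)) sep_bands <- default_sep_bands(resolution, radius_um,
                                                         max_separation)
  if (is.null(timelapse)) timelapse <- default_timelapse()
  p <- structure(as.list(environment()), class = "cohort_profile")
  validate_profile(p)
  p
}

default_timelapse <- function() {
  list(severity_mixture = c(none = 0.55, mild = 0.27, severe = 0.18),
       progression = c(none = 1.0, mild = 1.0, severe = 0.92),
       lagging = c(none = 0.05, mild = 0.30, severe = 0.60),
       congression_mean_h = 16.3, congression_sd_h = 2.3,
       onset_delay_shape = 4, onset_delay_rate = 2)
}

# Bands strictly inside the geometric category intervals, with a safety
# margin against localization noise so that noisy pipelines still recover
# the sampled category.
default_sep_bands <- function(resolution, radius_um, max_separation,
                              margin = 0.05) {
  touch <- 2 * radius_um
  lo <- resolution$overlap_factor * touch
  ml <- resolution$merge_distance_lateral
  list(
    indistinguishable = list(min = 0.02, max = max(0.03, ml / 2)),
    overlapping = list(min = ml + margin, max = lo - margin),
    distinct = list(min = lo + margin, max = touch - margin),
    separated = list(offset = touch + margin + 0.01, shape = 2, rate = 6,
                     max = max_separation)
  )
}

validate_profile <- function(p) {
  chk01 <- function(x, nm) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
      ma_stop(paste0("profile: ", nm, " must be in [0, 1]"))
  }
  if (p$n_oocytes < 1L) ma_stop("profile: n_oocytes must be >= 1")
  if (abs(sum(p$config_mixture) - 1) > 1e-8)
    ma_stop("profile: config_mixture must sum to 1")
  if (!identical(sort(names(p$config_mixture)), sort(CONFIG_LEVELS)))
    ma_stop("profile: config_mixture needs the four category names")
  chk01(p$config_mixture, "config_mixture")
  chk01(p$merotelic_given_config, "merotelic_given_config")
  for (nm in c("lateral_rate", "unattached_rate", "p_two_fibers", "p_typeA",
               "p_fully_inverted", "p_half_inverted", "p_twisted_given_split",
               "p_weak_gap", "p_disintegrate", "p_univalent_bioriented",
               "p_proximal", "p_at_pole"))
    chk01(p[[nm]], nm)
  if (p$p_fully_inverted + p$p_half_inverted > 1)
    ma_stop("profile: inversion probabilities exceed 1")
  if (any(p$noise_sigma_um < 0)) ma_stop("profile: noise sigma must be >= 0")

  # geometric feasibility of the category bands
  touch <- 2 * p$radius_um
  lo <- p$resolution$overlap_factor * touch
  ml <- p$resolution$merge_distance_lateral
  b <- p$sep_bands
  infeas <- function(msg) ma_stop(paste0("infeasible profile: ", msg),
                                  class = "meioarch_infeasible_error")
  if (b$indistinguishable$max >= ml)
    infeas("indistinguishable separations reach the lateral merge distance")
  if (ml >= lo)
    infeas(sprintf(
      "overlapping category empty: lateral merge distance %.2f um >= overlap boundary %.2f um (enlarge radius_um or overlap_factor)",
      ml, lo))
  if (b$overlapping$min <= ml || b$overlapping$max >= lo)
    infeas("overlapping band crosses a category boundary")
  if (b$distinct$min <= lo || b$distinct$max >= touch)
    infeas("distinct band crosses a category boundary")
  if (b$separated$offset <= touch || b$separated$max > p$max_separation)
    infeas("separated band must lie in (touching threshold, max_separation]")
  if (b$separated$max <= b$separated$offset)
    infeas("separated band empty")
  if (p$p_twisted_given_split > 0 &&
      b$separated$offset <= p$resolution$merge_distance_axial)
    infeas("twisted pairs need separated distances above the axial merge distance")
  if (any(p$intact_fill <= 0) || any(p$intact_fill >= 1) ||
      p$intact_fill[1] > p$intact_fill[2])
    ma_stop("profile: intact_fill must be an increasing pair in (0, 1)")
  # pairing identifiability: the smallest inter-homolog centroid distance,
  # reduced by axis jitter, must exceed the largest sister separation
  cdist_min <- 2 * p$extent_range[1] * p$intact_fill[1]
  shrink <- 2 * sin(p$axis_jitter_deg * pi / 180) * p$max_separation / 2
  if (cdist_min - shrink <= p$max_separation)
    infeas("largest sister separation reaches the inter-homolog distance; closest-pair assignment would be ambiguous")

  # attachment calibration must be solvable in every stratum
  for (s in names(p$merotelic_given_config)) amphi_two_fiber_rate(p, s)
  invisible(p)
}

# Amphitelic-conditional two-fibre probability that reproduces the marginal
# p_two_fibers among attached pairs of a stratum.
amphi_two_fiber_rate <- function(profile, stratum) {
  m <- profile$merotelic_given_config[[stratum]]
  l <- profile$lateral_rate
  u <- profile$unattached_rate
  a <- 1 - m - l - u
  if (a <= 0)
    ma_stop(paste0("infeasible profile: no amphitelic mass left in stratum ",
                   stratum), class = "meioarch_infeasible_error")
  p2 <- (profile$p_two_fibers * (1 - u) - m - l) / a
  if (p2 < 0 || p2 > 1)
    ma_stop(sprintf(
      "infeasible profile: two-fibre marginal %.2f unreachable in stratum %s (needs amphitelic rate %.2f)",
      profile$p_two_fibers, stratum, p2), class = "meioarch_infeasible_error")
  p2
}

sample_sep <- function(profile, category, n) {
  if (n == 0L) return(numeric(0))
  b <- profile$sep_bands[[category]]
  if (category == "separated") {
    x <- b$offset + stats::rgamma(n, shape = b$shape, rate = b$rate)
    over <- which(x > b$max)
    while (length(over)) {
      x[over] <- b$offset + stats::rgamma(length(over), shape = b$shape,
                                          rate = b$rate)
      over <- over[x[over] > b$max]
    }
    x
  } else {
    stats::runif(n, b$min, b$max)
  }
}

sample_gap <- function(profile, n) {
  if (n == 0L) return(numeric(0))
  g <- profile$gap_sampler
  x <- g$offset + stats::rgamma(n, shape = g$shape, rate = g$rate)
  over <- which(x > g$max)
  while (length(over)) {
    x[over] <- g$offset + stats::rgamma(length(over), shape = g$shape,
                                        rate = g$rate)
    over <- over[x[over] > g$max]
  }
  x
}

#' Packaged baseline profiles
#'
#' `young_baseline` encodes the published rates for donors up to 30 years:
#' a 60% two-discrete-spot (split) fraction, merotelic rates of 12/17/28%
#' conditional on the unified/distinct/separated configuration strata, a
#' ~90% two-fibre rate among attached pairs, 20% twist among
#' split-configuration bivalents, 10% weak arm cohesion, 1.2% bivalent
#' disintegration, 95% univalent biorientation, 3% half- or fully-inverted
#' bivalents, sister separations up to 1.7 um and cohesion gaps up to
#' 3.2 um. `over35_baseline` moves the mixture to an 87% split fraction
#' (overall merotelic ~21%) and raises weak cohesion to 8% plus
#' disintegration to 3% per bivalent (11% of bivalents gap-separated or
#' disintegrated; >40% of oocytes carry univalents). `mid_baseline` (30-35
#' years) interpolates with a 75% split fraction. The exact four-way
#' mixture partition and the over-35 disintegration rate are package
#' choices anchored to the published split fractions and oocyte-level
#' univalent incidence; see the methods vignette.
#'
#' @param name `"young"`, `"mid"` or `"over35"` (aliases
#'   `"young_baseline"` etc. accepted).
#' @param n_oocytes optional override of the cohort size.
#' @param seed integer seed.
#' @param ... further overrides passed to [cohort_profile()].
#' @return a `cohort_profile`.
#' @export
baseline_profile <- function(name = c("young", "mid", "over35"),
                             n_oocytes = NULL, seed = 1L, ...) {
  name <- sub("_baseline$", "", name[1])
  name <- match.arg(name, c("young", "mid", "over35"))
  base <- switch(name,
    young = list(name = "young_baseline", n_oocytes = 23L,
                 age_range = c(23, 29),
                 config_mixture = c(indistinguishable = 0.25,
                                    overlapping = 0.15,
                                    distinct = 0.30, separated = 0.30),
                 p_weak_gap = 0.10, p_disintegrate = 0.012,
                 p_fully_inverted = 0.015, p_half_inverted = 0.015),
    mid = list(name = "mid_baseline", n_oocytes = 20L,
               age_range = c(30, 35),
               config_mixture = c(indistinguishable = 0.12,
                                  overlapping = 0.13,
                                  distinct = 0.36, separated = 0.39),
               p_weak_gap = 0.085, p_disintegrate = 0.025,
               p_fully_inverted = 0.008, p_half_inverted = 0.008),
    over35 = list(name = "over35_baseline", n_oocytes = 20L,
                  age_range = c(36, 44),
                  config_mixture = c(indistinguishable = 0.06,
                                     overlapping = 0.07,
                                     distinct = 0.40, separated = 0.47),
                  p_weak_gap = 0.07, p_disintegrate = 0.04,
                  p_fully_inverted = 0.011, p_half_inverted = 0.011))
  dots <- list(...)
  if (!is.null(n_oocytes)) base$n_oocytes <- as.integer(n_oocytes)
  base$seed <- as.integer(seed)
  base[names(dots)] <- dots
  do.call(cohort_profile, base)
}

#' Profile interpolated for a donor age
#'
#' Mean sister-kinetochore separation increases linearly with donor age, so
#' continuous-age cohorts are generated by linear interpolation of the
#' configuration mixture and of the cohesion-loss and inversion
#' probabilities between the three baseline anchors (ages 27, 32.5 and 38);
#' outside the anchors the nearest baseline applies.
#'
#' @param age donor age in years.
#' @param n_oocytes,seed,... passed through to [cohort_profile()].
#' @return a `cohort_profile` with `age_range = c(age, age)`.
#' @export
profile_for_age <- function(age, n_oocytes = 1L, seed = 1L, ...) {
  anchors <- c(young = 27, mid = 32.5, over35 = 38)
  profs <- list(young = baseline_profile("young"),
                mid = baseline_profile("mid"),
                over35 = baseline_profile("over35"))
  fields <- c("p_weak_gap", "p_disintegrate", "p_fully_inverted",
              "p_half_inverted")
  interp <- function(f) {
    v <- vapply(profs, function(p) p[[f]], numeric(1))
    stats::approx(anchors, v, xout = min(max(age, anchors[1]), anchors[3]))$y
  }
  mix <- sapply(CONFIG_LEVELS, function(cat) {
    v <- vapply(profs, function(p) p$config_mixture[[cat]], numeric(1))
    stats::approx(anchors, v, xout = min(max(age, anchors[1]), anchors[3]))$y
  })
  mix <- mix / sum(mix)
  args <- list(name = sprintf("age_%g", age), n_oocytes = n_oocytes,
               seed = seed, age_range = c(age, age),
               config_mixture = mix)
  for (f in fields) args[[f]] <- interp(f)
  args <- utils::modifyList(args, list(...))
  do.call(cohort_profile, args)
}

#' @export
print.cohort_profile <- function(x, ...) {
  cat("<cohort_profile>", x$name, "\n")
  cat(sprintf("  %d oocytes, ages %.0f-%.0f, stage %s, cold_treated=%s, seed %d\n",
              x$n_oocytes, x$age_range[1], x$age_range[2], x$stage,
              x$cold_treated, x$seed))
  cat("  config mixture:",
      paste(sprintf("%s=%.2f", names(x$config_mixture), x$config_mixture),
            collapse = " "), "\n")
  cat(sprintf("  merotelic u/d/s: %.2f/%.2f/%.2f  twist|split: %.2f  weak: %.3f  disint: %.3f\n",
              x$merotelic_given_config[["unified"]],
              x$merotelic_given_config[["distinct"]],
              x$merotelic_given_config[["separated"]],
              x$p_twisted_given_split, x$p_weak_gap, x$p_disintegrate))
  invisible(x)
}
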