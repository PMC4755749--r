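test_that("simulate_cohort is deterministic for identical profiles", {
  pr <- baseline_profile("young", seed = 17)
  a <- simulate_cohort(pr, n_oocytes = 3)
  b <- simulate_cohort(baseline_profile("young", seed = 17), n_oocytes = 3)
  for (f in c("spots", "truth_spots", "fibers", "chromatin", "spindles",
              "truth_pairs", "truth_bivalents"))
    expect_identical(a[[f]], b[[f]], label = f)
  # different seeds differ
  c <- simulate_cohort(baseline_profile("young", seed = 18), n_oocytes = 3)
  expect_false(identical(a$spots$x_um, c$spots$x_um))
})

test_that("derived per-oocyte seeds stay below 2^31 and are distinct", {
  s <- vapply(1:500, function(i) derive_oocyte_seed(123456L, i), numeric(1))
  expect_true(all(s > 0 & s < 2^31))
  expect_equal(length(unique(s)), 500L)
})

test_that("every generated oocyte satisfies the 46-chromosome accounting", {
  pr <- baseline_profile("young", seed = 19, p_disintegrate = 0.15)
  cl <- classify_cohort(simulate_cohort(pr, n_oocytes = 8))
  expect_true(all(2L * cl$oocytes$n_bivalents + cl$oocytes$n_univalents == 46L))
  expect_true(all(cl$oocytes$n_units >= 23L & cl$oocytes$n_units <= 46L))
  expect_true(all(cl$oocytes$n_spots_detected <= 92L))
})

test_that("p_disintegrate = 1 yields 46 univalents and zero bivalents", {
  pr <- noise_free_profile(seed = 23, p_disintegrate = 1)
  cl <- classify_cohort(simulate_cohort(pr, n_oocytes = 1))
  expect_equal(cl$oocytes$n_bivalents, 0L)
  expect_equal(cl$oocytes$n_univalents, 46L)
  expect_equal(cl$oocytes$n_chromosomes, 46L)
  expect_equal(nrow(cl$univalents), 46L)
})

test_that("a degenerate noise-free profile is recovered label-for-label", {
  pr <- noise_free_profile(
    seed = 31,
    config_mixture = c(indistinguishable = 0, overlapping = 0,
                       distinct = 1, separated = 0),
    merotelic_given_config = c(unified = 0, distinct = 0, separated = 0),
    lateral_rate = 0, unattached_rate = 0, p_two_fibers = 1, p_typeA = 1,
    p_fully_inverted = 0, p_half_inverted = 0, p_twisted_given_split = 0,
    p_weak_gap = 0, p_disintegrate = 0, p_at_pole = 0)
  co <- simulate_cohort(pr, n_oocytes = 2)
  cl <- classify_cohort(co)
  expect_true(all(cl$pairs$configuration == "distinct"))
  expect_true(all(cl$pairs$attach_mode == "amphitelic"))
  expect_true(all(cl$pairs$fiber_type == "A"))
  expect_true(all(cl$bivalents$rotation == "in_axis"))
  expect_true(all(cl$bivalents$twist == "undistorted"))
  expect_true(all(cl$bivalents$cohesion_state == "intact"))
})

test_that("noise-free cohorts recover 100% of ground-truth labels", {
  pr <- noise_free_profile(seed = 37, p_disintegrate = 0.05)
  co <- simulate_cohort(pr, n_oocytes = 5)
  rep <- recovery_report(co, classify_cohort(co))
  for (f in setdiff(names(rep), "homologs_resolved"))
    if (!is.na(rep[[f]])) expect_equal(rep[[f]], 1, label = f)
  expect_true(rep$homologs_resolved)
})

test_that("generator rates are recovered within 3 binomial s.e.", {
  pr <- baseline_profile("young", seed = 41)
  co <- simulate_cohort(pr, n_oocytes = 60)
  r <- summarize_classification(classify_cohort(co))$rates
  within3 <- function(est, p0) {
    se <- sqrt(p0 * (1 - p0) / est$total)
    abs(est$pct / 100 - p0) < 3 * se + 1e-9
  }
  expect_true(within3(r$split, 0.60 * 0.97 + 0.03))  # inverted/univalents forced split
  expect_true(within3(r$merotelic_unified, 0.12))
  expect_true(within3(r$merotelic_distinct, 0.17))
  expect_true(within3(r$merotelic_separated, 0.28))
  expect_true(within3(r$two_fibers_split, 0.90))
  expect_true(within3(r$twisted, 0.20))
  expect_true(within3(r$weak_gap, 0.10))
  expect_true(within3(r$disintegrated, 0.012))
  expect_true(within3(r$inverted, 0.03))
})

test_that("merotelic fraction is non-decreasing across configuration strata", {
  pr <- baseline_profile("young", seed = 43)
  r <- summarize_classification(
    classify_cohort(simulate_cohort(pr, n_oocytes = 50)))$rates
  expect_lte(r$merotelic_unified$pct, r$merotelic_distinct$pct + 1e-9)
  expect_lte(r$merotelic_distinct$pct, r$merotelic_separated$pct + 1e-9)
})

test_that("invalid cohort sizes and infeasible profiles are rejected", {
  pr <- baseline_profile("young")
  expect_error(simulate_cohort(pr, n_oocytes = 0),
               class = "meioarch_validation_error")
  # small spots make the overlapping category geometrically empty
  expect_error(baseline_profile("young", radius_um = 0.2),
               class = "meioarch_infeasible_error")
  # separated band must start above the touching threshold
  bands <- cohort_profile()$sep_bands
  bands$separated$offset <- 0.5
  expect_error(baseline_profile("young", sep_bands = bands),
               class = "meioarch_infeasible_error")
  # sister separations must stay below the inter-homolog distance
  expect_error(baseline_profile("young", intact_fill = c(0.5, 0.6)),
               class = "meioarch_infeasible_error")
  # unreachable two-fibre marginal
  expect_error(baseline_profile("young", p_two_fibers = 0.05),
               class = "meioarch_infeasible_error")
})

test_that("profile_for_age interpolates between the baseline anchors", {
  young <- baseline_profile("young")
  old <- baseline_profile("over35")
  p27 <- profile_for_age(27)
  p38 <- profile_for_age(38)
  expect_equal(p27$config_mixture, young$config_mixture)
  expect_equal(p38$p_disintegrate, old$p_disintegrate)
  p32 <- profile_for_age(32.5)
  expect_equal(p32$config_mixture[["separated"]], 0.39)
  # monotone split fraction along age
  splits <- vapply(c(25, 31, 34, 40), function(a) {
    m <- profile_for_age(a)$config_mixture
    m[["distinct"]] + m[["separated"]]
  }, numeric(1))
  expect_true(all(diff(splits) > 0))
})

test_that("time-lapse cohorts derive severity and progression correctly", {
  tl <- simulate_timelapse_cohort(4000, seed = 47)
  expect_identical(tl$severity, severity_from_misaligned(tl$n_misaligned))
  expect_true(all(tl$severity[tl$n_misaligned == 0] == "none"))
  expect_true(all(tl$severity[tl$n_misaligned == 2] == "mild"))
  expect_true(all(tl$severity[tl$n_misaligned > 3] == "severe"))
  # none and mild strata always progress by default
  expect_true(all(tl$progressed[tl$severity != "severe"]))
  expect_true(all(is.na(tl$t_anaphase_onset_h[!tl$progressed])))
  expect_true(all(tl$t_anaphase_onset_h >= tl$t_congression_h, na.rm = TRUE))
  # congression time: mean 16.3 h within 3 s.e.m.
  expect_lt(abs(mean(tl$t_congression_h) - 16.3),
            3 * 2.3 / sqrt(nrow(tl)) + 0.02)
  # determinism
  expect_identical(tl, simulate_timelapse_cohort(4000, seed = 47))
})
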