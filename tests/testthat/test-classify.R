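test_that("classify_fiber_topology types multi-fibre attachments", {
  thr <- angle_thresholds()
  expect_equal(classify_fiber_topology(NULL, thr),
               list(n_fibers = 0L, fiber_type = "none"))
  expect_equal(classify_fiber_topology(mk_fibers(0L), thr)$fiber_type, "single")
  # shared trunk: type C
  fc <- mk_fibers(c(0L, 0L), trunk_group = "T1",
                  ends = c(-6, -6.1, 0, 0.1, 0, 0))
  expect_equal(classify_fiber_topology(fc, thr)$fiber_type, "C")
  # two parallel fibres to adjacent endpoints at one pole: type A
  fa <- mk_fibers(c(0L, 0L), ends = c(-6, -6, 0.1, -0.1, 0, 0))
  topo <- classify_fiber_topology(fa, thr)
  expect_equal(topo$fiber_type, "A")
  expect_equal(topo$n_fibers, 2L)
  # endpoints 5 um apart on the spindle: type B
  fbig <- mk_fibers(c(0L, 0L), ends = c(-6, -6, 2.5, -2.5, 0, 0))
  expect_equal(classify_fiber_topology(fbig, thr)$fiber_type, "B")
  # opposite poles: type B
  fopp <- mk_fibers(c(0L, 1L))
  expect_equal(classify_fiber_topology(fopp, thr)$fiber_type, "B")
})

test_that("classify_attachment_mode follows the end-on/lateral rules", {
  expect_equal(classify_attachment_mode(NULL), "unattached")
  expect_equal(classify_attachment_mode(mk_fibers(c(0L, 0L))), "amphitelic")
  expect_equal(classify_attachment_mode(mk_fibers(c(0L, 1L))), "merotelic")
  # lateral contact, not merotelic by end-on: lateral (lateral-merotelic folds in)
  expect_equal(classify_attachment_mode(mk_fibers(c(0L, 1L),
                                                  contact = c("end_on", "lateral"))),
               "lateral")
  # end-on to both poles wins over an extra lateral contact
  expect_equal(classify_attachment_mode(mk_fibers(c(0L, 1L, 1L),
                                                  contact = c("end_on", "end_on", "lateral"))),
               "merotelic")
})

mk_pair <- function(axis, centroid) list(axis = axis, centroid = centroid)

test_that("score_rotation labels in-axis, half- and fully-inverted bivalents", {
  s <- c(1, 0, 0); thr <- angle_thresholds()
  # bivalent axis || spindle, pair axes perpendicular: in_axis
  r <- score_rotation(mk_pair(c(0, 1, 0), c(-1, 0, 0)),
                      mk_pair(c(0, 0, 1), c(1, 0, 0)), s, thr)
  expect_equal(r$label, "in_axis")
  expect_false(r$low_confidence)
  expect_equal(r$bivalent_axis_deg, 0)
  # bivalent rotated by 90 degrees, sisters of both pairs facing opposite
  # poles: fully_inverted
  r <- score_rotation(mk_pair(c(1, 0, 0), c(0, -1, 0)),
                      mk_pair(c(1, 0, 0), c(0, 1, 0)), s, thr)
  expect_equal(r$label, "fully_inverted")
  # one pair facing one pole, the other facing opposite poles: half_inverted
  r <- score_rotation(mk_pair(c(1, 0, 0), c(-0.7, -0.7, 0)),
                      mk_pair(c(0, 1, 0), c(0.7, 0.7, 0)), s, thr)
  expect_equal(r$label, "half_inverted")
  # intermediate orientations are ambiguous, not forced
  r <- score_rotation(mk_pair(c(1, 1, 0), c(-1, 0, 0)),
                      mk_pair(c(1, 1, 0), c(1, 0, 0)), s, thr)
  expect_equal(r$label, "ambiguous")
  # merged pair: label from bivalent axis + remaining pair, low confidence
  r <- score_rotation(mk_pair(c(NA, NA, NA), c(-1, 0, 0)),
                      mk_pair(c(0, 1, 0), c(1, 0, 0)), s, thr)
  expect_equal(r$label, "in_axis")
  expect_true(r$low_confidence)
  expect_error(score_rotation(mk_pair(c(0, 1, 0), c(0, 0, 0)),
                              mk_pair(c(0, 1, 0), c(0, 0, 0)), s, thr),
               class = "meioarch_validation_error")
})

test_that("score_rotation is invariant under rigid motion and axis flip", {
  s <- c(1, 0, 0); thr <- angle_thresholds()
  set.seed(9)
  cases <- list(
    list(mk_pair(c(0, 1, 0), c(-1, 0, 0)), mk_pair(c(0, 0, 1), c(1, 0, 0))),
    list(mk_pair(c(1, 0, 0), c(0, -1, 0)), mk_pair(c(1, 0, 0), c(0, 1, 0))),
    list(mk_pair(c(1, 0, 0), c(-0.7, -0.7, 0)), mk_pair(c(0, 1, 0), c(0.7, 0.7, 0))))
  for (cs in cases) {
    base <- score_rotation(cs[[1]], cs[[2]], s, thr)$label
    expect_equal(score_rotation(cs[[1]], cs[[2]], -s, thr)$label, base)
    for (i in 1:20) {
      qr_ <- qr(matrix(rnorm(9), 3))
      R <- qr.Q(qr_) * sign(diag(qr.R(qr_)))[col(matrix(0, 3, 3))]
      tr <- rnorm(3, 0, 5)
      p1 <- mk_pair(as.vector(R %*% cs[[1]]$axis),
                    as.vector(R %*% cs[[1]]$centroid + tr))
      p2 <- mk_pair(as.vector(R %*% cs[[2]]$axis),
                    as.vector(R %*% cs[[2]]$centroid + tr))
      expect_equal(score_rotation(p1, p2, as.vector(R %*% s), thr)$label, base)
    }
  }
})

test_that("score_twist needs two split pairs and applies the angle rule", {
  thr <- angle_thresholds()
  expect_equal(score_twist(c(0, 1, 0), c(0, 1, 0), TRUE, thr)$label,
               "undistorted")
  expect_equal(score_twist(c(0, 1, 0), c(0, 0, 1), TRUE, thr)$label, "twisted")
  tw70 <- score_twist(c(0, 1, 0), c(0, cos(70 * pi / 180), sin(70 * pi / 180)),
                      TRUE, thr)
  expect_equal(tw70$label, "twisted")
  expect_equal(tw70$angle_deg, 70)
  expect_equal(score_twist(c(0, 1, 0), c(0, 0, 1), FALSE, thr)$label,
               "not_scorable")
  expect_equal(score_twist(c(NA, NA, NA), c(0, 0, 1), TRUE, thr)$label,
               "not_scorable")
  mid <- score_twist(c(0, 1, 0), c(0, cos(0.7), sin(0.7)), TRUE, thr)  # ~40 deg
  expect_equal(mid$label, "undistorted")
  expect_true(mid$ambiguous)
})

test_that("detect_cohesion_state measures the inter-homolog surface gap", {
  # centroids 2.0 um apart, extents 1.2 + 1.0: touching, intact
  r <- detect_cohesion_state(c(0, 0, 0), 1.2, c(2, 0, 0), 1.0)
  expect_equal(r, list(state = "intact", gap_um = 0))
  # gap of 3.2 um (the largest observed): still weakly associated
  r <- detect_cohesion_state(c(0, 0, 0), 1.2, c(5.4, 0, 0), 1.0)
  expect_equal(r$state, "weak_gap")
  expect_equal(r$gap_um, 3.2)
  # a few 100 nm only
  r <- detect_cohesion_state(c(0, 0, 0), 1.2, c(2.5, 0, 0), 1.0)
  expect_equal(r$state, "weak_gap")
  expect_equal(r$gap_um, 0.3)
  # beyond max_gap: disintegrated
  r <- detect_cohesion_state(c(0, 0, 0), 1.2, c(7, 0, 0), 1.0)
  expect_equal(r$state, "disintegrated")
})

test_that("chromosome accounting enforces the 46-chromosome invariant", {
  expect_false(check_chromosome_accounting(23L, 0L)$has_univalents)
  r <- check_chromosome_accounting(22L, 2L)
  expect_true(r$has_univalents)
  expect_equal(r$n_units, 24L)
  expect_equal(r$n_chromosomes, 46L)
  expect_error(check_chromosome_accounting(23L, 1L),
               class = "meioarch_validation_error")
  expect_error(check_chromosome_accounting(20L, 2L),
               class = "meioarch_validation_error")
})

test_that("univalent biorientation needs a parallel axis and fibres to both poles", {
  s <- c(1, 0, 0); thr <- angle_thresholds()
  both <- mk_fibers(c(0L, 1L))
  one <- mk_fibers(c(0L, 0L))
  expect_true(univalent_biorientation(c(1, 0, 0), s, both, thr)$bioriented)
  expect_false(univalent_biorientation(c(0, 1, 0), s, both, thr)$bioriented)
  expect_false(univalent_biorientation(c(1, 0, 0), s, one, thr)$bioriented)
  # boundary inclusive at exactly parallel_max
  ax30 <- c(cos(30 * pi / 180), sin(30 * pi / 180), 0)
  expect_true(univalent_biorientation(ax30, s, both, thr)$bioriented)
  merged <- univalent_biorientation(c(NA, NA, NA), s, both, thr)
  expect_false(merged$bioriented)
  expect_true(merged$low_confidence)
})

test_that("predict_segregation_outcome implements the deterministic table", {
  r <- predict_segregation_outcome("in_axis", c("intact", "intact"))
  expect_equal(r$predicted_event, "normal_disjunction")
  r <- predict_segregation_outcome("fully_inverted", c("intact", "intact"))
  expect_equal(r$predicted_event, "lagging")
  r <- predict_segregation_outcome("fully_inverted", c("intact", "compromised"))
  expect_equal(r$predicted_event, "univalent_plus_chromatids")
  expect_equal(sort(r$predicted_products),
               c("chromatid", "chromatid", "chromosome"))
  r <- predict_segregation_outcome("fully_inverted",
                                   c("compromised", "compromised"))
  expect_equal(r$predicted_event, "reverse_segregation")
  expect_equal(r$predicted_products, rep("chromatid", 4))
  r <- predict_segregation_outcome("half_inverted", c("compromised", "intact"))
  expect_equal(r$predicted_event, "univalent_plus_chromatids")
  expect_error(predict_segregation_outcome("sideways", c("intact", "intact")),
               class = "meioarch_validation_error")
  expect_error(predict_segregation_outcome("in_axis", c("intact", "weak")),
               class = "meioarch_validation_error")
})

test_that("every prediction conserves four chromatids per bivalent", {
  for (o in c("in_axis", "half_inverted", "fully_inverted"))
    for (c1 in c("intact", "compromised"))
      for (c2 in c("intact", "compromised")) {
        r <- predict_segregation_outcome(o, c(c1, c2))
        expect_equal(count_chromatids(r$predicted_products), 4L)
      }
})

test_that("identify_univalents reports accounting per oocyte", {
  pr <- noise_free_profile(seed = 21, p_disintegrate = 0.3)
  co <- simulate_cohort(pr, n_oocytes = 2)
  cl <- classify_cohort(co)
  for (oid in unique(cl$oocytes$oocyte_id)) {
    r <- identify_univalents(cl, oid)
    expect_equal(r$accounting$n_chromosomes, 46L)
    expect_equal(nrow(r$univalents),
                 cl$oocytes$n_univalents[cl$oocytes$oocyte_id == oid])
  }
  expect_error(identify_univalents(cl, "nope"),
               class = "meioarch_validation_error")
})
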