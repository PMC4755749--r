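test_that("apply_resolution merges sub-resolution sisters anisotropically", {
  model <- resolution_model(merge_distance_lateral = 0.25,
                            merge_distance_axial = 0.65)
  # 0.1 um lateral separation: merged into one detection at the midpoint
  close <- mk_spots(c(0, 0, 0,  0.1, 0, 0), homolog_id = 1L)
  det <- apply_resolution(close, model)
  expect_equal(nrow(det), 1L)
  expect_true(det$merged)
  expect_equal(det$x_um, 0.05)
  expect_equal(det$homolog_id, 1L)

  # 1.0 um apart: unchanged
  far <- mk_spots(c(0, 0, 0,  1, 0, 0))
  expect_equal(nrow(apply_resolution(far, model)), 2L)

  # purely axial 0.5 um with axial merge distance 0.65: merged
  ax <- mk_spots(c(0, 0, 0,  0, 0, 0.5))
  expect_equal(nrow(apply_resolution(ax, model)), 1L)
  # but the same 0.5 um laterally is resolved
  lat <- mk_spots(c(0, 0, 0,  0.5, 0, 0))
  expect_equal(nrow(apply_resolution(lat, model)), 2L)
})

test_that("apply_resolution does not merge across bivalents", {
  a <- mk_spots(c(0, 0, 0), bivalent_id = "B01")
  b <- mk_spots(c(0.05, 0, 0), bivalent_id = "B02")
  det <- apply_resolution(rbind(a, b))
  expect_equal(nrow(det), 2L)
  expect_false(any(det$merged))
})

test_that("classify_configuration applies the four-way rule", {
  model <- resolution_model(overlap_factor = 0.6)
  # merged detection: indistinguishable with distance reported as 0
  expect_equal(classify_configuration(1L, 0, 0.4, 0.4, model),
               "indistinguishable")
  # r1 = r2 = 0.25, d = 0.6 > r1 + r2: separated
  expect_equal(classify_configuration(2L, 0.6, 0.25, 0.25, model), "separated")
  # r1 = r2 = 0.25, d = 0.35 in [0.30, 0.50]: distinct
  expect_equal(classify_configuration(2L, 0.35, 0.25, 0.25, model), "distinct")
  # below the overlap boundary: overlapping; boundaries inclusive for distinct
  expect_equal(classify_configuration(2L, 0.29, 0.25, 0.25, model), "overlapping")
  expect_equal(classify_configuration(2L, 0.30, 0.25, 0.25, model), "distinct")
  expect_equal(classify_configuration(2L, 0.50, 0.25, 0.25, model), "distinct")
  expect_error(classify_configuration(3L, 1, 0.25, 0.25, model),
               class = "meioarch_validation_error")
})

test_that("classify_configuration is monotone in distance", {
  model <- resolution_model()
  ord <- c(indistinguishable = 1, overlapping = 2, distinct = 3, separated = 4)
  set.seed(5)
  d <- sort(runif(200, 0, 2))
  cats <- classify_configuration(rep(2L, 200), d, 0.4, 0.4, model)
  expect_true(all(diff(ord[cats]) >= 0))
})

test_that("is_split groups distinct and separated as two discrete spots", {
  expect_false(is_split("indistinguishable"))
  expect_false(is_split("overlapping"))
  expect_true(is_split("distinct"))
  expect_true(is_split("separated"))
  expect_error(is_split("nonsense"), class = "meioarch_validation_error")
})

test_that("threshold and resolution constructors validate their domains", {
  expect_error(angle_thresholds(parallel_max = 0),
               class = "meioarch_validation_error")
  expect_error(angle_thresholds(parallel_max = 70, perpendicular_min = 60),
               class = "meioarch_validation_error")
  expect_error(angle_thresholds(twist_min = 20),
               class = "meioarch_validation_error")
  expect_error(resolution_model(merge_distance_lateral = 0),
               class = "meioarch_validation_error")
  expect_error(resolution_model(overlap_factor = 1),
               class = "meioarch_validation_error")
})
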