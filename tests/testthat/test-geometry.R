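test_that("dist3 computes Euclidean distances and validates input", {
  expect_equal(dist3(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(dist3(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(dist3(c(0, 0, 0), c(1, 2, 2)), 3)
  expect_error(dist3(c(NA, 0, 0), c(0, 0, 0)), class = "meioarch_validation_error")
  expect_error(dist3(c(Inf, 0, 0), c(0, 0, 0)), class = "meioarch_validation_error")
})

test_that("dist3 behaves as a metric on random triples", {
  set.seed(42)
  for (i in 1:200) {
    p <- rnorm(3); q <- rnorm(3); r <- rnorm(3)
    expect_gte(dist3(p, q), 0)
    expect_equal(dist3(p, q), dist3(q, p))
    expect_lte(dist3(p, r), dist3(p, q) + dist3(q, r) + 1e-12)
  }
})

test_that("axis_angle is the acute angle between undirected axes", {
  expect_equal(axis_angle(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(axis_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(axis_angle(c(1, 1, 0), c(-1, -1, 0)), 0,
               tolerance = 1e-5)  # sign-invariant (up to acos rounding)
  expect_equal(axis_angle(c(1, 0, 0), c(1, 1, 0)), 45)
  expect_error(axis_angle(c(0, 0, 0), c(1, 0, 0)),
               class = "meioarch_validation_error")
  set.seed(7)
  for (i in 1:100) {
    u <- rnorm(3); v <- rnorm(3)
    a <- axis_angle(u, v)
    expect_true(a >= 0 && a <= 90)
    expect_equal(axis_angle(-u, v), a)
    expect_equal(axis_angle(3 * u, -2 * v), a)
  }
})

test_that("assign_sister_pairs picks the most proximal pair first", {
  # square of side 1 um with one side shortened to 0.4 um
  sq <- mk_spots(c(0, 0, 0,  0.4, 0, 0,  0, 1, 0,  1, 1, 0))
  prs <- assign_sister_pairs(sq)
  expect_equal(nrow(prs), 2L)
  expect_equal(sort(prs$distance_um), c(0.4, 1.0))
  got <- lapply(seq_len(2), function(k) sort(c(prs$spot_id_1[k], prs$spot_id_2[k])))
  expect_true(list(c("S01", "S02")) %in% got)
  expect_true(list(c("S03", "S04")) %in% got)

  # two tight doublets 0.2 um wide, 1.5 um apart
  db <- mk_spots(c(0, 0, 0,  0.2, 0, 0,  1.5, 0, 0,  1.7, 0, 0))
  prs <- assign_sister_pairs(db)
  got <- lapply(seq_len(2), function(k) sort(c(prs$spot_id_1[k], prs$spot_id_2[k])))
  expect_true(list(c("S01", "S02")) %in% got)
  expect_equal(sort(prs$distance_um), c(0.2, 0.2))
})

test_that("assign_sister_pairs handles merged spots and rejects bad input", {
  m <- mk_spots(c(0, 0, 0,  1, 0, 0,  1.4, 0, 0), merged = c(TRUE, FALSE, FALSE))
  prs <- assign_sister_pairs(m)
  expect_equal(nrow(prs), 2L)
  one <- prs[prs$n_spots == 1L, ]
  expect_equal(one$distance_um, 0)
  expect_true(is.na(one$ax))
  two <- prs[prs$n_spots == 2L, ]
  expect_equal(two$distance_um, 0.4)
  expect_equal(sqrt(two$ax^2 + two$ay^2 + two$az^2), 1)  # unit pair axis

  expect_error(assign_sister_pairs(mk_spots(rep(0, 15))),
               class = "meioarch_validation_error")  # 5 unmerged spots
  expect_error(assign_sister_pairs(mk_spots(rep(0, 9))),
               class = "meioarch_validation_error")  # odd unmerged count
})

test_that("assign_sister_pairs matches the exhaustive oracle on random quadruples", {
  set.seed(11)
  for (i in 1:100) {
    sp <- mk_spots(runif(12, 0, 3))
    prs <- assign_sister_pairs(sp)
    got <- lapply(seq_len(2), function(k)
      sort(c(prs$spot_id_1[k], prs$spot_id_2[k])))
    want <- oracle_pairs(sp)
    expect_true(list(want$first) %in% got, label = paste("iter", i))
    expect_true(list(want$second) %in% got, label = paste("iter", i))
  }
})
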