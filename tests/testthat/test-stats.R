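test_that("frequency_table returns integer counts and per-group proportions", {
  ft <- frequency_table(c("split", "split", "split", "unified", "unified"))
  expect_equal(ft$n[ft$label == "split"], 3L)
  expect_equal(ft$prop[ft$label == "split"], 0.6)
  expect_equal(sum(ft$prop), 1)

  ft <- frequency_table("a")
  expect_equal(ft$prop, 1)

  # empty forced group: count 0, proportion flagged undefined
  ft <- frequency_table(c("a", "b"), c("g1", "g1"), groups = c("g1", "g2"))
  g2 <- ft[ft$group == "g2", ]
  expect_true(all(g2$n == 0L))
  expect_true(all(is.na(g2$prop)))
  expect_error(frequency_table(c("a"), c("g", "g")),
               class = "meioarch_validation_error")
})

test_that("proportions are scale-free under record duplication", {
  set.seed(3)
  labels <- sample(letters[1:4], 60, replace = TRUE)
  grp <- sample(c("x", "y"), 60, replace = TRUE)
  a <- frequency_table(labels, grp)
  b <- frequency_table(rep(labels, 2), rep(grp, 2))
  expect_equal(a$prop, b$prop)
  expect_equal(b$n, 2L * a$n)
})

test_that("fisher_exact_2x2 reproduces known exact p-values", {
  # fully discordant table: p = 2 / choose(20, 10)
  expect_equal(fisher_exact_2x2(matrix(c(0, 10, 10, 0), 2, byrow = TRUE)),
               2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(0, 10, 10, 0), 2, byrow = TRUE)),
               1.0825088e-5, tolerance = 1e-6)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(0L, 2, 2)), 1)
  expect_error(fisher_exact_2x2(1, 2, -1, 0),
               class = "meioarch_validation_error")
  expect_error(fisher_exact_2x2(1.5, 2, 1, 0),
               class = "meioarch_validation_error")
})

test_that("fisher_exact_2x2 agrees with stats::fisher.test on random tables", {
  set.seed(13)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(1:25, 1)), 2)
    expect_equal(fisher_exact_2x2(tab), stats::fisher.test(tab)$p.value,
                 tolerance = 1e-9, label = paste(tab, collapse = ","))
  }
})

test_that("t_test_two_tailed matches the pooled-variance formula", {
  r <- t_test_two_tailed(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3.674, tolerance = 1e-3)
  expect_equal(r$dof, 4)
  expect_equal(r$p, 2 * pt(-abs(r$t), 4))
  expect_equal(r$p, stats::t.test(c(1, 2, 3), c(4, 5, 6),
                                  var.equal = TRUE)$p.value)

  ident <- t_test_two_tailed(c(2, 2.5, 3), c(2, 2.5, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)

  # zero variance, equal/unequal means
  expect_equal(t_test_two_tailed(c(1, 1), c(1, 1))$p, 1)
  deg <- t_test_two_tailed(c(1, 1), c(2, 2))
  expect_equal(deg$p, 0)
  expect_true(deg$degenerate)
  expect_error(t_test_two_tailed(1, c(1, 2)),
               class = "meioarch_validation_error")

  # Welch flag reproduces stats::t.test default
  a <- rnorm(10); b <- rnorm(12, sd = 3)
  expect_equal(t_test_two_tailed(a, b, welch = TRUE)$p,
               stats::t.test(a, b)$p.value)
})

test_that("t-test type-I error is calibrated under the null", {
  set.seed(29)
  nrep <- 10000L; n <- 10L
  p <- vapply(seq_len(nrep), function(i)
    t_test_two_tailed(rnorm(n), rnorm(n))$p, numeric(1))
  rate <- mean(p < 0.05)
  se <- sqrt(0.05 * 0.95 / nrep)
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("age_trend fits ordinary least squares with Pearson r", {
  age <- c(24, 28, 32, 36, 40)
  r <- age_trend(0.5 + 0.02 * age, age)
  expect_equal(r$slope, 0.02)
  expect_equal(r$intercept, 0.5)
  expect_equal(r$r, 1)
  flat <- age_trend(rep(0.7, 5) + c(1, -1, 1, -1, 0) * 1e-9, age)
  expect_lt(abs(flat$slope), 1e-9)
  expect_error(age_trend(c(1, 2, 3), c(30, 30, 30)),
               class = "meioarch_validation_error")
  expect_error(age_trend(c(1, 2), c(30, 31)),
               class = "meioarch_validation_error")
})

test_that("age_trend recovers the simulated increase of distance with age", {
  sims <- lapply(seq(24, 42, by = 2), function(a) {
    co <- simulate_cohort(profile_for_age(a, seed = 50 + a), n_oocytes = 2)
    cl <- classify_cohort(co)
    inc <- !cl$pairs$excluded_at_pole
    data.frame(age = a, mean_d = mean(cl$pairs$report_distance_um[inc]))
  })
  sims <- do.call(rbind, sims)
  tr <- age_trend(sims$mean_d, sims$age)
  expect_gt(tr$slope, 0)
  expect_gt(tr$r, 0.5)
})

test_that("age_group bins donors with the 35-year boundary in the middle bin", {
  expect_equal(as.character(age_group(c(23, 29.9, 30, 35, 35.1, 46))),
               c("under30", "under30", "from30to35", "from30to35",
                 "over35", "over35"))
  expect_error(age_group(-1), class = "meioarch_validation_error")
})

test_that("anaphase_summary stratifies efficiency and timing", {
  tl <- simulate_timelapse_cohort(2000, seed = 53)
  s <- anaphase_summary(tl)
  expect_equal(s$efficiency$efficiency[s$efficiency$severity == "none"], 1)
  expect_equal(s$efficiency$efficiency[s$efficiency$severity == "mild"], 1)
  sev <- s$efficiency[s$efficiency$severity == "severe", ]
  expect_equal(sev$efficiency, sev$n_progressed / sev$n)
  expect_lt(abs(sev$efficiency - 0.92), 3 * sqrt(0.92 * 0.08 / sev$n))
  expect_true(all(s$onset_by_severity$mean_h > s$congression$mean_h - 5,
                  na.rm = TRUE))
  # records without an NEBD reference are excluded with a warning
  tl$t_nebd_h[1:5] <- NA
  expect_warning(s2 <- anaphase_summary(tl), "excluded 5")
  expect_equal(s2$n_excluded, 5L)
})
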