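# Frequency tables, exact and t tests, age-trend regression and
# anaphase-timing summaries.

#' Assign donor ages to the reporting age groups
#'
#' Bins are `under30` (< 30 years), `from30to35` (30 to 35 inclusive; the
#' boundary at exactly 35 belongs to the middle bin) and `over35`
#' (> 35 years).
#'
#' @param age numeric vector of donor ages in years.
#' @return factor with levels `under30`, `from30to35`, `over35`.
#' @export
age_group <- function(age) {
  if (any(!is.finite(age) | age < 0)) ma_stop("age_group: invalid age")
  factor(ifelse(age < 30, "under30", ifelse(age <= 35, "from30to35", "over35")),
         levels = c("under30", "from30to35", "over35"))
}

#' Derive misalignment severity from the misaligned-chromosome count
#'
#' 0 misaligned chromosomes at anaphase onset is `none`, 1-3 is `mild`,
#' more than 3 is `severe`.
#'
#' @param n_misaligned integer vector of counts.
#' @return character vector of severities.
#' @export
severity_from_misaligned <- function(n_misaligned) {
  if (any(n_misaligned < 0)) ma_stop("severity_from_misaligned: negative count")
  ifelse(n_misaligned == 0, "none", ifelse(n_misaligned <= 3, "mild", "severe"))
}

#' Grouped frequency table with integer counts and proportions
#'
#' Every reported percentage in the package derives from the integer counts
#' in the same table. Empty groups are reported with count 0 and an
#' NA (undefined) proportion.
#'
#' @param labels vector of category labels.
#' @param group_by optional grouping vector of the same length (a single
#'   group when NULL).
#' @param levels optional label levels to force into the table.
#' @param groups optional group levels to force (so empty groups appear).
#' @return data.frame with `group`, `label`, `n`, `n_group`, `prop`.
#' @export
frequency_table <- function(labels, group_by = NULL, levels = NULL,
                            groups = NULL) {
  if (is.null(group_by)) group_by <- rep("all", length(labels))
  if (length(labels) != length(group_by))
    ma_stop("frequency_table: labels and group_by lengths differ")
  keep <- !is.na(labels) & !is.na(group_by)
  labels <- as.character(labels[keep]); group_by <- as.character(group_by[keep])
  if (is.null(levels)) levels <- sort(unique(labels))
  if (is.null(groups)) groups <- sort(unique(group_by))
  tab <- table(factor(group_by, levels = groups),
               factor(labels, levels = levels))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("group", "label", "n")
  ng <- rowSums(tab)
  out$n_group <- ng[out$group]
  out$prop <- ifelse(out$n_group > 0, out$n / out$n_group, NA_real_)
  out[order(out$group, out$label), , drop = FALSE]
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditional on the observed margins, the exact two-sided p-value is the
#' sum of hypergeometric probabilities of all tables whose probability does
#' not exceed the observed table's (within a relative slack of 1e-12, so
#' that exact ties are included despite floating-point rounding).
#'
#' @param table 2x2 matrix of non-negative integer counts, or the count `a`
#'   when `b`, `c`, `d` are given separately.
#' @param b,c,d remaining cells (row-wise: `a`,`b` / `c`,`d`).
#' @return two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)) # 1
#' @export
fisher_exact_2x2 <- function(table, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(table) || inherits(table, "table")) {
    if (!all(dim(table) == c(2L, 2L))) ma_stop("fisher_exact_2x2: need a 2x2 table")
    a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  } else a <- table
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    ma_stop("fisher_exact_2x2: counts must be non-negative integers")
  n <- a + b + c + d
  if (n == 0) return(1)
  r1 <- a + b; c1 <- a + c
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  x <- lo:hi
  pmf <- stats::dhyper(x, c1, n - c1, r1)
  p_obs <- pmf[x == a]
  min(1, sum(pmf[pmf <= p_obs * (1 + 1e-12)]))
}

#' Two-tailed two-sample Student's t-test
#'
#' Pooled-variance Student's t by default (Welch's unequal-variance form is
#' available behind a flag). With zero pooled variance the p-value is 1 for
#' equal means and 0 (flagged degenerate) for unequal means.
#'
#' @param sample_a,sample_b numeric samples, each of length >= 2.
#' @param welch use Welch's correction instead of the pooled variance.
#' @return list: `t`, `dof`, `p`, `mean_a`, `mean_b`, `degenerate`.
#' @export
t_test_two_tailed <- function(sample_a, sample_b, welch = FALSE) {
  na <- length(sample_a); nb <- length(sample_b)
  if (na < 2L || nb < 2L) ma_stop("t_test_two_tailed: each sample needs n >= 2")
  ma <- mean(sample_a); mb <- mean(sample_b)
  va <- stats::var(sample_a); vb <- stats::var(sample_b)
  if (welch) {
    se2 <- va / na + vb / nb
    dof <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    dof <- na + nb - 2
  }
  if (se2 <= 0) {
    if (ma == mb) return(list(t = 0, dof = dof, p = 1, mean_a = ma,
                              mean_b = mb, degenerate = TRUE))
    return(list(t = sign(ma - mb) * Inf, dof = dof, p = 0, mean_a = ma,
                mean_b = mb, degenerate = TRUE))
  }
  t <- (ma - mb) / sqrt(se2)
  list(t = t, dof = dof, p = 2 * stats::pt(-abs(t), dof),
       mean_a = ma, mean_b = mb, degenerate = FALSE)
}

#' Linear trend of mean sister-kinetochore distance with donor age
#'
#' Ordinary least squares of the per-oocyte mean distance on donor age,
#' with the Pearson correlation.
#'
#' @param mean_distance numeric, per-oocyte mean sister distances (um).
#' @param age numeric donor ages (years), same length, at least 3 oocytes.
#' @return list: `slope` (um/year), `intercept`, `r`.
#' @export
age_trend <- function(mean_distance, age) {
  if (length(mean_distance) != length(age) || length(age) < 3L)
    ma_stop("age_trend: need >= 3 paired observations")
  keep <- is.finite(mean_distance) & is.finite(age)
  mean_distance <- mean_distance[keep]; age <- age[keep]
  if (length(age) < 3L) ma_stop("age_trend: need >= 3 finite observations")
  if (stats::var(age) == 0) ma_stop("age_trend: constant age, trend undefined")
  fit <- stats::lm.fit(cbind(1, age), mean_distance)
  r <- if (stats::var(mean_distance) == 0) 0 else
    stats::cor(age, mean_distance)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]), r = r)
}

#' Anaphase efficiency and timing summary of a time-lapse cohort
#'
#' Per severity stratum: the fraction of oocytes that progressed into
#' anaphase (with integer numerators/denominators) and the NEBD-relative
#' anaphase-onset mean and s.d. among progressed oocytes; onset timing is
#' also stratified by the lagging-chromosome flag, and congression times
#' are summarised overall.
#'
#' @param records data.frame from [simulate_timelapse_cohort()] (or a read
#'   time-lapse table). Records lacking an NEBD reference are excluded with
#'   a warning count.
#' @return list of data.frames: `efficiency`, `onset_by_severity`,
#'   `onset_by_lagging`, `congression`; plus `n_excluded`.
#' @export
anaphase_summary <- function(records) {
  n_excluded <- sum(!is.finite(records$t_nebd_h))
  if (n_excluded > 0) {
    warning(sprintf("anaphase_summary: excluded %d records without NEBD time",
                    n_excluded))
    records <- records[is.finite(records$t_nebd_h), , drop = FALSE]
  }
  sev_lv <- c("none", "mild", "severe")
  records$severity <- factor(records$severity, levels = sev_lv)
  eff <- do.call(rbind, lapply(sev_lv, function(s) {
    r <- records[records$severity == s, , drop = FALSE]
    data.frame(severity = s, n = nrow(r), n_progressed = sum(r$progressed),
               efficiency = if (nrow(r)) mean(r$progressed) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  onset_stats <- function(r) {
    t <- r$t_anaphase_onset_h - r$t_nebd_h
    t <- t[is.finite(t)]
    data.frame(n = length(t),
               mean_h = if (length(t)) mean(t) else NA_real_,
               sd_h = if (length(t) > 1) stats::sd(t) else NA_real_)
  }
  onset_sev <- do.call(rbind, lapply(sev_lv, function(s) {
    cbind(data.frame(severity = s, stringsAsFactors = FALSE),
          onset_stats(records[records$severity == s, , drop = FALSE]))
  }))
  onset_lag <- do.call(rbind, lapply(c(FALSE, TRUE), function(l) {
    cbind(data.frame(lagging = l),
          onset_stats(records[records$lagging == l, , drop = FALSE]))
  }))
  cong <- records$t_congression_h - records$t_nebd_h
  cong <- cong[is.finite(cong)]
  list(efficiency = eff, onset_by_severity = onset_sev,
       onset_by_lagging = onset_lag,
       congression = data.frame(n = length(cong), mean_h = mean(cong),
                                sd_h = stats::sd(cong)),
       n_excluded = n_excluded)
}
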