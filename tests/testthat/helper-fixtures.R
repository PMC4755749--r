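# Shared fixture builders: everything is generated in code at test time.

noise_free_profile <- function(seed = 1L, ...) {
  baseline_profile("young", seed = seed, noise_sigma_um = c(0, 0, 0), ...)
}

mk_spots <- function(xyz, bivalent_id = "B01", oocyte_id = "O1",
                     radius_um = 0.4, merged = FALSE, homolog_id = NA_integer_,
                     spot_id = NULL) {
  xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  n <- nrow(xyz)
  data.frame(oocyte_id = oocyte_id, bivalent_id = bivalent_id,
             homolog_id = rep_len(homolog_id, n),
             spot_id = if (is.null(spot_id)) sprintf("S%02d", seq_len(n))
               else spot_id,
             x_um = xyz[, 1], y_um = xyz[, 2], z_um = xyz[, 3],
             radius_um = rep_len(radius_um, n),
             merged = rep_len(merged, n), stringsAsFactors = FALSE)
}

mk_fibers <- function(pole_index, contact = "end_on", trunk_group = NA_character_,
                      start = c(0, 0, 0), ends = NULL, spot_id = "S01") {
  n <- length(pole_index)
  if (is.null(ends)) ends <- t(vapply(pole_index, function(p)
    c(ifelse(p == 0, -6, 6), 0, 0), numeric(3)))
  ends <- matrix(ends, ncol = 3, byrow = FALSE)
  start <- matrix(rep(start, length.out = 3 * n), ncol = 3, byrow = TRUE)
  data.frame(oocyte_id = "O1", fiber_id = sprintf("F%02d", seq_len(n)),
             spot_id = rep_len(spot_id, n), bivalent_id = "B01",
             homolog_id = 1L, pole_index = pole_index,
             start_x_um = start[, 1], start_y_um = start[, 2],
             start_z_um = start[, 3],
             end_x_um = ends[, 1], end_y_um = ends[, 2], end_z_um = ends[, 3],
             contact = rep_len(contact, n),
             trunk_group = rep_len(trunk_group, n), stringsAsFactors = FALSE)
}

# independent brute-force oracle for sister-pair assignment: enumerate the 6
# candidate pairs, take the minimum-distance pair (lexicographic tie-break
# on the sorted spot-id tuple), remainder is the second pair
oracle_pairs <- function(spots) {
  xyz <- as.matrix(spots[, c("x_um", "y_um", "z_um")])
  cand <- utils::combn(seq_len(4), 2)
  dd <- apply(cand, 2, function(ij) sqrt(sum((xyz[ij[1], ] - xyz[ij[2], ])^2)))
  best <- which(dd <= min(dd) + 1e-9)
  if (length(best) > 1) {
    keys <- vapply(best, function(k)
      paste(sort(spots$spot_id[cand[, k]]), collapse = "\r"), character(1))
    best <- best[order(keys)][1]
  }
  first <- sort(spots$spot_id[cand[, best[1]]])
  second <- sort(setdiff(spots$spot_id, first))
  list(first = first, second = second)
}

# independent hypergeometric enumeration oracle for the exact test, built
# from log-binomial coefficients rather than dhyper
oracle_fisher <- function(a, b, c, d) {
  n <- a + b + c + d
  if (n == 0) return(1)
  r1 <- a + b; c1 <- a + c
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  x <- lo:hi
  lp <- lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1)
  p <- exp(lp)
  min(1, sum(p[p <= p[x == a] * (1 + 1e-12)]))
}

# truth/classification agreement report for a simulated cohort
recovery_report <- function(cohort, classified) {
  b <- classified$bivalents
  tb <- cohort$truth_bivalents[match(paste(b$oocyte_id, b$bivalent_id),
                                     paste(cohort$truth_bivalents$oocyte_id,
                                           cohort$truth_bivalents$bivalent_id)), ]
  p <- classified$pairs
  tp <- cohort$truth_pairs[match(paste(p$oocyte_id, p$bivalent_id, p$homolog_id),
                                 paste(cohort$truth_pairs$oocyte_id,
                                       cohort$truth_pairs$bivalent_id,
                                       cohort$truth_pairs$homolog_id)), ]
  u <- classified$univalents
  tu <- cohort$truth_pairs[match(paste(u$oocyte_id, u$origin_bivalent_id,
                                       u$homolog_id),
                                 paste(cohort$truth_pairs$oocyte_id,
                                       cohort$truth_pairs$bivalent_id,
                                       cohort$truth_pairs$homolog_id)), ]
  list(
    homologs_resolved = !anyNA(tp$configuration),
    config = mean(p$configuration == tp$configuration),
    attach = mean(p$attach_mode == tp$expected_attach_mode),
    fiber_type = mean(p$fiber_type == tp$expected_fiber_type),
    n_fibers = mean(p$n_fibers == tp$expected_n_fibers),
    at_pole = mean(p$excluded_at_pole == tp$at_pole),
    rotation = mean(is.na(tb$expected_rotation) |
                      b$rotation == tb$expected_rotation),
    twist = mean(is.na(tb$expected_twist) |
                   (!is.na(b$twist) & b$twist == tb$expected_twist)),
    cohesion = mean(b$cohesion_state == tb$cohesion_state),
    univ_bioriented = if (nrow(u)) mean(u$bioriented == tu$univ_bioriented)
      else NA_real_,
    univ_position = if (nrow(u)) mean(u$position == tu$univ_position)
      else NA_real_)
}
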