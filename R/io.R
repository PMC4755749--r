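# Table readers/writers, pipeline configuration and the end-to-end pipeline.
# All tables are comma-delimited UTF-8 with one header row; column names are
# snake_case with unit suffixes (x_um, angle_deg). World coordinates are
# continuous um; voxel-indexed data are converted at this boundary with
# voxel centres at half-integer world offsets.

SPOT_COLUMNS <- c("oocyte_id", "bivalent_id", "homolog_id", "spot_id",
                  "x_um", "y_um", "z_um", "radius_um", "merged")
FIBER_COLUMNS <- c("oocyte_id", "fiber_id", "spot_id", "bivalent_id",
                   "homolog_id", "pole_index", "start_x_um", "start_y_um",
                   "start_z_um", "end_x_um", "end_y_um", "end_z_um",
                   "contact", "trunk_group")
CHROMATIN_COLUMNS <- c("oocyte_id", "bivalent_id", "homolog_id",
                       "cx_um", "cy_um", "cz_um", "extent_um")
SPINDLE_COLUMNS <- c("oocyte_id", "donor_age", "stage", "cold_treated",
                     "pole0_x_um", "pole0_y_um", "pole0_z_um",
                     "pole1_x_um", "pole1_y_um", "pole1_z_um")
TIMELAPSE_COLUMNS <- c("oocyte_id", "t_nebd_h", "t_congression_h",
                       "t_anaphase_onset_h", "n_misaligned", "severity",
                       "lagging", "progressed")

read_table_checked <- function(path, required, numeric_cols = character(0),
                               unique_cols = character(0), what = "table") {
  if (!file.exists(path)) ma_stop(paste0(what, ": file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    ma_stop(sprintf("%s %s: missing required column(s): %s", what, path,
                    paste(missing, collapse = ", ")))
  for (cl in numeric_cols) {
    v <- df[[cl]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(df[[cl]]) & is.na(v))
    if (length(bad))
      ma_stop(sprintf("%s %s: non-numeric value in column %s at row %d",
                      what, path, cl, bad[1]))
    df[[cl]] <- v
  }
  for (cl in unique_cols) {
    dup <- which(duplicated(df[[cl]]))
    if (length(dup))
      ma_stop(sprintf("%s %s: duplicate %s '%s' at row %d", what, path, cl,
                      df[[cl]][dup[1]], dup[1]))
  }
  df
}

#' Read a kinetochore spot table
#'
#' Validates the documented schema (coordinates in um), coerces types and
#' reports schema violations with row numbers. Unknown columns are
#' preserved.
#'
#' @param path CSV file path.
#' @return data.frame of spots ordered by oocyte.
#' @export
read_spot_table <- function(path) {
  df <- read_table_checked(path, SPOT_COLUMNS,
                           numeric_cols = c("x_um", "y_um", "z_um", "radius_um"),
                           unique_cols = "spot_id", what = "spot table")
  df$merged <- as.logical(df$merged)
  df$homolog_id <- as.integer(df$homolog_id)
  if (any(!is.na(df$radius_um) & df$radius_um <= 0))
    ma_stop("spot table: radius_um must be > 0")
  df[order(df$oocyte_id, df$bivalent_id, df$spot_id), , drop = FALSE]
}

#' Read a k-fibre table
#' @param path CSV file path.
#' @return data.frame of fibre records.
#' @export
read_fiber_table <- function(path) {
  df <- read_table_checked(path, FIBER_COLUMNS,
                           numeric_cols = c("start_x_um", "start_y_um",
                                            "start_z_um", "end_x_um",
                                            "end_y_um", "end_z_um"),
                           unique_cols = "fiber_id", what = "fiber table")
  df$pole_index <- as.integer(df$pole_index)
  if (any(!df$pole_index %in% c(0L, 1L)))
    ma_stop("fiber table: pole_index must be 0 or 1")
  if (any(!df$contact %in% c("end_on", "lateral")))
    ma_stop("fiber table: contact must be end_on or lateral")
  df$trunk_group <- as.character(df$trunk_group)
  df$trunk_group[df$trunk_group %in% c("", "NA")] <- NA_character_
  df
}

#' Read a chromatin-envelope table
#' @param path CSV file path.
#' @return data.frame of chromatin records.
#' @export
read_chromatin_table <- function(path) {
  read_table_checked(path, CHROMATIN_COLUMNS,
                     numeric_cols = c("cx_um", "cy_um", "cz_um", "extent_um"),
                     what = "chromatin table")
}

#' Read a spindle table
#' @param path CSV file path.
#' @return data.frame with one row per oocyte.
#' @export
read_spindle_table <- function(path) {
  df <- read_table_checked(path, SPINDLE_COLUMNS,
                           numeric_cols = c("donor_age", "pole0_x_um",
                                            "pole0_y_um", "pole0_z_um",
                                            "pole1_x_um", "pole1_y_um",
                                            "pole1_z_um"),
                           unique_cols = "oocyte_id", what = "spindle table")
  df$cold_treated <- as.logical(df$cold_treated)
  df
}

#' Read a time-lapse table
#' @param path CSV file path.
#' @return data.frame of time-lapse records.
#' @export
read_timelapse_table <- function(path) {
  df <- read_table_checked(path, TIMELAPSE_COLUMNS,
                           numeric_cols = c("t_nebd_h", "t_congression_h",
                                            "t_anaphase_onset_h"),
                           what = "timelapse table")
  df$n_misaligned <- as.integer(df$n_misaligned)
  df$lagging <- as.logical(df$lagging)
  df$progressed <- as.logical(df$progressed)
  df
}

#' Write a cohort to a directory of CSV tables
#'
#' Emits `spots.csv`, `fibers.csv`, `chromatin.csv`, `spindles.csv`,
#' `truth_pairs.csv`, `truth_bivalents.csv` (and `truth_spots.csv`); every
#' file re-reads losslessly through the package's readers.
#'
#' @param cohort a `meioarch_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(spots = "spots.csv", fibers = "fibers.csv",
             chromatin = "chromatin.csv", spindles = "spindles.csv",
             truth_spots = "truth_spots.csv", truth_pairs = "truth_pairs.csv",
             truth_bivalents = "truth_bivalents.csv")
  written <- character(0)
  for (nm in names(files)) {
    if (is.null(cohort[[nm]])) next
    p <- file.path(dir, files[[nm]])
    utils::write.csv(cohort[[nm]], p, row.names = FALSE, quote = FALSE)
    written <- c(written, p)
  }
  invisible(written)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir directory containing the CSV tables.
#' @return a `meioarch_cohort` (without a generator profile).
#' @export
read_cohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  out <- list(
    spots = read_spot_table(p("spots.csv")),
    fibers = if (file.exists(p("fibers.csv"))) read_fiber_table(p("fibers.csv")) else NULL,
    chromatin = if (file.exists(p("chromatin.csv")))
      read_chromatin_table(p("chromatin.csv")) else NULL,
    spindles = read_spindle_table(p("spindles.csv")),
    truth_pairs = if (file.exists(p("truth_pairs.csv")))
      utils::read.csv(p("truth_pairs.csv"), stringsAsFactors = FALSE) else NULL,
    truth_bivalents = if (file.exists(p("truth_bivalents.csv")))
      utils::read.csv(p("truth_bivalents.csv"), stringsAsFactors = FALSE) else NULL)
  structure(out, class = "meioarch_cohort")
}

# ---------------------------------------------------------------------------
# Summaries

#' Summarise a classified cohort
#'
#' Builds the frequency tables and headline rates of the analysis. All
#' percentages derive from the integer counts carried in the same tables.
#' Reporting conventions: configuration statistics exclude bivalents at the
#' spindle poles (not under tension); attachment-mode statistics are
#' restricted to cold-treated oocytes and to pairs of normally oriented
#' (non-inverted) bivalent units; twist is reported for scorable
#' (both-pairs-split), non-inverted bivalents; cohesion states are reported
#' over all bivalent slots.
#'
#' @param classified result of [classify_cohort()].
#' @return list with data.frames (`config_by_age`, `attach_by_stratum`,
#'   `rotation`, `twist`, `cohesion`, `univalents`) and a `rates` list of
#'   headline percentages with their integer numerators/denominators.
#' @export
summarize_classification <- function(classified) {
  pairs <- classified$pairs
  biv <- classified$bivalents
  oo <- classified$oocytes
  uni <- classified$univalents

  pairs$age <- oo$donor_age[match(pairs$oocyte_id, oo$oocyte_id)]
  pairs$age_grp <- as.character(age_group(pairs$age))
  pairs$cold <- oo$cold_treated[match(pairs$oocyte_id, oo$oocyte_id)]
  rot_of <- biv$rotation[match(paste(pairs$oocyte_id, pairs$bivalent_id),
                               paste(biv$oocyte_id, biv$bivalent_id))]
  pairs$stratum <- ifelse(pairs$configuration %in%
                            c("indistinguishable", "overlapping"),
                          "unified", pairs$configuration)

  inc <- !pairs$excluded_at_pole
  config_by_age <- frequency_table(pairs$configuration[inc],
                                   pairs$age_grp[inc],
                                   levels = CONFIG_LEVELS)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  rates <- list()
  rates$split <- list(n = sum(pairs$split[inc]), total = sum(inc),
                      pct = pct(sum(pairs$split[inc]), sum(inc)))

  elig <- inc & pairs$cold & pairs$unit_type == "bivalent" &
    (is.na(rot_of) | !rot_of %in% c("half_inverted", "fully_inverted"))
  attach_by_stratum <- frequency_table(
    pairs$attach_mode[elig], pairs$stratum[elig],
    levels = c("amphitelic", "merotelic", "lateral", "unattached"),
    groups = c("unified", "distinct", "separated"))
  mero <- function(sel) list(n = sum(pairs$attach_mode[sel] == "merotelic"),
                             total = sum(sel),
                             pct = pct(sum(pairs$attach_mode[sel] == "merotelic"),
                                       sum(sel)))
  rates$merotelic_overall <- mero(elig)
  for (s in c("unified", "distinct", "separated"))
    rates[[paste0("merotelic_", s)]] <- mero(elig & pairs$stratum == s)

  att <- elig & pairs$split & pairs$n_fibers >= 1L
  rates$two_fibers_split <- list(
    n = sum(pairs$fiber_type[att] %in% c("A", "B")), total = sum(att),
    pct = pct(sum(pairs$fiber_type[att] %in% c("A", "B")), sum(att)))

  rot_scored <- !is.na(biv$rotation)
  rotation <- frequency_table(biv$rotation[rot_scored],
                              levels = c("in_axis", "half_inverted",
                                         "fully_inverted", "ambiguous"))
  n_inv <- sum(biv$rotation[rot_scored] %in% c("half_inverted", "fully_inverted"))
  rates$inverted <- list(n = n_inv, total = sum(rot_scored),
                         pct = pct(n_inv, sum(rot_scored)))

  tw_sel <- !is.na(biv$twist) & biv$twist != "not_scorable" &
    !biv$rotation %in% c("half_inverted", "fully_inverted")
  twist <- frequency_table(biv$twist[tw_sel],
                           levels = c("undistorted", "twisted"))
  rates$twisted <- list(n = sum(biv$twist[tw_sel] == "twisted"),
                        total = sum(tw_sel),
                        pct = pct(sum(biv$twist[tw_sel] == "twisted"),
                                  sum(tw_sel)))

  coh_scored <- !is.na(biv$cohesion_state)
  cohesion <- frequency_table(biv$cohesion_state[coh_scored],
                              levels = c("intact", "weak_gap", "disintegrated"))
  rates$weak_gap <- list(n = sum(biv$cohesion_state[coh_scored] == "weak_gap"),
                         total = sum(coh_scored),
                         pct = pct(sum(biv$cohesion_state[coh_scored] == "weak_gap"),
                                   sum(coh_scored)))
  rates$disintegrated <- list(
    n = sum(biv$cohesion_state[coh_scored] == "disintegrated"),
    total = sum(coh_scored),
    pct = pct(sum(biv$cohesion_state[coh_scored] == "disintegrated"),
              sum(coh_scored)))

  rates$oocytes_with_univalents <- list(
    n = sum(oo$has_univalents), total = nrow(oo),
    pct = pct(sum(oo$has_univalents), nrow(oo)))
  rates$univalent_bioriented <- list(
    n = sum(uni$bioriented), total = nrow(uni),
    pct = pct(sum(uni$bioriented), nrow(uni)))

  list(config_by_age = config_by_age, attach_by_stratum = attach_by_stratum,
       rotation = rotation, twist = twist, cohesion = cohesion,
       univalents = uni, rates = rates)
}

#' Render a human-readable text report from a summary
#' @param summaries result of [summarize_classification()].
#' @return character vector of report lines.
#' @export
report_lines <- function(summaries) {
  r <- summaries$rates
  fmt <- function(nm, x) sprintf("%-28s %5d / %5d  (%.1f%%)", nm, x$n, x$total,
                                 x$pct)
  c("meioarch classification report",
    "------------------------------",
    fmt("split pairs", r$split),
    fmt("merotelic (overall)", r$merotelic_overall),
    fmt("merotelic | unified", r$merotelic_unified),
    fmt("merotelic | distinct", r$merotelic_distinct),
    fmt("merotelic | separated", r$merotelic_separated),
    fmt("two k-fibres | split", r$two_fibers_split),
    fmt("inverted bivalents", r$inverted),
    fmt("twisted | scorable", r$twisted),
    fmt("weak arm cohesion", r$weak_gap),
    fmt("disintegrated bivalents", r$disintegrated),
    fmt("oocytes with univalents", r$oocytes_with_univalents),
    if (r$univalent_bioriented$total > 0)
      fmt("univalents bioriented", r$univalent_bioriented)
    else "univalents bioriented            none observed")
}

# ---------------------------------------------------------------------------
# Pipeline configuration and end-to-end run

#' Build a pipeline configuration
#'
#' @param profile profile name (`"young"`, `"mid"`, `"over35"`), a
#'   [cohort_profile()], or a list with `name` plus overrides.
#' @param seed integer seed (overrides the profile seed).
#' @param n_oocytes optional cohort-size override.
#' @param thresholds an [angle_thresholds()].
#' @param resolution a [resolution_model()].
#' @param at_pole_fraction pole-exclusion fraction of spindle length.
#' @param outdir output directory, or NULL for no file output.
#' @param log_level `"info"` or `"quiet"`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(profile = "young", seed = 1L, n_oocytes = NULL,
                            thresholds = angle_thresholds(),
                            resolution = resolution_model(),
                            at_pole_fraction = 0.1, outdir = NULL,
                            log_level = "info") {
  structure(list(profile = profile, seed = as.integer(seed),
                 n_oocytes = n_oocytes, thresholds = thresholds,
                 resolution = resolution,
                 at_pole_fraction = at_pole_fraction, outdir = outdir,
                 log_level = log_level),
            class = "pipeline_config")
}

resolve_profile <- function(profile, seed = NULL, n_oocytes = NULL) {
  pr <- if (inherits(profile, "cohort_profile")) {
    profile
  } else if (is.character(profile)) {
    baseline_profile(profile, seed = if (is.null(seed)) 1L else seed)
  } else if (is.list(profile)) {
    nm <- if (!is.null(profile$name)) profile$name else "young"
    args <- profile[setdiff(names(profile), "name")]
    do.call(baseline_profile, c(list(name = nm), args))
  } else ma_stop("resolve_profile: unsupported profile specification")
  if (!is.null(seed)) pr$seed <- as.integer(seed)
  if (!is.null(n_oocytes)) pr$n_oocytes <- as.integer(n_oocytes)
  pr
}

#' Save / load a pipeline configuration as JSON
#'
#' The configuration round-trips losslessly: profiles are stored as their
#' full parameter list.
#'
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @return `read_pipeline_config` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  ser <- unclass(config)
  keep_names <- function(x) {
    if (inherits(x, c("resolution_model", "angle_thresholds"))) unclass(x)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)  # keep JSON keys
    else if (is.list(x)) lapply(x, keep_names)
    else x
  }
  if (inherits(ser$profile, "cohort_profile"))
    ser$profile <- lapply(unclass(ser$profile), keep_names)
  ser$thresholds <- unclass(ser$thresholds)
  ser$resolution <- unclass(ser$resolution)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  thr <- do.call(angle_thresholds, raw$thresholds)
  res <- do.call(resolution_model, raw$resolution)
  profile <- raw$profile
  if (is.list(profile) && !is.null(profile$config_mixture)) {
    profile$resolution <- do.call(resolution_model, as.list(profile$resolution))
    profile$thresholds <- do.call(angle_thresholds, as.list(profile$thresholds))
    profile$config_mixture <- unlist(profile$config_mixture)
    profile$merotelic_given_config <- unlist(profile$merotelic_given_config)
    profile$sep_bands <- lapply(profile$sep_bands, as.list)
    profile$timelapse <- lapply(profile$timelapse, function(x)
      if (is.list(x)) unlist(x) else x)
    profile <- do.call(cohort_profile, profile)
  }
  pipeline_config(profile = profile, seed = raw$seed,
                  n_oocytes = raw$n_oocytes, thresholds = thr,
                  resolution = res, at_pole_fraction = raw$at_pole_fraction,
                  outdir = raw$outdir, log_level = raw$log_level)
}

#' Run the end-to-end analysis pipeline
#'
#' Simulate (or read) a cohort, apply detection and pairing, classify every
#' unit, summarise, and optionally write all result tables plus a text
#' report. Deterministic given the seed. Each stage logs records in / out /
#' excluded.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional pre-built or imported cohort; when NULL the
#'   configured profile is simulated.
#' @return invisibly, a list with `cohort`, `classified`, `summaries`,
#'   `report`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  log_msg <- function(...) if (!identical(config$log_level, "quiet"))
    message(sprintf(...))
  if (is.null(cohort)) {
    pr <- resolve_profile(config$profile, config$seed, config$n_oocytes)
    log_msg("simulate: profile %s, %d oocytes, seed %d", pr$name,
            pr$n_oocytes, pr$seed)
    cohort <- simulate_cohort(pr)
  }
  log_msg("simulate: %d spots in / %d detections out (%d merged)",
          if (is.null(cohort$truth_spots)) nrow(cohort$spots)
          else nrow(cohort$truth_spots),
          nrow(cohort$spots), sum(cohort$spots$merged))
  classified <- classify_cohort(cohort, thresholds = config$thresholds,
                                resolution = config$resolution,
                                at_pole_fraction = config$at_pole_fraction)
  log_msg("classify: %d pairs out, %d excluded at poles; %d bivalent slots, %d univalents",
          nrow(classified$pairs), sum(classified$pairs$excluded_at_pole),
          nrow(classified$bivalents), nrow(classified$univalents))
  summaries <- summarize_classification(classified)
  report <- report_lines(summaries)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(cohort, file.path(config$outdir, "cohort"))
    for (nm in c("pairs", "bivalents", "univalents", "oocytes"))
      utils::write.csv(classified[[nm]],
                       file.path(config$outdir, paste0(nm, ".csv")),
                       row.names = FALSE, quote = FALSE)
    for (nm in c("config_by_age", "attach_by_stratum", "rotation", "twist",
                 "cohesion"))
      utils::write.csv(summaries[[nm]],
                       file.path(config$outdir, paste0("summary_", nm, ".csv")),
                       row.names = FALSE, quote = FALSE)
    writeLines(report, file.path(config$outdir, "report.txt"))
    log_msg("write: results under %s", config$outdir)
  }
  invisible(list(cohort = cohort, classified = classified,
                 summaries = summaries, report = report))
}
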