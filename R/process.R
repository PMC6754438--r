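# End-to-end processing: raw recording traces -> cleaned averaged beats
# -> kinetic parameters -> baseline-normalised well table.

#' Run configuration
#'
#' A flat key-value configuration bundling the cleaning parameters, the
#' kinetic measurement levels and the scoring options. Unknown keys are
#' rejected so typos in a config file fail loudly.
#'
#' @param ... Overrides of the defaults: `pacing_hz`, `ma_window`,
#'   `events_to_average`, `interpeak_tol`, `onset_frac`, `pre_frac`,
#'   `apd_level`, `decay_level`, `sd_mode`, `tie_epsilon`, `seed`.
#' @return A `ttm_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    pacing_hz = 1.2, ma_window = 2L, events_to_average = 5L,
    interpeak_tol = 0.1, onset_frac = 0.1, pre_frac = 0.05,
    apd_level = 0.9, decay_level = 0.5, sd_mode = "sd",
    tie_epsilon = 1e-6, seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown) > 0) {
    .ttm_stop(paste0("Unknown configuration key(s): ",
                     paste(unknown, collapse = ", ")), "ttm_error_schema")
  }
  cfg <- modifyList(defaults, dots)
  structure(cfg, class = "ttm_config")
}

#' Read and write run configurations
#'
#' Configurations are stored as flat YAML key-value files.
#'
#' @param path File path.
#' @return `read_run_config()` returns a `ttm_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @param config A `ttm_config`.
#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

as_cleaning_config <- function(config) {
  cleaning_config(
    pacing_hz = config$pacing_hz, ma_window = config$ma_window,
    events_to_average = config$events_to_average,
    interpeak_tol = config$interpeak_tol,
    onset_frac = config$onset_frac, pre_frac = config$pre_frac
  )
}

#' Quantify one recording (three raw traces) into kinetic parameters
#'
#' Cleans each channel with [clean_trace()] and measures the averaged
#' beats with [beat_kinetics()].
#'
#' @param ap,ca,co Raw channel `ttm_trace`s.
#' @param ma Optional motion-artifact trace for ratiometric correction.
#' @param config A [run_config()].
#' @return A one-row kinetic parameter tibble (with `usable`).
#' @export
quantify_recording <- function(ap, ca, co, ma = NULL,
                               config = run_config()) {
  ccfg <- as_cleaning_config(config)
  beat_kinetics(
    clean_trace(ap, ma, ccfg),
    clean_trace(ca, ma, ccfg),
    clean_trace(co, NULL, ccfg),
    apd_level = config$apd_level,
    decay_level = config$decay_level
  )
}

#' Process a recording table into the per-well normalised parameter table
#'
#' The workhorse of the screening pipeline: for every (drug,
#' concentration, well, area) the baseline and post recordings are
#' cleaned, quantified and normalised (post / baseline), then areas are
#' averaged into wells. Recordings that fail cleaning (pacing-consistency
#' rejection, too few events) or normalisation (degenerate baseline) are
#' dropped and reported in the `rejected` attribute, not raised, so one
#' bad area does not abort a plate.
#'
#' @param recordings A tibble with columns `drug`, `concentration_uM`,
#'   `well`, `area`, `phase` (`"baseline"`/`"post"`) and list-columns
#'   `ap`, `ca`, `co` and optionally `ma` holding `ttm_trace`s (the
#'   `recordings` element of a [simulate_experiment()] dataset has this
#'   shape).
#' @param config A [run_config()].
#' @return Per-well tibble: `drug`, `concentration_uM`, `well`,
#'   `n_areas`, the ten normalised parameter columns; attribute
#'   `rejected` is a tibble of dropped records with reasons.
#' @export
process_recordings <- function(recordings, config = run_config()) {
  if (inherits(recordings, "ttm_dataset")) {
    recordings <- recordings$recordings
  }
  has_ma <- "ma" %in% names(recordings)
  rejected <- list()
  area_rows <- list()
  groups <- recordings |>
    group_by(.data$drug, .data$concentration_uM, .data$well, .data$area) |>
    dplyr::group_split()
  for (g in groups) {
    id <- sprintf("%s/%g/%s/a%s", g$drug[1], g$concentration_uM[1],
                  g$well[1], g$area[1])
    res <- tryCatch({
      kin <- lapply(c("baseline", "post"), function(ph) {
        r <- g[g$phase == ph, ]
        if (nrow(r) != 1) {
          .ttm_stop(paste0("Missing ", ph, " recording."), "ttm_error_input")
        }
        quantify_recording(r$ap[[1]], r$ca[[1]], r$co[[1]],
                           if (has_ma) r$ma[[1]] else NULL, config)
      })
      if (!kin[[1]]$usable || !kin[[2]]$usable) {
        .ttm_stop("Unusable kinetic record.", "ttm_error_input")
      }
      normalize_to_baseline(kin[[2]], kin[[1]])
    }, ttm_error = function(e) e)
    if (inherits(res, "ttm_error")) {
      rejected[[length(rejected) + 1L]] <- tibble(
        record = id, reason = conditionMessage(res))
    } else {
      area_rows[[length(area_rows) + 1L]] <- bind_cols(
        tibble(drug = g$drug[1], concentration_uM = g$concentration_uM[1],
               well = g$well[1], area = g$area[1]), res)
    }
  }
  if (length(area_rows) == 0) {
    .ttm_stop("No recording survived processing.", "ttm_error_empty_aggregate")
  }
  areas <- bind_rows(area_rows)
  wells <- areas |>
    group_by(.data$drug, .data$concentration_uM, .data$well) |>
    dplyr::group_modify(function(d, key) {
      agg <- aggregate_kinetics(d)
      dplyr::rename(agg, n_areas = "n")[, c(kinetic_parameters()$parameter,
                                            "n_areas")]
    }) |>
    ungroup()
  attr(wells, "rejected") <- if (length(rejected) > 0) bind_rows(rejected) else
    tibble(record = character(), reason = character())
  # area-level records are kept alongside: the vehicle Gaussians are, by
  # default, fitted on individual vehicle measurements rather than on the
  # well means (see score_conditions)
  attr(wells, "areas") <- areas
  wells
}

#' Write a simulated dataset to disk
#'
#' Materialises a [simulate_experiment()] dataset as plain files: one
#' trace CSV per recording and channel, a tab-separated manifest
#' (`manifest.tsv`: `drug`, `concentration_uM`, `well`, `area`, `phase`,
#' `channel`, `file`), the design as YAML and the ground truth as JSON.
#'
#' @param dataset A `ttm_dataset`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "ttm_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "traces"), showWarnings = FALSE)
  recs <- dataset$recordings
  rows <- list()
  for (i in seq_len(nrow(recs))) {
    for (ch in c("ap", "ca", "co", "ma")) {
      if (!ch %in% names(recs)) next
      fn <- sprintf("traces/%s_c%g_%s_a%s_%s_%s.csv",
                    recs$drug[i], recs$concentration_uM[i], recs$well[i],
                    recs$area[i], recs$phase[i], ch)
      write_trace_csv(recs[[ch]][[i]], file.path(dir, fn))
      rows[[length(rows) + 1L]] <- tibble(
        drug = recs$drug[i], concentration_uM = recs$concentration_uM[i],
        well = recs$well[i], area = recs$area[i], phase = recs$phase[i],
        channel = toupper(ch), file = fn)
    }
  }
  manifest <- bind_rows(rows)
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  yaml::write_yaml(
    list(drug = dataset$design$drug, moa = dataset$design$moa,
         concentrations_uM = dataset$design$concentrations_uM,
         magnitude = dataset$design$magnitude,
         wells = dataset$design$wells, areas = dataset$design$areas,
         duration_s = dataset$design$duration_s,
         pacing_hz = dataset$design$pacing_hz, fps = dataset$design$fps,
         noise_sd = dataset$design$noise_sd,
         crosstalk_gain = dataset$design$crosstalk_gain,
         seed = dataset$design$seed),
    file.path(dir, "design.yaml"))
  gt <- dataset$ground_truth
  jsonlite::write_json(
    list(moa = gt$moa,
         directions = gt$directions,
         concentrations_uM = gt$concentrations_uM,
         effect_magnitude = gt$effect_magnitude, seed = gt$seed),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(dir, "manifest.tsv"))
}

#' Process a manifest of trace files
#'
#' File-based twin of [process_recordings()]: reads the per-channel trace
#' CSVs listed in a manifest (as written by [write_dataset()]), assembles
#' them into recordings and runs the processing pipeline. Missing or
#' unreadable files reject the affected recording with a logged reason;
#' the run continues.
#'
#' @param manifest_path Path to a `manifest.tsv`.
#' @param config A [run_config()].
#' @return As [process_recordings()].
#' @export
process_manifest <- function(manifest_path, config = run_config()) {
  manifest <- readr::read_tsv(manifest_path, col_types = readr::cols(
    drug = "c", concentration_uM = "d", well = "c", area = "c",
    phase = "c", channel = "c", file = "c"))
  base_dir <- dirname(manifest_path)
  wide <- manifest |>
    mutate(channel = tolower(.data$channel)) |>
    pivot_wider(names_from = "channel", values_from = "file")
  rows <- list()
  failed <- list()
  for (i in seq_len(nrow(wide))) {
    res <- tryCatch({
      tr <- lapply(intersect(c("ap", "ca", "co", "ma"), names(wide)),
                   function(ch) {
                     f <- file.path(base_dir, wide[[ch]][i])
                     if (is.na(wide[[ch]][i]) || !file.exists(f)) {
                       .ttm_stop(paste0("Missing trace file: ", wide[[ch]][i]),
                                 "ttm_error_input")
                     }
                     read_trace_csv(f)
                   })
      names(tr) <- intersect(c("ap", "ca", "co", "ma"), names(wide))
      bind_cols(wide[i, c("drug", "concentration_uM", "well", "area",
                          "phase")],
                tibble(ap = list(tr$ap), ca = list(tr$ca),
                       co = list(tr$co),
                       ma = list(tr$ma %||% NULL)))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[[length(failed) + 1L]] <- tibble(
        record = paste(wide[i, 1:5], collapse = "/"),
        reason = conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(rows) == 0) {
    .ttm_stop("No readable recordings in the manifest.",
              "ttm_error_empty_aggregate")
  }
  out <- process_recordings(bind_rows(rows), config)
  attr(out, "rejected") <- bind_rows(c(failed, list(attr(out, "rejected"))))
  out
}

provenance_header <- function(config, seed = NULL) {
  c(
    paste0("# ttmkit ", as.character(utils::packageVersion("ttmkit"))),
    paste0("# config_hash=", rlang::hash(unclass(config))),
    if (!is.null(seed)) paste0("# seed=", seed)
  )
}

#' Write the per-well parameter table with provenance headers
#'
#' The area-level records attached to a [process_recordings()] result are
#' written to a companion file (`<path>` with suffix `_areas.csv`) so
#' that [score_conditions()] can fit the vehicle Gaussians on individual
#' measurements after a round trip through disk.
#'
#' @param wells A [process_recordings()] result.
#' @param path Output CSV path.
#' @param config The [run_config()] used (hashed into the header).
#' @return `path`, invisibly.
#' @export
write_well_params <- function(wells, path, config = run_config()) {
  write_one <- function(tbl, p) {
    con <- file(p, "wb")
    on.exit(close(con))
    writeLines(provenance_header(config, config$seed), con)
    readr::write_csv(as_tibble(tbl), con)
  }
  write_one(wells, path)
  areas <- attr(wells, "areas")
  if (!is.null(areas)) {
    write_one(areas, areas_companion_path(path))
  }
  invisible(path)
}

areas_companion_path <- function(path) {
  sub("(\\.[A-Za-z]+)?$", "_areas.csv", path)
}

#' @rdname write_well_params
#' @export
read_well_params <- function(path) {
  read_one <- function(p) {
    readr::read_csv(p, comment = "#", col_types = readr::cols(
      drug = "c", well = "c", .default = readr::col_guess()))
  }
  out <- read_one(path)
  companion <- areas_companion_path(path)
  if (file.exists(companion)) {
    attr(out, "areas") <- read_one(companion)
  }
  out
}

#' Write score tables and assignments
#'
#' Emits, per drug, a TSV with one row per concentration and one column
#' per MOA total for each channel subset plus the assignment columns, and
#' a JSON export of the full score set.
#'
#' @param scores A [score_conditions()] result.
#' @param dir Output directory.
#' @param config The [run_config()] used.
#' @return `dir`, invisibly.
#' @export
write_scores <- function(scores, dir, config = run_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wide <- scores$scores |>
    mutate(column = paste(.data$subset, .data$moa, sep = ".")) |>
    select("drug", "concentration_uM", "column", "total") |>
    pivot_wider(names_from = "column", values_from = "total")
  assign_wide <- scores$assignments |>
    mutate(column = paste0("assigned.", .data$subset)) |>
    select("drug", "concentration_uM", "column", "assigned_moa") |>
    pivot_wider(names_from = "column", values_from = "assigned_moa")
  for (drug in unique(wide$drug)) {
    out <- left_join(filter(wide, .data$drug == !!drug),
                     filter(assign_wide, .data$drug == !!drug),
                     by = c("drug", "concentration_uM")) |>
      arrange(.data$concentration_uM)
    path <- file.path(dir, paste0("scores_", drug, ".tsv"))
    con <- file(path, "wb")
    writeLines(provenance_header(config, config$seed), con)
    readr::write_tsv(out, con)
    close(con)
  }
  jsonlite::write_json(
    list(scores = scores$scores, assignments = scores$assignments,
         vehicle_stats = as_tibble(scores$vehicle_stats)),
    file.path(dir, "scores.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
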