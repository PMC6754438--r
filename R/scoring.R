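#' Fit the vehicle reference distribution
#'
#' The probability-score algorithm judges every drug measurement against
#' the vehicle (solvent-only) population: for each kinetic parameter a
#' Gaussian is fitted to the normalised vehicle well values, with the
#' arithmetic mean and the sample standard deviation (n - 1 denominator).
#' Setting `sd_mode = "sem"` uses the standard error of the mean instead,
#' for users who read the reference spread as the uncertainty of the
#' vehicle mean rather than the spread of vehicle wells.
#'
#' @param vehicle A tibble of normalised vehicle well records (one row per
#'   well, the ten kinetic parameter columns).
#' @param sd_mode `"sd"` (default, sample standard deviation) or `"sem"`.
#' @return A `ttm_vehicle_stats` tibble: `parameter`, `mean`, `sd`, `n`.
#' @export
fit_vehicle <- function(vehicle, sd_mode = c("sd", "sem")) {
  sd_mode <- match.arg(sd_mode)
  cols <- kinetic_parameters()$parameter
  missing <- setdiff(cols, names(vehicle))
  if (length(missing) > 0) {
    .ttm_stop(paste0("Vehicle table lacks parameter column(s): ",
                     paste(missing, collapse = ", ")), "ttm_error_schema")
  }
  if ("usable" %in% names(vehicle)) {
    vehicle <- filter(vehicle, .data$usable %in% TRUE)
  }
  long <- vehicle |>
    select(all_of(cols)) |>
    pivot_longer(everything(), names_to = "parameter", values_to = "x") |>
    filter(!is.na(.data$x))
  out <- long |>
    group_by(.data$parameter) |>
    summarise(mean = mean(.data$x), sd = sd(.data$x), n = n(),
              .groups = "drop")
  if (any(out$n < 2)) {
    .ttm_stop("At least 2 vehicle values per parameter are required.",
              "ttm_error_degenerate_vehicle")
  }
  if (sd_mode == "sem") out$sd <- out$sd / sqrt(out$n)
  if (any(out$sd <= 0)) {
    .ttm_stop(
      "Vehicle standard deviation is zero for at least one parameter; scoring is impossible.",
      "ttm_error_degenerate_vehicle")
  }
  out <- out[match(cols, out$parameter), ]
  class(out) <- c("ttm_vehicle_stats", class(out))
  out
}

#' @export
tidy.ttm_vehicle_stats <- function(x, ...) as_tibble(x)

#' @export
glance.ttm_vehicle_stats <- function(x, ...) {
  tibble(n_parameters = nrow(x), n_vehicle = x$n[1],
         min_cv = min(x$sd / x$mean), max_cv = max(x$sd / x$mean))
}

#' Probability scores for "unchanged", "increased" and "decreased"
#'
#' The probability of a normalised parameter value being unchanged equals
#' its density under the vehicle Gaussian, rescaled so the peak is 10:
#' `ps_same(x) = 10 * exp(-(x - mean)^2 / (2 * sd^2))`. The density's
#' complement is split at the mean into the "increased" and "decreased"
#' scores: `ps_up(x)` is 0 below the mean and `10 - ps_same(x)` at or
#' above it; `ps_down(x)` mirrors it below the mean. The three scores sum
#' to 10 at every x, so each complement (NOT) effect scores
#' `10 - ps_effect` of the negated effect.
#'
#' @param x Normalised parameter value(s); vectorised.
#' @param mean,sd Vehicle Gaussian parameters for the kinetic parameter.
#' @return Numeric score(s) in \[0, 10\].
#' @examples
#' ps_same(1, mean = 1, sd = 0.05)        # 10 at the vehicle mean
#' ps_up(1.05, mean = 1, sd = 0.05)       # 10 - 10 * exp(-1/2)
#' @export
ps_same <- function(x, mean, sd) {
  10 * exp(-(x - mean)^2 / (2 * sd^2))
}

#' @rdname ps_same
#' @export
ps_up <- function(x, mean, sd) {
  ifelse(x < mean, 0, 10 - ps_same(x, mean, sd))
}

#' @rdname ps_same
#' @export
ps_down <- function(x, mean, sd) {
  ifelse(x > mean, 0, 10 - ps_same(x, mean, sd))
}

#' @rdname ps_same
#' @param effect An effect token (`"up"`, `"down"`, `"same"`, `"not_up"`,
#'   `"not_down"`, `"not_same"`).
#' @export
ps_effect <- function(x, mean, sd, effect) {
  switch(effect,
    same = ps_same(x, mean, sd),
    up = ps_up(x, mean, sd),
    down = ps_down(x, mean, sd),
    not_up = 10 - ps_up(x, mean, sd),
    not_down = 10 - ps_down(x, mean, sd),
    not_same = 10 - ps_same(x, mean, sd),
    .ttm_stop(paste0("Unknown effect token '", effect, "'."),
              "ttm_error_identifier")
  )
}

subset_parameters <- function(subset) {
  pc <- kinetic_parameters()
  if (subset == "ALL") pc$parameter else pc$parameter[pc$channel == subset]
}

#' Total probability score of every MOA hypothesis
#'
#' For one normalised measurement (the ten kinetic parameters, or the
#' subset from a single channel), evaluates the probability score of every
#' hypothesis-table cell and sums per MOA column. With all ten parameters
#' the totals range 0--100 (10 per parameter); the `AP`, `Ca` and `Co`
#' subsets cap at 40, 30 and 30 and implement the single-modality ablation
#' analysis.
#'
#' @param params A one-row tibble or named numeric vector of normalised
#'   parameter values.
#' @param stats A [fit_vehicle()] result.
#' @param table A hypothesis table (default: built-in).
#' @param subset `"ALL"` (default), `"AP"`, `"Ca"` or `"Co"`.
#' @return A tibble `moa`, `subset`, `total`.
#' @export
score_hypotheses <- function(params, stats, table = ttm_hypotheses(),
                             subset = "ALL") {
  subset <- match.arg(subset, c("ALL", "AP", "Ca", "Co"))
  wanted <- subset_parameters(subset)
  x <- if (is.data.frame(params)) {
    setNames(as.numeric(params[1, intersect(wanted, names(params))]),
             intersect(wanted, names(params)))
  } else {
    params[intersect(wanted, names(params))]
  }
  if (!all(wanted %in% names(x)) || anyNA(x)) {
    .ttm_stop(paste0("Missing parameter value(s) for subset ", subset, "."),
              "ttm_error_input")
  }
  cells <- hypotheses_long(table) |>
    filter(.data$parameter %in% wanted) |>
    left_join(as_tibble(stats)[, c("parameter", "mean", "sd")],
              by = "parameter")
  cells$x <- unname(x[cells$parameter])
  cells$ps <- map_dbl(seq_len(nrow(cells)), function(i) {
    ps_effect(cells$x[i], cells$mean[i], cells$sd[i], cells$effect[i])
  })
  cells |>
    group_by(.data$moa) |>
    summarise(total = sum(.data$ps), .groups = "drop") |>
    mutate(subset = subset, .after = "moa") |>
    arrange(match(.data$moa, moa_categories()$moa))
}

#' Assign the most likely MOA from hypothesis totals
#'
#' The hypothesis with the highest total probability score is reported as
#' the mechanism of action. If the top two totals differ by less than
#' `tie_epsilon` the assignment is flagged as a tie and all tied
#' hypotheses are listed rather than silently picking one.
#'
#' @param totals A tibble `moa`, `total` (one subset).
#' @param tie_epsilon Minimal separation regarded as a decision (default
#'   `1e-6`, i.e. exact-tie detection only).
#' @return A one-row tibble: `assigned_moa`, `top_total`, `tie`,
#'   `tied_moas` (comma-separated when tied).
#' @export
assign_moa <- function(totals, tie_epsilon = 1e-6) {
  if (nrow(totals) == 0) {
    .ttm_stop("No totals to assign from.", "ttm_error_input")
  }
  ord <- order(totals$total, decreasing = TRUE)
  top <- totals$total[ord[1]]
  tied <- totals$moa[totals$total > top - tie_epsilon]
  tibble(
    assigned_moa = totals$moa[ord[1]],
    top_total = top,
    tie = length(tied) > 1,
    tied_moas = paste(tied, collapse = ",")
  )
}

#' Score every drug x concentration x channel subset of an experiment
#'
#' Takes the per-well normalised parameter table of a whole plate run
#' (vehicle wells at `concentration_uM == 0`), fits the vehicle Gaussians,
#' and emits hypothesis totals plus the MOA assignment for every drug,
#' concentration and channel subset. The value entering the score
#' functions is the across-well mean of the normalised well values at that
#' concentration. Vehicle conditions are scored leave-one-well-out (each
#' vehicle well against the Gaussians fitted on the remaining wells, totals
#' averaged) so the vehicle's own assignment is not trivially inflated.
#'
#' @param well_params Tibble with columns `drug`, `concentration_uM`,
#'   `well`, the ten parameter columns (normalised post/baseline). A
#'   [process_recordings()] result additionally carries the area-level
#'   records as attribute `"areas"`.
#' @param table A hypothesis table.
#' @param subsets Channel subsets to score (default all four).
#' @param sd_mode Passed to [fit_vehicle()].
#' @param vehicle_level `"area"` (default) fits the vehicle Gaussians on
#'   the individual vehicle measurements (area-level records) when they
#'   are available, which gives a larger and much more stably estimated
#'   reference spread than the handful of well means; `"well"` forces
#'   fitting on vehicle well means.
#' @param tie_epsilon Passed to [assign_moa()].
#' @return A `ttm_scores` object: list with `scores` (long totals tibble)
#'   and `assignments` (one row per drug x concentration x subset), plus
#'   the fitted `vehicle_stats`.
#' @export
score_conditions <- function(well_params, table = ttm_hypotheses(),
                             subsets = c("ALL", "AP", "Ca", "Co"),
                             sd_mode = c("sd", "sem"),
                             vehicle_level = c("area", "well"),
                             tie_epsilon = 1e-6) {
  sd_mode <- match.arg(sd_mode)
  vehicle_level <- match.arg(vehicle_level)
  need <- c("drug", "concentration_uM", "well")
  if (!all(need %in% names(well_params))) {
    .ttm_stop(paste0("Parameter table lacks column(s): ",
                     paste(setdiff(need, names(well_params)), collapse = ", ")),
              "ttm_error_schema")
  }
  cols <- kinetic_parameters()$parameter
  missing <- setdiff(cols, names(well_params))
  if (length(missing) > 0) {
    .ttm_stop(paste0("Parameter table lacks parameter column(s): ",
                     paste(missing, collapse = ", ")), "ttm_error_schema")
  }
  vehicle <- filter(well_params, .data$concentration_uM == 0)
  if (nrow(vehicle) == 0) {
    .ttm_stop("No vehicle rows (concentration_uM == 0) in the table.",
              "ttm_error_missing_vehicle")
  }
  areas <- attr(well_params, "areas")
  vehicle_src <- if (vehicle_level == "area" && !is.null(areas)) {
    filter(areas, .data$concentration_uM == 0)
  } else {
    vehicle
  }
  stats <- fit_vehicle(vehicle_src, sd_mode)

  score_one <- function(x, drug, conc, st) {
    purrr::map(subsets, function(ss) {
      tot <- score_hypotheses(x, st, table, ss)
      mutate(tot, drug = drug, concentration_uM = conc, .before = 1)
    }) |> bind_rows()
  }

  rows <- list()
  drug_conditions <- well_params |>
    filter(.data$concentration_uM > 0) |>
    group_by(.data$drug, .data$concentration_uM)
  for (grp in dplyr::group_split(drug_conditions)) {
    x <- colMeans(grp[, cols])
    rows[[length(rows) + 1L]] <-
      score_one(x, grp$drug[1], grp$concentration_uM[1], stats)
  }
  # vehicle: score leave-current-well-out means (so the vehicle's own
  # assignment is informative rather than trivially x == mean), totals
  # averaged across the held-out wells
  for (drug in unique(vehicle$drug)) {
    vd <- filter(vehicle, .data$drug == !!drug)
    per_well <- purrr::map(seq_len(nrow(vd)), function(i) {
      x_loo <- if (nrow(vd) >= 2) {
        colMeans(vd[-i, cols])
      } else {
        setNames(as.numeric(vd[i, cols]), cols)
      }
      score_one(x_loo, drug, 0, stats)
    }) |> bind_rows()
    rows[[length(rows) + 1L]] <- per_well |>
      group_by(.data$drug, .data$concentration_uM, .data$moa, .data$subset) |>
      summarise(total = mean(.data$total), .groups = "drop")
  }
  scores <- bind_rows(rows) |>
    arrange(.data$drug, .data$concentration_uM,
            match(.data$subset, c("ALL", "AP", "Ca", "Co")),
            match(.data$moa, moa_categories()$moa))
  assignments <- scores |>
    group_by(.data$drug, .data$concentration_uM, .data$subset) |>
    dplyr::group_modify(function(d, key) assign_moa(d, tie_epsilon)) |>
    ungroup()
  structure(
    list(scores = scores, assignments = assignments,
         vehicle_stats = stats),
    class = "ttm_scores"
  )
}

#' @export
print.ttm_scores <- function(x, ...) {
  cat("<ttm_scores>\n")
  print(x$assignments, n = 20)
  invisible(x)
}

#' @export
tidy.ttm_scores <- function(x, ...) x$scores

#' @export
glance.ttm_scores <- function(x, ...) x$assignments

#' Plot hypothesis totals across concentrations
#'
#' @param object A `ttm_scores` object.
#' @param subset Channel subset to plot (default `"ALL"`).
#' @param ... Unused.
#' @return A ggplot object: per-MOA total probability score against
#'   concentration, one panel per drug.
#' @export
autoplot.ttm_scores <- function(object, subset = "ALL", ...) {
  d <- filter(object$scores, .data$subset == !!subset)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$concentration_uM),
                                  y = .data$total,
                                  group = .data$moa, colour = .data$moa)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~drug) +
    ggplot2::labs(x = "concentration (uM)",
                  y = paste0("total probability score (", subset, ")"),
                  colour = "hypothesis") +
    ggplot2::theme_minimal()
}

#' Concentration-response plot of one kinetic parameter
#'
#' @param well_params Per-well normalised parameter table (see
#'   [score_conditions()]).
#' @param parameter One kinetic parameter id.
#' @return A ggplot object; points are wells, the line the across-well
#'   mean.
#' @export
plot_concentration_response <- function(well_params, parameter) {
  stopifnot(parameter %in% kinetic_parameters()$parameter)
  ggplot2::ggplot(well_params,
                  ggplot2::aes(x = factor(.data$concentration_uM),
                               y = .data[[parameter]])) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "line",
                          ggplot2::aes(group = 1), colour = "red") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(~drug) +
    ggplot2::labs(x = "concentration (uM)",
                  y = paste0(parameter, " (fold of baseline)")) +
    ggplot2::theme_minimal()
}
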