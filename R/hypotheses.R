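#' The ten kinetic parameters of a triple transient beat
#'
#' Each averaged beat is summarised by ten kinetic parameters: four for the
#' optical action potential (AP), three for the cytosolic calcium transient
#' (Ca) and three for contraction (Co). Amplitudes are dimensionless
#' (pseudo-ratio dF/F for AP and Ca) or arbitrary motion units (Co); all
#' times are in milliseconds.
#'
#' @return A tibble with columns `parameter`, `channel` (`"AP"`, `"Ca"` or
#'   `"Co"`) and `unit`, one row per parameter in canonical order.
#' @examples
#' kinetic_parameters()
#' @export
kinetic_parameters <- function() {
  tibble(
    parameter = c(
      "AP_amplitude", "AP_t_rise", "AP_t_APD", "AP_triangulation",
      "Ca_amplitude", "Ca_t_to_peak", "Ca_t_decay",
      "Co_amplitude", "Co_t_contraction", "Co_t_relaxation"
    ),
    channel = rep(c("AP", "Ca", "Co"), times = c(4, 3, 3)),
    unit = c(
      "dF/F", "ms", "ms", "ms",
      "dF/F", "ms", "ms",
      "a.u.", "ms", "ms"
    )
  )
}

#' The six contractile mechanism-of-action categories
#'
#' Contractile drug responses are classified into six hypotheses: no effect
#' (`Co_same`), contraction increase mediated by calcium (`Co_plus_Ca`),
#' myosin (`Co_plus_Myosin`) or cAMP/beta-adrenergic signalling
#' (`Co_plus_cAMP`), and contraction decrease mediated by calcium
#' (`Co_minus_Ca`) or by general toxicity (`Co_minus_Tox`).
#'
#' @return A tibble with columns `moa`, `label` and `typical_compound`.
#' @examples
#' moa_categories()
#' @export
moa_categories <- function() {
  tibble(
    moa = c(
      "Co_same", "Co_plus_Ca", "Co_plus_Myosin",
      "Co_plus_cAMP", "Co_minus_Ca", "Co_minus_Tox"
    ),
    label = c(
      "Co= (no effect)", "Co+ Ca-mediated", "Co+ myosin-mediated",
      "Co+ cAMP-mediated", "Co- Ca-mediated", "Co- toxicity"
    ),
    typical_compound = c(
      "aspirin", "ouabain", "omecamtiv mecarbil",
      "beta-adrenergic agonist", "verapamil", "doxorubicin (long term)"
    )
  )
}

#' Effect-direction tokens and their complements
#'
#' A hypothesis-table cell states the expected change of one kinetic
#' parameter under one MOA: `"up"`, `"down"`, `"same"`, or a complement
#' `"not_up"`, `"not_down"`, `"not_same"` meaning "any effect other than"
#' the named one (used for drug classes with heterogeneous members).
#'
#' @return A tibble with columns `effect` and `complement_of` (`NA` for the
#'   plain directions).
#' @export
effect_directions <- function() {
  tibble(
    effect = .effects_all,
    complement_of = c(rep(NA_character_, 3), unname(.effects_not))
  )
}

#' Built-in contractile-MOA hypothesis table
#'
#' Returns the built-in 10 parameter x 6 MOA table of expected effect
#' directions that drives probability scoring. The table ships as a
#' tab-separated file (see [read_hypotheses()]) so users can supply an
#' edited hypothesis set; it is validated on load.
#'
#' @return A validated hypothesis table: a tibble with a `parameter` column
#'   and one column of effect tokens per MOA category, class
#'   `ttm_hypotheses`.
#' @examples
#' h <- ttm_hypotheses()
#' expected_effect(h, "Co_plus_Ca", "Ca_amplitude")
#' @seealso [expected_effect()], [validate_hypotheses()], [read_hypotheses()]
#' @export
ttm_hypotheses <- function() {
  path <- system.file("extdata", "hypotheses_table.tsv", package = "ttmkit",
                      mustWork = TRUE)
  read_hypotheses(path)
}

#' Read and write hypothesis tables
#'
#' A hypothesis-table file is a TSV whose first column (`parameter`) lists
#' the ten kinetic parameter ids and whose remaining columns, one per MOA
#' category, hold effect tokens (`up`, `down`, `same`, `not_up`,
#' `not_down`, `not_same`).
#'
#' @param path File path.
#' @return `read_hypotheses()` returns a validated `ttm_hypotheses` tibble;
#'   `write_hypotheses()` returns `path` invisibly.
#' @export
read_hypotheses <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  tbl <- as_hypotheses(tbl)
  viol <- validate_hypotheses(tbl)
  if (nrow(viol) > 0) {
    .ttm_stop(
      c("Invalid hypothesis table.",
        setNames(viol$message, rep("x", nrow(viol)))),
      "ttm_error_schema"
    )
  }
  tbl
}

#' @param table A `ttm_hypotheses` table.
#' @rdname read_hypotheses
#' @export
write_hypotheses <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}

as_hypotheses <- function(tbl) {
  tbl <- as_tibble(tbl)
  class(tbl) <- c("ttm_hypotheses", class(tbl))
  tbl
}

#' Validate a hypothesis table
#'
#' Checks that all 60 cells (10 kinetic parameters x 6 MOA categories) are
#' present and that every cell holds a valid effect token. Violations are
#' returned, not raised, so a partially edited table can be inspected.
#'
#' @param table A candidate hypothesis table (data frame with a `parameter`
#'   column and one column per MOA).
#' @return A tibble of violations with columns `moa`, `parameter`,
#'   `message`; zero rows if the table is valid.
#' @export
validate_hypotheses <- function(table) {
  params <- kinetic_parameters()$parameter
  moas <- moa_categories()$moa
  v <- list()
  if (!"parameter" %in% names(table)) {
    return(tibble(moa = NA_character_, parameter = NA_character_,
                  message = "missing 'parameter' column"))
  }
  for (p in setdiff(params, table$parameter)) {
    v[[length(v) + 1L]] <- tibble(
      moa = NA_character_, parameter = p,
      message = paste0("missing row for parameter '", p, "'"))
  }
  for (p in setdiff(table$parameter, params)) {
    v[[length(v) + 1L]] <- tibble(
      moa = NA_character_, parameter = p,
      message = paste0("unknown parameter '", p, "'"))
  }
  for (m in setdiff(moas, names(table))) {
    v[[length(v) + 1L]] <- tibble(
      moa = m, parameter = NA_character_,
      message = paste0("missing column for MOA '", m, "'"))
  }
  for (m in intersect(moas, names(table))) {
    for (p in intersect(params, table$parameter)) {
      cell <- table[[m]][table$parameter == p]
      if (length(cell) != 1L || is.na(cell) || !cell %in% .effects_all) {
        v[[length(v) + 1L]] <- tibble(
          moa = m, parameter = p,
          message = paste0("cell (", m, ", ", p, ") is not a valid effect"))
      }
    }
  }
  if (length(v) == 0) {
    tibble(moa = character(), parameter = character(), message = character())
  } else {
    bind_rows(v)
  }
}

#' Look up the expected effect for one MOA and parameter
#'
#' @param table A `ttm_hypotheses` table.
#' @param moa One of the six MOA category ids (see [moa_categories()]).
#' @param parameter One of the ten kinetic parameter ids.
#' @return A single effect token.
#' @examples
#' expected_effect(ttm_hypotheses(), "Co_plus_Myosin", "Co_t_contraction")
#' @export
expected_effect <- function(table, moa, parameter) {
  if (!moa %in% names(table)) {
    .ttm_stop(paste0("Unknown MOA category '", moa, "'."),
              "ttm_error_identifier")
  }
  i <- match(parameter, table$parameter)
  if (is.na(i)) {
    .ttm_stop(paste0("Unknown kinetic parameter '", parameter, "'."),
              "ttm_error_identifier")
  }
  table[[moa]][i]
}

# Long form (parameter, channel, moa, effect) used by the scorer.
hypotheses_long <- function(table) {
  table |>
    pivot_longer(-"parameter", names_to = "moa", values_to = "effect") |>
    left_join(kinetic_parameters()[, c("parameter", "channel")],
              by = "parameter")
}
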