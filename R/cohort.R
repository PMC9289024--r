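#' Trajectory table validation and column dictionary
#'
#' A cohort is a data frame with one row per 4-hour timestep and the
#' following columns (units fixed):
#'
#' * `stay_id` — integer stay identifier, unique per stay.
#' * `step_index` — 1-based step number, consecutive within a stay.
#' * `map` — mean arterial pressure, mm Hg.
#' * `cvp` — central venous pressure, mm Hg.
#' * `cumulative_balance` — running sum of fluid inputs minus urine output up
#'   to and including this step, mL.
#' * `urine_output` — urine produced during this step, mL.
#' * `sofa` — Sequential Organ Failure Assessment score, integer 0-24.
#' * `lactate` — serum lactate, mmol/L.
#' * `sedation` — 0/1 sedation indicator.
#' * `total_fluid_input` — cumulative fluid given up to and including this
#'   step, mL.
#' * `weight` — body weight, kg.
#' * `action_fluid` — intravenous fluid volume given this step, mL; the
#'   fluid *rate* in mL/hour is `action_fluid / step_hours`.
#' * `action_vaso` — vasopressor dose, ug/kg/min.
#' * `survived_90d` — 0/1 stay outcome, constant within a stay.
#'
#' Additional numeric columns are allowed and carried through (extra
#' clustering features).
#'
#' @param cohort a cohort data frame.
#' @return the validated cohort, invisibly classed as `sepsafe_cohort`.
#' @export
validate_cohort <- function(cohort) {
  required <- c("stay_id", "step_index", "map", "cvp", "cumulative_balance",
                "urine_output", "sofa", "lactate", "sedation",
                "total_fluid_input", "weight", "action_fluid", "action_vaso",
                "survived_90d")
  missing <- setdiff(required, names(cohort))
  if (length(missing)) {
    stop_sepsafe("cohort is missing column(s): ",
                 paste(missing, collapse = ", "),
                 class = "sepsafe_parse_error")
  }
  for (col in setdiff(required, "stay_id")) {
    if (!is.numeric(cohort[[col]])) {
      stop_sepsafe("cohort column '", col, "' is not numeric",
                   class = "sepsafe_parse_error")
    }
  }
  if (any(cohort$map < 0) || any(cohort$cvp < 0) ||
      any(cohort$action_fluid < 0) || any(cohort$action_vaso < 0)) {
    stop_sepsafe("MAP, CVP and doses must be non-negative",
                 class = "sepsafe_parse_error")
  }
  if (any(cohort$sofa < 0 | cohort$sofa > 24)) {
    stop_sepsafe("SOFA must lie in [0, 24]", class = "sepsafe_parse_error")
  }
  # step_index consecutive from 1 within each stay; outcome constant.
  split_idx <- split(seq_len(nrow(cohort)), cohort$stay_id)
  for (ix in split_idx) {
    steps <- cohort$step_index[ix]
    if (!identical(as.integer(steps), seq_along(ix))) {
      stop_sepsafe("non-consecutive step_index in stay ",
                   cohort$stay_id[ix[1]], " (row ", ix[1], ")",
                   class = "sepsafe_parse_error")
    }
    if (length(unique(cohort$survived_90d[ix])) != 1L) {
      stop_sepsafe("outcome not constant within stay ", cohort$stay_id[ix[1]],
                   class = "sepsafe_parse_error")
    }
  }
  if (!inherits(cohort, "sepsafe_cohort")) {
    class(cohort) <- c("sepsafe_cohort", class(cohort))
  }
  invisible(cohort)
}

#' Write / read a cohort as delimited text
#'
#' Round-trips all columns through a UTF-8 comma-separated file with a header
#' row; the provenance note is stored in a leading `#` comment line.
#'
#' @param cohort a validated cohort.
#' @param path file path.
#' @return `read_cohort()` returns the cohort; `write_cohort()` returns the
#'   path invisibly.
#' @export
write_cohort <- function(cohort, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  prov <- attr(cohort, "provenance") %||% "unspecified source"
  writeLines(paste0("# provenance: ", prov), con)
  write.csv(as.data.frame(cohort), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  first <- readLines(path, n = 1L)
  prov <- NULL
  skip <- 0L
  if (startsWith(first, "# provenance: ")) {
    prov <- sub("^# provenance: ", "", first)
    skip <- 1L
  }
  df <- tryCatch(
    read.csv(path, skip = skip, comment.char = "", stringsAsFactors = FALSE),
    error = function(e) stop_sepsafe("malformed cohort file: ",
                                     conditionMessage(e),
                                     class = "sepsafe_parse_error")
  )
  for (col in setdiff(names(df), "stay_id")) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      stop_sepsafe("non-numeric value in column '", col, "' (row ",
                   bad %||% 1L, ")", class = "sepsafe_parse_error")
    }
  }
  attr(df, "provenance") <- prov
  class(df) <- c("sepsafe_cohort", "data.frame")
  validate_cohort(df)
  df
}
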