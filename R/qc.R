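#' Default quality-control exclusion rules
#'
#' The two class-specific mean-phase floors remove out-of-focus or
#' fragmented cells: normal cells with mean phase below 0.4 rad and
#' disease-sample cells with mean phase below 0.3 rad are excluded. The
#' remaining rules remove clumps and debris: cells outside a plausible
#' area range and cells whose mask is too concave to be a single cell.
#' The solidity floor (0.65) is set below the solidity reached by strongly
#' bent crescents so that genuinely sickled cells are never removed as
#' debris.
#'
#' @param nor_mean_phase_min,scd_mean_phase_min Mean-phase floors, radians.
#' @param area_min,area_max Area bounds, square micrometres.
#' @param solidity_min Solidity floor.
#' @return A tibble of rules with columns `parameter`, `bound`,
#'   `direction` (`exclude_below`/`exclude_above`) and `applies_to`
#'   (`"NOR"`, `"SCD"` or `"all"`).
#' @export
qc_rules <- function(nor_mean_phase_min = 0.4,
                     scd_mean_phase_min = 0.3,
                     area_min = 15,
                     area_max = 90,
                     solidity_min = 0.65) {
  tibble(
    parameter = c("mean_phase", "mean_phase", "area_um2", "area_um2",
                  "solidity"),
    bound = c(nor_mean_phase_min, scd_mean_phase_min, area_min, area_max,
              solidity_min),
    direction = c("exclude_below", "exclude_below", "exclude_below",
                  "exclude_above", "exclude_below"),
    applies_to = c("NOR", "SCD", "all", "all", "all")
  )
}

#' Apply quality-control exclusion rules to a feature table
#'
#' Rules are evaluated in order; each cell is annotated with whether it
#' passes all applicable rules and, if not, the first rule it violated.
#' Exclusion is strict: a value exactly at the bound is kept.
#'
#' @param features Feature table with a `class` column and the feature
#'   columns referenced by the rules.
#' @param rules A rule tibble as returned by [qc_rules()].
#' @param class_col Name of the class-label column.
#' @return `features` with two added columns: `qc_pass` (logical) and
#'   `qc_rule` (label of the first violated rule, `NA` if kept). The
#'   partition is exhaustive: every row is either kept or carries a rule.
#' @examples
#' tb <- tibble::tibble(class = c("NOR", "SCD"), mean_phase = c(0.39, 0.31),
#'                      area_um2 = 40, solidity = 0.95)
#' qc_filter(tb)$qc_pass
#' @export
qc_filter <- function(features, rules = qc_rules(), class_col = "class") {
  unknown <- setdiff(rules$parameter, names(features))
  if (length(unknown) > 0) {
    abort(sprintf("QC rule references unknown parameter(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  if (!class_col %in% names(features)) {
    abort(sprintf("feature table has no '%s' column", class_col))
  }
  n <- nrow(features)
  pass <- rep(TRUE, n)
  rule_hit <- rep(NA_character_, n)
  cls <- features[[class_col]]
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    applies <- if (r$applies_to == "all") rep(TRUE, n) else cls == r$applies_to
    v <- features[[r$parameter]]
    viol <- if (r$direction == "exclude_below") v < r$bound else v > r$bound
    hit <- applies & viol & pass
    label <- sprintf("%s_%s_%g", r$parameter,
                     sub("exclude_", "", r$direction), r$bound)
    rule_hit[hit] <- label
    pass <- pass & !hit
  }
  features$qc_pass <- pass
  features$qc_rule <- rule_hit
  features
}

#' Summarize a QC-annotated feature table
#'
#' @param features Output of [qc_filter()].
#' @return A tibble with one row per violated rule plus a `kept` row.
#' @export
qc_summary <- function(features) {
  stopifnot("qc_pass" %in% names(features))
  excl <- dplyr::count(
    dplyr::filter(features, !.data$qc_pass), .data$qc_rule
  )
  dplyr::bind_rows(
    tibble(qc_rule = "kept", n = sum(features$qc_pass)),
    excl
  )
}
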