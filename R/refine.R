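#' Configuration for the selective-search training-set refinement
#'
#' The refinement isolates "critically sickled" cells: for each
#' morphological parameter it finds the histogram-tail threshold at which
#' the fraction of the disease population in the tail exceeds the fraction
#' of the normal population by at least `ratio` (default 21:1), then pools
#' the qualifying tails.
#'
#' @param ratio Required disease:normal population-fraction ratio in the
#'   tail (> 1).
#' @param min_refined_size Minimum acceptable refined-set size; a smaller
#'   union is still returned but flagged with a warning status.
#' @param pseudo_count Smoothing count added to the normal-tail numerator
#'   (and denominator population) so single-cell normal tails cannot
#'   qualify by division by zero; set 0 for the unsmoothed ratio.
#' @param parameters_searched Feature names searched (default all 25).
#' @param seed Seed for drawing the size-matched random normal subset.
#' @return An object of class `refine_config`.
#' @export
refine_config <- function(ratio = 21,
                          min_refined_size = 5000,
                          pseudo_count = 1,
                          parameters_searched = feature_names(),
                          seed = 1L) {
  stopifnot(ratio > 1, min_refined_size >= 1, pseudo_count >= 0)
  structure(
    list(
      ratio = ratio,
      min_refined_size = as.integer(min_refined_size),
      pseudo_count = pseudo_count,
      parameters_searched = parameters_searched,
      seed = as.integer(seed)
    ),
    class = "refine_config"
  )
}

# Lower-tail search on raw vectors. Candidate thresholds are the sorted
# unique pooled values; the tail at t is {v <= t}. Returns the most
# inclusive qualifying threshold (maximal n_scd) or NULL.
tail_search_lower <- function(values_scd, values_nor, config) {
  s <- sort(values_scd)
  n <- sort(values_nor)
  cand <- sort(unique(c(s, n)))
  n_s <- findInterval(cand, s)            # count of scd values <= t
  n_n <- findInterval(cand, n)
  N_s <- length(s)
  N_n <- length(n)
  pc <- config$pseudo_count
  ratio <- (n_s / N_s) / ((n_n + pc) / (N_n + pc))
  ok <- n_s >= 1 & ratio >= config$ratio
  if (!any(ok)) {
    return(NULL)
  }
  best <- which(ok)[which.max(n_s[ok])]
  list(threshold = cand[best], achieved_ratio = ratio[best],
       n_scd_tail = n_s[best], n_nor_tail = n_n[best])
}

#' Find the tail threshold satisfying the population-ratio criterion
#'
#' Scans all candidate thresholds (the sorted unique pooled values) of one
#' parameter and returns the most inclusive threshold whose tail holds at
#' least `config$ratio` times more of the disease population (as a
#' fraction) than of the normal population, with pseudo-count smoothing of
#' the normal fraction. A threshold's tail is closed: cells exactly at the
#' threshold are included.
#'
#' @param values_scd,values_nor Numeric vectors of one parameter for the
#'   disease and normal populations (both non-empty).
#' @param direction `"lower"` (tail is `value <= t`) or `"upper"`
#'   (`value >= t`).
#' @param config A [refine_config()].
#' @return A one-row tibble (`direction`, `threshold`, `achieved_ratio`,
#'   `n_scd_tail`, `n_nor_tail`), or `NULL` if no threshold qualifies.
#' @examples
#' find_tail_criterion(c(rep(0, 78), rep(10, 22)), rep(0, 100), "upper")
#' @export
find_tail_criterion <- function(values_scd, values_nor,
                                direction = c("lower", "upper"),
                                config = refine_config()) {
  direction <- match.arg(direction)
  if (length(values_scd) == 0 || length(values_nor) == 0) {
    abort("both value vectors must be non-empty")
  }
  if (direction == "lower") {
    res <- tail_search_lower(values_scd, values_nor, config)
  } else {
    res <- tail_search_lower(-values_scd, -values_nor, config)
    if (!is.null(res)) res$threshold <- -res$threshold
  }
  if (is.null(res)) {
    return(NULL)
  }
  tibble(
    direction = direction,
    threshold = res$threshold,
    achieved_ratio = res$achieved_ratio,
    n_scd_tail = as.integer(res$n_scd_tail),
    n_nor_tail = as.integer(res$n_nor_tail)
  )
}

#' Search every morphological parameter for qualifying tail criteria
#'
#' Runs [find_tail_criterion()] for both tail directions of every searched
#' parameter of a post-QC feature table. Each qualifying
#' (parameter, direction) pair contributes at most one criterion.
#'
#' @param features Feature table containing a class column and the
#'   searched feature columns, with both classes present.
#' @param config A [refine_config()].
#' @param class_col,positive,negative Class column and the labels of the
#'   disease and normal classes.
#' @return A tibble of criteria (possibly zero rows) with columns
#'   `parameter`, `direction`, `threshold`, `achieved_ratio`,
#'   `n_scd_tail`, `n_nor_tail`, of class `tail_criteria`.
#' @export
search_all_parameters <- function(features, config = refine_config(),
                                  class_col = "class",
                                  positive = "SCD", negative = "NOR") {
  cls <- features[[class_col]]
  if (is.null(cls) || !positive %in% cls || !negative %in% cls) {
    abort("feature table must contain both classes")
  }
  missing <- setdiff(config$parameters_searched, names(features))
  if (length(missing) > 0) {
    abort(sprintf("feature table lacks searched parameter(s): %s",
                  paste(missing, collapse = ", ")))
  }
  is_scd <- cls == positive
  is_nor <- cls == negative
  out <- list()
  for (par in config$parameters_searched) {
    v <- features[[par]]
    for (dir in c("lower", "upper")) {
      crit <- find_tail_criterion(v[is_scd], v[is_nor], dir, config)
      if (!is.null(crit)) {
        out[[length(out) + 1]] <- dplyr::bind_cols(
          tibble(parameter = par), crit
        )
      }
    }
  }
  res <- if (length(out) > 0) {
    dplyr::bind_rows(out)
  } else {
    tibble(parameter = character(), direction = character(),
           threshold = numeric(), achieved_ratio = numeric(),
           n_scd_tail = integer(), n_nor_tail = integer())
  }
  class(res) <- c("tail_criteria", class(res))
  res
}

criterion_matches <- function(values, direction, threshold) {
  if (direction == "lower") values <= threshold else values >= threshold
}

#' Build the refined training set from tail criteria
#'
#' The refined disease set is the union, over all criteria, of
#' disease-class cells falling in a qualifying tail (each cell counted
#' once, with per-cell provenance recording which criteria matched). An
#' equal number of normal-class cells is drawn uniformly at random
#' without replacement using the configured seed.
#'
#' @param features Feature table with `cell_id`, class column and the
#'   criteria's parameters.
#' @param criteria A non-empty criteria tibble from
#'   [search_all_parameters()].
#' @param config A [refine_config()].
#' @param class_col,positive,negative As in [search_all_parameters()].
#' @return An object of class `refined_set`: list with `scd_ids`,
#'   `nor_ids` (same length), `provenance` (tibble `cell_id`, `parameter`,
#'   `direction`), `criteria`, `undersized` flag and the balancing `seed`.
#' @export
build_refined_set <- function(features, criteria, config = refine_config(),
                              class_col = "class",
                              positive = "SCD", negative = "NOR") {
  if (is.null(criteria) || nrow(criteria) == 0) {
    abort("`criteria` must contain at least one tail criterion")
  }
  if (!"cell_id" %in% names(features)) {
    abort("feature table needs a `cell_id` column")
  }
  scd <- features[features[[class_col]] == positive, , drop = FALSE]
  nor_ids_all <- features$cell_id[features[[class_col]] == negative]
  prov <- list()
  for (i in seq_len(nrow(criteria))) {
    cr <- criteria[i, ]
    hit <- criterion_matches(scd[[cr$parameter]], cr$direction, cr$threshold)
    if (any(hit)) {
      prov[[i]] <- tibble(
        cell_id = scd$cell_id[hit],
        parameter = cr$parameter,
        direction = cr$direction
      )
    }
  }
  prov <- dplyr::bind_rows(prov)
  scd_ids <- unique(prov$cell_id)
  if (length(scd_ids) == 0) {
    abort("no disease cells match any criterion")
  }
  if (length(nor_ids_all) < length(scd_ids)) {
    abort(sprintf(
      "cannot balance refined set: %d normal cells available for %d selected disease cells",
      length(nor_ids_all), length(scd_ids)
    ))
  }
  undersized <- length(scd_ids) < config$min_refined_size
  if (undersized) {
    warn(sprintf(
      "refined set has %d cells, below the configured minimum of %d",
      length(scd_ids), config$min_refined_size
    ))
  }
  nor_ids <- with_seed(config$seed,
                       sample(nor_ids_all, length(scd_ids)))
  structure(
    list(
      scd_ids = scd_ids,
      nor_ids = nor_ids,
      provenance = prov,
      criteria = criteria,
      undersized = undersized,
      seed = config$seed
    ),
    class = "refined_set"
  )
}

#' @export
print.refined_set <- function(x, ...) {
  cat(sprintf(
    "<refined_set> %d disease cells (union of %d criteria) + %d matched normals%s\n",
    length(x$scd_ids), nrow(x$criteria), length(x$nor_ids),
    if (x$undersized) " [undersized]" else ""
  ))
  invisible(x)
}

#' @describeIn build_refined_set Tidy per-cell membership of a refined set.
#' @param x A `refined_set`.
#' @param ... Unused.
#' @export
tidy.refined_set <- function(x, ...) {
  counts <- dplyr::count(x$provenance, .data$cell_id, name = "n_criteria")
  dplyr::bind_rows(
    dplyr::mutate(counts, role = "scd"),
    tibble(cell_id = x$nor_ids, n_criteria = NA_integer_,
           role = "matched_nor")
  )
}

#' @describeIn build_refined_set One-row summary of a refined set.
#' @export
glance.refined_set <- function(x, ...) {
  tibble(
    n_scd = length(x$scd_ids),
    n_nor = length(x$nor_ids),
    n_criteria = nrow(x$criteria),
    undersized = x$undersized
  )
}

#' Subset a feature table to the refined training set
#'
#' @param features Feature table the refined set was built from.
#' @param refined A `refined_set`.
#' @return The rows of `features` belonging to the refined set, in
#'   selected-disease-then-matched-normal order.
#' @export
refined_training_table <- function(features, refined) {
  ids <- c(refined$scd_ids, refined$nor_ids)
  features[match(ids, features$cell_id), , drop = FALSE]
}
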