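# Expression breadth across cohorts. A feature is "expressed in a cohort"
# under the same prevalence rule the candidate filter uses, restricted to
# one condition (tumor or normal); categories follow the count of cohorts:
# exactly one = tissue-specific, all = ubiquitous, anything between = other.

#' Classify expression breadth across cohorts
#'
#' For each feature, counts the cohorts (within one condition) in which it
#' passes the prevalence criterion, then assigns tissue_specific
#' (n_expressed = 1), ubiquitous (n_expressed = number of cohorts) or
#' other. Features expressed in no cohort are excluded from classification
#' and returned separately.
#'
#' @param m Expression matrix (features x samples).
#' @param sheet Sample sheet.
#' @param cfg A [pipeline_config()].
#' @param condition "tumor" or "normal".
#' @return List with `records` (data.frame feature_id, condition,
#'   n_expressed, category), `unexpressed` (feature ids expressed nowhere),
#'   and `n_cohorts`.
#' @export
expression_breadth <- function(m, sheet, cfg = pipeline_config(),
                               condition = c("tumor", "normal")) {
  if (length(condition) != 1 || !condition %in% c("tumor", "normal")) {
    stop("condition must be 'tumor' or 'normal'")
  }
  cohorts <- sort(unique(sheet$tissue))
  if (length(cohorts) < 2) stop("breadth classification needs >= 2 cohorts")
  thr <- cfg$expressed_threshold
  expressed <- vapply(cohorts, function(co) {
    ss <- cohort_samples(sheet, co, condition)
    if (!length(ss)) stop("cohort '", co, "' has no ", condition, " samples")
    rowMeans(m[, ss, drop = FALSE] > thr) >= cfg$prevalence_min
  }, logical(nrow(m)))
  n_expressed <- rowSums(expressed)
  classified <- n_expressed >= 1
  category <- classify_breadth(n_expressed[classified], length(cohorts))
  records <- data.frame(
    feature_id = rownames(m)[classified],
    condition = condition,
    n_expressed = n_expressed[classified],
    category = category,
    row.names = NULL, stringsAsFactors = FALSE)
  list(records = records,
       unexpressed = rownames(m)[!classified],
       n_cohorts = length(cohorts))
}

#' Breadth category from a cohort count
#'
#' Total function of (n_expressed, n_cohorts): tissue_specific iff
#' n_expressed == 1, ubiquitous iff n_expressed == n_cohorts, other
#' otherwise. (With n_cohorts == 1 a single-cohort feature is ubiquitous;
#' the pipeline requires >= 2 cohorts so the case is moot.)
#'
#' @param n_expressed Integer vector in 1..n_cohorts.
#' @param n_cohorts Number of configured cohorts.
#' @return Character vector of categories.
#' @export
classify_breadth <- function(n_expressed, n_cohorts) {
  if (any(n_expressed < 1) || any(n_expressed > n_cohorts)) {
    stop("n_expressed must lie in 1..n_cohorts")
  }
  ifelse(n_expressed == n_cohorts, "ubiquitous",
         ifelse(n_expressed == 1, "tissue_specific", "other"))
}

#' Distribution of breadth counts and categories
#'
#' @param breadth Result of [expression_breadth()] (or its `records`).
#' @param n_cohorts Required when passing a bare records data.frame.
#' @return List with `by_count` (n_expressed 1..n_cohorts, count,
#'   proportion) and `by_category` data.frames; proportions sum to 1.
#' @export
breadth_distribution <- function(breadth, n_cohorts = NULL) {
  if (is.data.frame(breadth)) {
    records <- breadth
    if (is.null(n_cohorts)) stop("n_cohorts required with a records data.frame")
  } else {
    records <- breadth$records
    n_cohorts <- breadth$n_cohorts
  }
  if (!nrow(records)) stop("no classified features to tabulate")
  counts <- tabulate(records$n_expressed, nbins = n_cohorts)
  by_count <- data.frame(n_expressed = seq_len(n_cohorts),
                         count = counts,
                         proportion = counts / nrow(records))
  cats <- c("tissue_specific", "other", "ubiquitous")
  ccount <- vapply(cats, function(cc) sum(records$category == cc), 1L)
  by_category <- data.frame(category = cats, count = ccount,
                            proportion = ccount / nrow(records),
                            row.names = NULL, stringsAsFactors = FALSE)
  list(by_count = by_count, by_category = by_category)
}

# Round half away from zero to `digits` decimals (printed-percentage style;
# base round() is round-half-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Cross-tabulate breadth against regulation status
#'
#' Among a set of regulated DE enhancers, how many are ubiquitously
#' expressed: returns the numerator, denominator and percentage (rounded
#' half-up to 2 decimals).
#'
#' @param breadth Result of [expression_breadth()] or its `records`
#'   data.frame.
#' @param regulated_ids Enhancer ids with at least one significant link;
#'   must all be classified in `breadth`.
#' @return List: numerator, denominator, percentage.
#' @export
cross_tabulate_breadth_vs_regulation <- function(breadth, regulated_ids) {
  records <- if (is.data.frame(breadth)) breadth else breadth$records
  if (!all(regulated_ids %in% records$feature_id)) {
    bad <- setdiff(regulated_ids, records$feature_id)
    stop("regulated enhancers missing from breadth records: ",
         paste(utils::head(bad, 3), collapse = ", "))
  }
  sub <- records[records$feature_id %in% regulated_ids, ]
  numerator <- sum(sub$category == "ubiquitous")
  denominator <- length(unique(regulated_ids))
  pct <- if (denominator == 0) NA_real_ else
    round_half_up(100 * numerator / denominator, 2)
  list(numerator = numerator, denominator = denominator, percentage = pct)
}
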