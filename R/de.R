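# Differential expression of enhancers and genes, one cohort at a time.
# The statistic is deliberately simple: the inputs are RPKM-scale
# continuous values, so the caller is a prevalence filter, a log2 ratio of
# group means with a small pseudocount, a Welch t-test, and BH adjustment
# within the (cohort x feature-class) family.

cohort_samples <- function(sheet, cohort, condition) {
  sheet$sample_id[sheet$tissue == cohort & sheet$condition == condition]
}

#' Prevalence filter for testable features
#'
#' A feature is a candidate when it is expressed (value strictly above
#' `expressed_threshold`) in at least `prevalence_min` of the cohort's tumor
#' samples OR of its normal samples. The disjunction keeps a feature seen
#' only in normals testable as a down event. The boundary is inclusive:
#' exactly 10% counts.
#'
#' @param m Expression matrix (features x samples).
#' @param sheet Sample sheet data.frame.
#' @param cohort Cohort (tissue) label.
#' @param cfg A [pipeline_config()].
#' @return Character vector of candidate feature ids, in matrix row order.
#' @export
filter_candidates <- function(m, sheet, cohort, cfg = pipeline_config()) {
  ts <- cohort_samples(sheet, cohort, "tumor")
  ns <- cohort_samples(sheet, cohort, "normal")
  if (!length(ts) || !length(ns)) {
    stop("cohort '", cohort, "' has no tumor or no normal samples")
  }
  missing <- setdiff(c(ts, ns), colnames(m))
  if (length(missing)) {
    stop("samples missing from expression matrix: ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  thr <- cfg$expressed_threshold
  frac_t <- rowMeans(m[, ts, drop = FALSE] > thr)
  frac_n <- rowMeans(m[, ns, drop = FALSE] > thr)
  keep <- frac_t >= cfg$prevalence_min | frac_n >= cfg$prevalence_min
  rownames(m)[keep]
}

#' Log2 fold change of group means
#'
#' log2((mean_t + c) / (mean_n + c)) with pseudocount c > 0. Antisymmetric
#' under swapping the groups.
#'
#' @param mean_t,mean_n Non-negative group means (vectorized).
#' @param pseudocount Positive pseudocount.
#' @return Numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(mean_t, mean_n, pseudocount = 0.01) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (any(mean_t < 0) || any(mean_n < 0)) stop("group means must be >= 0")
  log2((mean_t + pseudocount) / (mean_n + pseudocount))
}

#' Two-sample t-test p-value with degenerate-input conventions
#'
#' Welch's unequal-variance statistic with Satterthwaite degrees of freedom
#' (the default), or the pooled-variance Student variant when
#' `pooled = TRUE`. When both groups are constant the test statistic is
#' undefined; by convention p = 1 if the two constants are equal and p = 0
#' if they differ.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param pooled Use pooled variance (Student) instead of Welch.
#' @return Two-sided p-value.
#' @export
welch_t_test <- function(x, y, pooled = FALSE) {
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 values")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  stats::t.test(x, y, var.equal = pooled)$p.value
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH with enforced monotonicity, preserving input order.
#'
#' @param pvals p-values in [0, 1].
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Call differential expression within one cohort
#'
#' Runs the prevalence filter (unless `features` is supplied), computes per
#' feature the tumor and normal means, log2 fold change, t-test p-value and
#' BH q-value (family = this call, i.e. one cohort and one feature class),
#' and labels each feature up / down / ns: up iff log2fc >= log2fc_min and
#' q < q_max, down iff log2fc <= -log2fc_min and q < q_max.
#'
#' @param m Expression matrix (features x samples).
#' @param sheet Sample sheet.
#' @param cohort Cohort label.
#' @param cfg A [pipeline_config()].
#' @param features Optional pre-filtered feature ids.
#' @return data.frame: feature_id, cohort, mean_tumor, mean_normal, log2fc,
#'   p, q, call.
#' @export
call_de <- function(m, sheet, cohort, cfg = pipeline_config(),
                    features = NULL) {
  if (is.null(features)) features <- filter_candidates(m, sheet, cohort, cfg)
  ts <- cohort_samples(sheet, cohort, "tumor")
  ns <- cohort_samples(sheet, cohort, "normal")
  if (length(ts) < 2 || length(ns) < 2) {
    stop("cohort '", cohort, "' needs >= 2 tumor and >= 2 normal samples")
  }
  if (!length(features)) {
    return(data.frame(feature_id = character(), cohort = character(),
                      mean_tumor = numeric(), mean_normal = numeric(),
                      log2fc = numeric(), p = numeric(), q = numeric(),
                      call = character(), stringsAsFactors = FALSE))
  }
  mt <- m[features, ts, drop = FALSE]
  mn <- m[features, ns, drop = FALSE]
  mean_t <- rowMeans(mt)
  mean_n <- rowMeans(mn)
  lfc <- log2_fold_change(mean_t, mean_n, cfg$pseudocount)
  p <- vapply(seq_along(features), function(i) {
    welch_t_test(mt[i, ], mn[i, ], pooled = cfg$t_test_pooled)
  }, numeric(1))
  q <- bh_adjust(p)
  call <- rep("ns", length(features))
  call[lfc >= cfg$log2fc_min & q < cfg$q_max] <- "up"
  call[lfc <= -cfg$log2fc_min & q < cfg$q_max] <- "down"
  data.frame(feature_id = features, cohort = cohort,
             mean_tumor = mean_t, mean_normal = mean_n,
             log2fc = lfc, p = p, q = q, call = call,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' DE calls for every cohort in the sample sheet
#'
#' Convenience wrapper applying [call_de()] per cohort and binding the
#' results; the BH family stays per cohort.
#'
#' @inheritParams call_de
#' @return data.frame of stacked per-cohort DE records.
#' @export
call_de_all <- function(m, sheet, cfg = pipeline_config()) {
  cohorts <- sort(unique(sheet$tissue))
  do.call(rbind, lapply(cohorts, function(co) call_de(m, sheet, co, cfg)))
}
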