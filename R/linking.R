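# Enhancer -> target-gene linking: a geometric screen (gene promoter
# intersects the +/-100 kb window around the enhancer center) followed by a
# Spearman coexpression screen with BH control within the cohort.

#' Candidate enhancer-gene pairs by promoter/window intersection
#'
#' Emits (enhancer, gene, distance) for every gene whose promoter region
#' overlaps the enhancer's search window (half-open semantics; abutting
#' intervals do not overlap). Distance is |gene TSS - enhancer center|.
#' Genes without an annotation are skipped with a warning.
#'
#' @param de_enhancers data.frame of enhancers (id, chrom, start, end),
#'   typically restricted to one cohort's DE enhancers.
#' @param de_gene_ids Character vector of DE gene ids.
#' @param annotations Gene annotation data.frame (id, chrom, tss, strand).
#' @param cfg A [pipeline_config()].
#' @return data.frame enhancer_id, gene_id, distance, sorted by
#'   (enhancer_id, distance, gene_id).
#' @export
candidate_pairs <- function(de_enhancers, de_gene_ids, annotations,
                            cfg = pipeline_config()) {
  empty <- data.frame(enhancer_id = character(), gene_id = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (!nrow(de_enhancers) || !length(de_gene_ids)) return(empty)
  missing <- setdiff(de_gene_ids, annotations$id)
  if (length(missing)) {
    warning(length(missing), " DE gene(s) without annotation skipped: ",
            paste(utils::head(missing, 3), collapse = ", "))
    de_gene_ids <- setdiff(de_gene_ids, missing)
  }
  if (!length(de_gene_ids)) return(empty)
  genes <- annotations[match(de_gene_ids, annotations$id), ]

  windows <- enhancer_window(de_enhancers, cfg)
  promoters <- promoter_region(genes, cfg)
  hits <- GenomicRanges::findOverlaps(as_granges0(windows),
                                      as_granges0(promoters))
  ei <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  out <- data.frame(
    enhancer_id = de_enhancers$id[ei],
    gene_id = genes$id[gi],
    distance = abs(genes$tss[gi] - enhancer_center(de_enhancers)[ei]),
    stringsAsFactors = FALSE)
  out <- out[order(out$enhancer_id, out$distance, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# All permutations of 1..n as an (n! x n) matrix, lexicographic.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Spearman correlation with a small-sample exact p-value
#'
#' rho is the Pearson correlation of average-assigned ranks (ties allowed).
#' For n <= `exact_n_max` the two-sided p-value is exact, from the full
#' permutation distribution of rho under exchangeability; above that it
#' uses the t approximation with n - 2 degrees of freedom. When either
#' vector has zero rank variance rho is undefined and NA is returned (the
#' caller drops the pair).
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @param exact_n_max Largest n for the exact permutation p-value
#'   (default 8; the permutation count grows factorially).
#' @return List with rho, p, and method ("exact" or "t").
#' @export
spearman_test <- function(x, y, exact_n_max = 8) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 4) stop("spearman_test needs n >= 4")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, method = "degenerate"))
  }
  rho <- stats::cor(rx, ry)
  if (n <= exact_n_max) {
    perms <- all_permutations(n)
    ry_perm <- matrix(ry[perms], nrow(perms), n)
    rho_perm <- as.vector(stats::cor(t(ry_perm), rx))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    return(list(rho = rho, p = p, method = "exact"))
  }
  if (abs(rho) >= 1 - 1e-15) {
    return(list(rho = sign(rho), p = 0, method = "t"))
  }
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(rho = rho, p = p, method = "t")
}

#' Coexpression screen over candidate pairs
#'
#' Computes the Spearman correlation for each candidate pair over one
#' cohort's samples (tumor only by default; `cfg$link_samples = "all"`
#' pools tumor and normal), BH-adjusts within the cohort across all
#' candidate pairs, and flags links: rho >= corr_min (or |rho| >= corr_min
#' when `link_use_abs_corr`) and q < link_q_max. Pairs with undefined rho
#' (zero rank variance) are dropped with a message.
#'
#' @param candidates data.frame from [candidate_pairs()].
#' @param enh_m,gene_m Expression matrices.
#' @param sheet Sample sheet.
#' @param cohort Cohort label.
#' @param cfg A [pipeline_config()].
#' @return data.frame enhancer_id, gene_id, cohort, distance, rho, p, q,
#'   linked.
#' @export
link_targets <- function(candidates, enh_m, gene_m, sheet, cohort,
                         cfg = pipeline_config()) {
  empty <- data.frame(enhancer_id = character(), gene_id = character(),
                      cohort = character(), distance = numeric(),
                      rho = numeric(), p = numeric(), q = numeric(),
                      linked = logical(), stringsAsFactors = FALSE)
  if (!nrow(candidates)) return(empty)
  samples <- cohort_samples(sheet, cohort, "tumor")
  if (cfg$link_samples == "all") {
    samples <- c(samples, cohort_samples(sheet, cohort, "normal"))
  }
  if (length(samples) < 4) stop("cohort '", cohort, "' has < 4 samples for correlation")
  res <- lapply(seq_len(nrow(candidates)), function(i) {
    spearman_test(enh_m[candidates$enhancer_id[i], samples],
                  gene_m[candidates$gene_id[i], samples])
  })
  rho <- vapply(res, `[[`, numeric(1), "rho")
  p <- vapply(res, `[[`, numeric(1), "p")
  ok <- !is.na(rho)
  if (any(!ok)) {
    message(sum(!ok), " candidate pair(s) dropped in cohort ", cohort,
            ": zero rank variance")
  }
  out <- candidates[ok, , drop = FALSE]
  if (!nrow(out)) return(empty)
  out$cohort <- cohort
  out$rho <- rho[ok]
  out$p <- p[ok]
  out$q <- bh_adjust(out$p)
  screen <- if (cfg$link_use_abs_corr) abs(out$rho) else out$rho
  out$linked <- screen >= cfg$corr_min & out$q < cfg$link_q_max
  rownames(out) <- NULL
  out[, c("enhancer_id", "gene_id", "cohort", "distance",
          "rho", "p", "q", "linked")]
}

#' Partition DE enhancers by regulation status
#'
#' Regulated = DE enhancers with at least one significant link; the two
#' sets are disjoint and their union is the input DE enhancer set.
#'
#' @param de_enhancer_ids DE enhancer ids.
#' @param links data.frame from [link_targets()] (possibly stacked).
#' @return List with `regulated` and `nonregulated` id vectors.
#' @export
partition_regulated <- function(de_enhancer_ids, links) {
  linked_ids <- unique(links$enhancer_id[links$linked])
  regulated <- intersect(de_enhancer_ids, linked_ids)
  list(regulated = regulated,
       nonregulated = setdiff(de_enhancer_ids, regulated))
}

#' Compare expression of regulated vs nonregulated DE enhancers
#'
#' Two-sided Wilcoxon rank-sum on per-enhancer mean tumor expression within
#' one cohort, with the group medians.
#'
#' @param enh_m Enhancer expression matrix.
#' @param regulated_ids,nonregulated_ids Disjoint enhancer id sets, both
#'   non-empty.
#' @param sheet Sample sheet.
#' @param cohort Cohort label.
#' @return List: statistic, p, median_regulated, median_nonregulated, n.
#' @export
compare_regulated_vs_nonregulated <- function(enh_m, regulated_ids,
                                              nonregulated_ids, sheet,
                                              cohort) {
  if (!length(regulated_ids) || !length(nonregulated_ids)) {
    stop("cohort '", cohort, "': both enhancer groups must be non-empty")
  }
  ts <- cohort_samples(sheet, cohort, "tumor")
  mr <- rowMeans(enh_m[regulated_ids, ts, drop = FALSE])
  mn <- rowMeans(enh_m[nonregulated_ids, ts, drop = FALSE])
  wt <- suppressWarnings(stats::wilcox.test(mr, mn, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       median_regulated = stats::median(mr),
       median_nonregulated = stats::median(mn),
       n = c(regulated = length(mr), nonregulated = length(mn)))
}
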