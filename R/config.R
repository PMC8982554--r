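#' Pipeline configuration
#'
#' Builds the single configuration object consumed by every stage. Defaults
#' are the thresholds of the published analysis this package implements:
#' features must be expressed in at least 10% of tumor or of normal samples
#' to be testable; a DE call requires |log2FC| >= 1 and BH q < 0.05;
#' promoters are the strand-aware window 0.5 kb upstream to 1 kb downstream
#' of the TSS; candidate target genes lie within 100 kb of the enhancer
#' center; links require Spearman corr >= 0.3 at q < 0.05; SNPs are mapped
#' into enhancers extended by 0.5 kb on each side.
#'
#' @param prevalence_min Minimum fraction of samples (tumor or normal) in
#'   which a feature must be expressed to enter testing. Default 0.10.
#' @param expressed_threshold A feature counts as expressed in a sample when
#'   its value is strictly greater than this. Default 0.
#' @param log2fc_min Absolute log2 fold-change gate for a DE call. Default 1.
#' @param q_max BH q-value threshold for DE and enrichment calls. Default 0.05.
#' @param promoter_upstream,promoter_downstream Promoter extent in bp
#'   upstream/downstream of the TSS (strand-aware). Defaults 500 and 1000.
#' @param link_window Half-width in bp of the search window around the
#'   enhancer center for candidate target genes. Default 100000.
#' @param corr_min Minimum Spearman correlation for a link. Default 0.3.
#' @param link_q_max BH q-value threshold for links. Default 0.05.
#' @param snp_flank Extension in bp applied to each enhancer boundary before
#'   SNP mapping. Default 500.
#' @param tfbs_p_max Motif-binding p-value threshold: a window is called
#'   bound when the background tail probability of its best score is at or
#'   below this. Default 1e-4.
#' @param pseudocount Added to both group means before the log2 ratio.
#'   Default 0.01.
#' @param seed Integer seed recorded in run manifests. Default 1.
#' @param t_test_pooled Use the pooled-variance Student t-test instead of
#'   Welch. Default FALSE.
#' @param link_use_abs_corr Screen links on |corr| rather than the one-sided
#'   positive rule. Default FALSE.
#' @param link_samples Which samples of a cohort feed the coexpression
#'   screen: "tumor" (default) or "all" (tumor + normal).
#'
#' @return A named list of class "pipeline_config".
#' @export
pipeline_config <- function(prevalence_min = 0.10,
                            expressed_threshold = 0,
                            log2fc_min = 1.0,
                            q_max = 0.05,
                            promoter_upstream = 500L,
                            promoter_downstream = 1000L,
                            link_window = 100000L,
                            corr_min = 0.3,
                            link_q_max = 0.05,
                            snp_flank = 500L,
                            tfbs_p_max = 1e-4,
                            pseudocount = 0.01,
                            seed = 1L,
                            t_test_pooled = FALSE,
                            link_use_abs_corr = FALSE,
                            link_samples = c("tumor", "all")) {
  link_samples <- match.arg(link_samples)
  cfg <- list(
    prevalence_min = as.numeric(prevalence_min),
    expressed_threshold = as.numeric(expressed_threshold),
    log2fc_min = as.numeric(log2fc_min),
    q_max = as.numeric(q_max),
    promoter_upstream = as.integer(promoter_upstream),
    promoter_downstream = as.integer(promoter_downstream),
    link_window = as.integer(link_window),
    corr_min = as.numeric(corr_min),
    link_q_max = as.numeric(link_q_max),
    snp_flank = as.integer(snp_flank),
    tfbs_p_max = as.numeric(tfbs_p_max),
    pseudocount = as.numeric(pseudocount),
    seed = as.integer(seed),
    t_test_pooled = isTRUE(t_test_pooled),
    link_use_abs_corr = isTRUE(link_use_abs_corr),
    link_samples = link_samples
  )
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$prevalence_min >= 0, cfg$prevalence_min <= 1,
    cfg$expressed_threshold >= 0,
    cfg$log2fc_min >= 0,
    cfg$q_max > 0, cfg$q_max <= 1,
    cfg$promoter_upstream >= 0, cfg$promoter_downstream >= 0,
    cfg$promoter_upstream + cfg$promoter_downstream > 0,
    cfg$corr_min >= -1, cfg$corr_min <= 1,
    cfg$link_q_max > 0, cfg$link_q_max <= 1,
    cfg$snp_flank >= 0,
    cfg$tfbs_p_max > 0, cfg$tfbs_p_max <= 1,
    cfg$pseudocount > 0
  )
  if (cfg$link_window <= 0) {
    stop("link_window must be a positive number of base pairs")
  }
  invisible(cfg)
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value`; blank lines and lines starting with `#`
#' are ignored. Keys must be [pipeline_config()] argument names; values are
#' coerced to the type of the corresponding default. Keys that name input
#' files for [run_pipeline()] (e.g. `enhancer_bed`, `gene_expression`) are
#' carried through as character paths.
#'
#' @param path Configuration file.
#' @return A "pipeline_config" list; path-valued keys are kept in an
#'   `inputs` attribute-free named sublist element `paths`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed config line: ", lines[which(bad)[1]])
  }
  keys <- vapply(kv, `[`, "", 2L)
  vals <- trimws(vapply(kv, `[`, "", 3L))
  if (anyDuplicated(keys)) stop("duplicate config key: ", keys[duplicated(keys)][1])

  defaults <- formals(pipeline_config)
  scalar_keys <- setdiff(names(defaults), "link_samples")
  args <- list()
  paths <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    if (k %in% scalar_keys) {
      proto <- eval(defaults[[k]])
      args[[k]] <- if (is.logical(proto)) as.logical(v) else as.numeric(v)
    } else if (k == "link_samples") {
      args[[k]] <- v
    } else if (grepl("^(enhancer|gene|sample|snp|pfm|gmt|fasta|out)", k)) {
      paths[[k]] <- v
    } else {
      stop("unknown config key: ", k)
    }
  }
  cfg <- do.call(pipeline_config, args)
  cfg$paths <- paths
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (k in setdiff(names(x), "paths")) {
    cat(sprintf("  %-20s %s\n", k, format(x[[k]])))
  }
  if (!is.null(x$paths) && length(x$paths)) {
    cat("  inputs:\n")
    for (k in names(x$paths)) cat(sprintf("    %-18s %s\n", k, x$paths[[k]]))
  }
  invisible(x)
}
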