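# End-to-end orchestration: filter -> DE (enhancers, genes) -> breadth ->
# link -> partition -> enrichment -> SNP/TFBS -> summaries, with a
# machine-readable manifest. Every stage is deterministic given the inputs
# and configuration, so repeated runs are byte-identical.

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full enhancer analysis pipeline
#'
#' Reads every input named in the configuration, runs all stages in order,
#' and writes one TSV per stage plus `manifest.json` into `out_dir`. Any
#' stage failure aborts with the stage name; missing inputs are reported
#' before any computation starts.
#'
#' Required path keys (in `cfg$paths`, or as `key = value` lines in a
#' config file): enhancer_bed, enhancer_expression, gene_expression,
#' sample_sheet, gene_table, snp_table, pfm, gmt, fasta.
#'
#' @param config A "pipeline_config" with a `paths` element, or the path of
#'   a config file for [read_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) read_config(config) else config
  need <- c("enhancer_bed", "enhancer_expression", "gene_expression",
            "sample_sheet", "gene_table", "snp_table", "pfm", "gmt", "fasta")
  paths <- cfg$paths
  missing <- setdiff(need, names(paths))
  if (length(missing)) {
    stop("config is missing input path(s): ", paste(missing, collapse = ", "))
  }
  absent <- unlist(paths[need])[!file.exists(unlist(paths[need]))]
  if (length(absent)) {
    stop("input file(s) not found: ", paste(absent, collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage_log("read", "loading inputs")
  enhancers <- read_enhancer_bed(paths$enhancer_bed)
  enh_m <- read_expression_tsv(paths$enhancer_expression)
  gene_m <- read_expression_tsv(paths$gene_expression)
  sheet <- read_sample_sheet(paths$sample_sheet)
  genes <- read_gene_table(paths$gene_table)
  snps <- read_snp_table(paths$snp_table)
  pwms <- pfms_to_pwms(read_pfm(paths$pfm))
  gene_sets <- read_gmt(paths$gmt)
  seqs <- read_fasta(paths$fasta)
  cohorts <- sort(unique(sheet$tissue))

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  stage_log("de", "differential expression in ", length(cohorts), " cohorts")
  de_enh <- run_stage("de-enhancers", call_de_all(enh_m, sheet, cfg))
  de_gene <- run_stage("de-genes", call_de_all(gene_m, sheet, cfg))

  stage_log("breadth", "expression breadth classification")
  breadth_t <- run_stage("breadth", expression_breadth(enh_m, sheet, cfg, "tumor"))
  breadth_n <- run_stage("breadth", expression_breadth(enh_m, sheet, cfg, "normal"))

  stage_log("link", "candidate pairs and coexpression screen")
  links <- run_stage("link", {
    do.call(rbind, lapply(cohorts, function(co) {
      de_e <- de_enh$feature_id[de_enh$cohort == co & de_enh$call != "ns"]
      de_g <- de_gene$feature_id[de_gene$cohort == co & de_gene$call != "ns"]
      cand <- candidate_pairs(enhancers[enhancers$id %in% de_e, ],
                              de_g, genes, cfg)
      link_targets(cand, enh_m, gene_m, sheet, co, cfg)
    }))
  })
  if (is.null(links)) {
    links <- data.frame(enhancer_id = character(), gene_id = character(),
                        cohort = character(), distance = numeric(),
                        rho = numeric(), p = numeric(), q = numeric(),
                        linked = logical(), stringsAsFactors = FALSE)
  }

  de_enh_ids <- unique(de_enh$feature_id[de_enh$call != "ns"])
  parts <- run_stage("partition", partition_regulated(de_enh_ids, links))
  crosstab <- if (length(parts$regulated) &&
                  all(parts$regulated %in% breadth_t$records$feature_id)) {
    cross_tabulate_breadth_vs_regulation(breadth_t, parts$regulated)
  } else list(numerator = 0L, denominator = length(parts$regulated),
              percentage = NA_real_)

  stage_log("enrich", "gene-set over-representation")
  linked_genes <- unique(links$gene_id[links$linked])
  universe <- unique(unlist(lapply(cohorts, function(co) {
    filter_candidates(gene_m, sheet, co, cfg)
  })))
  enrichment <- if (length(linked_genes)) {
    run_stage("enrich", run_enrichment(linked_genes, gene_sets, universe, cfg))
  } else {
    data.frame(set_name = character(), k = integer(), K = integer(),
               n = integer(), N = integer(), p = numeric(), q = numeric(),
               significant = logical(), stringsAsFactors = FALSE)
  }

  stage_log("snp-tfbs", "SNP mapping and allelic TFBS scoring")
  de_enh_tbl <- enhancers[enhancers$id %in% de_enh_ids, , drop = FALSE]
  mapped <- run_stage("snp-map", map_snps(snps, de_enh_tbl, cfg))
  events <- run_stage("snp-tfbs",
                      classify_snps(mapped, seqs, enhancers, pwms, cfg))
  summaries <- summarize_events(events)
  de_by_enh <- split(de_enh$cohort[de_enh$call != "ns"],
                     de_enh$feature_id[de_enh$call != "ns"])
  snp_cohorts <- do.call(rbind, lapply(seq_len(nrow(mapped)), function(i) {
    cos <- de_by_enh[[mapped$enhancer_id[i]]]
    if (is.null(cos)) return(NULL)
    data.frame(rs_id = mapped$rs_id[i], cohort = unique(cos),
               stringsAsFactors = FALSE)
  }))
  snp_props <- if (!is.null(snp_cohorts) && nrow(snp_cohorts)) {
    cohort_snp_proportions(snp_cohorts)
  } else data.frame(cohort = character(), n_snps = integer(),
                    proportion = numeric(), percentage = numeric())

  stage_log("write", "stage outputs and manifest")
  o <- function(f) file.path(out_dir, f)
  write_records_tsv(de_enh, o("de_enhancers.tsv"))
  write_records_tsv(de_gene, o("de_genes.tsv"))
  write_records_tsv(breadth_t$records, o("breadth_tumor.tsv"))
  write_records_tsv(breadth_n$records, o("breadth_normal.tsv"))
  write_records_tsv(breadth_distribution(breadth_t)$by_count,
                    o("breadth_tumor_distribution.tsv"))
  write_records_tsv(links, o("links.tsv"))
  write_records_tsv(
    data.frame(enhancer_id = c(parts$regulated, parts$nonregulated),
               status = rep(c("regulated", "nonregulated"),
                            c(length(parts$regulated),
                              length(parts$nonregulated)))),
    o("regulated_partition.tsv"))
  write_records_tsv(enrichment, o("enrichment.tsv"))
  write_records_tsv(mapped, o("mapped_snps.tsv"))
  write_records_tsv(events, o("tfbs_events.tsv"))
  write_records_tsv(snp_props, o("snp_cohort_proportions.tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("enhancerDE")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "paths")],
    input_md5 = as.list(tools::md5sum(unlist(paths[need]))),
    counts = list(
      cohorts = length(cohorts),
      enhancers = nrow(enhancers),
      genes = nrow(genes),
      de_enhancer_records = sum(de_enh$call != "ns"),
      de_gene_records = sum(de_gene$call != "ns"),
      de_enhancers_unique = length(de_enh_ids),
      de_genes_unique = length(unique(de_gene$feature_id[de_gene$call != "ns"])),
      candidate_links = nrow(links),
      links = sum(links$linked),
      linked_genes_unique = length(linked_genes),
      regulated = length(parts$regulated),
      nonregulated = length(parts$nonregulated),
      regulated_ubiquitous_pct = crosstab$percentage,
      mapped_snps = length(unique(mapped$rs_id)),
      snp_host_enhancers = length(unique(mapped$enhancer_id)),
      tfbs_events = nrow(events),
      tfs_affected = summaries$n_tfs_overall,
      significant_sets = sum(enrichment$significant)
    )
  )
  jsonlite::write_json(manifest, o("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(de_enhancers = de_enh, de_genes = de_gene,
                 breadth_tumor = breadth_t, breadth_normal = breadth_n,
                 links = links, partition = parts, crosstab = crosstab,
                 enrichment = enrichment, mapped_snps = mapped,
                 events = events, summaries = summaries,
                 snp_proportions = snp_props, manifest = manifest))
}
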