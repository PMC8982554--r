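# Synthetic multi-cohort tumor/normal data with known ground truth.
#
# Expression noise model: RPKM-scale values drawn from a log-normal
# baseline; planted DE features have their tumor mean scaled by
# 2^(+/- log2fc); planted enhancer-gene pairs share a latent Gaussian
# factor (Gaussian copula) whose Pearson correlation is chosen so the rank
# correlation equals the target rho (r = 2 sin(pi rho / 6)). Dropout is
# modeled as detection-limit censoring: values below the baseline
# log-normal's `dropout` quantile are recorded as 0, so the expected zero
# fraction at baseline equals `dropout` and zeros concentrate in
# low-abundance measurements, as in real RPKM data. This exercises the
# prevalence filter without scrambling planted rank correlations.

#' Default simulation truth specification
#'
#' @param log2fc Planted absolute log2 fold change. Default 2.
#' @param frac_de Fraction of features planted DE per cohort. Default 0.1.
#' @param rho Target Spearman correlation of planted links. Default 0.6.
#' @param meanlog,sdlog Baseline log-normal parameters. Defaults 1 and 1.
#' @param dropout Expected zero fraction at baseline (detection-limit
#'   censoring quantile). Default 0.2.
#' @return Named list.
#' @export
truth_spec <- function(log2fc = 2, frac_de = 0.1, rho = 0.6,
                       meanlog = 1, sdlog = 1, dropout = 0.2) {
  if (rho <= -1 || rho >= 1) stop("rho must lie in (-1, 1)")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (frac_de < 0 || frac_de > 1) stop("frac_de must lie in [0, 1]")
  list(log2fc = log2fc, frac_de = frac_de, rho = rho,
       meanlog = meanlog, sdlog = sdlog, dropout = dropout)
}

#' Generate a genomic layout of genes and enhancers
#'
#' Places gene TSSs and enhancers on `n_chroms` chromosomes of length
#' `chrom_length`. A fraction `prop_proximal` of enhancers is placed so
#' that at least one gene promoter lies inside the enhancer's
#' +/- link_window search region by construction; the rest are placed
#' uniformly. Deterministic for a fixed seed.
#'
#' @param n_genes,n_enhancers Feature counts (>= 1).
#' @param n_chroms Number of chromosomes. Default 2.
#' @param chrom_length Chromosome length in bp. Default 5e6.
#' @param seed Integer seed.
#' @param cfg A [pipeline_config()] (supplies link_window and promoter
#'   extents).
#' @param prop_proximal Fraction of enhancers guaranteed a nearby promoter.
#'   Default 0.8.
#' @param enhancer_length Enhancer width in bp. Default 400.
#' @return List with `genes` (id, symbol, chrom, tss, strand) and
#'   `enhancers` (id, chrom, start, end) data.frames.
#' @export
generate_layout <- function(n_genes, n_enhancers, n_chroms = 2,
                            chrom_length = 5e6, seed = 1,
                            cfg = pipeline_config(), prop_proximal = 0.8,
                            enhancer_length = 400) {
  if (n_genes < 1 || n_enhancers < 1) stop("feature counts must be >= 1")
  margin <- cfg$link_window + enhancer_length + 1000
  per_chrom <- ceiling((n_genes + n_enhancers) / n_chroms)
  if (chrom_length < 2 * margin || per_chrom * 2000 > chrom_length) {
    stop("chrom_length too small for the requested feature density")
  }
  set.seed(seed)
  chroms <- paste0("chr", seq_len(n_chroms))

  gene_chrom <- sample(chroms, n_genes, replace = TRUE)
  tss <- floor(stats::runif(n_genes, margin, chrom_length - margin))
  genes <- data.frame(
    id = sprintf("gene_%04d", seq_len(n_genes)),
    symbol = sprintf("SYM%04d", seq_len(n_genes)),
    chrom = gene_chrom, tss = tss,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE)

  n_prox <- round(prop_proximal * n_enhancers)
  half <- floor(enhancer_length / 2)
  # proximal: center within link_window minus a safety margin of a gene TSS,
  # so the promoter is inside the window by construction
  reach <- cfg$link_window -
    max(cfg$promoter_upstream, cfg$promoter_downstream) - 100
  anchor <- sample(seq_len(n_genes), n_prox, replace = TRUE)
  center_prox <- genes$tss[anchor] +
    floor(stats::runif(n_prox, -reach, reach))
  chrom_prox <- genes$chrom[anchor]
  n_rand <- n_enhancers - n_prox
  chrom_rand <- sample(chroms, n_rand, replace = TRUE)
  center_rand <- floor(stats::runif(n_rand, margin, chrom_length - margin))
  center <- c(center_prox, center_rand)
  chrom_e <- c(chrom_prox, chrom_rand)
  enhancers <- data.frame(
    id = sprintf("enh_%04d", seq_len(n_enhancers)),
    chrom = chrom_e,
    start = pmax(center - half, 0),
    end = pmax(center - half, 0) + enhancer_length,
    stringsAsFactors = FALSE)
  list(genes = genes, enhancers = enhancers)
}

#' Generate a multi-cohort sample sheet
#'
#' @param n_cohorts Number of cohorts (the study design this emulates has
#'   13 paired tumor/normal cancer cohorts). Default 13.
#' @param n_tumor,n_normal Samples per cohort. Defaults 50 and 50.
#' @param cohorts Optional explicit cohort labels.
#' @return Sample sheet data.frame.
#' @export
generate_sample_sheet <- function(n_cohorts = 13, n_tumor = 50,
                                  n_normal = 50, cohorts = NULL) {
  if (is.null(cohorts)) cohorts <- sprintf("cohort%02d", seq_len(n_cohorts))
  do.call(rbind, lapply(cohorts, function(co) {
    data.frame(
      sample_id = c(sprintf("%s_T%03d", co, seq_len(n_tumor)),
                    sprintf("%s_N%03d", co, seq_len(n_normal))),
      tissue = co,
      condition = rep(c("tumor", "normal"), c(n_tumor, n_normal)),
      stringsAsFactors = FALSE)
  }))
}

# Pearson correlation of the Gaussian copula that induces Spearman rho.
copula_r_for_spearman <- function(rho) 2 * sin(pi * rho / 6)

#' Generate expression matrices with planted ground truth
#'
#' Per cohort: a `frac_de` fraction of enhancers and of genes is planted DE
#' with random sign and |log2FC| = `log2fc` (tumor mean scaled by
#' 2^(sign * log2fc)); among distance-eligible (DE enhancer, DE gene) pairs,
#' links are planted by sharing a latent Gaussian factor across the
#' cohort's tumor samples, targeting Spearman correlation `rho`. Values are
#' exp(meanlog + sdlog * z) with detection-limit censoring at the baseline
#' `dropout` quantile. Deterministic for a fixed seed.
#'
#' @param layout Result of [generate_layout()].
#' @param sheet Sample sheet ([generate_sample_sheet()]).
#' @param spec A [truth_spec()].
#' @param seed Integer seed.
#' @param cfg A [pipeline_config()] (distance eligibility of planted pairs).
#' @param max_links_per_cohort Cap on planted links per cohort. Default 20.
#' @return List: `enhancer_expr`, `gene_expr` (matrices), `truth` (list
#'   with per-cohort de_enhancers, de_genes data.frames (feature_id, sign),
#'   linked_pairs data.frame (cohort, enhancer_id, gene_id, rho)).
#' @export
generate_expression <- function(layout, sheet, spec = truth_spec(),
                                seed = 1, cfg = pipeline_config(),
                                max_links_per_cohort = 20) {
  set.seed(seed)
  enh_ids <- layout$enhancers$id
  gene_ids <- layout$genes$id
  cohorts <- unique(sheet$tissue)
  detect_limit <- if (spec$dropout > 0) {
    stats::qlnorm(spec$dropout, spec$meanlog, spec$sdlog)
  } else -Inf

  enh_m <- matrix(NA_real_, length(enh_ids), nrow(sheet),
                  dimnames = list(enh_ids, sheet$sample_id))
  gene_m <- matrix(NA_real_, length(gene_ids), nrow(sheet),
                   dimnames = list(gene_ids, sheet$sample_id))
  truth <- list(de_enhancers = list(), de_genes = list(),
                linked_pairs = data.frame())

  r <- copula_r_for_spearman(spec$rho)
  # distance-eligible pairs over the whole layout; planted links per cohort
  # are drawn from these, so they satisfy the distance rule by construction
  eligible <- candidate_pairs(layout$enhancers, gene_ids, layout$genes, cfg)
  for (co in cohorts) {
    ts <- sheet$sample_id[sheet$tissue == co & sheet$condition == "tumor"]
    ns <- sheet$sample_id[sheet$tissue == co & sheet$condition == "normal"]
    samples <- c(ts, ns)
    n_de_e <- round(spec$frac_de * length(enh_ids))
    n_de_g <- round(spec$frac_de * length(gene_ids))

    # planted links first (distinct enhancers and genes), capped by the DE
    # budget of both feature classes; their members are forced DE
    planted <- data.frame()
    if (nrow(eligible) && n_de_e > 0 && n_de_g > 0) {
      shuffled <- eligible[sample(nrow(eligible)), , drop = FALSE]
      keep <- !duplicated(shuffled$enhancer_id) & !duplicated(shuffled$gene_id)
      planted <- utils::head(shuffled[keep, , drop = FALSE],
                             min(max_links_per_cohort, n_de_e, n_de_g))
    }
    # link members are planted as concordant up events: the coexpression
    # screen is one-sided positive, and a down-shifted feature would sit
    # mostly below the detection limit, leaving no rank signal to recover
    pick_de <- function(ids, n_de, forced) {
      extra <- if (n_de > length(forced)) {
        sample(setdiff(ids, forced), n_de - length(forced))
      } else character()
      chosen <- sort(unique(c(forced, extra)))
      if (!length(chosen)) {
        return(data.frame(feature_id = character(), sign = numeric(),
                          stringsAsFactors = FALSE))
      }
      sign <- sample(c(-1, 1), length(chosen), replace = TRUE)
      sign[chosen %in% forced] <- 1
      data.frame(feature_id = chosen, sign = sign,
                 stringsAsFactors = FALSE)
    }
    de_e <- pick_de(enh_ids, n_de_e, planted$enhancer_id)
    de_g <- pick_de(gene_ids, n_de_g, planted$gene_id)

    ze <- matrix(stats::rnorm(length(enh_ids) * length(samples)),
                 length(enh_ids), dimnames = list(enh_ids, samples))
    zg <- matrix(stats::rnorm(length(gene_ids) * length(samples)),
                 length(gene_ids), dimnames = list(gene_ids, samples))
    if (nrow(planted)) {
      for (i in seq_len(nrow(planted))) {   # couple tumor samples only
        e <- planted$enhancer_id[i]; g <- planted$gene_id[i]
        zg[g, ts] <- r * ze[e, ts] + sqrt(1 - r^2) * stats::rnorm(length(ts))
      }
    }
    fill <- function(z, de, ids) {
      mu <- matrix(spec$meanlog, nrow(z), ncol(z), dimnames = dimnames(z))
      if (nrow(de)) {
        mu[de$feature_id, ts] <- spec$meanlog +
          de$sign * spec$log2fc * log(2)
      }
      v <- exp(mu + spec$sdlog * z)
      v[v < detect_limit] <- 0
      v
    }
    enh_m[, samples] <- fill(ze, de_e, enh_ids)[, samples]
    gene_m[, samples] <- fill(zg, de_g, gene_ids)[, samples]

    truth$de_enhancers[[co]] <- de_e
    truth$de_genes[[co]] <- de_g
    if (nrow(planted)) {
      planted$cohort <- co
      planted$rho <- spec$rho
      truth$linked_pairs <- rbind(
        truth$linked_pairs,
        planted[, c("cohort", "enhancer_id", "gene_id", "rho")])
    }
  }
  list(enhancer_expr = enh_m, gene_expr = gene_m, truth = truth)
}

pwm_consensus_info <- function(pwm) {
  S <- pwm_score_matrix(pwm)
  ic <- rowSums(pwm$probs * log2(sweep(pwm$probs, 2, pwm$background, `/`)))
  list(consensus = BASES[apply(pwm$probs, 1, which.max)],
       worst = BASES[apply(pwm$probs, 1, which.min)],
       top_info_pos = which.max(ic))
}

#' Demo motif library for the synthetic fixture
#'
#' Count matrices with an 8-position informative core (one strongly
#' preferred base per core position) padded to the requested lengths with
#' exactly uniform positions. The core concentration is chosen so that at
#' the default binding threshold (tail p <= 1e-4) the consensus is a
#' significant match while a single core mismatch is not - the regime in
#' which one SNP can create or destroy a binding site.
#'
#' @param lengths Motif lengths (>= 8). Default c(8, 10, 12).
#' @param seed Integer seed.
#' @return Named list of L x 4 count matrices.
#' @export
make_demo_pfms <- function(lengths = c(8, 10, 12), seed = 1) {
  if (any(lengths < 8)) stop("demo motifs need length >= 8")
  set.seed(seed)
  out <- lapply(seq_along(lengths), function(i) {
    L <- lengths[i]
    counts <- matrix(25, L, 4, dimnames = list(NULL, BASES))
    core <- sort(sample(seq_len(L), 8))
    pref <- sample(1:4, 8, replace = TRUE)
    for (j in seq_len(8)) {
      counts[core[j], ] <- 2
      counts[core[j], pref[j]] <- 94
    }
    counts
  })
  names(out) <- sprintf("TF%02d", seq_along(lengths))
  out
}

#' Generate enhancer sequences and motif-disrupting SNPs
#'
#' Builds an i.i.d.-background sequence for each used enhancer's extended
#' region and plants SNPs of three kinds. Loss: a motif consensus is
#' embedded and the SNP mutates its highest-information position to the
#' least-preferred base (ref binds, alt does not). Gain: the consensus with
#' that position pre-mutated is embedded and the alt allele restores it
#' (alt binds, ref does not). Neutral: the SNP sits at least one motif
#' length away from any embedded motif. Deterministic for a fixed seed.
#'
#' @param enhancers Enhancer data.frame (id, chrom, start, end).
#' @param pwms Named list of "pwm" objects.
#' @param n_disruptive Number of gain/loss SNPs (alternating, one per
#'   enhancer).
#' @param n_neutral Number of neutral SNPs.
#' @param seed Integer seed.
#' @param cfg A [pipeline_config()].
#' @return List: `sequences` (named character vector keyed by enhancer id,
#'   covering the extended region), `snps` (data.frame rs_id, chrom, pos,
#'   ref, alt, pos0), `truth` (data.frame rs_id, tf_name, expected in
#'   gain/loss/neutral, enhancer_id).
#' @export
generate_snps_and_sequences <- function(enhancers, pwms, n_disruptive = 6,
                                        n_neutral = 6, seed = 1,
                                        cfg = pipeline_config()) {
  set.seed(seed)
  if (n_disruptive > nrow(enhancers)) {
    stop("need at least one enhancer per disruptive SNP")
  }
  ext <- extend_enhancer(enhancers, cfg)
  widths <- ext$end - ext$start
  max_L <- max(vapply(pwms, pwm_length, 1L))
  if (any(widths < 3 * max_L)) {
    stop("motif longer than an enhancer window allows")
  }
  bg <- pwms[[1]]$background
  host <- sample(nrow(enhancers), n_disruptive)
  seq_ids <- enhancers$id[host]
  sequences <- stats::setNames(vapply(widths[host], function(w) {
    paste(sample(BASES, w, replace = TRUE, prob = bg), collapse = "")
  }, ""), seq_ids)

  snps <- list(); truth <- list(); motif_span <- list()
  for (i in seq_len(n_disruptive)) {
    eid <- seq_ids[i]
    pwm_i <- ((i - 1) %% length(pwms)) + 1
    pwm <- pwms[[pwm_i]]
    info <- pwm_consensus_info(pwm)
    L <- pwm_length(pwm)
    w <- nchar(sequences[[eid]])
    off <- sample((L + 1):(w - 2 * L), 1)   # clear of the edges
    kind <- if (i %% 2 == 1) "loss" else "gain"
    cons <- info$consensus
    pstar <- info$top_info_pos
    embedded <- cons
    if (kind == "gain") embedded[pstar] <- info$worst[pstar]
    s <- sequences[[eid]]
    substr(s, off, off + L - 1) <- paste(embedded, collapse = "")
    sequences[[eid]] <- s
    ref <- embedded[pstar]
    alt <- if (kind == "loss") info$worst[pstar] else cons[pstar]
    pos0 <- ext$start[host[i]] + off + pstar - 2   # 0-based genomic
    snps[[length(snps) + 1]] <- data.frame(
      rs_id = sprintf("rs%06d", i), chrom = enhancers$chrom[host[i]],
      pos = pos0 + 1, ref = ref, alt = alt, stringsAsFactors = FALSE)
    truth[[length(truth) + 1]] <- data.frame(
      rs_id = sprintf("rs%06d", i), tf_name = names(pwms)[pwm_i],
      expected = kind, enhancer_id = eid, stringsAsFactors = FALSE)
    motif_span[[eid]] <- c(off, off + L - 1)
  }
  for (j in seq_len(n_neutral)) {
    k <- ((j - 1) %% n_disruptive) + 1
    eid <- seq_ids[k]
    w <- nchar(sequences[[eid]])
    span <- motif_span[[eid]]
    ok <- setdiff(seq(max_L, w - max_L),
                  seq(max(1, span[1] - max_L), min(w, span[2] + max_L)))
    pos_in_seq <- sample(ok, 1)
    ref <- substr(sequences[[eid]], pos_in_seq, pos_in_seq)
    alt <- sample(setdiff(BASES, ref), 1)
    pos0 <- ext$start[match(eid, enhancers$id)] + pos_in_seq - 1
    rs <- sprintf("rs%06d", n_disruptive + j)
    snps[[length(snps) + 1]] <- data.frame(
      rs_id = rs, chrom = enhancers$chrom[match(eid, enhancers$id)],
      pos = pos0 + 1, ref = ref, alt = alt, stringsAsFactors = FALSE)
    truth[[length(truth) + 1]] <- data.frame(
      rs_id = rs, tf_name = NA_character_, expected = "neutral",
      enhancer_id = eid, stringsAsFactors = FALSE)
  }
  snps <- do.call(rbind, snps)
  snps$pos0 <- snps$pos - 1
  list(sequences = sequences, snps = snps, truth = do.call(rbind, truth))
}

#' Generate gene sets with one planted enriched set
#'
#' The planted set draws most of its members from `enriched_genes` (the
#' genes the query of interest will contain); decoy sets are uniform draws
#' from the universe.
#'
#' @param universe Character vector of gene ids.
#' @param enriched_genes Genes over-represented in the planted set.
#' @param n_sets Total number of sets (>= 1). Default 10.
#' @param set_size Members per set. Default 40.
#' @param planted_fraction Fraction of the planted set drawn from
#'   `enriched_genes`. Default 0.5.
#' @param seed Integer seed.
#' @return List: `sets` (named list), `enriched_set_name`.
#' @export
generate_gene_sets <- function(universe, enriched_genes, n_sets = 10,
                               set_size = 40, planted_fraction = 0.5,
                               seed = 1) {
  set.seed(seed)
  enriched_genes <- intersect(enriched_genes, universe)
  if (!length(enriched_genes)) stop("no enriched genes inside the universe")
  n_from <- min(length(enriched_genes), round(planted_fraction * set_size))
  planted <- unique(c(sample(enriched_genes, n_from),
                      sample(setdiff(universe, enriched_genes),
                             set_size - n_from)))
  sets <- c(list(planted),
            lapply(seq_len(n_sets - 1), function(i) sample(universe, set_size)))
  names(sets) <- c("planted_set", sprintf("decoy_set%02d", seq_len(n_sets - 1)))
  list(sets = sets, enriched_set_name = "planted_set")
}

#' Generate a complete synthetic dataset
#'
#' One call producing every input the pipeline consumes, with ground truth:
#' layout, sample sheet (13 paired tumor/normal cohorts by default),
#' expression matrices with planted DE features and links, enhancer
#' sequences with planted gain/loss/neutral SNPs, a demo motif library, and
#' gene sets with one planted enriched set.
#'
#' @param n_cohorts,n_tumor,n_normal Cohort design. Defaults 13, 50, 50.
#' @param n_genes,n_enhancers Feature counts. Defaults 400 and 200.
#' @param spec A [truth_spec()].
#' @param seed Integer seed driving every stage.
#' @param cfg A [pipeline_config()].
#' @param n_disruptive,n_neutral SNP counts. Defaults 6 and 6.
#' @return List: genes, enhancers, sheet, enhancer_expr, gene_expr, pfms,
#'   pwms, sequences, snps, gene_sets, truth (de/link truth plus snp truth
#'   and enriched_set_name).
#' @export
simulate_dataset <- function(n_cohorts = 13, n_tumor = 50, n_normal = 50,
                             n_genes = 400, n_enhancers = 200,
                             spec = truth_spec(), seed = 1,
                             cfg = pipeline_config(),
                             n_disruptive = 6, n_neutral = 6) {
  layout <- generate_layout(n_genes, n_enhancers, seed = seed, cfg = cfg)
  sheet <- generate_sample_sheet(n_cohorts, n_tumor, n_normal)
  expr <- generate_expression(layout, sheet, spec, seed = seed + 1, cfg = cfg)
  pfms <- make_demo_pfms(seed = seed + 2)
  pwms <- pfms_to_pwms(pfms)
  snpgen <- generate_snps_and_sequences(layout$enhancers, pwms,
                                        n_disruptive, n_neutral,
                                        seed = seed + 3, cfg = cfg)
  linked_genes <- unique(expr$truth$linked_pairs$gene_id)
  gs <- generate_gene_sets(layout$genes$id, linked_genes, seed = seed + 4)
  truth <- expr$truth
  truth$snps <- snpgen$truth
  truth$enriched_set_name <- gs$enriched_set_name
  list(genes = layout$genes, enhancers = layout$enhancers, sheet = sheet,
       enhancer_expr = expr$enhancer_expr, gene_expr = expr$gene_expr,
       pfms = pfms, pwms = pwms, sequences = snpgen$sequences,
       snps = snpgen$snps, gene_sets = gs$sets, truth = truth)
}

#' Write a synthetic dataset to a directory of pipeline inputs
#'
#' Emits the same formats the readers consume (BED, expression TSVs, sample
#' sheet, gene table, SNP table, PFM, GMT, FASTA) plus `truth.json` and a
#' ready-to-run `config.txt` for [run_pipeline()].
#'
#' @param ds Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_enhancer_bed(ds$enhancers, p("enhancers.bed"))
  write_expression_tsv(ds$enhancer_expr, p("enhancer_expression.tsv"))
  write_expression_tsv(ds$gene_expr, p("gene_expression.tsv"))
  write_sample_sheet(ds$sheet, p("sample_sheet.tsv"))
  write_gene_table(ds$genes, p("genes.tsv"))
  write_snp_table(ds$snps, p("snps.tsv"))
  write_pfm(ds$pfms, p("motifs.pfm"))
  write_gmt(ds$gene_sets, p("gene_sets.gmt"))
  write_fasta(ds$sequences, p("enhancer_sequences.fa"))
  jsonlite::write_json(ds$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  writeLines(c(
    sprintf("enhancer_bed = %s", p("enhancers.bed")),
    sprintf("enhancer_expression = %s", p("enhancer_expression.tsv")),
    sprintf("gene_expression = %s", p("gene_expression.tsv")),
    sprintf("sample_sheet = %s", p("sample_sheet.tsv")),
    sprintf("gene_table = %s", p("genes.tsv")),
    sprintf("snp_table = %s", p("snps.tsv")),
    sprintf("pfm = %s", p("motifs.pfm")),
    sprintf("gmt = %s", p("gene_sets.gmt")),
    sprintf("fasta = %s", p("enhancer_sequences.fa"))
  ), p("config.txt"))
  invisible(dir)
}
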