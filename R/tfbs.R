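# Allele-specific TFBS scoring. SNPs are mapped into DE enhancers extended
# by snp_flank on each side; for each SNP x motif, the best log-odds score
# over every window (both strands) overlapping the SNP is computed under
# the ref and the alt allele, each converted to an exact background tail
# probability via a discretized convolution of the per-column score
# distributions. A motif is "bound" when that tail probability is at or
# below tfbs_p_max; gain/loss means the bound call flips between alleles.

BASES <- c("A", "C", "G", "T")

#' Convert a position frequency matrix to a position weight matrix
#'
#' Counts plus a total pseudocount distributed by the background
#' composition, normalized per position: probs[i, j] =
#' (counts[i, j] + pc * bg[j]) / (sum_j counts[i, j] + pc).
#'
#' @param counts L x 4 count matrix (columns A, C, G, T).
#' @param tf_name Transcription-factor name.
#' @param background Base composition, sums to 1. Default uniform.
#' @param pseudocount Total pseudocount per position. Default 0.8.
#' @return List of class "pwm": tf_name, probs (L x 4), background.
#' @export
pfm_to_pwm <- function(counts, tf_name = "TF",
                       background = rep(0.25, 4), pseudocount = 0.8) {
  if (ncol(counts) != 4 || nrow(counts) < 1) stop("counts must be L x 4, L >= 1")
  if (abs(sum(background) - 1) > 1e-6 || any(background <= 0)) {
    stop("background must be positive and sum to 1")
  }
  probs <- sweep(counts, 2, pseudocount * background, `+`)
  probs <- probs / rowSums(probs)
  if (any(abs(rowSums(probs) - 1) > 1e-6)) stop("PWM rows failed to normalize")
  colnames(probs) <- BASES
  names(background) <- BASES
  structure(list(tf_name = tf_name, probs = unname(probs) ,
                 background = background),
            class = "pwm")
}

#' Convert a list of PFMs to PWMs
#' @param pfms Named list of count matrices ([read_pfm()]).
#' @inheritParams pfm_to_pwm
#' @return Named list of "pwm" objects.
#' @export
pfms_to_pwms <- function(pfms, background = rep(0.25, 4), pseudocount = 0.8) {
  out <- lapply(names(pfms), function(nm) {
    pfm_to_pwm(pfms[[nm]], tf_name = nm, background = background,
               pseudocount = pseudocount)
  })
  names(out) <- names(pfms)
  out
}

pwm_length <- function(pwm) nrow(pwm$probs)

# L x 4 matrix of per-position log2 odds.
pwm_score_matrix <- function(pwm) {
  log2(sweep(pwm$probs, 2, pwm$background, `/`))
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""),
                "", USE.NAMES = FALSE))
}

#' PWM log-odds score of one sequence window
#'
#' Sum over positions of log2(probs[i, base_i] / background[base_i]) for a
#' window whose length equals the motif length. Windows containing
#' ambiguous bases return NA (skipped by callers).
#'
#' @param pwm A "pwm" object.
#' @param window Character string of length == motif length.
#' @return Numeric score in bits, or NA for ambiguous bases.
#' @export
pwm_log_odds <- function(pwm, window) {
  L <- pwm_length(pwm)
  if (nchar(window) != L) stop("window length must equal motif length")
  idx <- match(strsplit(toupper(window), "")[[1]], BASES)
  if (anyNA(idx)) return(NA_real_)
  S <- pwm_score_matrix(pwm)
  sum(S[cbind(seq_len(L), idx)])
}

#' Exact null distribution of a single-window PWM score
#'
#' The distribution of the log-odds score of one window drawn i.i.d. from
#' the background composition, computed by convolving the per-position
#' 4-point score distributions on a fixed grid (default granularity 1e-3
#' bits). Returned with a monotone tail-probability accessor via
#' [tail_prob()].
#'
#' @param pwm A "pwm" object of length <= 30.
#' @param granularity Score grid step in bits. Default 1e-3.
#' @return List of class "pwm_null": score (sorted grid values with
#'   positive mass), prob, granularity.
#' @export
score_null_distribution <- function(pwm, granularity = 1e-3) {
  L <- pwm_length(pwm)
  if (L > 30) stop("motif length > 30 unsupported for the exact null")
  S <- pwm_score_matrix(pwm)
  G <- round(S / granularity)                    # integer grid, L x 4
  span <- sum(apply(G, 1, max) - apply(G, 1, min))
  if (span > 5e7) stop("score grid too large; use a coarser granularity")
  offset <- sum(apply(G, 1, min))                # grid value of the minimum
  dist <- 1
  for (i in seq_len(L)) {
    gi <- G[i, ] - min(G[i, ])
    width <- max(gi)
    new <- numeric(length(dist) + width)
    for (j in 1:4) {
      sh <- gi[j]
      new[(sh + 1):(sh + length(dist))] <-
        new[(sh + 1):(sh + length(dist))] + dist * pwm$background[j]
    }
    dist <- new
  }
  if (abs(sum(dist) - 1) > 1e-9) stop("probability mass not conserved")
  pos <- which(dist > 0)
  structure(list(score = (offset + pos - 1) * granularity,
                 prob = dist[pos],
                 granularity = granularity,
                 L = L),
            class = "pwm_null")
}

#' Background tail probability of a score
#'
#' P(single-window score >= s) under the background model, evaluated
#' against the discretized exact distribution. Because each of the L
#' per-position scores is rounded to the grid independently, an exact
#' window score can sit up to L * granularity / 2 away from its own grid
#' mass; scores within that accumulated tolerance are counted in the tail
#' (the conservative direction for binding calls).
#'
#' @param null A "pwm_null" from [score_null_distribution()].
#' @param s Score(s) in bits.
#' @return Tail probabilities, monotone non-increasing in s.
#' @export
tail_prob <- function(null, s) {
  cum <- rev(cumsum(rev(null$prob)))   # P(score >= score[i])
  tol <- null$L * null$granularity / 2 + 1e-12
  vapply(s, function(si) {
    i <- which(null$score >= si - tol)
    if (!length(i)) 0 else cum[i[1]]
  }, numeric(1))
}

#' Map SNPs into extended enhancer regions
#'
#' A SNP maps to an enhancer when its 0-based position lies inside the
#' half-open extended interval [start - snp_flank, end + snp_flank). A SNP
#' overlapping several extended enhancers yields one row per enhancer.
#' When both inputs carry an `assembly` attribute the tags must agree
#' (coordinate lifting between assemblies is out of scope).
#'
#' @param snps SNP data.frame ([read_snp_table()]).
#' @param enhancers Enhancer data.frame (id, chrom, start, end).
#' @param cfg A [pipeline_config()].
#' @return data.frame: rs_id, enhancer_id, chrom, pos, pos0, ref, alt.
#' @export
map_snps <- function(snps, enhancers, cfg = pipeline_config()) {
  a1 <- attr(snps, "assembly"); a2 <- attr(enhancers, "assembly")
  if (!is.null(a1) && !is.null(a2) && !identical(a1, a2)) {
    stop("assembly mismatch between SNPs (", a1, ") and enhancers (", a2,
         "); all coordinates must share one assembly")
  }
  ext <- extend_enhancer(enhancers, cfg)
  snp_gr <- GenomicRanges::GRanges(snps$chrom,
                                   IRanges::IRanges(snps$pos0 + 1, width = 1))
  hits <- GenomicRanges::findOverlaps(snp_gr, as_granges0(ext))
  si <- S4Vectors::queryHits(hits)
  ei <- S4Vectors::subjectHits(hits)
  out <- data.frame(rs_id = snps$rs_id[si],
                    enhancer_id = enhancers$id[ei],
                    chrom = snps$chrom[si],
                    pos = snps$pos[si],
                    pos0 = snps$pos0[si],
                    ref = snps$ref[si],
                    alt = snps$alt[si],
                    stringsAsFactors = FALSE)
  out <- out[order(out$rs_id, out$enhancer_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Best score over all windows of length L overlapping position idx (1-based
# within seq), both strands. Returns -Inf when no window fits.
best_overlapping_score <- function(pwm, seq, idx) {
  L <- pwm_length(pwm)
  n <- nchar(seq)
  offs <- max(1, idx - L + 1):min(idx, n - L + 1)
  offs <- offs[offs >= 1 & offs <= n - L + 1]
  if (!length(offs)) return(-Inf)
  best <- -Inf
  for (o in offs) {
    w <- substr(seq, o, o + L - 1)
    s1 <- pwm_log_odds(pwm, w)
    s2 <- pwm_log_odds(pwm, revcomp(w))
    best <- max(best, s1, s2, na.rm = TRUE)
  }
  best
}

#' Classify allele-specific TFBS gain/loss for one mapped SNP
#'
#' For each motif, finds the best-scoring window overlapping the SNP under
#' the reference and the alternate allele (all offsets, both strands),
#' converts both scores to background tail probabilities, and classifies:
#' gain when only the alt allele is bound (alt_p <= tfbs_p_max < ref_p),
#' loss when only the ref allele is bound, unchanged otherwise. The
#' supplied sequence must cover the extended enhancer and carry the ref
#' allele at the SNP position.
#'
#' @param snp One row of [map_snps()] output.
#' @param seq Extended-enhancer sequence (character string).
#' @param seq_start0 0-based genomic start of `seq`.
#' @param pwms Named list of "pwm" objects.
#' @param cfg A [pipeline_config()].
#' @param nulls Optional named list of precomputed "pwm_null" objects.
#' @return data.frame: rs_id, tf_name, enhancer_id, ref_best, alt_best,
#'   delta, ref_p, alt_p, classification.
#' @export
classify_snp <- function(snp, seq, seq_start0, pwms,
                         cfg = pipeline_config(), nulls = NULL) {
  idx <- snp$pos0 - seq_start0 + 1
  if (idx < 1 || idx > nchar(seq)) {
    stop("SNP ", snp$rs_id, " falls outside the supplied sequence")
  }
  have <- substr(seq, idx, idx)
  if (have != snp$ref) {
    stop("reference allele mismatch for ", snp$rs_id, ": sequence has ",
         have, ", SNP table says ", snp$ref)
  }
  alt_seq <- seq
  substr(alt_seq, idx, idx) <- snp$alt
  if (is.null(nulls)) nulls <- lapply(pwms, score_null_distribution)
  rows <- lapply(names(pwms), function(nm) {
    pwm <- pwms[[nm]]
    ref_best <- best_overlapping_score(pwm, seq, idx)
    alt_best <- best_overlapping_score(pwm, alt_seq, idx)
    if (!is.finite(ref_best) && !is.finite(alt_best)) {
      return(data.frame(rs_id = snp$rs_id, tf_name = nm,
                        enhancer_id = snp$enhancer_id,
                        ref_best = NA_real_, alt_best = NA_real_, delta = 0,
                        ref_p = 1, alt_p = 1, classification = "unchanged",
                        stringsAsFactors = FALSE))
    }
    ref_p <- tail_prob(nulls[[nm]], ref_best)
    alt_p <- tail_prob(nulls[[nm]], alt_best)
    cls <- if (alt_p <= cfg$tfbs_p_max && ref_p > cfg$tfbs_p_max) "gain"
           else if (ref_p <= cfg$tfbs_p_max && alt_p > cfg$tfbs_p_max) "loss"
           else "unchanged"
    data.frame(rs_id = snp$rs_id, tf_name = nm,
               enhancer_id = snp$enhancer_id,
               ref_best = ref_best, alt_best = alt_best,
               delta = alt_best - ref_best,
               ref_p = ref_p, alt_p = alt_p, classification = cls,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify all mapped SNPs against a motif library
#'
#' @param mapped data.frame from [map_snps()].
#' @param seqs Named character vector of extended-enhancer sequences keyed
#'   by enhancer id; enhancers without a sequence are skipped with a
#'   message.
#' @param enhancers Enhancer data.frame used to recover each extended
#'   region's genomic start.
#' @param pwms Named list of "pwm" objects.
#' @param cfg A [pipeline_config()].
#' @return data.frame of stacked [classify_snp()] events.
#' @export
classify_snps <- function(mapped, seqs, enhancers, pwms,
                          cfg = pipeline_config()) {
  nulls <- lapply(pwms, score_null_distribution)
  ext <- extend_enhancer(enhancers, cfg)
  start0 <- stats::setNames(ext$start, enhancers$id)
  have <- mapped$enhancer_id %in% names(seqs)
  if (any(!have)) {
    message(sum(!have), " mapped SNP(s) skipped: no sequence for enhancer")
  }
  mapped <- mapped[have, , drop = FALSE]
  rows <- lapply(seq_len(nrow(mapped)), function(i) {
    snp <- mapped[i, ]
    classify_snp(snp, seqs[[snp$enhancer_id]], start0[[snp$enhancer_id]],
                 pwms, cfg, nulls = nulls)
  })
  if (!length(rows)) {
    return(data.frame(rs_id = character(), tf_name = character(),
                      enhancer_id = character(), ref_best = numeric(),
                      alt_best = numeric(), delta = numeric(),
                      ref_p = numeric(), alt_p = numeric(),
                      classification = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Summarize TFBS gain/loss events
#'
#' Counts of distinct TFs with a gain or loss per SNP and per enhancer,
#' plus the overall number of distinct affected TFs.
#'
#' @param events data.frame from [classify_snps()].
#' @return List: per_snp, per_enhancer (data.frames with n_tfs_affected),
#'   n_tfs_overall.
#' @export
summarize_events <- function(events) {
  hit <- events[events$classification %in% c("gain", "loss"), , drop = FALSE]
  count_by <- function(key) {
    if (!nrow(hit)) {
      return(data.frame(key = character(), n_tfs_affected = integer(),
                        stringsAsFactors = FALSE))
    }
    tab <- tapply(hit$tf_name, hit[[key]], function(x) length(unique(x)))
    data.frame(key = names(tab), n_tfs_affected = as.integer(tab),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  per_snp <- count_by("rs_id"); names(per_snp)[1] <- "rs_id"
  per_enh <- count_by("enhancer_id"); names(per_enh)[1] <- "enhancer_id"
  list(per_snp = per_snp, per_enhancer = per_enh,
       n_tfs_overall = length(unique(hit$tf_name)))
}

#' Per-cohort enhancer-SNP proportions
#'
#' Given each enhancer SNP's cohort assignment, the share of distinct SNPs
#' per cohort as a percentage of all distinct SNPs (rounded half-up to one
#' decimal, the convention of the published summary tables).
#'
#' @param snp_cohorts data.frame with columns rs_id and cohort.
#' @return data.frame: cohort, n_snps, proportion, percentage; percentages
#'   are computed against the total number of distinct SNPs.
#' @export
cohort_snp_proportions <- function(snp_cohorts) {
  if (!nrow(snp_cohorts)) stop("no enhancer SNPs to tabulate")
  u <- unique(snp_cohorts[, c("rs_id", "cohort")])
  total <- length(unique(u$rs_id))
  tab <- tapply(u$rs_id, u$cohort, function(x) length(unique(x)))
  out <- data.frame(cohort = names(tab), n_snps = as.integer(tab),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$proportion <- out$n_snps / total
  out$percentage <- round_half_up(100 * out$proportion, 1)
  out[order(-out$n_snps, out$cohort), , drop = FALSE]
}
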