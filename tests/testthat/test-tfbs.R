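toy_pwm <- function(counts_list, name = "toy") {
  counts <- do.call(rbind, counts_list)
  colnames(counts) <- c("A", "C", "G", "T")
  pfm_to_pwm(counts, name)
}

test_that("SNP mapping matches the quadratic oracle and enforces assemblies", {
  cfg <- fixture_cfg
  set.seed(19)
  n <- 1000
  enh <- data.frame(id = sprintf("e%03d", 1:60),
                    chrom = sample(c("chr1", "chr2"), 60, replace = TRUE),
                    start = sample.int(2e5, 60))
  enh$end <- enh$start + 1500
  snps <- data.frame(rs_id = sprintf("rs%04d", 1:n),
                     chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                     pos = sample.int(2e5 + 2000, n),
                     ref = "A", alt = "C")
  snps$pos0 <- snps$pos - 1
  got <- map_snps(snps, enh, cfg)
  got_keys <- sort(paste(got$rs_id, got$enhancer_id, sep = "|"))
  expect_gt(length(got_keys), 0)
  expect_equal(got_keys, map_snps_oracle(snps, enh, cfg))

  # half-open boundaries of the extended region
  e1 <- data.frame(id = "e1", chrom = "chr1", start = 1000, end = 2000)
  s <- data.frame(rs_id = c("in_left", "out_right"), chrom = "chr1",
                  pos = c(501, 2501), ref = "A", alt = "C")
  s$pos0 <- s$pos - 1
  expect_equal(map_snps(s, e1, cfg)$rs_id, "in_left")

  attr(snps, "assembly") <- "GRCh38"
  attr(enh, "assembly") <- "hg19"
  expect_error(map_snps(snps, enh, cfg), "assembly mismatch")
})

test_that("PWM log-odds scoring is exact on consensus, uniform and scanned windows", {
  pwm <- toy_pwm(list(c(10, 0, 0, 0), c(0, 10, 0, 0), c(0, 0, 0, 10)))
  S <- log2(sweep(pwm$probs, 2, pwm$background, "/"))
  expect_equal(pwm_log_odds(pwm, "ACT"), sum(apply(S, 1, max)))
  # PWM equal to background scores 0 on every window
  unif <- toy_pwm(list(c(5, 5, 5, 5), c(5, 5, 5, 5)))
  for (w in c("AA", "CG", "TT", "GA")) {
    expect_equal(pwm_log_odds(unif, w), 0)
  }
  expect_true(is.na(pwm_log_odds(pwm, "ANT")))
  expect_error(pwm_log_odds(pwm, "ACGT"), "length")
  # best placement over offsets and strands matches an exhaustive scan
  seq6 <- "ACTAGT"
  best <- -Inf
  for (o in 1:4) {
    w <- substr(seq6, o, o + 2)
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(w, "")[[1]]), collapse = ""))
    best <- max(best, pwm_log_odds(pwm, w), pwm_log_odds(pwm, rc))
  }
  got <- enhancerDE:::best_overlapping_score(pwm, seq6, 4)
  scan4 <- max(vapply(2:4, function(o) {
    w <- substr(seq6, o, o + 2)
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(w, "")[[1]]), collapse = ""))
    max(pwm_log_odds(pwm, w), pwm_log_odds(pwm, rc))
  }, numeric(1)))
  expect_equal(got, scan4)
  expect_lte(got, best)
})

test_that("the discretized score null equals exhaustive 4^L enumeration", {
  set.seed(37)
  pwms <- c(pfms_to_pwms(make_demo_pfms(lengths = 8, seed = 2)),
            list(short = toy_pwm(list(c(8, 1, 1, 0), c(1, 1, 4, 4),
                                      c(0, 0, 10, 0), c(2, 3, 3, 2)))))
  for (pwm in pwms) {
    null <- score_null_distribution(pwm)
    expect_equal(sum(null$prob), 1, tolerance = 1e-9)
    # tails compared at scores spanning the support
    probe <- quantile(null$score, c(0, 0.25, 0.5, 0.9, 0.99, 1))
    oracle <- pwm_tail_oracle(pwm, probe)
    got <- tail_prob(null, probe)
    L <- nrow(pwm$probs)
    for (i in seq_along(probe)) {
      # grid tolerance: scores within L*granularity/2 of a mass point may
      # land on either side in the oracle
      lo <- pwm_tail_oracle(pwm, probe[i] + L * null$granularity)
      hi <- pwm_tail_oracle(pwm, probe[i] - L * null$granularity)
      expect_gte(got[i] + 1e-12, lo)
      expect_lte(got[i] - 1e-12, hi)
    }
    # monotone non-increasing tail
    expect_true(all(diff(tail_prob(null, sort(null$score))) <= 1e-12))
  }
  # length-1 PWM: the four weighted column scores
  p1 <- toy_pwm(list(c(6, 2, 1, 1)))
  null1 <- score_null_distribution(p1)
  col_scores <- round(log2(p1$probs[1, ] / 0.25), 3)
  expect_equal(sort(null1$score), sort(unique(col_scores)),
               tolerance = 1e-9, ignore_attr = TRUE)
  # mass at each support point aggregates the bases sharing that score
  for (i in seq_along(null1$score)) {
    expect_equal(null1$prob[i],
                 sum(0.25 * (abs(col_scores - null1$score[i]) < 1e-9)))
  }
})

test_that("allele swap exchanges gain and loss; distant SNPs are unchanged", {
  cfg <- fixture_cfg
  pwms <- pfms_to_pwms(make_demo_pfms(lengths = 8, seed = 4))
  enh <- data.frame(id = "e1", chrom = "chr1", start = 2000, end = 2400)
  gen <- generate_snps_and_sequences(enh, pwms, n_disruptive = 1,
                                     n_neutral = 0, seed = 6, cfg = cfg)
  snp <- map_snps(gen$snps, enh, cfg)
  ev <- classify_snps(snp, gen$sequences, enh, pwms, cfg)
  expect_equal(ev$classification, gen$truth$expected)
  # swap ref/alt (with the sequence carrying the other allele)
  seq2 <- gen$sequences
  idx <- snp$pos0 - (enh$start - cfg$snp_flank) + 1
  substr(seq2[[1]], idx, idx) <- snp$alt
  snp2 <- snp; snp2$ref <- snp$alt; snp2$alt <- snp$ref
  ev2 <- classify_snps(snp2, seq2, enh, pwms, cfg)
  flip <- c(gain = "loss", loss = "gain", unchanged = "unchanged")
  expect_equal(unname(flip[ev$classification]), ev2$classification)
  expect_equal(ev2$delta, -ev$delta)
  # a ref-mismatching table is an error naming the SNP
  snp3 <- snp; snp3$ref <- setdiff(c("A", "C", "G", "T"),
                                   c(snp$ref, snp$alt))[1]
  expect_error(classify_snps(snp3, gen$sequences, enh, pwms, cfg),
               snp$rs_id[1])
  # SNP with no overlapping window on a tiny sequence: unchanged, delta 0
  tiny_enh <- data.frame(id = "t1", chrom = "chr1", start = 0, end = 4)
  cfg0 <- fixture_cfg; cfg0$snp_flank <- 0L
  tiny_snp <- data.frame(rs_id = "rs_t", enhancer_id = "t1", chrom = "chr1",
                         pos = 1, pos0 = 0, ref = "A", alt = "C")
  ev3 <- classify_snps(tiny_snp, c(t1 = "ACGT"), tiny_enh, pwms, cfg0)
  expect_equal(unique(ev3$classification), "unchanged")
  expect_equal(unique(ev3$delta), 0)
})

test_that("planted gain/loss SNPs are recovered and neutral SNPs stay quiet", {
  cfg <- fixture_cfg
  ds <- fixture_dataset()
  mapped <- map_snps(ds$snps, ds$enhancers, cfg)
  ev <- classify_snps(mapped, ds$sequences, ds$enhancers, ds$pwms, cfg)
  m <- merge(ev, ds$truth$snps, by = "rs_id")
  planted <- m[m$expected %in% c("gain", "loss") & m$tf_name.x == m$tf_name.y, ]
  expect_equal(nrow(planted), 6)
  expect_gte(mean(planted$classification == planted$expected), 0.9)
  neutral <- m[m$expected == "neutral", ]
  expect_lte(mean(neutral$classification != "unchanged"), 0.1)
})

test_that("event summaries count distinct TFs and normalize cohort proportions", {
  ev <- data.frame(
    rs_id = c("rs1", "rs1", "rs1", "rs2", "rs2"),
    tf_name = c("TFA", "TFB", "TFC", "TFA", "TFA"),
    enhancer_id = c("e1", "e1", "e1", "e2", "e2"),
    classification = c("gain", "gain", "loss", "loss", "unchanged"))
  s <- summarize_events(ev)
  expect_equal(s$per_snp$n_tfs_affected[s$per_snp$rs_id == "rs1"], 3)
  expect_equal(s$per_snp$n_tfs_affected[s$per_snp$rs_id == "rs2"], 1)
  expect_equal(s$n_tfs_overall, 3)
  s0 <- summarize_events(ev[ev$classification == "unchanged", ])
  expect_equal(nrow(s0$per_snp), 0)
  expect_equal(s0$n_tfs_overall, 0)

  sc <- data.frame(rs_id = c(sprintf("k%02d", 1:21), sprintf("o%02d", 1:53)),
                   cohort = c(rep("KIRC", 21), rep(c("BRCA", "LUAD"), c(30, 23))))
  props <- cohort_snp_proportions(sc)
  expect_equal(sum(props$n_snps), 74)
  expect_equal(props$percentage[props$cohort == "KIRC"], 28.4)
  expect_equal(sum(props$proportion), 1, tolerance = 1e-9)
})
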