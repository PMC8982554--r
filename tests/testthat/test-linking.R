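test_that("candidate pairs match the quadratic oracle on random layouts", {
  cfg <- fixture_cfg
  set.seed(3)
  n <- 200
  enh <- data.frame(id = sprintf("e%03d", 1:n),
                    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                    start = sample.int(3e6, n))
  enh$end <- enh$start + 400
  genes <- data.frame(id = sprintf("g%03d", 1:n),
                      symbol = sprintf("G%03d", 1:n),
                      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                      tss = sample.int(3e6, n),
                      strand = sample(c("+", "-"), n, replace = TRUE))
  got <- candidate_pairs(enh, genes$id, genes, cfg)
  want <- candidate_pairs_oracle(enh, genes$id, genes, cfg)
  expect_gt(nrow(want), 0)       # layout dense enough to be informative
  expect_equal(got, want)
})

test_that("candidate pairs respect half-open abutment and warn on missing annotation", {
  cfg <- fixture_cfg
  enh <- data.frame(id = "e1", chrom = "chr1", start = 1e6, end = 1e6 + 1000)
  center <- 1e6 + 500
  # "+"-strand promoter [tss-500, tss+1000); abut the window end exactly
  tss_abut <- center + cfg$link_window + 500
  genes <- data.frame(id = c("inside", "abut"), symbol = c("I", "A"),
                      chrom = "chr1", tss = c(center + 1000, tss_abut),
                      strand = "+")
  got <- candidate_pairs(enh, genes$id, genes, cfg)
  expect_equal(got$gene_id, "inside")
  expect_warning(candidate_pairs(enh, c("inside", "ghost"), genes, cfg),
                 "without annotation")
})

test_that("Spearman rho is rank-based, bounded, and monotone-invariant", {
  set.seed(9)
  x <- rnorm(30)
  y <- exp(x) + 0          # strictly monotone in x
  expect_equal(spearman_test(x, y)$rho, 1)
  expect_equal(spearman_test(x, -y)$rho, -1)
  z <- rnorm(30)
  a <- spearman_test(x, z)
  expect_equal(spearman_test(rank(x), rank(z))$rho, a$rho)
  expect_equal(spearman_test(exp(x), z)$rho, a$rho)    # monotone transform
  expect_true(abs(a$rho) <= 1)
  d <- spearman_test(rep(2, 10), rnorm(10))
  expect_true(is.na(d$rho))                            # degenerate ranks
  expect_error(spearman_test(1:3, 1:3), "n >= 4")
})

test_that("small-sample Spearman p equals the exhaustive permutation null, ties included", {
  set.seed(21)
  cases <- list(
    c(1.2, 0.4, 2.2, 1.9, 0.1),
    c(3, 1, 1, 2, 5),            # one tie
    rnorm(6),
    c(0, 0, 1, 2, 3, 3)          # ties in both tails
  )
  for (x in cases) {
    y <- rnorm(length(x))
    got <- spearman_test(x, y)
    expect_equal(got$method, "exact")
    expect_equal(got$p, spearman_perm_oracle(x, y), tolerance = 1e-12)
  }
  # large-n t approximation agrees with the classical formula
  set.seed(22)
  x <- rnorm(40); y <- rnorm(40)
  got <- spearman_test(x, y)
  rho <- cor(x, y, method = "spearman")
  tt <- rho * sqrt(38 / (1 - rho^2))
  expect_equal(got$p, 2 * pt(-abs(tt), 38))
})

test_that("link screen applies the one-sided corr and q gates per cohort", {
  cfg <- fixture_cfg
  ds <- fixture_dataset()
  co <- "cohort01"
  de_e <- ds$truth$de_enhancers[[co]]$feature_id
  de_g <- ds$truth$de_genes[[co]]$feature_id
  cand <- candidate_pairs(ds$enhancers[ds$enhancers$id %in% de_e, ],
                          de_g, ds$genes, cfg)
  links <- link_targets(cand, ds$enhancer_expr, ds$gene_expr, ds$sheet, co, cfg)
  expect_true(all(links$linked == (links$rho >= cfg$corr_min &
                                     links$q < cfg$link_q_max)))
  expect_true(all(links$rho >= -1 & links$rho <= 1))
  # a pair below the corr threshold is not linked no matter how small q is
  if (any(links$rho < cfg$corr_min)) {
    expect_false(any(links$linked[links$rho < cfg$corr_min]))
  }
  # planted pairs show strong positive correlation
  pl <- ds$truth$linked_pairs
  pl <- pl[pl$cohort == co, ]
  planted_rows <- merge(links, pl, by = c("enhancer_id", "gene_id"))
  expect_gt(nrow(planted_rows), 0)
  expect_gt(mean(planted_rows$rho.x), 0.4)
  expect_true(all(planted_rows$rho.x > 0))
})

test_that("regulated/nonregulated partition conserves the DE enhancer set", {
  links <- data.frame(enhancer_id = c("e1", "e2", "e3"),
                      linked = c(TRUE, FALSE, TRUE))
  de <- c("e1", "e2", "e3", "e4")
  p <- partition_regulated(de, links)
  expect_setequal(p$regulated, c("e1", "e3"))
  expect_setequal(p$nonregulated, c("e2", "e4"))
  expect_length(intersect(p$regulated, p$nonregulated), 0)
  expect_setequal(c(p$regulated, p$nonregulated), de)
  expect_length(partition_regulated(de, links[links$linked == FALSE, ])$regulated, 0)
  p0 <- partition_regulated(de, data.frame(enhancer_id = character(),
                                           linked = logical()))
  expect_length(p0$regulated, 0)
  expect_setequal(p0$nonregulated, de)
})

test_that("regulated-vs-nonregulated comparison detects a planted shift and stays level under the null", {
  sheet <- data.frame(sample_id = sprintf("T%02d", 1:10), tissue = "c",
                      condition = "tumor")
  set.seed(41)
  # power: regulated shifted +1 log-unit
  reject <- replicate(200, {
    m <- rbind(matrix(rlnorm(50 * 10, 1.5), 50),
               matrix(rlnorm(50 * 10, 0.5), 50))
    rownames(m) <- sprintf("e%03d", 1:100); colnames(m) <- sheet$sample_id
    compare_regulated_vs_nonregulated(m, rownames(m)[1:50], rownames(m)[51:100],
                                      sheet, "c")$p < 0.05
  })
  expect_gte(mean(reject), 0.9)
  # identical distributions: approximately nominal rejection
  null_reject <- replicate(1000, {
    m <- matrix(rlnorm(40 * 10, 1), 40)
    rownames(m) <- sprintf("e%03d", 1:40); colnames(m) <- sheet$sample_id
    compare_regulated_vs_nonregulated(m, rownames(m)[1:20], rownames(m)[21:40],
                                      sheet, "c")$p < 0.05
  })
  expect_equal(mean(null_reject), 0.05, tolerance = 0.4)
  expect_error(compare_regulated_vs_nonregulated(
    matrix(1, 1, 10, dimnames = list("e1", sheet$sample_id)),
    "e1", character(), sheet, "c"), "non-empty")
})
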