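test_that("genomic intervals enforce the 0-based half-open invariants", {
  ok <- genomic_interval("chr1", 0, 1)
  expect_equal(ok$end - ok$start, 1)
  expect_error(genomic_interval("chr1", 100, 50), "start >= end")
  expect_error(genomic_interval("chr1", 100, 100), "start >= end")
  expect_error(genomic_interval("", 1, 2), "non-empty")
  expect_error(genomic_interval("chr1", -5, 2), ">= 0")
})

test_that("promoter regions follow strand geometry and clamp at zero", {
  cfg <- fixture_cfg
  g <- data.frame(id = c("a", "b", "c"), symbol = c("A", "B", "C"),
                  chrom = "chr1", tss = c(10000, 10000, 200),
                  strand = c("+", "-", "+"))
  p <- promoter_region(g, cfg)
  expect_equal(p$start, c(9500, 9000, 0))
  expect_equal(p$end, c(11000, 10500, 1200))
  # width = upstream + downstream whenever no clamping, both strands
  unclamped <- p$start > 0
  expect_true(all((p$end - p$start)[unclamped] ==
                  cfg$promoter_upstream + cfg$promoter_downstream))
  g$strand <- "*"
  expect_error(promoter_region(g, cfg), "strand")
})

test_that("enhancer windows center correctly, clamp, and reject degenerate widths", {
  cfg <- fixture_cfg
  e <- data.frame(chrom = "chr1", start = c(1000000, 0), end = c(1001000, 1000))
  expect_equal(enhancer_center(e), c(1000500, 500))
  w <- enhancer_window(e, cfg)
  expect_equal(w$start, c(900500, 0))
  expect_equal(w$end, c(1100500, 100500))
  bad_cfg <- fixture_cfg
  bad_cfg$link_window <- 0L
  expect_error(enhancer_window(e, bad_cfg), "positive")
  # odd-length interval: floor of the midpoint
  expect_equal(enhancer_center(data.frame(start = 0, end = 3)), 1)
})

test_that("half-open overlap is symmetric and excludes abutment", {
  a <- data.frame(chrom = "chr1", start = 100, end = 200)
  expect_true(intervals_overlap(a, data.frame(chrom = "chr1", start = 150, end = 250)))
  expect_false(intervals_overlap(a, data.frame(chrom = "chr1", start = 200, end = 300)))
  expect_false(intervals_overlap(a, data.frame(chrom = "chr2", start = 100, end = 200)))
  r1 <- random_intervals(200, seed = 7)
  r2 <- random_intervals(200, seed = 8)
  expect_equal(intervals_overlap(r1, r2), intervals_overlap(r2, r1))
})

test_that("extended enhancers add the flank on both sides and clamp", {
  cfg <- fixture_cfg
  e <- data.frame(chrom = "chr1", start = c(1000, 200), end = c(2000, 300))
  x <- extend_enhancer(e, cfg)
  expect_equal(x$start, c(500, 0))
  expect_equal(x$end, c(2500, 800))
  cfg0 <- fixture_cfg; cfg0$snp_flank <- 0L
  expect_equal(extend_enhancer(e, cfg0)[, c("start", "end")],
               e[, c("start", "end")])
})

test_that("BED reading parses coordinates, synthesizes ids, and names bad lines", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr20\t59164329\t59165752",
               "chr1\t0\t1",
               "chr2\t10\t500\tmy_enh"), bed)
  e <- read_enhancer_bed(bed)
  expect_equal(e$start[1], 59164329)
  expect_equal(e$end[1], 59165752)
  expect_equal(e$id[1], "chr20:59164329-59165752")
  expect_equal(e$id[3], "my_enh")
  expect_equal(e$end[2] - e$start[2], 1)

  writeLines(c("chr1\t10\t20", "chr1\t100\t50"), bed)
  expect_error(read_enhancer_bed(bed), "line 2")
  writeLines("chr1 10 20", bed)   # spaces, not tabs
  expect_error(read_enhancer_bed(bed), "tab-separated")
})

test_that("tabular readers round-trip what the writers emit", {
  d <- tempfile(); dir.create(d)
  m <- matrix(c(0, 1.5, 2.25, 3), 2, 2,
              dimnames = list(c("f1", "f2"), c("s1", "s2")))
  write_expression_tsv(m, file.path(d, "m.tsv"))
  expect_identical(read_expression_tsv(file.path(d, "m.tsv")), m)

  genes <- data.frame(id = c("g1", "g2"), symbol = c("S1", "S2"),
                      chrom = "chr1", tss = c(100L, 5000L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  write_gene_table(genes, file.path(d, "g.tsv"))
  expect_equal(read_gene_table(file.path(d, "g.tsv")), genes)

  snps <- data.frame(rs_id = "rs1", chrom = "chr1", pos = 501L,
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  write_snp_table(snps, file.path(d, "s.tsv"))
  back <- read_snp_table(file.path(d, "s.tsv"))
  expect_equal(back$pos0, 500)

  sets <- list(setA = c("g1", "g2"), setB = c("g2", "g3", "g4"))
  write_gmt(sets, file.path(d, "x.gmt"))
  expect_equal(read_gmt(file.path(d, "x.gmt")), sets)

  seqs <- c(e1 = "ACGTACGT", e2 = "TTTTCCCC")
  write_fasta(seqs, file.path(d, "x.fa"))
  expect_equal(read_fasta(file.path(d, "x.fa")), seqs)
})

test_that("readers reject invariant-violating inputs rather than coercing", {
  f <- tempfile()
  writeLines(c("feature_id\ts1\ts2", "f1\t1\t2", "f1\t3\t4"), f)
  expect_error(read_expression_tsv(f), "duplicate feature id")
  writeLines(c("feature_id\ts1\ts2", "f1\t1\tx"), f)
  expect_error(read_expression_tsv(f), "non-numeric|non-finite")
  writeLines(c("feature_id\ts1", "f1\t-2"), f)
  expect_error(read_expression_tsv(f), "negative")
  writeLines("", f)
  expect_error(read_expression_tsv(f), "empty")
  writeLines(c("rs_id\tchrom\tpos\tref\talt", "rs1\tchr1\t100\tA\tA"), f)
  expect_error(read_snp_table(f), "ref == alt")
  writeLines(c("setA\tdesc"), f)
  expect_error(read_gmt(f), "members")
})

test_that("PFM parsing handles the JASPAR bracket dialect and normalizes", {
  f <- tempfile()
  writeLines(c(">TFX",
               "A [ 4 0 ]",
               "C [ 0 4 ]",
               "G [ 0 0 ]",
               "T [ 0 0 ]"), f)
  pfms <- read_pfm(f)
  expect_equal(dim(pfms$TFX), c(2L, 4L))
  pwm <- pfm_to_pwm(pfms$TFX, "TFX")
  expect_equal(rowSums(pwm$probs), c(1, 1), tolerance = 1e-9)
  expect_true(all(pwm$probs > 0))   # pseudocount removes zeros
  # round trip
  write_pfm(pfms, f)
  expect_equal(read_pfm(f), pfms)
  writeLines(c(">TFY", "A [ 1 ]", "C [ 1 ]", "G [ 1 ]"), f)
  expect_error(read_pfm(f), "4 count rows")
})

test_that("flat config files parse, validate, and reject unknown keys", {
  f <- tempfile()
  writeLines(c("# comment", "prevalence_min = 0.2", "q_max = 0.01",
               "t_test_pooled = TRUE", "enhancer_bed = /x/y.bed"), f)
  cfg <- read_config(f)
  expect_equal(cfg$prevalence_min, 0.2)
  expect_equal(cfg$q_max, 0.01)
  expect_true(cfg$t_test_pooled)
  expect_equal(cfg$paths$enhancer_bed, "/x/y.bed")
  writeLines("no_such_option = 3", f)
  expect_error(read_config(f), "unknown config key")
})
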