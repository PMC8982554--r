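# Coordinate convention: BED-style 0-based half-open [start, end) on every
# internal interval. SNP positions arrive 1-based (VCF convention) and are
# converted on ingest. GRanges used for bulk overlap joins are built with
# start0 + 1 .. end0 (1-based closed), which represents the same base set.

#' Construct a table of genomic intervals
#'
#' @param chrom Chromosome names (non-empty strings).
#' @param start 0-based inclusive starts.
#' @param end 0-based exclusive ends; must satisfy start < end.
#' @param strand "+", "-" or "*" (unstranded).
#' @return data.frame with columns chrom, start, end, strand.
#' @export
genomic_interval <- function(chrom, start, end, strand = "*") {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end))
  strand <- rep_len(as.character(strand), n)
  if (any(!nzchar(chrom)) || anyNA(chrom)) stop("chrom must be non-empty")
  if (anyNA(start) || anyNA(end)) stop("interval coordinates must be numeric")
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(start >= end)) {
    i <- which(start >= end)[1]
    stop(sprintf("invalid interval %s:%d-%d (start >= end)",
                 chrom[i], start[i], end[i]))
  }
  if (!all(strand %in% c("+", "-", "*"))) stop("strand must be +, - or *")
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

#' Enhancer center
#'
#' Midpoint of the enhancer interval, floor of (start + end)/2 for
#' even-length regions.
#'
#' @param enhancers data.frame with start, end (0-based half-open).
#' @return Integer-valued vector of center positions.
#' @export
enhancer_center <- function(enhancers) {
  floor((enhancers$start + enhancers$end) / 2)
}

#' Promoter region of a gene
#'
#' The strand-aware window `promoter_upstream` bp upstream to
#' `promoter_downstream` bp downstream of the TSS: on "+" this is
#' [tss - upstream, tss + downstream), on "-" it is
#' [tss - downstream, tss + upstream). Clamped at position 0.
#'
#' @param genes data.frame with columns chrom, tss, strand ("+" or "-").
#' @param cfg A [pipeline_config()].
#' @return data.frame chrom, start, end (0-based half-open).
#' @export
promoter_region <- function(genes, cfg = pipeline_config()) {
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-' (promoter geometry is strand-dependent)")
  }
  up <- cfg$promoter_upstream
  dn <- cfg$promoter_downstream
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - up, genes$tss - dn)
  end <- ifelse(plus, genes$tss + dn, genes$tss + up)
  start <- pmax(start, 0)
  data.frame(chrom = genes$chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Search window around an enhancer center
#'
#' [center - link_window, center + link_window) on the enhancer's
#' chromosome, clamped at 0. Genes whose promoter intersects this window
#' are candidate targets.
#'
#' @param enhancers data.frame with chrom, start, end.
#' @param cfg A [pipeline_config()]; `link_window` must be > 0.
#' @return data.frame chrom, start, end.
#' @export
enhancer_window <- function(enhancers, cfg = pipeline_config()) {
  if (cfg$link_window <= 0) stop("link_window must be a positive number of base pairs")
  center <- enhancer_center(enhancers)
  data.frame(chrom = enhancers$chrom,
             start = pmax(center - cfg$link_window, 0),
             end = center + cfg$link_window,
             stringsAsFactors = FALSE)
}

#' Half-open interval overlap
#'
#' TRUE iff the intervals share a chromosome and a.start < b.end and
#' b.start < a.end. Abutting half-open intervals do not overlap.
#'
#' @param a,b data.frames with chrom, start, end (recycled elementwise).
#' @return Logical vector.
#' @export
intervals_overlap <- function(a, b) {
  a$chrom == b$chrom & a$start < b$end & b$start < a$end
}

#' Extend an enhancer for SNP mapping
#'
#' [start - snp_flank, end + snp_flank), clamped at 0.
#'
#' @param enhancers data.frame with chrom, start, end.
#' @param cfg A [pipeline_config()].
#' @return data.frame chrom, start, end (plus id if present in input).
#' @export
extend_enhancer <- function(enhancers, cfg = pipeline_config()) {
  out <- data.frame(chrom = enhancers$chrom,
                    start = pmax(enhancers$start - cfg$snp_flank, 0),
                    end = enhancers$end + cfg$snp_flank,
                    stringsAsFactors = FALSE)
  if (!is.null(enhancers$id)) out$id <- enhancers$id
  out
}

# GRanges view of a 0-based half-open interval table (1-based closed shift).
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end)
  )
}
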