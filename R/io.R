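# Readers and writers for every external format the pipeline touches.
# All tabular outputs are plain TSV with a header row; readers validate
# rather than coerce, and name the offending line or id in their errors.

#' Read enhancers from a BED file
#'
#' Standard BED semantics: tab-separated, 0-based half-open, at least three
#' columns. The id is taken from column 4 when present, otherwise
#' synthesized as `chrom:start-end`. `track`/`browser` header lines and
#' comments are skipped.
#'
#' @param path BED file.
#' @param assembly Optional assembly tag (e.g. "hg19") attached as an
#'   attribute and checked by [map_snps()].
#' @return data.frame with columns id, chrom, start, end.
#' @export
read_enhancer_bed <- function(path, assembly = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) &
    !grepl("^(#|track\\b|browser\\b)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty BED file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf < 3)) {
    i <- which(nf < 3)[1]
    stop(sprintf("malformed BED line %d in %s: fewer than 3 tab-separated columns",
                 lineno[i], path))
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    i <- which(is.na(start) | is.na(end))[1]
    stop(sprintf("malformed BED line %d in %s: non-numeric coordinate",
                 lineno[i], path))
  }
  bad <- start < 0 | start >= end
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("invalid interval at BED line %d in %s: %s:%s-%s",
                 lineno[i], path, chrom[i], start[i], end[i]))
  }
  id <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4, length(f))], ""),
               sprintf("%s:%d-%d", chrom, start, end))
  id[!nzchar(id)] <- sprintf("%s:%d-%d", chrom, start, end)[!nzchar(id)]
  if (anyDuplicated(id)) stop("duplicate enhancer id in ", path, ": ",
                              id[duplicated(id)][1])
  out <- data.frame(id = id, chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  attr(out, "assembly") <- assembly
  out
}

#' Write enhancers as BED
#' @param enhancers data.frame with id, chrom, start, end.
#' @param path Output file.
#' @export
write_enhancer_bed <- function(enhancers, path) {
  utils::write.table(
    enhancers[, c("chrom", "start", "end", "id")], path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' First row: sample ids (the first cell names the feature-id column and is
#' ignored). First column: feature ids. Values must be finite, numeric and
#' non-negative (RPKM-scale expression).
#'
#' @param path TSV file.
#' @return Numeric matrix, rownames = feature ids, colnames = sample ids.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  first <- readLines(path, n = 1, warn = FALSE)
  if (!length(first) || !nzchar(trimws(first))) {
    stop("empty expression matrix: ", path)
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) stop("empty expression matrix: ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate feature id in ", path, ": ", ids[duplicated(ids)][1])
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    stop("non-numeric expression cell in ", path)
  }
  if (anyNA(m) || any(!is.finite(m))) stop("non-finite expression value in ", path)
  if (any(m < 0)) stop("negative expression value in ", path)
  rownames(m) <- ids
  if (anyDuplicated(colnames(m))) {
    stop("duplicate sample id in ", path, ": ",
         colnames(m)[duplicated(colnames(m))][1])
  }
  m
}

#' Write an expression matrix as TSV
#' @param m Numeric matrix with feature rownames and sample colnames.
#' @param path Output file.
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' TSV with columns sample_id, tissue, condition (tumor | normal).
#' @param path TSV file.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "condition")
  if (!all(need %in% names(df))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ", df$sample_id[duplicated(df$sample_id)][1])
  }
  if (!all(df$condition %in% c("tumor", "normal"))) {
    stop("condition must be 'tumor' or 'normal'")
  }
  df
}

#' Read a pre-collapsed gene annotation table
#'
#' TSV with columns id, symbol, chrom, tss (0-based), strand (+/-). One TSS
#' per gene id: multi-isoform collapsing is the caller's responsibility.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "symbol", "chrom", "tss", "strand")
  if (!all(need %in% names(df))) {
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$id)) {
    stop("duplicate gene id: ", df$id[duplicated(df$id)][1])
  }
  if (!is.numeric(df$tss) || any(df$tss < 0)) stop("tss must be numeric and >= 0")
  if (!all(df$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  df
}

#' Write a gene annotation table
#' @param genes data.frame with id, symbol, chrom, tss, strand.
#' @param path Output file.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes[, c("id", "symbol", "chrom", "tss", "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SNP table
#'
#' TSV with columns rs_id, chrom, pos (1-based, VCF convention), ref, alt.
#' Positions are converted to the internal 0-based convention in a `pos0`
#' column. Single-base ref/alt in A/C/G/T with ref != alt.
#'
#' @param path TSV file.
#' @param assembly Optional assembly tag checked by [map_snps()].
#' @return data.frame with an added pos0 column.
#' @export
read_snp_table <- function(path, assembly = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("rs_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df))) {
    stop("SNP table must have columns: ", paste(need, collapse = ", "))
  }
  if (!is.numeric(df$pos) || any(df$pos < 1)) stop("pos must be 1-based positive")
  bases <- c("A", "C", "G", "T")
  if (!all(df$ref %in% bases) || !all(df$alt %in% bases)) {
    stop("ref/alt must be single bases in A/C/G/T")
  }
  if (any(df$ref == df$alt)) {
    stop("ref == alt for SNP ", df$rs_id[df$ref == df$alt][1])
  }
  df$pos0 <- df$pos - 1
  attr(df, "assembly") <- assembly
  df
}

#' Write a SNP table
#' @param snps data.frame with rs_id, chrom, pos, ref, alt.
#' @param path Output file.
#' @export
write_snp_table <- function(snps, path) {
  utils::write.table(snps[, c("rs_id", "chrom", "pos", "ref", "alt")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read position frequency matrices (JASPAR-style PFM)
#'
#' Records start with `>name`; the four following rows give counts for A, C,
#' G, T across positions, either bare numbers or in the
#' `A [ 12 0 3 ... ]` JASPAR dialect.
#'
#' @param path PFM file.
#' @return Named list of count matrices (L x 4, columns A,C,G,T).
#' @export
read_pfm <- function(path) {
  if (!file.exists(path)) stop("PFM file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty PFM file: ", path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no '>' record headers in PFM file: ", path)
  out <- list()
  bounds <- c(hdr, length(lines) + 1L)
  for (i in seq_along(hdr)) {
    name <- sub("^>\\s*", "", lines[hdr[i]])
    name <- strsplit(name, "\\s+")[[1]][1]
    body <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(body) != 4) {
      stop("PFM record '", name, "' must have exactly 4 count rows")
    }
    rows <- lapply(body, function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("[\\[\\]]", "", l, perl = TRUE)
      v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
      if (anyNA(v)) stop("non-numeric count in PFM record '", name, "'")
      v
    })
    if (length(unique(lengths(rows))) != 1) {
      stop("ragged count rows in PFM record '", name, "'")
    }
    counts <- t(do.call(rbind, rows))          # L x 4
    colnames(counts) <- c("A", "C", "G", "T")
    if (any(counts < 0)) stop("negative count in PFM record '", name, "'")
    out[[name]] <- counts
  }
  out
}

#' Write position frequency matrices in JASPAR style
#' @param pfms Named list of L x 4 count matrices.
#' @param path Output file.
#' @export
write_pfm <- function(pfms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (name in names(pfms)) {
    counts <- pfms[[name]]
    writeLines(paste0(">", name), con)
    for (j in 1:4) {
      writeLines(sprintf("%s [ %s ]", c("A", "C", "G", "T")[j],
                         paste(counts[, j], collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member gene ids,
#' tab-separated.
#'
#' @param path GMT file.
#' @return Named list of character vectors of member gene ids.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 1L) < 3
  if (any(short)) {
    stop("GMT line ", which(short)[1], " has no members (need name, description, >=1 gene)")
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(names(sets))) {
    stop("duplicate gene-set name: ", names(sets)[duplicated(names(sets))][1])
  }
  sets
}

#' Write gene sets as GMT
#' @param sets Named list of character vectors.
#' @param path Output file.
#' @param descriptions Optional character vector of descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read sequences from a FASTA file
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
  seqs
}

#' Write sequences to a FASTA file
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(unlist(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write a records table as TSV
#' @param records data.frame.
#' @param path Output file.
#' @export
write_records_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a sample sheet as TSV
#' @param sheet data.frame with sample_id, tissue, condition.
#' @param path Output file.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet[, c("sample_id", "tissue", "condition")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
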