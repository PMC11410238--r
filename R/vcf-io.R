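# VCF / BED / coverage-table I/O for the popgen and introgression modules.
# Reading goes through vcfR; the writers emit minimal deterministic text so
# simulator truth sets round-trip byte for byte.

#' Read a multi-sample VCF into a variant table
#'
#' Keeps biallelic SNPs only. Genotypes are collapsed to alt-allele dosage:
#' `0/0 -> 0`, `1/1 -> 1`, `0/1 -> 0.5`, missing -> `NA`. Per-sample `DP` is
#' summarized per site as its minimum (so a strict site-level depth filter
#' honors the weakest genotype), site quality comes from `QUAL`.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param populations named character vector, sample to population; defaults
#'   to one population `"all"`.
#' @param L callable genome length; defaults to the sum of contig lengths in
#'   the header when present, otherwise errors.
#' @return a [variant_table()].
#' @export
read_variants <- function(path, populations = NULL, L = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L & !grepl(",", fix$ALT)
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- function(x) {
    x <- sub("\\|", "/", x)
    out <- rep(NA_real_, length(x))
    out[x %in% c("0", "0/0")] <- 0
    out[x %in% c("1", "1/1")] <- 1
    out[x %in% c("0/1", "1/0")] <- 0.5
    out
  }
  geno <- apply(gt[snp, , drop = FALSE], 2L, code)
  if (!is.matrix(geno)) geno <- matrix(geno, nrow = sum(snp),
                                       dimnames = list(NULL, colnames(gt)))
  sites <- data.frame(chrom = fix$CHROM[snp], pos = as.integer(fix$POS[snp]),
                      ref = fix$REF[snp], alt = fix$ALT[snp],
                      qual = suppressWarnings(as.numeric(fix$QUAL[snp])),
                      stringsAsFactors = FALSE)
  dp <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
                 error = function(e) NULL)
  if (!is.null(dp) && !all(is.na(dp)))
    sites$depth <- apply(dp[snp, , drop = FALSE], 1L, min)
  if (is.null(L)) {
    meta <- v@meta
    lens <- as.numeric(sub(".*length=(\\d+).*", "\\1",
                           grep("##contig=.*length=", meta, value = TRUE)))
    if (length(lens) == 0L)
      stop_bad("VCF header has no contig lengths; supply callable length L")
    L <- sum(lens)
  }
  if (is.null(populations))
    populations <- stats::setNames(rep("all", ncol(geno)), colnames(geno))
  o <- order(sites$chrom, sites$pos)
  variant_table(sites[o, , drop = FALSE], geno[o, , drop = FALSE],
                populations, L)
}

#' Write a variant table as VCF 4.2
#'
#' Minimal deterministic writer (GT field, contig header lines); dosage 0.5
#' is emitted as `0/1`.
#'
#' @param table a [variant_table()].
#' @param path output path.
#' @param contig_lengths optional named vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_variants <- function(table, path, contig_lengths = NULL) {
  stopifnot(inherits(table, "variant_table"))
  gt_chr <- function(x) {
    out <- rep("./.", length(x))
    out[!is.na(x) & x == 0] <- "0/0"
    out[!is.na(x) & x == 1] <- "1/1"
    out[!is.na(x) & x == 0.5] <- "0/1"
    out
  }
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contig_lengths))
             sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                     as.integer(contig_lengths)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(table$geno)), collapse = "\t"))
  qual <- if (is.null(table$sites$qual)) "." else
    ifelse(is.na(table$sites$qual), ".", format(table$sites$qual))
  body <- character(n_sites(table))
  gm <- apply(table$geno, 2L, gt_chr)
  if (!is.matrix(gm)) gm <- matrix(gm, nrow = n_sites(table))
  for (i in seq_len(n_sites(table))) {
    body[i] <- paste(c(table$sites$chrom[i], table$sites$pos[i], ".",
                       table$sites$ref[i], table$sites$alt[i], qual[i], "PASS",
                       ".", "GT", gm[i, ]), collapse = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write intervals as BED
#'
#' @param intervals data.frame with `chrom`, `start` (0-based), `end` and
#'   optional `name`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  nm <- intervals$name %||% rep(".", nrow(intervals))
  writeLines(sprintf("%s\t%d\t%d\t%s", intervals$chrom,
                     as.integer(intervals$start), as.integer(intervals$end),
                     nm), path)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path BED path (first three columns used).
#' @return data.frame `chrom`, `start` (0-based), `end`, and `name` when
#'   present.
#' @export
read_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  out <- data.frame(chrom = tab[[1L]], start = as.integer(tab[[2L]]),
                    end = as.integer(tab[[3L]]), stringsAsFactors = FALSE)
  if (ncol(tab) >= 4L) out$name <- tab[[4L]]
  out
}
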