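#' Genome container
#'
#' A genome is a named character vector of chromosome sequences (A/C/G/T,
#' uppercase). Coordinates are 0-based half-open internally; all emitted
#' formats (VCF, GFF3, BED-adjacent reports) are converted at the boundary.
#'
#' @param x named character vector of chromosome sequences.
#' @return an object of class `genome`.
#' @export
as_genome <- function(x) {
  if (!is.character(x) || length(x) == 0L)
    stop_bad("a genome needs at least one chromosome sequence")
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "") ||
      anyDuplicated(names(x)))
    stop_bad("chromosomes must carry unique non-empty names")
  x <- toupper(x)
  if (any(nchar(x) == 0L))
    stop_bad("empty chromosome sequence: %s",
             paste(names(x)[nchar(x) == 0L], collapse = ", "))
  if (any(grepl("[^ACGT]", x)))
    stop_bad("genome sequences may only contain A, C, G, T")
  structure(x, class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %d chromosome(s), %s bp total\n",
              length(x), format(genome_length(x), big.mark = ",")))
  for (nm in names(x))
    cat(sprintf("  %-12s %10s bp\n", nm, format(nchar(x[[nm]]), big.mark = ",")))
  invisible(x)
}

#' @rdname as_genome
#' @export
is_genome <- function(x) inherits(x, "genome")

#' Chromosome lengths of a genome
#' @param genome a [as_genome()] object.
#' @return named integer vector of lengths in bp.
#' @export
chrom_lengths <- function(genome) {
  stopifnot(is_genome(genome))
  vapply(genome, nchar, integer(1))
}

#' @rdname chrom_lengths
#' @export
genome_length <- function(genome) sum(chrom_lengths(genome))

#' Read / write genomes as FASTA
#'
#' Thin wrappers around Biostrings so that all sequence I/O uses the standard
#' machinery; [write_genome_fasta()] emits a fixed 70-column wrap so identical
#' genomes serialize to identical bytes.
#'
#' @param path FASTA file path.
#' @param genome a `genome` object.
#' @return [read_genome_fasta()] returns a `genome`; [write_genome_fasta()]
#'   returns `path` invisibly.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  as_genome(stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss))))
}

#' @rdname read_genome_fasta
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(is_genome(genome))
  ss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

# raw byte views used by divergence and diff computations
.chrom_raw <- function(genome, chrom) charToRaw(genome[[chrom]])

.common_chroms <- function(a, b) {
  shared <- intersect(names(a), names(b))
  if (length(shared) == 0L)
    stop_bad("genomes share no chromosome names")
  bad <- shared[chrom_lengths(a)[shared] != chrom_lengths(b)[shared]]
  if (length(bad) > 0L)
    stop_bad("chromosome length mismatch (coordinate-matched genomes required): %s",
             paste(bad, collapse = ", "))
  shared
}

#' Column-wise divergence between coordinate-matched genomes
#'
#' Fraction of sites that differ between two genomes sharing chromosome names
#' and lengths (e.g. substitution-only lineages from the simulator, or
#' reference-projected consensus genomes).
#'
#' @param a,b `genome` objects with matching chromosome names and lengths.
#' @return divergence fraction in `[0, 1]`.
#' @export
genome_divergence <- function(a, b) {
  shared <- .common_chroms(a, b)
  diff <- 0; tot <- 0
  for (ch in shared) {
    ra <- .chrom_raw(a, ch); rb <- .chrom_raw(b, ch)
    diff <- diff + sum(ra != rb)
    tot <- tot + length(ra)
  }
  diff / tot
}

#' Per-site differences between coordinate-matched genomes
#'
#' @inheritParams genome_divergence
#' @return data.frame with `chrom`, `pos` (1-based), `ref` (base in `a`),
#'   `alt` (base in `b`), ordered by chromosome then position.
#' @export
genome_diff_positions <- function(a, b) {
  shared <- .common_chroms(a, b)
  out <- vector("list", length(shared))
  for (i in seq_along(shared)) {
    ch <- shared[i]
    ra <- .chrom_raw(a, ch); rb <- .chrom_raw(b, ch)
    idx <- which(ra != rb)
    out[[i]] <- data.frame(
      chrom = rep(ch, length(idx)),
      pos = idx,
      ref = strsplit(rawToChar(ra[idx]), "", fixed = TRUE)[[1]] %||% character(0),
      alt = strsplit(rawToChar(rb[idx]), "", fixed = TRUE)[[1]] %||% character(0),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
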