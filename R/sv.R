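# Structural variants from whole-genome alignment blocks.
#
# Blocks come either from a 9-column TSV (nucmer show-coords-like layout) or
# from the internal anchor aligner, which chains unique shared k-mers so the
# simulator's genome pairs can be compared end-to-end without an external
# aligner. The classifier walks each query contig's block chain: runs on a
# non-primary reference chromosome are translocations, minus-strand runs are
# inversions, and gaps between adjacent collinear blocks are deletions or
# insertions.

.block_cols <- c("ref_chrom", "ref_start", "ref_end", "query_chrom",
                 "query_start", "query_end", "strand", "identity",
                 "aligned_length")

#' Read whole-genome alignment blocks from TSV
#'
#' Expected layout (tab-separated, with header): `ref_chrom`, `ref_start`,
#' `ref_end`, `query_chrom`, `query_start`, `query_end`, `strand`,
#' `identity`, `aligned_length`; coordinates 1-based inclusive,
#' `ref_start <= ref_end`.
#'
#' @param path TSV path.
#' @return data.frame of validated blocks sorted by
#'   (`query_chrom`, `query_start`).
#' @export
read_alignment_blocks <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L)
    return(stats::setNames(data.frame(matrix(nrow = 0L, ncol = 9L)),
                           .block_cols))
  tab <- utils::read.table(text = lines, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!identical(names(tab), .block_cols))
    stop_bad("block table must carry columns: %s",
             paste(.block_cols, collapse = ", "))
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    bad <- !is.numeric(row$ref_start) || !is.numeric(row$ref_end) ||
      is.na(row$ref_start) || is.na(row$ref_end) ||
      row$ref_start > row$ref_end || row$query_start > row$query_end ||
      row$ref_start < 1 || row$query_start < 1 ||
      !(row$strand %in% c("+", "-"))
    if (bad) stop_bad("malformed block at line %d of %s", i + 1L, path)
  }
  validate_blocks(tab)
}

#' @rdname read_alignment_blocks
#' @param blocks a block data.frame.
#' @export
validate_blocks <- function(blocks) {
  stopifnot(all(.block_cols %in% names(blocks)))
  if (any(blocks$ref_end < blocks$ref_start) ||
      any(blocks$query_end < blocks$query_start))
    stop_bad("degenerate block (end < start)")
  blocks <- blocks[order(blocks$query_chrom, blocks$query_start), , drop = FALSE]
  rownames(blocks) <- NULL
  blocks
}

#' Write alignment blocks as TSV
#' @param blocks block data.frame.
#' @param path output path.
#' @export
write_alignment_blocks <- function(blocks, path) {
  utils::write.table(blocks[, .block_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- internal anchor aligner -------------------------------------------

.unique_kmer_table <- function(genome, k) {
  pos <- list(); km <- list()
  for (ch in names(genome)) {
    L <- nchar(genome[[ch]])
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    km[[ch]] <- substring(genome[[ch]], starts, starts + k - 1L)
    pos[[ch]] <- data.frame(chrom = ch, start = starts - 1L,
                            stringsAsFactors = FALSE)
  }
  kmer <- unlist(km, use.names = FALSE)
  tab <- do.call(rbind, pos)
  dup <- duplicated(kmer) | duplicated(kmer, fromLast = TRUE)
  tab <- tab[!dup, , drop = FALSE]
  tab$kmer <- kmer[!dup]
  tab
}

#' Align two genomes into collinear blocks
#'
#' Anchor-based aligner: k-mers unique in both genomes are matched (both
#' strands) and chained into maximal collinear runs (same reference
#' chromosome, same strand, consistent diagonal within `gap_tolerance`).
#' Suited to closely related assemblies; substitution divergence up to ~10%
#' leaves ample unique anchors at the default k.
#'
#' @param ref,query `genome` objects.
#' @param k anchor k-mer size.
#' @param gap_tolerance diagonal drift tolerated inside one block, bp.
#' @param max_anchor_gap largest anchor-to-anchor jump kept inside a block,
#'   bp.
#' @param min_anchors,min_span discard blocks with fewer anchors / smaller
#'   query span (noise suppression).
#' @return block data.frame as in [read_alignment_blocks()] (1-based
#'   inclusive coordinates); `identity` is estimated from anchor density as
#'   `100 * density^(1/k)`.
#' @export
genome_alignment_blocks <- function(ref, query, k = 21L, gap_tolerance = 200L,
                                    max_anchor_gap = 5000L, min_anchors = 5L,
                                    min_span = 200L) {
  stopifnot(is_genome(ref), is_genome(query))
  rt <- .unique_kmer_table(ref, k)
  anchors <- list()
  for (strand in c("+", "-")) {
    qg <- if (strand == "+") query else {
      as_genome(stats::setNames(.revcomp_chr(unclass(query)), names(query)))
    }
    qt <- .unique_kmer_table(qg, k)
    m <- match(qt$kmer, rt$kmer)
    hit <- !is.na(m)
    if (!any(hit)) next
    a <- data.frame(query_chrom = qt$chrom[hit],
                    q0 = qt$start[hit],
                    ref_chrom = rt$chrom[m[hit]],
                    r0 = rt$start[m[hit]],
                    strand = strand, stringsAsFactors = FALSE)
    if (strand == "-") {
      # map positions on the reverse-complemented query back to query coords
      qlen <- chrom_lengths(query)[a$query_chrom]
      a$q0 <- qlen - k - a$q0
    }
    anchors[[strand]] <- a
  }
  anchors <- do.call(rbind, anchors)
  if (is.null(anchors) || nrow(anchors) == 0L)
    return(stats::setNames(data.frame(matrix(nrow = 0L, ncol = 9L)),
                           .block_cols))
  blocks <- list()
  for (qc in unique(anchors$query_chrom)) {
    a <- anchors[anchors$query_chrom == qc, , drop = FALSE]
    a <- a[order(a$q0), , drop = FALSE]
    diag <- ifelse(a$strand == "+", a$r0 - a$q0, a$r0 + a$q0)
    brk <- c(TRUE, a$ref_chrom[-1L] != a$ref_chrom[-nrow(a)] |
               a$strand[-1L] != a$strand[-nrow(a)] |
               abs(diff(diag)) > gap_tolerance |
               diff(a$q0) > max_anchor_gap)
    run <- cumsum(brk)
    for (g in split(seq_len(nrow(a)), run)) {
      if (length(g) < min_anchors) next
      qa <- a[g, , drop = FALSE]
      span_q <- max(qa$q0) + k - min(qa$q0)
      if (span_q < min_span) next
      dens <- min(length(g) / max(span_q - k + 1L, 1L), 1)
      blocks[[length(blocks) + 1L]] <- data.frame(
        ref_chrom = qa$ref_chrom[1L],
        ref_start = min(qa$r0) + 1L,
        ref_end = max(qa$r0) + k,
        query_chrom = qc,
        query_start = min(qa$q0) + 1L,
        query_end = max(qa$q0) + k,
        strand = qa$strand[1L],
        identity = round(100 * dens^(1 / k), 3),
        aligned_length = span_q,
        stringsAsFactors = FALSE)
    }
  }
  validate_blocks(do.call(rbind, blocks))
}

# ---- classifier ---------------------------------------------------------

.empty_svs <- function() {
  data.frame(id = integer(0), kind = character(0), ref_chrom = character(0),
             ref_start = integer(0), ref_end = integer(0),
             query_chrom = character(0), query_start = integer(0),
             query_end = integer(0), size = integer(0),
             query_primary = character(0), partner_id = integer(0),
             genes_overlapped = integer(0), stringsAsFactors = FALSE)
}

#' Call structural variants from a block chain
#'
#' Per query contig: the primary reference chromosome is the one holding the
#' majority of aligned bases. Then
#' \itemize{
#'   \item a maximal run of blocks on a non-primary chromosome is a
#'     `translocation` (size = reference span); [pair_reciprocal()] resolves
#'     reciprocity afterwards;
#'   \item a maximal run of minus-strand blocks within plus-strand context on
#'     one chromosome is an `inversion`;
#'   \item adjacent collinear blocks with a reference gap of at least
#'     `min_size` but a query gap under `gap_tolerance` are a `deletion`
#'     (the converse is an `insertion`);
#'   \item two or more disjoint query intervals aligning to one reference
#'     interval (reciprocal overlap >= 0.9) are a `duplication`.
#' }
#' Deletions whose reference interval coincides (reciprocal overlap >= 0.9)
#' with a translocated segment are suppressed: they are the donor-side
#' footprint of the move, not an independent event.
#'
#' @param blocks block data.frame (one query assembly vs one reference).
#' @param gap_tolerance breakpoint fuzz in bp.
#' @param min_size smallest indel-class event emitted, bp.
#' @return SV data.frame: `id`, `kind`, `ref_chrom`, `ref_start`, `ref_end`
#'   (1-based inclusive), `query_chrom`, `query_start`, `query_end`, `size`,
#'   `query_primary`, `partner_id`, `genes_overlapped`.
#' @export
call_svs <- function(blocks, gap_tolerance = 200L, min_size = 50L) {
  blocks <- validate_blocks(blocks)
  if (nrow(blocks) == 0L) return(.empty_svs())
  evs <- list()
  add <- function(kind, rc, rs, re, qc, qs, qe, primary) {
    evs[[length(evs) + 1L]] <<- data.frame(
      kind = kind, ref_chrom = rc, ref_start = as.integer(rs),
      ref_end = as.integer(re), query_chrom = qc,
      query_start = as.integer(qs), query_end = as.integer(qe),
      size = as.integer(re - rs + 1L), query_primary = primary,
      stringsAsFactors = FALSE)
  }
  for (qc in unique(blocks$query_chrom)) {
    b <- blocks[blocks$query_chrom == qc, , drop = FALSE]
    b <- b[order(b$query_start), , drop = FALSE]
    aligned <- tapply(b$ref_end - b$ref_start + 1L, b$ref_chrom, sum)
    primary <- names(aligned)[which.max(aligned)]
    # translocation runs (non-primary reference chromosome)
    run <- cumsum(c(TRUE, b$ref_chrom[-1L] != b$ref_chrom[-nrow(b)]))
    for (g in split(seq_len(nrow(b)), run)) {
      rb <- b[g, , drop = FALSE]
      if (rb$ref_chrom[1L] != primary)
        add("translocation", rb$ref_chrom[1L], min(rb$ref_start),
            max(rb$ref_end), qc, min(rb$query_start), max(rb$query_end),
            primary)
    }
    # inversions: minus-strand runs per reference chromosome
    srun <- cumsum(c(TRUE, b$ref_chrom[-1L] != b$ref_chrom[-nrow(b)] |
                       b$strand[-1L] != b$strand[-nrow(b)]))
    for (g in split(seq_len(nrow(b)), srun)) {
      rb <- b[g, , drop = FALSE]
      if (rb$strand[1L] == "-")
        add("inversion", rb$ref_chrom[1L], min(rb$ref_start), max(rb$ref_end),
            qc, min(rb$query_start), max(rb$query_end), primary)
    }
    # indel-class gaps between adjacent collinear blocks
    if (nrow(b) >= 2L) {
      for (i in seq_len(nrow(b) - 1L)) {
        b1 <- b[i, ]; b2 <- b[i + 1L, ]
        if (b1$ref_chrom != b2$ref_chrom || b1$strand != b2$strand ||
            b1$strand != "+") next
        ref_gap <- b2$ref_start - b1$ref_end - 1L
        query_gap <- b2$query_start - b1$query_end - 1L
        if (ref_gap >= min_size && query_gap < gap_tolerance) {
          evs[[length(evs) + 1L]] <- data.frame(
            kind = "deletion", ref_chrom = b1$ref_chrom,
            ref_start = b1$ref_end + 1L, ref_end = b2$ref_start - 1L,
            query_chrom = qc, query_start = b1$query_end,
            query_end = b2$query_start, size = as.integer(ref_gap),
            query_primary = primary, stringsAsFactors = FALSE)
        } else if (query_gap >= min_size && ref_gap < gap_tolerance) {
          evs[[length(evs) + 1L]] <- data.frame(
            kind = "insertion", ref_chrom = b1$ref_chrom,
            ref_start = b1$ref_end, ref_end = b2$ref_start,
            query_chrom = qc, query_start = b1$query_end + 1L,
            query_end = b2$query_start - 1L, size = as.integer(query_gap),
            query_primary = primary, stringsAsFactors = FALSE)
        }
      }
    }
  }
  # duplications: disjoint query intervals over one reference interval
  nb <- nrow(blocks)
  if (nb >= 2L) {
    for (i in seq_len(nb - 1L)) for (j in (i + 1L):nb) {
      b1 <- blocks[i, ]; b2 <- blocks[j, ]
      if (b1$ref_chrom != b2$ref_chrom) next
      ov <- min(b1$ref_end, b2$ref_end) - max(b1$ref_start, b2$ref_start) + 1L
      if (ov <= 0) next
      l1 <- b1$ref_end - b1$ref_start + 1L; l2 <- b2$ref_end - b2$ref_start + 1L
      q_disjoint <- b1$query_chrom != b2$query_chrom ||
        b1$query_end < b2$query_start || b2$query_end < b1$query_start
      # the duplicated copy covers (>= 0.9) the smaller ref interval; the
      # other copy may sit inside a larger collinear block
      if (ov / min(l1, l2) >= 0.9 && q_disjoint) {
        evs[[length(evs) + 1L]] <- data.frame(
          kind = "duplication", ref_chrom = b1$ref_chrom,
          ref_start = max(b1$ref_start, b2$ref_start),
          ref_end = min(b1$ref_end, b2$ref_end),
          query_chrom = b2$query_chrom, query_start = b2$query_start,
          query_end = b2$query_end, size = as.integer(ov),
          query_primary = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(evs) == 0L) return(.empty_svs())
  out <- do.call(rbind, evs)
  # suppress donor-side deletion footprints of translocated segments
  if (any(out$kind == "deletion") && any(out$kind == "translocation")) {
    tr <- out[out$kind == "translocation", , drop = FALSE]
    drop <- vapply(seq_len(nrow(out)), function(i) {
      if (out$kind[i] != "deletion") return(FALSE)
      any(vapply(seq_len(nrow(tr)), function(j) {
        if (tr$ref_chrom[j] != out$ref_chrom[i]) return(FALSE)
        ov <- min(tr$ref_end[j], out$ref_end[i]) -
          max(tr$ref_start[j], out$ref_start[i]) + 1L
        ov > 0 && ov / out$size[i] >= 0.9 && ov / tr$size[j] >= 0.9
      }, logical(1)))
    }, logical(1))
    out <- out[!drop, , drop = FALSE]
  }
  out <- out[order(out$ref_chrom, out$ref_start, out$kind), , drop = FALSE]
  out$id <- seq_len(nrow(out))
  out$partner_id <- NA_integer_
  out$genes_overlapped <- NA_integer_
  rownames(out) <- NULL
  out[, names(.empty_svs())]
}

#' Resolve reciprocal translocation pairs
#'
#' Two translocations are reciprocal when each one's segment chromosome is
#' the other's contig-primary chromosome: a segment of chrA residing on the
#' contig that primarily represents chrB, and a segment of chrB on the contig
#' representing chrA. Paired events are relabelled
#' `reciprocal_translocation` and linked via `partner_id`; the rest become
#' `nonreciprocal_translocation`.
#'
#' @param svs [call_svs()] output.
#' @return the annotated SV data.frame.
#' @export
pair_reciprocal <- function(svs) {
  if (nrow(svs) == 0L) return(svs)
  tr <- which(svs$kind == "translocation")
  for (i in tr) {
    if (!is.na(svs$partner_id[i])) next
    mate <- tr[svs$ref_chrom[tr] == svs$query_primary[i] &
                 svs$query_primary[tr] == svs$ref_chrom[i] &
                 is.na(svs$partner_id[tr])]
    mate <- setdiff(mate, i)
    if (length(mate) > 0L) {
      j <- mate[1L]
      svs$kind[c(i, j)] <- "reciprocal_translocation"
      svs$partner_id[i] <- svs$id[j]
      svs$partner_id[j] <- svs$id[i]
    }
  }
  svs$kind[svs$kind == "translocation"] <- "nonreciprocal_translocation"
  svs
}

#' Filter structural variants by size and exclusion regions
#'
#' Keeps events with `size > min_size` (strict) that do not overlap any
#' exclusion interval (e.g. the rDNA locus, whose alignment artifacts the
#' caller should ignore).
#'
#' @param svs SV data.frame.
#' @param min_size size threshold in bp (exclusive; default 1000).
#' @param exclusion_regions optional data.frame `chrom`, `start` (0-based,
#'   BED-style), `end`; or a BED path.
#' @return filtered SV data.frame.
#' @export
filter_svs <- function(svs, min_size = 1000L, exclusion_regions = NULL) {
  if (is.character(exclusion_regions))
    exclusion_regions <- read_bed(exclusion_regions)
  keep <- svs$size > min_size
  if (!is.null(exclusion_regions) && nrow(svs) > 0L) {
    ex <- data.frame(chrom = exclusion_regions$chrom,
                     start = exclusion_regions$start + 1L, # to 1-based
                     end = exclusion_regions$end)
    hit <- vapply(seq_len(nrow(svs)), function(i)
      .overlaps_any(svs$ref_chrom[i], svs$ref_start[i], svs$ref_end[i], ex),
      logical(1))
    keep <- keep & !hit
  }
  out <- svs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count genes overlapped by each structural variant
#'
#' @param svs SV data.frame.
#' @param annotation GFF3 path or a `GRanges` of gene features (any feature
#'   overlap of >= 1 bp counts).
#' @return `svs` with `genes_overlapped` filled in.
#' @export
annotate_genes <- function(svs, annotation) {
  if (is.character(annotation))
    annotation <- rtracklayer::import(annotation)
  genes <- annotation[annotation$type == "gene"]
  if (nrow(svs) == 0L) return(svs)
  iv <- GenomicRanges::GRanges(svs$ref_chrom,
                               IRanges::IRanges(svs$ref_start, svs$ref_end))
  svs$genes_overlapped <- GenomicRanges::countOverlaps(iv, genes)
  svs
}

#' Summarize structural-variant calls
#'
#' @param svs SV data.frame.
#' @return list with `n_total`, `by_kind` (named counts) and `total_bp`.
#' @export
summarize_svs <- function(svs) {
  list(n_total = nrow(svs),
       by_kind = as.list(table(svs$kind)),
       total_bp = sum(svs$size))
}
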