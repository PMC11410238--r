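# Average nucleotide identity by fragment orthology (OANI).
#
# Both genomes are chopped into fixed-length fragments; orthologous fragment
# pairs are reciprocal best hits under affine global alignment; OANI is 100 x
# the mean alignment identity over those pairs. Candidate subjects for each
# query fragment are found by shared-k-mer counting so that the all-vs-all
# alignment cost is avoided; the exhaustive path is kept for small inputs and
# as the test oracle.

#' Cut a genome into consecutive fragments
#'
#' Non-overlapping fragments per chromosome; the trailing remainder shorter
#' than `fragment_length` is discarded.
#'
#' @param genome a `genome`.
#' @param fragment_length fragment size in bp (>= 100; default 1020, the
#'   orthology-ANI convention).
#' @return data.frame `id` (integer), `chrom`, `start` (0-based), `seq`.
#' @export
fragment_genome <- function(genome, fragment_length = 1020L) {
  stopifnot(is_genome(genome))
  if (!.is_count(fragment_length) || fragment_length < 100)
    stop_bad("fragment_length must be an integer >= 100")
  lens <- chrom_lengths(genome)
  parts <- lapply(names(lens), function(ch) {
    n <- lens[[ch]] %/% fragment_length
    if (n == 0L) return(NULL)
    start <- (seq_len(n) - 1L) * fragment_length
    data.frame(chrom = ch, start = start,
               seq = substring(genome[[ch]], start + 1L, start + fragment_length),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out) || nrow(out) == 0L)
    stop_bad("no chromosome reaches one fragment length (%d bp)", fragment_length)
  out$id <- seq_len(nrow(out))
  out[, c("id", "chrom", "start", "seq")]
}

# affine global alignment identity for paired character vectors.
# identity = matches / alignment columns (gaps count as columns).
.align_pairs <- function(query, subject) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(query), Biostrings::DNAStringSet(subject),
    type = "global", substitutionMatrix = mat,
    gapOpening = 10, gapExtension = 4)
  cols <- BiocGenerics::width(Biostrings::alignedPattern(aln))
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  list(identity = nm / cols,
       columns = cols,
       coverage = (nm + nmm) / nchar(query))
}

.revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

# shared-k-mer candidate subjects per query fragment (both strands).
# Subject fragments are indexed at every position; query k-mers are sampled
# every `stride` bp, which still guarantees shared seeds for homologous
# fragments at the divergences of interest.
.kmer_candidates <- function(frags_q, frags_s, k = 15L, stride = 7L,
                             max_candidates = 3L) {
  kmers_of <- function(seqs, ids, step) {
    len <- nchar(seqs[1L])
    starts <- seq.int(1L, len - k + 1L, by = step)
    data.table::data.table(
      kmer = as.vector(vapply(starts, function(s) substring(seqs, s, s + k - 1L),
                              character(length(seqs)))),
      id = rep(ids, times = length(starts)))
  }
  kmer <- id <- id_q <- id_s <- strand <- shared <- NULL # data.table NSE
  st <- kmers_of(frags_s$seq, frags_s$id, 1L)
  data.table::setkey(st, kmer)
  qf <- kmers_of(frags_q$seq, frags_q$id, stride)
  qr <- kmers_of(.revcomp_chr(frags_q$seq), frags_q$id, stride)
  qf$strand <- "+"; qr$strand <- "-"
  qt <- rbind(qf, qr)
  hits <- st[qt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0L)
    return(data.table::data.table(id_q = integer(0), id_s = integer(0),
                                  strand = character(0), shared = integer(0)))
  cnt <- hits[, list(shared = .N), by = list(id_q = i.id, id_s = id, strand)]
  data.table::setorder(cnt, id_q, -shared, id_s, strand)
  cnt[, utils::head(.SD, max_candidates), by = id_q]
}

.pick_best <- function(hits, min_coverage, min_identity) {
  # hits: data.frame id_q, id_s, strand, identity, columns, coverage
  ok <- hits$coverage >= min_coverage & hits$identity >= min_identity
  hits <- hits[ok, , drop = FALSE]
  if (nrow(hits) == 0L) return(NULL)
  # maximal identity; ties broken by lower subject fragment id
  hits <- hits[order(hits$id_q, -hits$identity, hits$id_s), , drop = FALSE]
  hits[!duplicated(hits$id_q), , drop = FALSE]
}

# best hit of every query fragment against the subject set; returns a
# data.frame with one row per query that has a qualifying hit.
.best_hits <- function(frags_q, frags_s, method = c("kmer", "exhaustive"),
                       k = 15L, min_coverage = 0.35, min_identity = 0,
                       max_candidates = 3L) {
  method <- match.arg(method)
  if (method == "exhaustive") {
    grid <- expand.grid(iq = seq_len(nrow(frags_q)), is = seq_len(nrow(frags_s)))
    cand <- data.frame(id_q = frags_q$id[grid$iq], id_s = frags_s$id[grid$is],
                       strand = "+", stringsAsFactors = FALSE)
    cand <- rbind(cand, transform(cand, strand = "-"))
  } else {
    cand <- as.data.frame(.kmer_candidates(frags_q, frags_s, k = k,
                                           max_candidates = max_candidates))
    if (nrow(cand) == 0L) return(NULL)
  }
  qseq <- frags_q$seq[match(cand$id_q, frags_q$id)]
  sseq <- frags_s$seq[match(cand$id_s, frags_s$id)]
  rc <- cand$strand == "-"
  if (any(rc)) sseq[rc] <- .revcomp_chr(sseq[rc])
  aln <- .align_pairs(qseq, sseq)
  cand$identity <- aln$identity
  cand$columns <- aln$columns
  cand$coverage <- pmin(aln$coverage, 1)
  .pick_best(cand, min_coverage, min_identity)
}

#' Best alignment hit of one fragment against a subject fragment set
#'
#' Exhaustive search (both strands) for the subject fragment with maximal
#' global-alignment identity, subject to minimum query coverage and identity;
#' ties go to the lower subject fragment id. Returns `NULL` when no subject
#' qualifies.
#'
#' @param fragment one row of [fragment_genome()] output (or any list with
#'   `id` and `seq`).
#' @param subject_fragments [fragment_genome()] output.
#' @param min_coverage minimum aligned query fraction.
#' @param min_identity minimum identity.
#' @return one-row data.frame `id_q`, `id_s`, `strand`, `identity`,
#'   `columns`, `coverage`, or `NULL`.
#' @export
best_fragment_hit <- function(fragment, subject_fragments,
                              min_coverage = 0.35, min_identity = 0) {
  if (nrow(subject_fragments) == 0L) stop_bad("subject set is empty")
  fq <- data.frame(id = fragment$id %||% 1L, seq = fragment$seq,
                   stringsAsFactors = FALSE)
  .best_hits(fq, subject_fragments, method = "exhaustive",
             min_coverage = min_coverage, min_identity = min_identity)
}

#' Reciprocal-best orthologous fragment pairs
#'
#' Pairs `(i, j)` such that `j` is the best hit of `i` in B and `i` is the
#' best hit of `j` in A; every fragment joins at most one pair.
#'
#' @param frags_a,frags_b [fragment_genome()] outputs.
#' @param method `"kmer"` (shared-k-mer prefilter, default) or `"exhaustive"`
#'   (all-vs-all; test oracle, small inputs only).
#' @inheritParams best_fragment_hit
#' @param k k-mer size for the prefilter.
#' @param max_candidates subjects aligned per query under the prefilter.
#' @return data.frame `id_a`, `id_b`, `identity_ab`, `identity_ba`,
#'   `identity` (their mean); zero rows when nothing is reciprocal.
#' @export
orthologous_pairs <- function(frags_a, frags_b, method = c("kmer", "exhaustive"),
                              k = 15L, min_coverage = 0.35, min_identity = 0,
                              max_candidates = 3L) {
  if (nrow(frags_a) == 0L || nrow(frags_b) == 0L)
    stop_bad("both fragment sets must be non-empty")
  method <- match.arg(method)
  ab <- .best_hits(frags_a, frags_b, method, k, min_coverage, min_identity,
                   max_candidates)
  ba <- .best_hits(frags_b, frags_a, method, k, min_coverage, min_identity,
                   max_candidates)
  empty <- data.frame(id_a = integer(0), id_b = integer(0),
                      identity_ab = numeric(0), identity_ba = numeric(0),
                      identity = numeric(0))
  if (is.null(ab) || is.null(ba)) return(empty)
  key_ab <- paste(ab$id_q, ab$id_s)
  key_ba <- paste(ba$id_s, ba$id_q)
  m <- match(key_ab, key_ba)
  keep <- !is.na(m)
  if (!any(keep)) return(empty)
  out <- data.frame(id_a = ab$id_q[keep], id_b = ab$id_s[keep],
                    identity_ab = ab$identity[keep],
                    identity_ba = ba$identity[m[keep]])
  out$identity <- (out$identity_ab + out$identity_ba) / 2
  out[order(out$id_a), , drop = FALSE]
}

#' Compute OANI between two genome assemblies
#'
#' @param genome_a,genome_b `genome` objects (each must yield at least two
#'   fragments).
#' @inheritParams orthologous_pairs
#' @param fragment_length fragment size in bp.
#' @param lower,upper species-delineation band in percent (defaults 95 and
#'   96).
#' @return an `ani_result`: list with `oani` (percent),
#'   `n_orthologous_pairs`, `pairs` (per-pair identities), `zone`
#'   (see [classify_ani()]) and `params`.
#' @export
compute_oani <- function(genome_a, genome_b, fragment_length = 1020L,
                         method = c("kmer", "exhaustive"), k = 15L,
                         min_coverage = 0.35, min_identity = 0,
                         max_candidates = 3L, lower = 95, upper = 96) {
  method <- match.arg(method)
  fa <- fragment_genome(genome_a, fragment_length)
  fb <- fragment_genome(genome_b, fragment_length)
  if (nrow(fa) < 2L || nrow(fb) < 2L)
    stop_bad("each genome must yield at least two fragments")
  pairs <- orthologous_pairs(fa, fb, method = method, k = k,
                             min_coverage = min_coverage,
                             min_identity = min_identity,
                             max_candidates = max_candidates)
  if (nrow(pairs) == 0L)
    stop_bad("no orthologous fragment pairs found between the two genomes")
  oani <- 100 * mean(pairs$identity)
  structure(list(oani = oani,
                 n_orthologous_pairs = nrow(pairs),
                 pairs = pairs,
                 zone = classify_ani(oani, lower, upper),
                 params = list(fragment_length = fragment_length,
                               method = method, k = k,
                               min_coverage = min_coverage,
                               min_identity = min_identity,
                               lower = lower, upper = upper)),
            class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("<ani_result> OANI = %.3f%% over %d orthologous fragment pairs (zone: %s)\n",
              x$oani, x$n_orthologous_pairs, x$zone))
  invisible(x)
}

#' Classify an OANI value against the species-delineation band
#'
#' Below `lower` the pair is called `distinct`; above `upper`, `conspecific`;
#' inside the band (inclusive), `ambiguous`. The band is reported, never
#' collapsed to a binary call.
#'
#' @param oani OANI in percent.
#' @param lower,upper band bounds in percent, `lower < upper`.
#' @return one of `"distinct"`, `"ambiguous"`, `"conspecific"` (vectorized).
#' @export
classify_ani <- function(oani, lower = 95, upper = 96) {
  if (!is.numeric(lower) || !is.numeric(upper) || lower >= upper)
    stop_bad("thresholds inverted: need lower < upper")
  if (any(oani < 0 | oani > 100, na.rm = TRUE))
    stop_bad("oani must lie in [0, 100]")
  ifelse(oani < lower, "distinct",
         ifelse(oani > upper, "conspecific", "ambiguous"))
}
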