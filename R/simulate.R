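# Synthetic lineage generator: divergence, introgression, rearrangements,
# coverage, crosses and growth curves, each with a recorded truth set.
#
# The mutation model is deliberately minimal: uniform substitutions at
# independent sites, no indels, back-mutation allowed when two branches hit
# the same site. For two branches at per-site rates p and q the expected
# differing fraction is p + q - (4/3)pq.

BASES <- c("A", "C", "G", "T")

#' Generate a random ancestral genome
#'
#' @param length chromosome length in bp (scalar, recycled, or one per
#'   chromosome).
#' @param n_chromosomes number of chromosomes.
#' @param gc_content target GC fraction in `[0, 1]`.
#' @param seed integer seed; the same seed reproduces the genome byte for
#'   byte.
#' @param chrom_names optional chromosome names (default `chrI`, `chrII`, ...).
#' @return a [as_genome()] object.
#' @export
generate_ancestor <- function(length, n_chromosomes = 1L, gc_content = 0.38,
                              seed = 1L, chrom_names = NULL) {
  if (!all(vapply(length, .is_count, logical(1))) || any(length <= 0))
    stop_bad("chromosome length must be a positive integer")
  if (!.is_count(n_chromosomes) || n_chromosomes < 1)
    stop_bad("n_chromosomes must be a positive integer")
  if (!.is_fraction(gc_content))
    stop_bad("gc_content must lie in [0, 1]")
  lens <- rep_len(as.integer(length), n_chromosomes)
  if (is.null(chrom_names))
    chrom_names <- paste0("chr", as.character(utils::as.roman(seq_len(n_chromosomes))))
  prob <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
            (1 - gc_content) / 2)
  seqs <- withr::with_seed(derive_seed(seed, "generate_ancestor"), {
    lapply(lens, function(L)
      paste(sample(BASES, L, replace = TRUE, prob = prob), collapse = ""))
  })
  as_genome(stats::setNames(unlist(seqs), chrom_names))
}

#' Evolve a descendant lineage by point substitutions
#'
#' Each site mutates independently with probability `divergence`; a mutated
#' site receives a uniformly chosen different base. No indels, so descendant
#' and ancestor stay coordinate-matched.
#'
#' @param ancestor a `genome`.
#' @param divergence per-site substitution fraction in `[0, 0.25]`.
#' @param seed integer seed.
#' @return list with `genome` (the descendant) and `truth`, a data.frame of
#'   mutated sites (`chrom`, `pos` 1-based, `ref`, `alt`).
#' @export
evolve_lineage <- function(ancestor, divergence, seed = 1L) {
  stopifnot(is_genome(ancestor))
  if (!is.numeric(divergence) || length(divergence) != 1L ||
      is.na(divergence) || divergence < 0 || divergence > 0.25)
    stop_bad("divergence must lie in [0, 0.25]")
  res <- withr::with_seed(derive_seed(seed, "evolve_lineage"), {
    out <- ancestor
    truth <- vector("list", length(ancestor))
    for (i in seq_along(ancestor)) {
      chars <- strsplit(ancestor[[i]], "", fixed = TRUE)[[1]]
      L <- length(chars)
      n_mut <- stats::rbinom(1L, L, divergence)
      if (n_mut > 0L) {
        pos <- sort(sample.int(L, n_mut))
        ref <- chars[pos]
        # uniform among the three non-ancestral bases
        shift <- sample.int(3L, n_mut, replace = TRUE)
        alt <- BASES[(match(ref, BASES) - 1L + shift) %% 4L + 1L]
        chars[pos] <- alt
        truth[[i]] <- data.frame(chrom = rep(names(ancestor)[i], n_mut),
                                 pos = pos, ref = ref, alt = alt,
                                 stringsAsFactors = FALSE)
      }
      out[[i]] <- paste(chars, collapse = "")
    }
    list(genome = as_genome(unclass(out)),
         truth = do.call(rbind, truth) %||%
           data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0)))
  })
  res
}

#' Implant introgression tracts from a donor genome
#'
#' Replaces the recipient sequence by the donor sequence over each tract.
#' Recipient and donor must be coordinate-matched on the affected chromosomes
#' (no prior rearrangements there). Tract coordinates are 0-based half-open
#' internally; the truth table also carries the 1-based inclusive form used in
#' emitted reports.
#'
#' @param recipient,donor `genome` objects sharing coordinates.
#' @param tracts data.frame with columns `chrom`, `start` (0-based), `length`
#'   and optionally `donor` (label).
#' @return list with `genome` and `truth` (tracts with both coordinate
#'   conventions).
#' @export
implant_introgression <- function(recipient, donor, tracts) {
  stopifnot(is_genome(recipient), is_genome(donor))
  need <- c("chrom", "start", "length")
  if (!is.data.frame(tracts) || !all(need %in% names(tracts)))
    stop_bad("tracts must be a data.frame with chrom, start, length")
  if (nrow(tracts) == 0L)
    return(list(genome = recipient,
                truth = data.frame(chrom = character(0), start = integer(0),
                                   end = integer(0), start1 = integer(0),
                                   end1 = integer(0), length = integer(0),
                                   donor = character(0))))
  if (is.null(tracts$donor)) tracts$donor <- "donor"
  lens_r <- chrom_lengths(recipient)
  for (ch in unique(tracts$chrom)) {
    tc <- tracts[tracts$chrom == ch, ]
    if (!ch %in% names(recipient) || !ch %in% names(donor))
      stop_bad("tract chromosome %s absent from recipient or donor", ch)
    if (nchar(recipient[[ch]]) != nchar(donor[[ch]]))
      stop_bad("recipient and donor disagree on length of %s (prior SVs?)", ch)
    if (any(tc$start < 0) || any(tc$start + tc$length > lens_r[[ch]]))
      stop_bad("tract out of bounds on %s", ch)
    if (.intervals_overlap(tc$start, tc$length))
      stop_bad("overlapping tracts on %s", ch)
  }
  out <- recipient
  for (i in seq_len(nrow(tracts))) {
    ch <- tracts$chrom[i]; s <- tracts$start[i]; len <- tracts$length[i]
    substr(out[[ch]], s + 1L, s + len) <- substr(donor[[ch]], s + 1L, s + len)
  }
  truth <- data.frame(chrom = tracts$chrom,
                      start = as.integer(tracts$start),
                      end = as.integer(tracts$start + tracts$length),
                      start1 = as.integer(tracts$start + 1L),
                      end1 = as.integer(tracts$start + tracts$length),
                      length = as.integer(tracts$length),
                      donor = tracts$donor,
                      stringsAsFactors = FALSE)
  list(genome = as_genome(unclass(out)), truth = truth)
}

#' Describe a structural-variant event
#'
#' @param kind one of `reciprocal_translocation`, `nonreciprocal_translocation`,
#'   `inversion`, `deletion`.
#' @param chrom_a first (or only) chromosome. For a reciprocal translocation
#'   the terminal segments `[pos_a, end)` of `chrom_a` and `[pos_b, end)` of
#'   `chrom_b` are exchanged. For a non-reciprocal translocation the segment
#'   `[pos_a, pos_a + size)` of `chrom_a` moves to the end of `chrom_b`.
#' @param chrom_b second chromosome (translocations only).
#' @param pos_a,pos_b 0-based breakpoints.
#' @param size segment size in bp (non-reciprocal translocation, inversion,
#'   deletion).
#' @return an `sv_spec` list.
#' @export
sv_spec <- function(kind, chrom_a, chrom_b = NA_character_,
                    pos_a, pos_b = NA_integer_, size = NA_integer_) {
  kinds <- c("reciprocal_translocation", "nonreciprocal_translocation",
             "inversion", "deletion")
  kind <- match.arg(kind, kinds)
  if (kind == "reciprocal_translocation" &&
      (is.na(chrom_b) || is.na(pos_b)))
    stop_bad("reciprocal translocation needs chrom_b and pos_b")
  if (kind == "nonreciprocal_translocation" && (is.na(chrom_b) || is.na(size)))
    stop_bad("non-reciprocal translocation needs chrom_b and size")
  if (kind %in% c("inversion", "deletion") && (is.na(size) || size < 1))
    stop_bad("%s needs size >= 1", kind)
  structure(list(kind = kind, chrom_a = chrom_a, chrom_b = chrom_b,
                 pos_a = as.integer(pos_a), pos_b = as.integer(pos_b),
                 size = as.integer(size)),
            class = "sv_spec")
}

#' Apply structural-variant events to a genome
#'
#' Events are applied in list order on the current (already rearranged)
#' genome. Total sequence length is conserved except by deletions. The truth
#' table records, per moved/changed segment, its source interval in the input
#' genome of this call and its destination interval in the output genome
#' (0-based half-open).
#'
#' @param genome a `genome`.
#' @param events list of [sv_spec()] objects.
#' @return list with `genome` and `truth` data.frame (`event`, `kind`,
#'   `src_chrom`, `src_start`, `src_end`, `dst_chrom`, `dst_start`,
#'   `dst_end`).
#' @export
apply_svs <- function(genome, events) {
  stopifnot(is_genome(genome))
  if (inherits(events, "sv_spec")) events <- list(events)
  g <- unclass(genome)
  rows <- list()
  rec <- function(ev, kind, sc, ss, se, dc, ds, de) {
    rows[[length(rows) + 1L]] <<- data.frame(
      event = ev, kind = kind, src_chrom = sc,
      src_start = as.integer(ss), src_end = as.integer(se),
      dst_chrom = dc, dst_start = as.integer(ds), dst_end = as.integer(de),
      stringsAsFactors = FALSE)
  }
  for (i in seq_along(events)) {
    e <- events[[i]]
    stopifnot(inherits(e, "sv_spec"))
    if (!e$chrom_a %in% names(g))
      stop_bad("unknown chromosome %s", e$chrom_a)
    La <- nchar(g[[e$chrom_a]])
    switch(e$kind,
      reciprocal_translocation = {
        if (!e$chrom_b %in% names(g)) stop_bad("unknown chromosome %s", e$chrom_b)
        Lb <- nchar(g[[e$chrom_b]])
        if (e$pos_a < 0 || e$pos_a > La || e$pos_b < 0 || e$pos_b > Lb)
          stop_bad("breakpoint beyond chromosome end")
        seg_a <- substr(g[[e$chrom_a]], e$pos_a + 1L, La) # leaves A
        seg_b <- substr(g[[e$chrom_b]], e$pos_b + 1L, Lb) # leaves B
        g[[e$chrom_a]] <- paste0(substr(g[[e$chrom_a]], 1L, e$pos_a), seg_b)
        g[[e$chrom_b]] <- paste0(substr(g[[e$chrom_b]], 1L, e$pos_b), seg_a)
        rec(i, e$kind, e$chrom_b, e$pos_b, Lb,
            e$chrom_a, e$pos_a, e$pos_a + (Lb - e$pos_b))
        rec(i, e$kind, e$chrom_a, e$pos_a, La,
            e$chrom_b, e$pos_b, e$pos_b + (La - e$pos_a))
      },
      nonreciprocal_translocation = {
        if (!e$chrom_b %in% names(g)) stop_bad("unknown chromosome %s", e$chrom_b)
        if (e$pos_a < 0 || e$pos_a + e$size > La)
          stop_bad("breakpoint beyond chromosome end")
        seg <- substr(g[[e$chrom_a]], e$pos_a + 1L, e$pos_a + e$size)
        g[[e$chrom_a]] <- paste0(substr(g[[e$chrom_a]], 1L, e$pos_a),
                                 substr(g[[e$chrom_a]], e$pos_a + e$size + 1L, La))
        Lb <- nchar(g[[e$chrom_b]])
        g[[e$chrom_b]] <- paste0(g[[e$chrom_b]], seg)
        rec(i, e$kind, e$chrom_a, e$pos_a, e$pos_a + e$size,
            e$chrom_b, Lb, Lb + e$size)
      },
      inversion = {
        if (e$pos_a < 0 || e$pos_a + e$size > La)
          stop_bad("breakpoint beyond chromosome end")
        seg <- substr(g[[e$chrom_a]], e$pos_a + 1L, e$pos_a + e$size)
        rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seg)))
        substr(g[[e$chrom_a]], e$pos_a + 1L, e$pos_a + e$size) <- rc
        rec(i, e$kind, e$chrom_a, e$pos_a, e$pos_a + e$size,
            e$chrom_a, e$pos_a, e$pos_a + e$size)
      },
      deletion = {
        if (e$pos_a < 0 || e$pos_a + e$size > La)
          stop_bad("breakpoint beyond chromosome end")
        g[[e$chrom_a]] <- paste0(substr(g[[e$chrom_a]], 1L, e$pos_a),
                                 substr(g[[e$chrom_a]], e$pos_a + e$size + 1L, La))
        rec(i, e$kind, e$chrom_a, e$pos_a, e$pos_a + e$size,
            NA_character_, NA_integer_, NA_integer_)
      })
  }
  truth <- do.call(rbind, rows) %||%
    data.frame(event = integer(0), kind = character(0),
               src_chrom = character(0), src_start = integer(0),
               src_end = integer(0), dst_chrom = character(0),
               dst_start = integer(0), dst_end = integer(0))
  list(genome = as_genome(g), truth = truth)
}

#' Simulate per-window read coverage
#'
#' Per-base depth is Poisson with mean `mean_cov`; the emitted value is the
#' window mean, i.e. `Poisson(mean_cov * width) / width`, so short terminal
#' windows are pro-rated and wider windows have proportionally tighter
#' means (sd ~ sqrt(mean_cov / width)), as in real mapping coverage.
#'
#' @param genome a `genome`.
#' @param mean_cov expected coverage (x).
#' @param window window size in bp.
#' @param seed integer seed.
#' @return data.frame `chrom`, `start` (0-based), `end`, `mean_cov`.
#' @export
simulate_coverage <- function(genome, mean_cov = 30, window = 1000L, seed = 1L) {
  stopifnot(is_genome(genome))
  if (!is.numeric(mean_cov) || mean_cov <= 0) stop_bad("mean_cov must be > 0")
  if (!.is_count(window) || window < 1) stop_bad("window must be >= 1")
  lens <- chrom_lengths(genome)
  tabs <- withr::with_seed(derive_seed(seed, "simulate_coverage"), {
    lapply(names(lens), function(ch) {
      L <- lens[[ch]]
      start <- as.integer(seq.int(0L, L - 1L, by = window))
      end <- as.integer(pmin(start + window, L))
      w <- end - start
      data.frame(chrom = ch, start = start, end = end,
                 mean_cov = stats::rpois(length(start), mean_cov * w) / w,
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, tabs)
}

#' Expected spore viability of a hybrid cross
#'
#' The generator's viability model: `v0 * exp(-alpha * divergence) * 0.5^s`
#' where `s` counts heterozygous reciprocal translocations (each halves the
#' fraction of balanced meiotic products).
#'
#' @param divergence pairwise nucleotide divergence fraction.
#' @param n_het_reciprocal_translocations count `s`.
#' @param v0 baseline viability percent in `(0, 100]`.
#' @param alpha viability decay per unit divergence.
#' @return expected viability percent.
#' @export
expected_viability <- function(divergence, n_het_reciprocal_translocations = 0L,
                               v0 = 95, alpha = 40) {
  if (!is.numeric(v0) || v0 <= 0 || v0 > 100) stop_bad("v0 must be in (0, 100]")
  v0 * exp(-alpha * divergence) * 0.5^n_het_reciprocal_translocations
}

#' Simulate a tetrad-dissection cross
#'
#' Draws the viable-spore count as Binomial(n_spores, expected/100) under the
#' [expected_viability()] model.
#'
#' @inheritParams expected_viability
#' @param n_spores number of dissected spores (>= 1).
#' @param seed integer seed.
#' @param parent_a,parent_b strain labels carried through to the record.
#' @return one-row data.frame: `parent_a`, `parent_b`, `dissected`, `viable`,
#'   `viability` (percent), `expected_viability`, `divergence`, `n_het_rt`.
#' @export
simulate_cross <- function(divergence, n_het_reciprocal_translocations = 0L,
                           v0 = 95, alpha = 40, n_spores = 96L, seed = 1L,
                           parent_a = "A", parent_b = "B") {
  if (!.is_count(n_spores) || n_spores < 1) stop_bad("n_spores must be >= 1")
  ev <- expected_viability(divergence, n_het_reciprocal_translocations, v0, alpha)
  viable <- withr::with_seed(derive_seed(seed, "simulate_cross"),
                             stats::rbinom(1L, n_spores, ev / 100))
  data.frame(parent_a = parent_a, parent_b = parent_b,
             dissected = as.integer(n_spores), viable = viable,
             viability = 100 * viable / n_spores,
             expected_viability = ev, divergence = divergence,
             n_het_rt = as.integer(n_het_reciprocal_translocations),
             stringsAsFactors = FALSE)
}

#' Simulate a logistic growth curve
#'
#' `N(t) = K / (1 + ((K - N0)/N0) exp(-r t))` plus Gaussian noise, clipped at
#' zero; mirrors optical-density microcultivation readings taken on a uniform
#' grid.
#'
#' @param K carrying capacity (OD units), must exceed `N0`.
#' @param r intrinsic growth rate per hour, > 0.
#' @param N0 initial size (OD), > 0.
#' @param duration total time in hours.
#' @param step sampling step in hours.
#' @param noise_sd Gaussian noise standard deviation (OD).
#' @param seed integer seed.
#' @return data.frame `time_h`, `od`.
#' @export
simulate_growth <- function(K = 1, r = 0.5, N0 = 0.05, duration = 48,
                            step = 0.5, noise_sd = 0, seed = 1L) {
  if (!(K > N0 && N0 > 0)) stop_bad("need K > N0 > 0")
  if (!is.numeric(r) || r <= 0) stop_bad("r must be > 0")
  t <- seq(0, duration, by = step)
  n <- K / (1 + ((K - N0) / N0) * exp(-r * t))
  if (noise_sd > 0) {
    n <- withr::with_seed(derive_seed(seed, "simulate_growth"),
                          n + stats::rnorm(length(t), 0, noise_sd))
    n <- pmax(n, 0)
  }
  data.frame(time_h = t, od = n)
}
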