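# Diversity, differentiation, divergence and divergence-time statistics on a
# biallelic SNP table, plus variant filtering/thinning and a distance-tree
# utility.

#' Biallelic SNP table
#'
#' Sites-by-samples genotype container. Genotypes are alt-allele dosage in
#' `[0, 1]` (0/1 for haploids or homozygous diploid collapse; a heterozygous
#' diploid call contributes 0.5). Positions are 1-based and strictly
#' increasing within a chromosome.
#'
#' @param sites data.frame with `chrom`, `pos`, `ref`, `alt` and optionally
#'   `depth`, `qual`.
#' @param geno numeric matrix, sites x samples, dosages in `[0, 1]` or `NA`.
#' @param populations named character vector mapping sample name to
#'   population label.
#' @param L callable genome length in bp (denominator of per-site
#'   statistics).
#' @return an object of class `variant_table`.
#' @export
variant_table <- function(sites, geno, populations, L) {
  need <- c("chrom", "pos", "ref", "alt")
  if (!is.data.frame(sites) || !all(need %in% names(sites)))
    stop_bad("sites must carry chrom, pos, ref, alt")
  geno <- as.matrix(geno)
  if (nrow(geno) != nrow(sites))
    stop_bad("geno must have one row per site")
  if (is.null(colnames(geno)))
    stop_bad("geno must carry sample names as column names")
  if (!all(names(populations) %in% colnames(geno)) ||
      !all(colnames(geno) %in% names(populations)))
    stop_bad("populations must name exactly the samples in geno")
  if (!is.numeric(L) || length(L) != 1L || L <= 0)
    stop_bad("callable length L must be a positive number")
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (any(diff(p) <= 0))
      stop_bad("positions must be strictly increasing within %s", ch)
  }
  structure(list(sites = sites, geno = geno,
                 populations = populations[colnames(geno)], L = L),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("<variant_table> %d sites x %d samples (%d population(s)), L = %s bp\n",
              nrow(x$sites), ncol(x$geno), length(unique(x$populations)),
              format(x$L, big.mark = ",")))
  invisible(x)
}

#' @rdname variant_table
#' @export
n_sites <- function(x) nrow(x$sites)

.pop_cols <- function(vt, population) {
  idx <- which(vt$populations == population)
  if (length(idx) == 0L) stop_bad("no samples in population %s", population)
  idx
}

#' Build a variant table from coordinate-matched sample genomes
#'
#' Diffs each sample genome against the reference; sites with more than one
#' alternate allele across samples are dropped (biallelic-only contract).
#'
#' @param samples named list of `genome` objects (coordinate-matched with the
#'   reference).
#' @param reference a `genome`.
#' @param populations named character vector, sample name to population.
#' @param L callable length; defaults to the reference length (with a
#'   warning, since callable length is normally shorter).
#' @return a [variant_table()].
#' @export
variant_table_from_genomes <- function(samples, reference, populations,
                                       L = NULL) {
  stopifnot(is.list(samples), length(samples) >= 1L, is_genome(reference))
  if (is.null(names(samples)) || anyDuplicated(names(samples)))
    stop_bad("samples must be a uniquely named list")
  if (is.null(L)) {
    L <- genome_length(reference)
    warning("callable length L not supplied; using full reference length",
            call. = FALSE)
  }
  diffs <- lapply(samples, genome_diff_positions, a = reference)
  all_sites <- unique(do.call(rbind, lapply(diffs, function(d)
    d[, c("chrom", "pos", "ref", "alt")])))
  if (nrow(all_sites) == 0L) {
    sites <- data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0))
    geno <- matrix(numeric(0), 0, length(samples),
                   dimnames = list(NULL, names(samples)))
    return(variant_table(sites, geno, populations, L))
  }
  key <- paste(all_sites$chrom, all_sites$pos)
  multi <- unique(key[duplicated(key)]) # >1 alt allele at a position
  sites <- all_sites[!key %in% multi, , drop = FALSE]
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  skey <- paste(sites$chrom, sites$pos, sites$alt)
  geno <- matrix(0, nrow(sites), length(samples),
                 dimnames = list(NULL, names(samples)))
  for (s in names(samples)) {
    d <- diffs[[s]]
    geno[match(paste(d$chrom, d$pos, d$alt), skey, nomatch = 0L), s] <- 1
  }
  rownames(sites) <- NULL
  variant_table(sites, geno, populations, L)
}

#' Filter variant sites on depth, quality and missingness
#'
#' Depth is filtered strictly (`depth > min_depth`), quality as
#' `qual >= min_quality`; sites with any missing genotype are always removed.
#' Pass `NULL` for either threshold to skip that filter.
#'
#' @param table a [variant_table()].
#' @param min_depth minimum read depth (exclusive); requires a `depth` column.
#' @param min_quality minimum site quality (inclusive); requires a `qual`
#'   column.
#' @return filtered `variant_table`; attribute `"filter_counts"` reports how
#'   many sites each rule removed.
#' @export
filter_variants <- function(table, min_depth = 10, min_quality = 30) {
  stopifnot(inherits(table, "variant_table"))
  keep <- rep(TRUE, n_sites(table))
  counts <- c(depth = 0L, quality = 0L, missing = 0L)
  if (!is.null(min_depth)) {
    if (is.null(table$sites$depth))
      stop_bad("depth filtering requested but sites carry no depth column")
    bad <- !(table$sites$depth > min_depth)
    counts["depth"] <- sum(bad & keep); keep <- keep & !bad
  }
  if (!is.null(min_quality)) {
    if (is.null(table$sites$qual))
      stop_bad("quality filtering requested but sites carry no qual column")
    bad <- !(table$sites$qual >= min_quality)
    counts["quality"] <- sum(bad & keep); keep <- keep & !bad
  }
  bad <- apply(is.na(table$geno), 1L, any)
  counts["missing"] <- sum(bad & keep); keep <- keep & !bad
  out <- variant_table(table$sites[keep, , drop = FALSE],
                       table$geno[keep, , drop = FALSE],
                       table$populations, table$L)
  attr(out, "filter_counts") <- counts
  out
}

#' Thin sites to a minimum spacing
#'
#' Greedy scan per chromosome: keep the first site, then every site at least
#' `min_spacing` bp from the last kept site (the `--thin` convention).
#'
#' @param x sorted numeric position vector (one chromosome) or a
#'   [variant_table()].
#' @param min_spacing minimum distance in bp between kept sites.
#' @return object of the same type as `x`, thinned.
#' @export
thin_variants <- function(x, min_spacing = 500) {
  UseMethod("thin_variants")
}

#' @export
thin_variants.numeric <- function(x, min_spacing = 500) {
  if (is.unsorted(x)) stop_bad("positions must be sorted")
  if (length(x) == 0L || min_spacing <= 0) return(x)
  keep <- logical(length(x))
  last <- -Inf
  for (i in seq_along(x)) {
    if (x[i] - last >= min_spacing) {
      keep[i] <- TRUE
      last <- x[i]
    }
  }
  x[keep]
}

#' @export
thin_variants.variant_table <- function(x, min_spacing = 500) {
  keep <- unlist(lapply(split(seq_len(n_sites(x)), x$sites$chrom), function(idx) {
    kept <- thin_variants(as.numeric(x$sites$pos[idx]), min_spacing)
    idx[x$sites$pos[idx] %in% kept]
  }), use.names = FALSE)
  keep <- sort(keep)
  variant_table(x$sites[keep, , drop = FALSE], x$geno[keep, , drop = FALSE],
                x$populations, x$L)
}

#' Nucleotide diversity and Watterson's theta for one population
#'
#' Per-site pairwise diversity
#' `pi = sum_sites 2 p (1 - p) n / (n - 1) / L`, which equals the mean
#' pairwise difference count over all sample pairs divided by `L`, and the
#' Watterson estimator `theta_w = S / (a_n L)` with
#' `a_n = sum_{i=1}^{n-1} 1/i` over the same population.
#'
#' @param table a [variant_table()].
#' @param population population label (>= 2 samples).
#' @return list of class `diversity_result`: `pi`, `theta_w`, `S`, `n`, `L`,
#'   `a_n`.
#' @export
nucleotide_diversity <- function(table, population) {
  stopifnot(inherits(table, "variant_table"))
  idx <- .pop_cols(table, population)
  n <- length(idx)
  if (n < 2L) stop_bad("population %s has fewer than 2 samples", population)
  g <- table$geno[, idx, drop = FALSE]
  if (anyNA(g)) stop_bad("missing genotypes present; filter first")
  p <- rowMeans(g)
  pi <- sum(2 * p * (1 - p)) * n / (n - 1) / table$L
  S <- sum(p > 0 & p < 1)
  structure(list(pi = pi, theta_w = watterson_theta(S, n, table$L),
                 S = S, n = n, L = table$L,
                 a_n = sum(1 / seq_len(n - 1L))),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("<diversity_result> pi = %.6g, theta_w = %.6g (S = %d, n = %d, L = %s)\n",
              x$pi, x$theta_w, x$S, x$n, format(x$L, big.mark = ",")))
  invisible(x)
}

#' Watterson's per-site theta
#'
#' @param S segregating-site count.
#' @param n number of sampled haplotypes (>= 2).
#' @param L callable length in bp.
#' @return `S / (a_n * L)` with `a_n = sum_{i=1}^{n-1} 1/i`.
#' @export
watterson_theta <- function(S, n, L) {
  if (!.is_count(S)) stop_bad("S must be a non-negative integer")
  if (!.is_count(n) || n < 2) stop_bad("n must be an integer >= 2")
  if (!is.numeric(L) || L <= 0) stop_bad("L must be > 0")
  S / (sum(1 / seq_len(n - 1L)) * L)
}

#' Mean pairwise divergence between two groups
#'
#' Mean over all cross-group sample pairs of the per-pair differing-site
#' count divided by `L`. Also accepts two coordinate-matched genomes, in
#' which case the column-wise differing fraction is returned.
#'
#' @param x a [variant_table()], or a `genome` (with `group_a` a second
#'   `genome`).
#' @param group_a,group_b disjoint character vectors of sample names or
#'   population labels (variant-table method).
#' @param ... unused.
#' @return divergence fraction.
#' @export
pairwise_divergence <- function(x, group_a, group_b = NULL, ...) {
  UseMethod("pairwise_divergence")
}

#' @export
pairwise_divergence.genome <- function(x, group_a, group_b = NULL, ...) {
  genome_divergence(x, group_a)
}

#' @export
pairwise_divergence.variant_table <- function(x, group_a, group_b = NULL, ...) {
  resolve <- function(g) {
    if (all(g %in% colnames(x$geno))) return(g)
    if (all(g %in% x$populations))
      return(names(x$populations)[x$populations %in% g])
    stop_bad("group members must be sample names or population labels")
  }
  a <- resolve(group_a); b <- resolve(group_b)
  if (length(a) == 0L || length(b) == 0L) stop_bad("groups must be non-empty")
  if (length(intersect(a, b)) > 0L) stop_bad("groups overlap")
  g <- x$geno
  if (anyNA(g)) stop_bad("missing genotypes present; filter first")
  tot <- 0
  for (i in a) for (j in b) tot <- tot + sum(abs(g[, i] - g[, j]))
  tot / (length(a) * length(b)) / x$L
}

#' Hudson-style Fst between two populations
#'
#' Ratio-of-averages estimator:
#' `Fst = sum_sites N / sum_sites D` with
#' `N = (p_a - p_b)^2 - p_a(1-p_a)/(n_a-1) - p_b(1-p_b)/(n_b-1)` and
#' `D = p_a(1-p_b) + p_b(1-p_a)`. The estimator name is carried in the result
#' since different packages default to different estimators.
#'
#' @param table a [variant_table()].
#' @param pop_a,pop_b population labels, each with >= 2 samples.
#' @return list of class `fst_result`: `fst`, `estimator`, `per_site`
#'   (data.frame of N and D).
#' @export
hudson_fst <- function(table, pop_a, pop_b) {
  stopifnot(inherits(table, "variant_table"))
  ia <- .pop_cols(table, pop_a); ib <- .pop_cols(table, pop_b)
  na <- length(ia); nb <- length(ib)
  if (na < 2L || nb < 2L) stop_bad("both populations need >= 2 samples")
  ga <- table$geno[, ia, drop = FALSE]; gb <- table$geno[, ib, drop = FALSE]
  if (anyNA(ga) || anyNA(gb)) stop_bad("missing genotypes present; filter first")
  pa <- rowMeans(ga); pb <- rowMeans(gb)
  N <- (pa - pb)^2 - pa * (1 - pa) / (na - 1) - pb * (1 - pb) / (nb - 1)
  D <- pa * (1 - pb) + pb * (1 - pa)
  if (sum(D) == 0)
    stop_bad("no between-population variation at any site (denominator 0)")
  structure(list(fst = sum(N) / sum(D),
                 estimator = "Hudson ratio-of-averages",
                 per_site = data.frame(N = N, D = D)),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("<fst_result> Fst = %.4f (%s, %d sites)\n",
              x$fst, x$estimator, nrow(x$per_site)))
  invisible(x)
}

#' Generations (and years) since divergence
#'
#' Applies the mutation parameter `theta = 2 N mu` at the divergence scale:
#' the number of generations separating two lineages at pairwise divergence
#' `d` is `d / (2 mu)`. Calendar bounds follow from a configurable
#' generations-per-year range (default 164-1870 per year, i.e. roughly
#' 0.45-5.1 divisions per day).
#'
#' @param d pairwise nucleotide divergence fraction (>= 0).
#' @param mu per-site per-generation mutation rate (default 1.84e-10, the
#'   yeast single-base rate).
#' @param generations_per_year length-2 numeric range.
#' @return list of class `divtime_result`: `d`, `mu`, `generations`,
#'   `years_low`, `years_high`.
#' @export
generations_since_divergence <- function(d, mu = 1.84e-10,
                                         generations_per_year = c(164, 1870)) {
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0)
    stop_bad("d must be a non-negative number")
  if (!is.numeric(mu) || mu <= 0) stop_bad("mu must be > 0")
  if (length(generations_per_year) != 2L || any(generations_per_year <= 0))
    stop_bad("generations_per_year must be a positive length-2 range")
  gpy <- sort(generations_per_year)
  gen <- d / (2 * mu)
  structure(list(d = d, mu = mu, generations = gen,
                 years_low = gen / gpy[2L], years_high = gen / gpy[1L],
                 generations_per_year = gpy),
            class = "divtime_result")
}

#' @export
print.divtime_result <- function(x, ...) {
  cat(sprintf("<divtime_result> d = %.4g: %.4g generations (~%.0f-%.0f KYA at %g-%g gen/yr)\n",
              x$d, x$generations, x$years_low / 1000, x$years_high / 1000,
              x$generations_per_year[1L], x$generations_per_year[2L]))
  invisible(x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' @param distance_matrix symmetric zero-diagonal matrix (or `dist`) over
#'   >= 3 taxa.
#' @return Newick string (with the `ape::phylo` object attached as attribute
#'   `"tree"`); additive matrices are recovered exactly.
#' @export
nj_tree <- function(distance_matrix) {
  if (inherits(distance_matrix, "dist"))
    distance_matrix <- as.matrix(distance_matrix)
  if (!is.matrix(distance_matrix) || nrow(distance_matrix) != ncol(distance_matrix))
    stop_bad("distance matrix must be square")
  if (nrow(distance_matrix) < 3L) stop_bad("need at least 3 taxa")
  if (max(abs(distance_matrix - t(distance_matrix))) > 1e-8)
    stop_bad("distance matrix must be symmetric")
  if (any(abs(diag(distance_matrix)) > 1e-12))
    stop_bad("distance matrix must have a zero diagonal")
  tree <- ape::nj(stats::as.dist(distance_matrix))
  structure(ape::write.tree(tree), tree = tree)
}
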