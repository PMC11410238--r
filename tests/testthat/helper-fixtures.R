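# Shared fixture builders. Everything is generated in code, seeded, and
# small enough to keep the suite fast.

fixture_genome <- function(len = 5000, n_chrom = 2, seed = 42, gc = 0.4) {
  generate_ancestor(len, n_chrom, gc, seed = seed)
}

# two descendants of a common ancestor, realized divergence ~ 2 * branch
fixture_pair <- function(len = 10000, n_chrom = 1, branch = 0.015, seed = 1) {
  anc <- generate_ancestor(len, n_chrom, seed = seed)
  list(ancestor = anc,
       a = evolve_lineage(anc, branch, seed = seed + 100)$genome,
       b = evolve_lineage(anc, branch, seed = seed + 200)$genome)
}

# haploid genotype matrix with the given alt counts per site (one population);
# alt alleles fill the leading samples, which leaves frequencies unchanged
fixture_geno <- function(alt_counts, n_samples, prefix = "s") {
  m <- t(vapply(alt_counts, function(k)
    c(rep(1, k), rep(0, n_samples - k)), numeric(n_samples)))
  colnames(m) <- paste0(prefix, seq_len(n_samples))
  m
}

fixture_variant_table <- function(geno, L = 10000, pops = NULL,
                                  chrom = "chrI") {
  n <- nrow(geno)
  sites <- data.frame(chrom = rep(chrom, n), pos = seq_len(n) * 10,
                      ref = rep("A", n), alt = rep("T", n))
  if (is.null(pops))
    pops <- stats::setNames(rep("all", ncol(geno)), colnames(geno))
  variant_table(sites, geno, pops, L)
}

# brute-force mean pairwise difference count / L (pi oracle)
oracle_pi <- function(geno, L) {
  n <- ncol(geno)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(abs(geno[, i] - geno[, j]))
    np <- np + 1
  }
  tot / np / L
}

# ordinary least squares by normal equations (regression oracle)
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- X %*% beta
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2], r2 = 1 - rss / tss)
}
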