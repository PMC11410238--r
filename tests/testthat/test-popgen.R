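test_that("thinning follows the greedy spacing rule", {
  expect_identical(thin_variants(c(100, 300, 700, 1300), 500),
                   c(100, 700, 1300))
  expect_identical(thin_variants(42, 500), 42)
  expect_identical(thin_variants(c(1, 2, 3), 0), c(1, 2, 3))
  x <- sort(c(5, 120, 480, 500, 505, 1000, 1600))
  expect_identical(thin_variants(thin_variants(x, 500), 500),
                   thin_variants(x, 500)) # idempotent
  expect_error(thin_variants(c(3, 1, 2)), "sorted")
})

test_that("pi equals the brute-force pairwise oracle", {
  # 2 haplotypes differing at 1 of 1000 sites
  vt <- fixture_variant_table(fixture_geno(1, 2), L = 1000)
  expect_equal(nucleotide_diversity(vt, "all")$pi, 0.001)
  # monomorphic population
  vt0 <- fixture_variant_table(fixture_geno(c(0, 0), 3), L = 1000)
  expect_equal(nucleotide_diversity(vt0, "all")$pi, 0)
  # n = 4, mixed frequencies: formula == mean pairwise differences / L
  g <- fixture_geno(c(1, 2, 3, 1, 2), 4)
  vt4 <- fixture_variant_table(g, L = 5000)
  expect_equal(nucleotide_diversity(vt4, "all")$pi, oracle_pi(g, 5000),
               tolerance = 1e-12)
  expect_error(nucleotide_diversity(fixture_variant_table(fixture_geno(1, 2),
                                                          L = 100,
                                                          pops = c(s1 = "a", s2 = "b")),
                                    "a"),
               "fewer than 2")
})

test_that("Watterson's theta matches the harmonic-sum arithmetic", {
  expect_equal(watterson_theta(0, 5, 1000), 0)
  expect_equal(watterson_theta(5, 4, 1000), 5 / ((1 + 1/2 + 1/3) * 1000),
               tolerance = 1e-12)
  expect_equal(watterson_theta(3, 2, 1000), 0.003)
  expect_error(watterson_theta(3, 1, 1000), ">= 2")
})

test_that("pi and theta_w agree in expectation under a neutral SFS", {
  # infinite-sites stand-in: alt count at each site drawn with P(i) ~ 1/i
  n <- 10; S <- 500
  probs <- (1 / seq_len(n - 1)) / sum(1 / seq_len(n - 1))
  ratios <- withr::with_seed(2024, vapply(1:50, function(r) {
    counts <- sample(seq_len(n - 1), S, replace = TRUE, prob = probs)
    vt <- fixture_variant_table(fixture_geno(counts, n), L = 1e5)
    dv <- nucleotide_diversity(vt, "all")
    dv$pi / dv$theta_w
  }, numeric(1)))
  expect_gt(mean(ratios), 0.9)
  expect_lt(mean(ratios), 1.1)
})

test_that("pairwise divergence averages cross-group differences", {
  g <- cbind(fixture_geno(c(1, 1, 0), 2, prefix = "a"),
             fixture_geno(c(0, 1, 1), 2, prefix = "b"))
  # a1 differs from b1 at sites 1,3 etc.; oracle by hand below
  vt <- fixture_variant_table(g, L = 10000,
                              pops = c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  hand <- mean(c(sum(abs(g[, 1] - g[, 3])), sum(abs(g[, 1] - g[, 4])),
                 sum(abs(g[, 2] - g[, 3])), sum(abs(g[, 2] - g[, 4])))) / 10000
  expect_equal(pairwise_divergence(vt, "A", "B"), hand, tolerance = 1e-12)
  # identical clone groups -> 0
  gg <- cbind(fixture_geno(c(2, 0), 2, prefix = "x"),
              fixture_geno(c(2, 0), 2, prefix = "y"))
  vt2 <- fixture_variant_table(gg, L = 1000,
                               pops = c(x1 = "X", x2 = "X", y1 = "Y", y2 = "Y"))
  expect_equal(pairwise_divergence(vt2, c("x1", "x2"), c("y1", "y2")), 0)
  expect_error(pairwise_divergence(vt2, c("x1", "y1"), c("y1", "y2")),
               "overlap")
  # 103 differing sites over 10,000 callable bp
  g3 <- fixture_geno(rep(1, 103), 2)
  g3[, 2] <- 0
  vt3 <- fixture_variant_table(g3, L = 10000)
  expect_equal(pairwise_divergence(vt3, "s1", "s2"), 0.0103)
})

test_that("divergence estimates are unbiased on simulated truth", {
  anc <- generate_ancestor(30000, 1, seed = 77)
  d <- 0.0103
  devs <- vapply(1:6, function(s) {
    a <- evolve_lineage(anc, d / 2, seed = 500 + s)$genome
    b <- evolve_lineage(anc, d / 2, seed = 600 + s)$genome
    genome_divergence(a, b)
  }, numeric(1))
  expected <- d / 2 + d / 2 - (4 / 3) * (d / 2)^2
  sd3 <- 3 * sqrt(expected * (1 - expected) / 30000)
  for (dv in devs) expect_lt(abs(dv - expected), sd3)
})

test_that("Hudson Fst matches hand arithmetic and its limits", {
  # fixed difference at every site -> exactly 1
  g <- cbind(fixture_geno(c(2, 2, 2), 2, prefix = "a"),
             fixture_geno(c(0, 0, 0), 2, prefix = "b"))
  vt <- fixture_variant_table(g, L = 1000,
                              pops = c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  expect_identical(hudson_fst(vt, "A", "B")$fst, 1)
  # single site, p_a = 1, p_b = 0.5, n = 10 each: N/D evaluated by hand
  ga <- matrix(1, 1, 10); gb <- matrix(rep(c(0, 1), 5), 1)
  g2 <- cbind(ga, gb)
  colnames(g2) <- c(paste0("a", 1:10), paste0("b", 1:10))
  vt2 <- fixture_variant_table(g2, L = 1000,
                               pops = stats::setNames(rep(c("A", "B"), each = 10),
                                                      colnames(g2)))
  N <- (1 - 0.5)^2 - 0 - 0.5 * 0.5 / 9
  D <- 1 * 0.5 + 0.5 * 0
  expect_equal(hudson_fst(vt2, "A", "B")$fst, N / D, tolerance = 1e-9)
  # panmixia: shared frequencies, n = 50, 1000 sites -> |Fst| < 0.02
  g3 <- withr::with_seed(31, {
    p <- stats::runif(1000, 0.1, 0.9)
    m <- vapply(seq_len(100), function(j) stats::rbinom(1000, 1, p),
                numeric(1000))
    colnames(m) <- c(paste0("a", 1:50), paste0("b", 1:50))
    m
  })
  keep <- rowSums(g3) > 0 & rowSums(g3) < 100
  vt3 <- fixture_variant_table(g3[keep, ], L = 1e5,
                               pops = stats::setNames(rep(c("A", "B"), each = 50),
                                                      colnames(g3)))
  fst <- hudson_fst(vt3, "A", "B")
  expect_lt(abs(fst$fst), 0.02)
  expect_lte(fst$fst, 1)
  expect_identical(fst$estimator, "Hudson ratio-of-averages")
})

test_that("generations since divergence apply theta = 2 N mu", {
  expect_equal(generations_since_divergence(0)$generations, 0)
  r1 <- generations_since_divergence(0.0103)
  expect_equal(r1$generations, 0.0103 / (2 * 1.84e-10))
  expect_equal(r1$generations, 2.80e7, tolerance = 0.005)
  r2 <- generations_since_divergence(0.0406)
  expect_equal(r2$generations, 1.10e8, tolerance = 0.005)
  expect_lt(r1$years_low, r1$years_high)
  expect_error(generations_since_divergence(0.01, mu = 0), "mu must be > 0")
})

test_that("variant filtering applies strict depth and quality rules", {
  sites <- data.frame(chrom = "chrI", pos = c(10, 20, 30, 40, 50),
                      ref = "A", alt = "T",
                      depth = c(50, 9, 11, 10, 30),
                      qual = c(60, 60, 60, 60, 10))
  geno <- matrix(c(rep(1, 5), rep(0, 5)), 5, 2,
                 dimnames = list(NULL, c("s1", "s2")))
  vt <- variant_table(sites, geno, c(s1 = "p", s2 = "p"), 1000)
  filt <- filter_variants(vt)
  # depth 9 and 10 fail (> 10 is strict), qual 10 fails
  expect_equal(filt$sites$pos, c(10, 30))
  all_pass <- filter_variants(vt, min_depth = NULL, min_quality = NULL)
  expect_identical(n_sites(all_pass), 5L)
  geno[2, 1] <- NA
  vtna <- variant_table(sites, geno, c(s1 = "p", s2 = "p"), 1000)
  expect_identical(n_sites(filter_variants(vtna, NULL, NULL)), 4L)
})

test_that("VCF writing and reading round-trip a variant table", {
  g <- cbind(fixture_geno(c(1, 2, 0, 1), 3, prefix = "x"))
  g[3, 2] <- 0.5 # heterozygous diploid collapse
  sites <- data.frame(chrom = rep(c("chrI", "chrII"), each = 2),
                      pos = c(5L, 105L, 7L, 99L),
                      ref = c("A", "C", "G", "T"), alt = c("T", "G", "A", "C"),
                      qual = c(50, 60, 70, 80))
  vt <- variant_table(sites, g, stats::setNames(rep("p", 3), colnames(g)),
                      2000)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_variants(vt, f, contig_lengths = c(chrI = 1000L, chrII = 1000L))
  back <- read_variants(f)
  expect_identical(back$sites$pos, vt$sites$pos)
  expect_identical(back$sites$ref, vt$sites$ref)
  expect_equal(unname(back$geno), unname(vt$geno))
  expect_equal(back$L, 2000)
})

test_that("neighbor joining recovers additive distances", {
  # tree ((A:2,B:3):1,(C:4,D:5)) -> additive distance matrix
  D <- matrix(c(0, 5, 7, 8,
                5, 0, 8, 9,
                7, 8, 0, 9,
                8, 9, 9, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  nwk <- nj_tree(D)
  expect_type(nwk, "character")
  tree <- attr(nwk, "tree")
  co <- ape::cophenetic.phylo(tree)[rownames(D), colnames(D)]
  expect_equal(co, D, tolerance = 1e-9)
  # three taxa: the unique unrooted topology
  D3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  expect_identical(attr(nj_tree(D3), "tree")$Nnode, 1L)
  # zero-distance taxon pair -> zero-length terminal branch
  D0 <- D; D0["A", "B"] <- D0["B", "A"] <- 0
  t0 <- attr(nj_tree(D0), "tree")
  expect_lte(min(t0$edge.length), 1e-9)
  asym <- D; asym[1, 2] <- 99
  expect_error(nj_tree(asym), "symmetric")
})
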