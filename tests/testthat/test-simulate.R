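test_that("ancestor generation honors length, GC and determinism", {
  expect_error(generate_ancestor(0), "positive integer")
  g1 <- generate_ancestor(100000, 1, gc_content = 0.40, seed = 1)
  g2 <- generate_ancestor(100000, 1, gc_content = 0.40, seed = 1)
  expect_identical(unclass(g1), unclass(g2))
  # binomial concentration: sd(GC) ~ sqrt(.4*.6/1e5) ~ 0.0015
  gc <- sum(strsplit(g1[[1]], "")[[1]] %in% c("G", "C")) / 100000
  expect_gte(gc, 0.39); expect_lte(gc, 0.41)
  g3 <- generate_ancestor(c(1000, 2000), 2, seed = 2)
  expect_identical(unname(chrom_lengths(g3)), c(1000L, 2000L))
})

test_that("lineage evolution matches the binomial substitution model", {
  anc <- fixture_genome(len = 50000, n_chrom = 2, seed = 3)
  expect_error(evolve_lineage(anc, 0.3), "0, 0.25")
  expect_identical(unclass(evolve_lineage(anc, 0, seed = 1)$genome),
                   unclass(anc))
  L <- genome_length(anc)
  d <- 0.07
  ev <- evolve_lineage(anc, d, seed = 4)
  n_diff <- nrow(genome_diff_positions(anc, ev$genome))
  expect_lt(abs(n_diff - d * L), 3 * sqrt(L * d * (1 - d)))
  # truth records exactly the mutated sites
  diff <- genome_diff_positions(anc, ev$genome)
  expect_identical(paste(ev$truth$chrom, ev$truth$pos, ev$truth$alt),
                   paste(diff$chrom, diff$pos, diff$alt))
})

test_that("independent branches diverge by p + q - (4/3)pq (back-mutation)", {
  anc <- fixture_genome(len = 60000, n_chrom = 1, seed = 9)
  L <- genome_length(anc)
  p <- q <- 0.035
  expected <- p + q - (4 / 3) * p * q
  devs <- vapply(1:5, function(s) {
    a <- evolve_lineage(anc, p, seed = 1000 + s)$genome
    b <- evolve_lineage(anc, q, seed = 2000 + s)$genome
    genome_divergence(a, b)
  }, numeric(1))
  sd3 <- 3 * sqrt(expected * (1 - expected) / L)
  for (dv in devs) expect_lt(abs(dv - expected), sd3)
})

test_that("introgression implanting replaces tracts exactly", {
  p <- fixture_pair(len = 20000, branch = 0.02, seed = 11)
  empty <- implant_introgression(p$a, p$b, data.frame(chrom = character(0),
                                                      start = integer(0),
                                                      length = integer(0)))
  expect_identical(unclass(empty$genome), unclass(p$a))
  tr <- data.frame(chrom = "chrI", start = 5000, length = 4000)
  res <- implant_introgression(p$a, p$b, tr)
  d <- genome_diff_positions(res$genome, p$b)
  expect_false(any(d$pos > 5000 & d$pos <= 9000)) # zero diffs inside tract
  expect_identical(res$truth$start1, 5001L)
  expect_identical(res$truth$end1, 9000L)
  over <- data.frame(chrom = c("chrI", "chrI"), start = c(100, 300),
                     length = c(500, 100))
  expect_error(implant_introgression(p$a, p$b, over), "overlap")
  expect_error(implant_introgression(p$a, p$b,
                                     data.frame(chrom = "chrI", start = 19000,
                                                length = 2000)),
               "out of bounds")
})

test_that("structural-variant application conserves sequence", {
  g <- fixture_genome(len = 6000, n_chrom = 2, seed = 21)
  # inversion is an involution
  inv <- sv_spec("inversion", "chrI", pos_a = 0, size = 6000)
  once <- apply_svs(g, inv)$genome
  twice <- apply_svs(once, inv)$genome
  expect_identical(unclass(twice), unclass(g))
  expect_false(identical(unclass(once), unclass(g)))
  # reciprocal translocation conserves total length and content
  rt <- sv_spec("reciprocal_translocation", "chrI", "chrII",
                pos_a = 4000, pos_b = 2500)
  swapped <- apply_svs(g, rt)$genome
  expect_identical(genome_length(swapped), genome_length(g))
  expect_identical(nchar(swapped[["chrI"]]), 4000L + 3500L)
  expect_identical(substr(swapped[["chrI"]], 4001, 7500),
                   substr(g[["chrII"]], 2501, 6000))
  # deletion removes exactly its size
  del <- apply_svs(g, sv_spec("deletion", "chrII", pos_a = 1000, size = 2000))
  expect_identical(genome_length(del$genome), genome_length(g) - 2000L)
  # non-reciprocal move conserves content across the genome
  nrt <- apply_svs(g, sv_spec("nonreciprocal_translocation", "chrI", "chrII",
                              pos_a = 100, size = 250))
  expect_identical(genome_length(nrt$genome), genome_length(g))
  expect_identical(substr(nrt$genome[["chrII"]], 6001, 6250),
                   substr(g[["chrI"]], 101, 350))
  expect_error(apply_svs(g, sv_spec("deletion", "chrI", pos_a = 5500,
                                    size = 1000)),
               "beyond chromosome end")
})

test_that("coverage simulation is Poisson-concentrated and deterministic", {
  g <- fixture_genome(len = 500000, n_chrom = 2, seed = 31)
  cov1 <- simulate_coverage(g, mean_cov = 30, window = 1000, seed = 8)
  cov2 <- simulate_coverage(g, mean_cov = 30, window = 1000, seed = 8)
  expect_identical(cov1, cov2)
  expect_identical(nrow(cov1), 1000L)
  expect_gte(mean(cov1$mean_cov), 28.5)
  expect_lte(mean(cov1$mean_cov), 31.5)
  # window larger than the chromosome -> a single pro-rated window
  small <- as_genome(c(chrI = strrep("ACGT", 100)))
  cv <- simulate_coverage(small, 30, window = 1000, seed = 1)
  expect_identical(nrow(cv), 1L)
  expect_identical(cv$end, 400L)
})

test_that("cross simulation follows the viability model", {
  expect_equal(expected_viability(0, 0, v0 = 90, alpha = 65), 90)
  expect_equal(expected_viability(0, 1, v0 = 90, alpha = 65), 45)
  cr <- simulate_cross(0.04, 1, v0 = 95, alpha = 40, n_spores = 96, seed = 3)
  expect_identical(cr$dissected, 96L)
  expect_lte(cr$viable, 96L)
  expect_equal(cr$viability, 100 * cr$viable / 96)
  expect_identical(simulate_cross(0.02, seed = 5),
                   simulate_cross(0.02, seed = 5))
})

test_that("growth simulation matches the logistic closed form", {
  g <- simulate_growth(K = 1, r = 0.5, N0 = 0.05, duration = 48, step = 0.5,
                       noise_sd = 0)
  t <- g$time_h
  expect_equal(g$od, 1 / (1 + ((1 - 0.05) / 0.05) * exp(-0.5 * t)),
               tolerance = 1e-12)
  expect_lt(abs(g$od[length(t)] - 1), 1e-9) # asymptote reached
  expect_error(simulate_growth(r = 0), "r must be > 0")
  expect_error(simulate_growth(K = 0.01, N0 = 0.05), "K > N0 > 0")
})
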