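test_that("trapezoidal AUC handles the elementary shapes", {
  t48 <- seq(0, 48, by = 0.5)
  expect_equal(auc_empirical(t48, rep(1, length(t48))), 48)
  t24 <- seq(0, 24, by = 0.5)
  expect_equal(auc_empirical(t24, t24 / 24), 12)
  expect_equal(auc_empirical(c(0, 1), c(0, 2)), 1)
  expect_error(auc_empirical(c(0, 0, 1), c(1, 1, 1)), "strictly increasing")
})

test_that("logistic fits recover known parameters", {
  g <- simulate_growth(K = 1, r = 0.5, N0 = 0.05, duration = 48, noise_sd = 0)
  fit <- fit_logistic_growth(g$time_h, g$od)
  expect_true(fit$converged)
  expect_lt(abs(fit$K - 1) / 1, 0.01)
  expect_lt(abs(fit$r - 0.5) / 0.5, 0.01)
  expect_lt(abs(fit$N0 - 0.05) / 0.05, 0.01)
  # noiseless: analytic and empirical AUC agree within 1%
  expect_lt(abs(fit$auc_fit - fit$auc_empirical) / fit$auc_empirical, 0.01)
  # mild noise: K within 5% across 20 seeds
  ks <- vapply(1:20, function(s) {
    gn <- simulate_growth(K = 1, r = 0.5, N0 = 0.05, duration = 48,
                          noise_sd = 0.01, seed = 3000 + s)
    fit_logistic_growth(gn$time_h, gn$od)$K
  }, numeric(1))
  expect_true(all(abs(ks - 1) < 0.05))
  # a monotone-decreasing curve falls back to the empirical AUC
  dec <- fit_logistic_growth(seq(0, 10, by = 1), seq(1, 0, length.out = 11))
  expect_false(dec$converged)
  expect_equal(dec$auc_fit, dec$auc_empirical)
  expect_error(fit_logistic_growth(0:5, rep(1, 6)), "at least 10")
})

test_that("the AUC matrix averages replicates and flags gaps", {
  tab <- data.frame(strain = rep(c("s1", "s2"), each = 6),
                    condition = rep(rep(c("c1", "c2"), each = 3), 2),
                    auc = c(10, 12, 14, 1, 2, 3, 20, 22, 24, 4, 5, 6))
  m <- build_phenotype_matrix(tab)
  expect_equal(m["s1", "c1"], 12)
  expect_equal(m["s2", "c2"], 5)
  expect_equal(dim(m), c(2L, 2L))
  gap <- tab[-(4:6), ]
  expect_error(build_phenotype_matrix(gap), "s1 has no replicate")
  m2 <- build_phenotype_matrix(gap, allow_missing = TRUE)
  expect_true(is.na(m2["s1", "c2"]))
})

test_that("z-scoring is exact, idempotent and order-preserving", {
  m <- matrix(c(1, 2, 3, 10, 20, 60), 3, 2,
              dimnames = list(c("a", "b", "c"), c("x", "y")))
  z <- zscore_columns(m)
  expect_equal(unname(z[, "x"]), c(-1, 0, 1))
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-9)
  expect_equal(zscore_columns(z), z, tolerance = 1e-12)
  expect_identical(rownames(z), rownames(m))
  m0 <- cbind(m, const = c(5, 5, 5))
  expect_error(zscore_columns(m0), "const")
})

test_that("clustering separates well-separated groups", {
  hits <- 0L
  for (s in 1:20) {
    m <- withr::with_seed(500 + s, {
      base <- matrix(rnorm(10 * 4), 10, 4) # unit-sd noise
      base[6:10, ] <- base[6:10, ] + 3 # 3-sd group shift
      rownames(base) <- sprintf("s%02d", 1:10)
      colnames(base) <- paste0("c", 1:4)
      base
    })
    cl <- cluster_phenotypes(m)
    split <- cl$top_split
    if (length(unique(split[1:5])) == 1 &&
        length(unique(split[6:10])) == 1 &&
        split[[1]] != split[[10]]) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
  # duplicate strains merge at height zero; two strains give a single join
  dup <- matrix(c(1, 1, 5, 2, 2, 7), 3, 2,
                dimnames = list(c("a", "b", "c"), c("x", "y")))
  hc <- cluster_phenotypes(dup)$hclust
  expect_equal(hc$height[1], 0)
  two <- cluster_phenotypes(dup[1:2, ])
  expect_equal(length(two$hclust$height), 1L)
})

test_that("one-way ANOVA matches the sums-of-squares oracle", {
  d <- data.frame(condition = "c1",
                  group = rep(c("g1", "g2", "g3"), each = 4),
                  value = c(5.1, 4.9, 5.3, 5.0, 6.2, 6.0, 6.4, 6.1,
                            4.0, 4.2, 3.9, 4.1))
  res <- anova_by_condition(d)
  # textbook decomposition
  gm <- mean(d$value)
  means <- tapply(d$value, d$group, mean)
  ssb <- sum(4 * (means - gm)^2)
  ssw <- sum((d$value - means[d$group])^2)
  f_oracle <- (ssb / 2) / (ssw / 9)
  expect_equal(res$F, f_oracle, tolerance = 1e-10)
  expect_equal(res$p_value, stats::pf(f_oracle, 2, 9, lower.tail = FALSE),
               tolerance = 1e-10)
  # letters separate all three groups here
  expect_equal(length(unique(attr(res, "letters")$c1)), 3L)
  # F is invariant to a constant shift
  d2 <- transform(d, value = value + 100)
  expect_equal(anova_by_condition(d2)$F, res$F, tolerance = 1e-8)
})

test_that("degenerate ANOVA inputs hit their contracts", {
  flat <- data.frame(condition = "c1", group = rep(c("a", "b"), each = 3),
                     value = rep(1, 6))
  res <- anova_by_condition(flat)
  expect_equal(res$F, 0)
  expect_equal(res$p_value, 1)
  expect_equal(unique(attr(res, "letters")$c1), "a")
  sep <- data.frame(condition = "c1", group = rep(c("a", "b"), each = 3),
                    value = rep(c(1, 2), each = 3))
  res2 <- anova_by_condition(sep)
  expect_lt(res2$p_value, 1e-10)
  expect_equal(length(unique(attr(res2, "letters")$c1)), 2L)
  bad <- data.frame(condition = "c1", group = c("a", "a", "b"),
                    value = c(1, 2, 3))
  expect_error(anova_by_condition(bad), "fewer than 2 observations")
})
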