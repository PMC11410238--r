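# Growth-curve phenotyping: AUC extraction, strain x condition matrix,
# per-column z-scoring, hierarchical clustering, and condition-wise one-way
# ANOVA with compact letter display.

#' Empirical area under a growth curve
#'
#' Trapezoidal integral of optical density over the observed time grid.
#'
#' @param times hours, strictly increasing, length >= 2.
#' @param od optical density readings.
#' @return AUC in OD*hours.
#' @export
auc_empirical <- function(times, od) {
  if (length(times) < 2L || length(times) != length(od))
    stop_bad("need >= 2 paired (time, od) points")
  if (any(diff(times) <= 0)) stop_bad("times must be strictly increasing")
  sum(diff(times) * (utils::head(od, -1L) + utils::tail(od, -1L)) / 2)
}

# analytic integral of K / (1 + A exp(-r t)) over [0, T], A = (K - N0)/N0
.logistic_auc <- function(K, r, N0, T) {
  A <- (K - N0) / N0
  (K / r) * (log(exp(r * T) + A) - log(1 + A))
}

#' Fit a logistic growth model to a curve
#'
#' Least-squares fit of `N(t) = K / (1 + ((K - N0)/N0) exp(-r t))`
#' (Levenberg-Marquardt). `auc_fit` is the analytic integral of the fitted
#' curve over the observation window; if the fit fails (e.g. a flat or
#' decreasing curve) the empirical AUC is returned with `converged = FALSE`.
#'
#' @param times hours, >= 10 points.
#' @param od optical density readings; `max(od) > min(od)` required for a
#'   fit attempt.
#' @return list of class `growth_fit`: `K`, `r`, `N0`, `auc_fit`,
#'   `auc_empirical`, `converged`.
#' @export
fit_logistic_growth <- function(times, od) {
  if (length(times) < 10L) stop_bad("need at least 10 time points")
  auc_emp <- auc_empirical(times, od)
  fallback <- structure(list(K = NA_real_, r = NA_real_, N0 = NA_real_,
                             auc_fit = auc_emp, auc_empirical = auc_emp,
                             converged = FALSE),
                        class = "growth_fit")
  if (max(od) <= min(od)) return(fallback)
  K0 <- max(od)
  N00 <- max(od[1L], 1e-4)
  if (N00 >= K0) N00 <- K0 / 2
  fit <- tryCatch(
    minpack.lm::nlsLM(od ~ K / (1 + ((K - N0) / N0) * exp(-r * t)),
                      data = data.frame(t = times, od = od),
                      start = list(K = K0, r = 0.5, N0 = N00),
                      lower = c(K = 1e-9, r = 1e-9, N0 = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) return(fallback)
  p <- as.list(stats::coef(fit))
  # a "fit" with N0 >= K is a decay curve, not growth
  if (!(p$K > 0 && p$r > 0 && p$N0 > 0 && p$N0 < p$K)) return(fallback)
  structure(list(K = p$K, r = p$r, N0 = p$N0,
                 auc_fit = .logistic_auc(p$K, p$r, p$N0, max(times)),
                 auc_empirical = auc_emp, converged = TRUE),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("<growth_fit> K = %.3f, r = %.3f/h, N0 = %.4f, AUC(fit) = %.2f OD*h\n",
                x$K, x$r, x$N0, x$auc_fit))
  else
    cat(sprintf("<growth_fit> not converged; empirical AUC = %.2f OD*h\n",
                x$auc_empirical))
  invisible(x)
}

#' Build the strain x condition AUC matrix
#'
#' Each cell is the mean AUC across replicates.
#'
#' @param auc_table data.frame with `strain`, `condition`, `auc` (one row per
#'   replicate).
#' @param allow_missing keep missing strain x condition cells as `NA` instead
#'   of erroring.
#' @return numeric matrix, strains as rows (sorted), conditions as columns
#'   (sorted).
#' @export
build_phenotype_matrix <- function(auc_table, allow_missing = FALSE) {
  need <- c("strain", "condition", "auc")
  if (!is.data.frame(auc_table) || !all(need %in% names(auc_table)))
    stop_bad("auc_table must carry strain, condition, auc")
  strains <- sort(unique(auc_table$strain))
  conds <- sort(unique(auc_table$condition))
  m <- matrix(NA_real_, length(strains), length(conds),
              dimnames = list(strains, conds))
  agg <- stats::aggregate(auc ~ strain + condition, data = auc_table, FUN = mean)
  m[cbind(match(agg$strain, strains), match(agg$condition, conds))] <- agg$auc
  if (anyNA(m) && !allow_missing) {
    gap <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop_bad("strain %s has no replicate for condition %s (use allow_missing to keep the gap)",
             strains[gap[1L]], conds[gap[2L]])
  }
  m
}

#' Z-score matrix columns
#'
#' Column-wise `(x - mean) / sd`; idempotent up to floating point.
#'
#' @param m numeric matrix (e.g. from [build_phenotype_matrix()]).
#' @return matrix of the same shape.
#' @export
zscore_columns <- function(m) {
  stopifnot(is.matrix(m))
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0 | is.na(sds)))
    stop_bad("zero-variance condition column(s): %s",
             paste(colnames(m)[sds == 0 | is.na(sds)], collapse = ", "))
  scaled <- scale(m)
  attr(scaled, "scaled:center") <- NULL
  attr(scaled, "scaled:scale") <- NULL
  scaled
}

#' Hierarchical clustering of strains
#'
#' Agglomerative clustering of matrix rows; rows are pre-sorted by strain id
#' so ties resolve deterministically.
#'
#' @param m numeric matrix, strains as rows.
#' @param linkage agglomeration method (see [stats::hclust()]).
#' @param metric distance metric (see [stats::dist()]).
#' @return list: `newick` (dendrogram as Newick), `order` (leaf order),
#'   `hclust`, `top_split` (named 1/2 membership of the two top-level
#'   clusters).
#' @export
cluster_phenotypes <- function(m, linkage = "average", metric = "euclidean") {
  if (nrow(m) < 2L) stop_bad("need at least 2 strains")
  m <- m[order(rownames(m)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(m, method = metric), method = linkage)
  list(newick = ape::write.tree(ape::as.phylo(hc)),
       order = hc$labels[hc$order],
       hclust = hc,
       top_split = stats::cutree(hc, k = 2L))
}

# compact letter display: groups sorted by mean share a letter iff no pair
# within the letter is significantly different (greedy assignment)
.letter_display <- function(means, sig_pairs) {
  groups <- names(sort(means, decreasing = TRUE))
  letters_of <- stats::setNames(vector("list", length(groups)), groups)
  sets <- list()
  is_sig <- function(a, b)
    any(vapply(sig_pairs, function(p) setequal(p, c(a, b)), logical(1)))
  for (g in groups) {
    placed <- FALSE
    for (k in seq_along(sets)) {
      if (!any(vapply(sets[[k]], is_sig, logical(1), b = g))) {
        sets[[k]] <- c(sets[[k]], g)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1L]] <- g
  }
  for (k in seq_along(sets))
    for (g in sets[[k]])
      letters_of[[g]] <- c(letters_of[[g]], letters[k])
  vapply(letters_of[names(means)], paste, character(1), collapse = "")
}

#' One-way ANOVA per condition with grouping letters
#'
#' For each condition column: standard one-way F test of the group effect,
#' then pairwise Welch t-tests with Holm correction at `alpha` to build a
#' compact letter display (groups sharing a letter are not significantly
#' different).
#'
#' @param obs data.frame with `condition`, `group`, `value` (one row per
#'   observation), or a strain x condition matrix plus `groups` giving the
#'   group of each row.
#' @param groups group label per matrix row (matrix input only).
#' @param alpha significance level for the letters.
#' @return data.frame `condition`, `F`, `p_value`, plus attribute
#'   `"letters"`: a named list of per-condition letter vectors.
#' @export
anova_by_condition <- function(obs, groups = NULL, alpha = 0.05) {
  if (is.matrix(obs)) {
    if (is.null(groups) || length(groups) != nrow(obs))
      stop_bad("groups must label every matrix row")
    obs <- data.frame(
      condition = rep(colnames(obs), each = nrow(obs)),
      group = rep(as.character(groups), times = ncol(obs)),
      value = as.vector(obs), stringsAsFactors = FALSE)
  }
  need <- c("condition", "group", "value")
  if (!all(need %in% names(obs)))
    stop_bad("obs must carry condition, group, value")
  res <- list(); letts <- list()
  for (cond in sort(unique(obs$condition))) {
    d <- obs[obs$condition == cond, , drop = FALSE]
    cnt <- table(d$group)
    if (length(cnt) < 2L) stop_bad("condition %s has fewer than 2 groups", cond)
    if (any(cnt < 2L))
      stop_bad("group %s has fewer than 2 observations in condition %s",
               names(cnt)[cnt < 2L][1L], cond)
    if (stats::var(d$value) == 0) {
      Fv <- 0; pv <- 1
      sig <- list()
    } else {
      # zero within-group variance triggers a benign perfect-fit warning
      a <- suppressWarnings(stats::anova(stats::aov(value ~ group, data = d)))
      Fv <- a[["F value"]][1L]; pv <- a[["Pr(>F)"]][1L]
      combs <- utils::combn(names(cnt), 2L, simplify = FALSE)
      praw <- vapply(combs, function(p) {
        x <- d$value[d$group == p[1L]]; y <- d$value[d$group == p[2L]]
        if (stats::sd(x) == 0 && stats::sd(y) == 0)
          return(if (mean(x) == mean(y)) 1 else 0)
        tryCatch(stats::t.test(x, y)$p.value, error = function(e) 1)
      }, numeric(1))
      padj <- stats::p.adjust(praw, method = "holm")
      sig <- combs[padj < alpha]
    }
    means <- tapply(d$value, d$group, mean)
    res[[cond]] <- data.frame(condition = cond, F = Fv, p_value = pv,
                              stringsAsFactors = FALSE)
    letts[[cond]] <- .letter_display(means, sig)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "letters") <- letts
  out
}
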