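# Nonparametric group comparisons: Kruskal-Wallis on pooled within-group
# pairwise distances with Siegel-Castellan post hoc letters, PERMANOVA on
# the distance matrix with Bonferroni pairwise tests, and Pearson
# correlation tests for group-level summaries.

#' Kruskal-Wallis test with post hoc compact letter display
#'
#' Rank-based H statistic (with tie correction) via [stats::kruskal.test()],
#' chi-squared approximation for the p-value. Post hoc: pairwise mean-rank
#' comparisons with the Siegel-Castellan critical difference at `alpha`,
#' summarized as letters — groups sharing a letter are not significantly
#' different.
#'
#' Intended input, matching the analysis convention for disparity data, is
#' the per-group list of within-group pairwise distances (which are not
#' independent observations; the test is used descriptively).
#'
#' @param values Named list of numeric vectors (one per group).
#' @param alpha Significance level for the post hoc comparisons.
#' @return Object of class `kw_result`: `H`, `df`, `p`, `posthoc` (pairwise
#'   table), `letters` (named character vector).
#' @export
kruskal_wallis <- function(values, alpha = 0.05) {
  stopifnot(is.list(values), length(values) >= 2)
  if (is.null(names(values))) names(values) <- paste0("g", seq_along(values))
  sizes <- lengths(values)
  if (any(sizes < 1)) stop("group with zero values: ",
                           paste(names(values)[sizes < 1], collapse = ", "))
  x <- unlist(values, use.names = FALSE)
  g <- factor(rep(names(values), sizes), levels = names(values))
  kt <- stats::kruskal.test(x, g)

  # Siegel-Castellan pairwise mean-rank comparisons
  r <- rank(x)
  mean_ranks <- tapply(r, g, mean)
  N <- length(x)
  gl <- names(values)
  pairs <- utils::combn(gl, 2)
  # tie correction factor for the critical difference variance
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  posthoc <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                        diff = NA_real_, critical = NA_real_,
                        significant = NA, stringsAsFactors = FALSE)
  z <- stats::qnorm(1 - alpha / (length(gl) * (length(gl) - 1)))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
                 (1 / sizes[[a]] + 1 / sizes[[b]]))
    posthoc$diff[i] <- abs(mean_ranks[[a]] - mean_ranks[[b]])
    posthoc$critical[i] <- z * se
    posthoc$significant[i] <- posthoc$diff[i] > posthoc$critical[i]
  }
  letters <- letter_display(gl, posthoc)
  structure(list(H = unname(kt$statistic), df = unname(kt$parameter),
                 p = kt$p.value, mean_ranks = mean_ranks,
                 posthoc = posthoc, letters = letters),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: chi-squared = %.4g, df = %d, p = %.3g\n",
              x$H, x$df, x$p))
  cat("  letters:", paste(names(x$letters), x$letters, sep = "=",
                          collapse = ", "), "\n")
  invisible(x)
}

# Compact letter display by greedy clique cover over the graph whose edges
# join non-significantly-different groups; alphabetical tie-breaking.
letter_display <- function(groups, posthoc) {
  groups <- sort(groups)
  ns <- matrix(TRUE, length(groups), length(groups),
               dimnames = list(groups, groups))
  for (i in seq_len(nrow(posthoc))) {
    if (isTRUE(posthoc$significant[i])) {
      ns[posthoc$group1[i], posthoc$group2[i]] <- FALSE
      ns[posthoc$group2[i], posthoc$group1[i]] <- FALSE
    }
  }
  cliques <- list()
  for (g in groups) {
    placed <- FALSE
    for (ci in seq_along(cliques)) {
      if (all(ns[g, cliques[[ci]]])) {
        cliques[[ci]] <- c(cliques[[ci]], g)
        placed <- TRUE
      }
    }
    if (!placed) cliques[[length(cliques) + 1]] <- g
  }
  lab <- stats::setNames(rep("", length(groups)), groups)
  for (ci in seq_along(cliques))
    for (g in cliques[[ci]])
      lab[g] <- paste0(lab[g], letters[ci])
  lab
}

#' PERMANOVA (npMANOVA) on a distance matrix
#'
#' One-way permutational multivariate analysis of variance from the sums of
#' squared distances: `SS_total = sum_{i<j} d_ij^2 / N`, `SS_within =
#' sum_g sum_{i<j in g} d_ij^2 / n_g`, `pseudo-F = (SS_between/(a-1)) /
#' (SS_within/(N-a))`, `r2 = SS_between/SS_total`. The p-value permutes
#' group labels; `p = (#{F* >= F} + 1)/(n_permutations + 1)`.
#'
#' @param dm An `mcd_dist` object (or plain symmetric matrix).
#' @param groups Group labels as in [group_disparity()]; `NA`-labelled taxa
#'   are dropped.
#' @param n_permutations Number of label permutations (default 9999).
#' @param seed Integer seed.
#' @return Object of class `permanova_result`: `pseudo_F`, `r2`, `p`,
#'   `df`, `n_permutations`.
#' @export
permanova <- function(dm, groups, n_permutations = 9999, seed = NULL) {
  D <- if (inherits(dm, "mcd_dist")) dm$D else as.matrix(dm)
  labs <- align_labels(rownames(D), groups)
  keep <- !is.na(labs)
  D <- D[keep, keep, drop = FALSE]
  labs <- labs[keep]
  tab <- table(labs)
  if (length(tab) < 2) stop("need at least two groups")
  if (any(tab < 2)) stop("group(s) of size one: ",
                         paste(names(tab)[tab < 2], collapse = ", "))
  N <- nrow(D)
  a <- length(tab)
  D2 <- D^2
  ss_total <- sum(D2[upper.tri(D2)]) / N
  sizes <- as.vector(tab)
  names(sizes) <- names(tab)
  f_of <- function(lab) {
    # sum of within-group squared distances via two rowsum folds
    M <- rowsum(D2, lab)                 # groups x N
    G <- rowsum(t(M), lab)               # N-fold -> groups x groups
    ssw <- sum(diag(G[names(sizes), names(sizes), drop = FALSE]) / 2 / sizes)
    ssb <- ss_total - ssw
    (ssb / (a - 1)) / (ssw / (N - a))
  }
  F_obs <- f_of(labs)
  M <- rowsum(D2, labs)
  G <- rowsum(t(M), labs)
  ssw <- sum(diag(G[names(sizes), names(sizes), drop = FALSE]) / 2 / sizes)
  r2 <- (ss_total - ssw) / ss_total
  count <- 0L
  with_seed(seed, {
    for (i in seq_len(n_permutations)) {
      if (f_of(sample(labs)) >= F_obs) count <- count + 1L
    }
  })
  structure(list(pseudo_F = F_obs, r2 = r2,
                 p = (count + 1) / (n_permutations + 1),
                 df = c(between = a - 1L, within = N - a),
                 n_permutations = n_permutations, n = N, n_groups = a),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g, r2 = %.3f, p = %.3g (%d perms)\n",
              x$pseudo_F, x$r2, x$p, x$n_permutations))
  invisible(x)
}

#' Pairwise PERMANOVAs with Bonferroni correction
#'
#' Every group pair is tested with [permanova()]; adjusted
#' `p = min(1, raw p * number of pairs)`.
#'
#' @inheritParams permanova
#' @return Data frame `group1`, `group2`, `pseudo_F`, `p_raw`,
#'   `p_adjusted`, `significant` (at `alpha`).
#' @param alpha Significance level applied to adjusted p-values.
#' @export
pairwise_permanova <- function(dm, groups, n_permutations = 9999,
                               seed = NULL, alpha = 0.05) {
  D <- if (inherits(dm, "mcd_dist")) dm$D else as.matrix(dm)
  labs <- align_labels(rownames(D), groups)
  gl <- sort(unique(labs[!is.na(labs)]))
  pairs <- utils::combn(gl, 2)
  m <- ncol(pairs)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    pseudo_F = NA_real_, p_raw = NA_real_,
                    p_adjusted = NA_real_, significant = NA,
                    stringsAsFactors = FALSE)
  for (i in seq_len(m)) {
    sel <- names(labs)[!is.na(labs) & labs %in% pairs[, i]]
    subD <- D[sel, sel, drop = FALSE]
    sublab <- labs[sel]
    fit <- permanova(structure(list(D = subD), class = "mcd_dist"),
                     sublab, n_permutations = n_permutations,
                     seed = if (is.null(seed)) NULL else derive_seed(seed, i))
    out$pseudo_F[i] <- fit$pseudo_F
    out$p_raw[i] <- fit$p
    out$p_adjusted[i] <- min(1, fit$p * m)
    out$significant[i] <- out$p_adjusted[i] < alpha
  }
  out
}

#' Pearson correlation test
#'
#' Thin wrapper over [stats::cor.test()] reporting `r`, `t`, `df` and the
#' two-sided p-value, as used for group-level correlations (disparity vs
#' species richness, clade age, and Ddelta).
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return Object of class `pearson_result`: `r`, `t`, `df`, `p`.
#' @export
pearson_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), t = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value),
            class = "pearson_result")
}

#' @export
print.pearson_result <- function(x, ...) {
  cat(sprintf("Pearson: r = %.3f, t = %.3f, df = %d, p = %.3g\n",
              x$r, x$t, x$df, x$p))
  invisible(x)
}
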