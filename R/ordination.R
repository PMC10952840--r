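# Nonmetric multidimensional scaling of the mean-character-difference
# matrix, with Shepard diagnostics, group centroids and convex-hull
# coverage. The stress engine is vegan's monoMDS (Kruskal stress-1, primary
# tie treatment) run from multiple random starts; the returned configuration
# is centered, principal-axis rotated, and sign-standardized so coordinates
# are comparable across runs.

#' Nonmetric multidimensional scaling of a distance matrix
#'
#' @param dm An `mcd_dist` object (fully defined, post-drop).
#' @param k Number of dimensions (default 2).
#' @param n_starts Number of random starts; the lowest-stress converged
#'   solution is kept (default 20).
#' @param seed Integer seed.
#' @param maxit Iteration cap per start.
#' @return Object of class `morphospace_ord`: list with `coordinates`
#'   (taxon x k matrix), `stress` (Kruskal stress-1 in [0, 1]),
#'   `shepard_nonmetric_r2`, `shepard_linear_r2`, `n_starts`, `seed`,
#'   `converged`, `taxa`.
#' @export
nmds_ordination <- function(dm, k = 2, n_starts = 20, seed = NULL,
                            maxit = 300) {
  d <- stats::as.dist(dm$D)
  n <- attr(d, "Size")
  if (n < k + 1) stop("need at least k+1 taxa for a k-dimensional nMDS")
  if (all(d == 0)) stop("degenerate distance matrix: all distances zero")
  with_seed(seed, {
    best <- NULL
    any_converged <- FALSE
    for (s in seq_len(n_starts)) {
      fit <- vegan::monoMDS(d, k = k, model = "global", maxit = maxit,
                            smin = 1e-6, sfgrmin = 1e-8)
      # icause 1 = iteration cap reached; 2-4 = a convergence criterion met
      if (fit$icause >= 2L) any_converged <- TRUE
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
    if (!any_converged)
      warning("no nMDS start converged; returning the best configuration found")
    coords <- standardize_configuration(best$points)
    rownames(coords) <- rownames(dm$D)
    colnames(coords) <- paste0("axis", seq_len(k))
    ord <- structure(
      list(coordinates = coords, stress = best$stress,
           n_starts = n_starts, seed = seed, converged = any_converged,
           taxa = dm$taxa),
      class = "morphospace_ord")
    r2 <- shepard_fit(dm, ord)
    ord$shepard_nonmetric_r2 <- r2[["nonmetric_r2"]]
    ord$shepard_linear_r2 <- r2[["linear_r2"]]
    ord
  })
}

# center, rotate to principal axes, fix signs (largest-|coordinate| point
# positive on each axis) so output is invariant to reflections/rotations of
# the engine's arbitrary frame
standardize_configuration <- function(pts) {
  pts <- scale(pts, center = TRUE, scale = FALSE)
  pr <- prcomp(pts, center = FALSE)
  rot <- pr$x
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  unclass(rot)
}

#' @export
print.morphospace_ord <- function(x, ...) {
  cat(sprintf("morphospace_ord: %d points, k = %d, stress = %.4f\n",
              nrow(x$coordinates), ncol(x$coordinates), x$stress))
  cat(sprintf("  Shepard nonmetric r2 = %.3f, linear r2 = %.3f\n",
              x$shepard_nonmetric_r2, x$shepard_linear_r2))
  invisible(x)
}

#' Shepard diagram goodness-of-fit
#'
#' From the Shepard point set (observed dissimilarities vs configuration
#' distances): the nonmetric r-squared is `1 - RSS/sum(d^2)` of the
#' monotone (isotonic) regression of configuration distances on observed
#' dissimilarities, which equals `1 - stress^2` under Kruskal stress-1;
#' the linear r-squared is the squared Pearson correlation between the
#' monotone fitted values and the configuration distances.
#'
#' @param dm The `mcd_dist` the ordination was computed from.
#' @param ord A `morphospace_ord`.
#' @return Named numeric vector `nonmetric_r2`, `linear_r2`.
#' @export
shepard_fit <- function(dm, ord) {
  obs <- stats::as.dist(dm$D[rownames(ord$coordinates),
                             rownames(ord$coordinates)])
  conf <- stats::dist(ord$coordinates)
  o <- as.vector(obs); cfg <- as.vector(conf)
  ordix <- order(o, cfg)
  iso <- stats::isoreg(o[ordix], cfg[ordix])
  rss <- sum((iso$y - iso$yf)^2)
  tss <- sum(cfg^2)
  lin <- if (stats::sd(iso$yf) == 0 || stats::sd(cfg) == 0) NA_real_
         else stats::cor(iso$yf, iso$y)^2
  c(nonmetric_r2 = if (tss == 0) 1 else 1 - rss / tss,
    linear_r2 = lin)
}

#' Group centroids in ordination space
#'
#' Arithmetic mean of the member coordinates per axis. Theoretical and
#' ancestor rows should normally be excluded by supplying labels only for
#' empirical taxa.
#'
#' @param ord A `morphospace_ord`.
#' @param groups Named vector/factor or data frame of group labels (as in
#'   [group_disparity()]); taxa with `NA` labels are ignored.
#' @return Matrix with one row per group.
#' @export
group_centroid <- function(ord, groups) {
  labs <- align_labels(rownames(ord$coordinates), groups)
  keep <- !is.na(labs)
  if (!any(keep)) stop("no labelled taxa in ordination")
  gl <- sort(unique(labs[keep]))
  out <- t(vapply(gl, function(g) {
    colMeans(ord$coordinates[keep & labs == g, , drop = FALSE])
  }, numeric(ncol(ord$coordinates))))
  rownames(out) <- gl
  out
}

align_labels <- function(taxa, groups) {
  if (is.data.frame(groups)) {
    lab_col <- intersect(c("group", "bin"), names(groups))[1]
    labs <- as.character(groups[[lab_col]][match(taxa, groups$name)])
  } else if (!is.null(names(groups))) {
    labs <- as.character(unname(groups[taxa]))
  } else if (length(groups) == length(taxa)) {
    labs <- as.character(groups)
  } else stop("cannot align group labels with ordination taxa")
  names(labs) <- taxa
  labs
}

#' Convex-hull coverage of a subset of the morphospace
#'
#' Area of the 2-D convex hull of `subset` divided by the hull area of
#' `reference` (default: all ordinated points, i.e. the total morphospace
#' including the theoretical background).
#'
#' @param ord A `morphospace_ord` with `k = 2`.
#' @param subset Character vector of taxon names.
#' @param reference Character vector of taxon names (default all).
#' @return Fraction in `[0, 1]` (collinear subsets give 0 with a warning).
#' @export
hull_coverage <- function(ord, subset, reference = NULL) {
  stopifnot(ncol(ord$coordinates) == 2)
  reference <- reference %||% rownames(ord$coordinates)
  a_sub <- hull_area(ord$coordinates[subset, , drop = FALSE])
  a_ref <- hull_area(ord$coordinates[reference, , drop = FALSE])
  if (a_ref == 0) stop("reference subset is collinear (zero hull area)")
  if (a_sub == 0) warning("subset is collinear; hull area is zero")
  a_sub / a_ref
}

hull_area <- function(pts) {
  if (nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts)
  x <- pts[h, 1]; y <- pts[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Write ordination coordinates and diagnostics
#'
#' @param ord A `morphospace_ord`.
#' @param coords_path Output CSV (taxon, status, group, axes).
#' @param diagnostics_path Optional JSON with stress, r2, starts, seed.
#' @return `coords_path`, invisibly.
#' @export
write_ordination <- function(ord, coords_path, diagnostics_path = NULL) {
  df <- data.frame(taxon = rownames(ord$coordinates),
                   status = ord$taxa$status[match(rownames(ord$coordinates),
                                                  ord$taxa$name)],
                   group = ord$taxa$group[match(rownames(ord$coordinates),
                                                ord$taxa$name)],
                   ord$coordinates, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, coords_path, row.names = FALSE)
  if (!is.null(diagnostics_path)) {
    jsonlite::write_json(
      list(stress = ord$stress,
           shepard_nonmetric_r2 = ord$shepard_nonmetric_r2,
           shepard_linear_r2 = ord$shepard_linear_r2,
           n_starts = ord$n_starts, seed = ord$seed,
           converged = ord$converged),
      diagnostics_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(coords_path)
}
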