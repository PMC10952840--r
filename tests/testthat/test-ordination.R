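planted_dist <- function(n = 10, seed = 1) {
  set.seed(seed)
  pts <- cbind(runif(n, -1, 1), runif(n, -1, 1))
  rownames(pts) <- sprintf("p%02d", seq_len(n))
  D <- as.matrix(dist(pts))
  list(pts = pts, dm = dist_from_matrix(D))
}

test_that("nMDS recovers a planted planar configuration", {
  pl <- planted_dist(20, seed = 3)
  ord <- nmds_ordination(pl$dm, k = 2, n_starts = 10, seed = 7)
  expect_lt(ord$stress, 0.01)
  pr <- vegan::procrustes(pl$pts, ord$coordinates, symmetric = TRUE)
  expect_lt(pr$ss, 1e-3)
})

test_that("three equidistant taxa embed with zero stress", {
  # all-tied dissimilarities impose no rank constraints under primary tie
  # treatment, so an exact (zero-stress) embedding exists; the shape itself
  # is unidentified and not asserted
  D <- matrix(0.5, 3, 3); diag(D) <- 0
  dimnames(D) <- list(c("a", "b", "c"), c("a", "b", "c"))
  ord <- nmds_ordination(dist_from_matrix(D), k = 2, n_starts = 5, seed = 1)
  expect_lt(ord$stress, 1e-3)
  expect_true(all(is.finite(ord$coordinates)))
})

test_that("nMDS is deterministic given a seed and flags convergence", {
  pl <- planted_dist(12, seed = 5)
  o1 <- nmds_ordination(pl$dm, seed = 11, n_starts = 4)
  o2 <- nmds_ordination(pl$dm, seed = 11, n_starts = 4)
  expect_identical(o1$coordinates, o2$coordinates)
  expect_identical(o1$stress, o2$stress)
  expect_true(is.logical(o1$converged))
  expect_error(nmds_ordination(dist_from_matrix(
    matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3])))),
    "degenerate|at least")
})

test_that("Shepard diagnostics reach 1 on perfectly embeddable data", {
  pl <- planted_dist(9, seed = 2)
  ord <- nmds_ordination(pl$dm, k = 2, n_starts = 10, seed = 3)
  r2 <- shepard_fit(pl$dm, ord)
  expect_gt(r2[["nonmetric_r2"]], 0.999)
  expect_gt(r2[["linear_r2"]], 0.99)
  # stored diagnostics agree with direct recomputation
  expect_equal(ord$shepard_nonmetric_r2, r2[["nonmetric_r2"]])
  expect_equal(ord$shepard_linear_r2, r2[["linear_r2"]])
})

test_that("Shepard nonmetric fit dominates the linear fit on curved data", {
  # distances with a monotone but nonlinear relation to an embeddable set
  pl <- planted_dist(12, seed = 8)
  Dc <- pl$dm$D^3  # strictly monotone transform, same ranks
  dmc <- dist_from_matrix(Dc)
  ord <- nmds_ordination(dmc, k = 2, n_starts = 10, seed = 4)
  r2 <- shepard_fit(dmc, ord)
  expect_gt(r2[["nonmetric_r2"]], r2[["linear_r2"]] - 1e-9)
})

test_that("group centroids are per-axis means with expected invariances", {
  pl <- planted_dist(8, seed = 4)
  ord <- nmds_ordination(pl$dm, seed = 2, n_starts = 4)
  taxa <- rownames(ord$coordinates)
  labs <- setNames(c("g1", rep("g2", 7)), taxa)
  cen <- group_centroid(ord, labs)
  # single-member group: its own coordinates
  expect_equal(unname(cen["g1", ]), unname(ord$coordinates[1, ]))
  # two points -> midpoint
  labs2 <- setNames(c("m", "m", rep(NA, 6)), taxa)
  cen2 <- group_centroid(ord, labs2)
  expect_equal(unname(cen2["m", ]),
               unname(colMeans(ord$coordinates[1:2, ])))
  # relabelling members does not move the centroid
  labs3 <- labs[sample(length(labs))]
  cen3 <- group_centroid(ord, labs3[taxa])
  expect_equal(cen3, cen)
})

test_that("hull coverage matches known geometry and is monotone", {
  sq <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1),
              c(0.25, 0.25), c(0.25, 0.75), c(0.75, 0.25), c(0.75, 0.75))
  rownames(sq) <- paste0("q", 1:8)
  ord <- structure(list(coordinates = sq,
                        taxa = data.frame(name = rownames(sq),
                                          status = "extant",
                                          group = NA, stringsAsFactors = FALSE)),
                   class = "morphospace_ord")
  # sub-square of half side inside unit square: area ratio 0.25
  expect_equal(hull_coverage(ord, paste0("q", 5:8)), 0.25)
  expect_equal(hull_coverage(ord, paste0("q", 1:4)), 1.0)
  # subset = reference -> 1
  expect_equal(hull_coverage(ord, rownames(sq), rownames(sq)), 1.0)
  # adding points never shrinks the hull
  cov1 <- hull_coverage(ord, paste0("q", 5:7))
  cov2 <- hull_coverage(ord, paste0("q", 5:8))
  cov3 <- hull_coverage(ord, paste0("q", c(1, 5:8)))
  expect_lte(cov1, cov2 + 1e-12)
  expect_lte(cov2, cov3 + 1e-12)
  # collinear subset warns and returns zero area
  expect_warning(z <- hull_coverage(ord, c("q1", "q2")), "collinear")
  expect_equal(z, 0)
})

test_that("centroids and hulls are equivariant under rigid motions", {
  pl <- planted_dist(8, seed = 6)
  ord <- nmds_ordination(pl$dm, seed = 9, n_starts = 4)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  ord_rot <- ord
  ord_rot$coordinates <- ord$coordinates %*% R
  labs <- setNames(rep(c("g1", "g2"), 4), rownames(ord$coordinates))
  cen <- group_centroid(ord, labs)
  cen_rot <- group_centroid(ord_rot, labs)
  expect_equal(cen_rot, cen %*% R, tolerance = 1e-12)
  sub <- rownames(ord$coordinates)[1:5]
  expect_equal(hull_coverage(ord_rot, sub), hull_coverage(ord, sub),
               tolerance = 1e-12)
})
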