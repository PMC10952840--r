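make_taxa <- function(names, status, max_ma = NA, min_ma = NA) {
  data.frame(name = names, status = status, group = NA_character_,
             max_ma = max_ma, min_ma = min_ma, stringsAsFactors = FALSE)
}

test_that("fossils are binned by age-range midpoint with exclusions", {
  taxa <- make_taxa(c("f1", "f2", "f3", "ext"),
                    c("fossil", "fossil", "fossil", "extant"),
                    max_ma = c(120, 20, 105, NA),
                    min_ma = c(110, 10, 95, NA))
  b <- assign_time_bins(taxa)
  expect_identical(b$bin[1], "Early Cretaceous")      # fully inside
  expect_true(b$excluded[2])                          # Neogene midpoint
  expect_true(is.na(b$bin[2]))
  expect_identical(b$bin[3], "Late Cretaceous")       # midpoint 100 Ma
  expect_identical(b$bin[4], "living")
  expect_error(assign_time_bins(make_taxa("f", "fossil")), "age range")
})

test_that("group disparity summarizes within-group pairwise distances", {
  D <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  D["a", "b"] <- D["b", "a"] <- 0.2
  D["a", "c"] <- D["c", "a"] <- 0.4
  D["b", "c"] <- D["c", "b"] <- 0.6
  dm <- dist_from_matrix(D)
  rep <- group_disparity(dm, c(a = "g", b = "g", c = "g"))
  expect_equal(rep$meanD, 0.4)
  expect_equal(rep$maxD, 0.6)
  expect_equal(rep$sdD, sd(c(0.2, 0.4, 0.6)))
  # two identical taxa
  D2 <- matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  rep2 <- group_disparity(dist_from_matrix(D2), c(x = "g", y = "g"))
  expect_equal(rep2$meanD, 0)
  expect_equal(rep2$maxD, 0)
  expect_error(group_disparity(dm, c(a = "g1", b = "g2", c = "g2")),
               "fewer than two")
})

test_that("disparity metrics are invariant to taxon ordering", {
  g <- generate_matrix(synth_config(n_groups = 3, taxa_per_group = 8, seed = 7))
  tm <- resolve_polymorphism(g$matrix, seed = 1)
  dm <- build_distance_matrix(tm)
  labs <- setNames(dm$taxa$group, dm$taxa$name)
  r1 <- group_disparity(dm, labs)
  perm <- rev(rownames(dm$D))
  dmp <- structure(list(D = dm$D[perm, perm],
                        comparable = dm$comparable[perm, perm],
                        taxa = dm$taxa[match(perm, dm$taxa$name), ],
                        dropped = dm$dropped), class = "mcd_dist")
  r2 <- group_disparity(dmp, labs)
  expect_equal(r1$meanD, r2$meanD, tolerance = 1e-15)
  expect_equal(r1$maxD, r2$maxD)
})

test_that("rarefaction at full group size reproduces unrarefied values", {
  g <- generate_matrix(synth_config(n_groups = 2, taxa_per_group = 6,
                                    missing_rate = 0.1, polymorphic_rate = 0,
                                    seed = 13))
  tm <- g$matrix
  dm <- build_distance_matrix(tm)
  labs <- setNames(dm$taxa$group, dm$taxa$name)
  base <- group_disparity(dm, labs)
  rr <- rarefy_disparity(tm, labs, metric = "meanD", reps = 5,
                         n_rarefied = 6, seed = 2)
  for (grp in base$group) {
    expect_equal(unique(rr$value[rr$group == grp]),
                 base$meanD[base$group == grp], tolerance = 1e-12)
  }
})

test_that("rarefied meanD is consistent and preserves group rank order", {
  g <- generate_matrix(synth_config(n_groups = 3, taxa_per_group = 12,
                                    divergence = 0.7, missing_rate = 0.05,
                                    polymorphic_rate = 0, seed = 23))
  tm <- g$matrix
  dm <- build_distance_matrix(tm)
  labs <- setNames(dm$taxa$group, dm$taxa$name)
  base <- group_disparity(dm, labs)
  rr <- rarefy_disparity(tm, labs, metric = "meanD", reps = 60, seed = 31)
  med <- tapply(rr$value, rr$group, stats::median)[base$group]
  mn <- tapply(rr$value, rr$group, mean)[base$group]
  expect_equal(as.numeric(mn), base$meanD, tolerance = 0.05)
  expect_identical(order(med), order(base$meanD))
  # replicate count honored per group
  expect_true(all(table(rr$group) == 60))
  # determinism
  rr2 <- rarefy_disparity(tm, labs, metric = "meanD", reps = 60, seed = 31)
  expect_identical(rr$value, rr2$value)
})

test_that("Ddelta measures a group's contribution to total disparity", {
  # all taxa identical -> Ddelta 0 for every group
  D0 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  dm0 <- dist_from_matrix(D0)
  labs <- c(a = "g1", b = "g1", c = "g2", d = "g2")
  expect_equal(ddelta(dm0, labs, "g1"), 0)
  # two tight clusters far apart: removing either collapses disparity
  D <- matrix(0.9, 6, 6)
  D[1:3, 1:3] <- 0.05; D[4:6, 4:6] <- 0.05
  diag(D) <- 0
  dimnames(D) <- list(letters[1:6], letters[1:6])
  dm <- dist_from_matrix(D)
  labs2 <- setNames(rep(c("g1", "g2"), each = 3), letters[1:6])
  expect_gt(ddelta(dm, labs2, "g1"), 0.3)
  expect_gt(ddelta(dm, labs2, "g2"), 0.3)
  # sign flag flips the convention
  expect_equal(ddelta(dm, labs2, "g1", sign = "difference"),
               -ddelta(dm, labs2, "g1"))
  expect_error(ddelta(dm, labs2, "nope"), "unknown group")
})

test_that("eccentricity ranks morphological outliers first", {
  # star geometry: center at distance 1 from all, others mutually 0
  n <- 5
  D <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
  D["a", -1] <- 1; D[-1, "a"] <- 1
  dm <- dist_from_matrix(D)
  ecc <- eccentricity(dm)
  expect_identical(ecc$taxon[1], "a")
  expect_equal(ecc$eccentricity[1], 1)
  expect_equal(ecc$eccentricity[-1], rep(1 / (n - 1), n - 1))
  # all-equal matrix -> all eccentricities equal
  De <- matrix(0.3, 4, 4); diag(De) <- 0
  dimnames(De) <- list(letters[1:4], letters[1:4])
  ecc2 <- eccentricity(dist_from_matrix(De))
  expect_true(all(abs(ecc2$eccentricity - 0.3) < 1e-15))
  expect_identical(sort(ecc2$rank), 1:4)
})

test_that("merged-group meanD lies between within/between extremes", {
  for (seed in 1:4) {
    tm <- random_matrix(10, missing_rate = 0.1, seed = seed + 40)
    dm <- build_distance_matrix(tm)
    taxa <- rownames(dm$D)
    g1 <- taxa[1:5]; g2 <- taxa[6:10]
    w1 <- mean(dm$D[g1, g1][upper.tri(dm$D[g1, g1])])
    w2 <- mean(dm$D[g2, g2][upper.tri(dm$D[g2, g2])])
    bt <- mean(dm$D[g1, g2])
    merged <- group_disparity(dm, setNames(rep("all", 10), taxa))$meanD
    expect_gte(merged, min(w1, w2, bt) - 1e-12)
    expect_lte(merged, max(w1, w2, bt) + 1e-12)
  }
})
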