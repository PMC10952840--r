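# small fixed trees built in code
cherry4 <- function() ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")

# independent brute-force Mk likelihood: explicit summation over all
# internal-node state assignments
oracle_mk_loglik <- function(tree, tip_states, k, Q, prior = rep(1 / k, k)) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    ape::matexpo(Q * tree$edge.length[e]))
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nnode)))
  total <- 0
  for (r in seq_len(nrow(grid))) {
    assign_ <- grid[r, ]
    lik <- prior[assign_[1]]  # root = node ntip+1 = first internal
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      sp <- assign_[par - ntip]
      if (ch <= ntip) {
        s <- tip_states[[tree$tip.label[ch]]]
        lik <- lik * if (is.na(s)) 1 else P[[e]][sp, s + 1]
      } else {
        lik <- lik * P[[e]][sp, assign_[ch - ntip]]
      }
    }
    total <- total + lik
  }
  log(total)
}

test_that("single-branch two-state likelihood matches the closed form", {
  tr <- ape::read.tree(text = "(a:1,b:1);")  # root with two length-1 edges
  # collapse to a single path of length 2 between differing tips:
  # P(differ in time t) = (1 - exp(-2qt))/2 under symmetric 2-state ER
  q <- 0.3
  ll <- mk_loglik(tr, c(a = 0L, b = 1L), 2, q, "ER")
  # sum over root states: 2 * (1/2) * P00(1) * P01(1) by symmetry
  p_same <- (1 + exp(-2 * q)) / 2
  p_diff <- (1 - exp(-2 * q)) / 2
  expect_equal(ll, log(p_same * p_diff), tolerance = 1e-12)
})

test_that("zero rate leaves only the root-prior mass on constant data", {
  tr <- cherry4()
  ll <- mk_loglik(tr, c(a = 1L, b = 1L, c = 1L, d = 1L), 3, 0, "ER")
  expect_equal(ll, log(1 / 3), tolerance = 1e-12)
})

test_that("pruning likelihood equals brute-force enumeration", {
  set.seed(9)
  for (k in c(2L, 3L)) {
    for (rep in 1:3) {
      tr <- ape::rtree(5)
      tips <- setNames(sample(0:(k - 1L), 5, replace = TRUE), tr$tip.label)
      tips[1] <- NA  # one ambiguous tip
      q <- runif(1, 0.05, 0.8)
      Qer <- matrix(q, k, k); diag(Qer) <- -(k - 1) * q
      expect_equal(mk_loglik(tr, tips, k, q, "ER"),
                   oracle_mk_loglik(tr, tips, k, Qer), tolerance = 1e-10)
      # ARD with random rates
      rates <- runif(k * (k - 1), 0.05, 0.5)
      Qard <- matrix(0, k, k)
      idx <- 1
      for (i in 1:k) for (j in 1:k) if (i != j) {
        Qard[i, j] <- rates[idx]; idx <- idx + 1
      }
      diag(Qard) <- -rowSums(Qard)
      expect_equal(mk_loglik(tr, tips, k, rates, "ARD"),
                   oracle_mk_loglik(tr, tips, k, Qard), tolerance = 1e-10)
    }
  }
})

test_that("likelihood agrees with phytools::fitMk at the fitted rates", {
  skip_if_not_installed("phytools")
  set.seed(15)
  sim <- generate_tree_with_characters(60, q = 0.015, seed = 44)
  pr <- prune_for_character(sim$tree, sim$matrix, "per_phyllotaxis")
  fit <- fit_mk(pr$tree, pr$tip_states, k = 3, models = "ER")
  x <- setNames(as.character(pr$tip_states), names(pr$tip_states))
  pf <- phytools::fitMk(pr$tree, x, model = "ER", pi = "equal")
  expect_equal(fit$logL, pf$logLik, tolerance = 1e-3)
  expect_equal(fit$rates[1], pf$rates[1], tolerance = 0.05)
})

test_that("ARD log-likelihood is never below ER (nesting)", {
  set.seed(3)
  for (rep in 1:3) {
    sim <- generate_tree_with_characters(25, q = 0.02, seed = 70 + rep)
    pr <- prune_for_character(sim$tree, sim$matrix, "flw_sex")
    fit <- fit_mk(pr$tree, pr$tip_states, k = 2)
    expect_gte(fit$fits$ARD$logL, fit$fits$ER$logL - 1e-6)
    expect_equal(fit$fits$ER$AIC,
                 2 * 1 - 2 * fit$fits$ER$logL, tolerance = 1e-12)
    expect_equal(fit$fits$ARD$AIC,
                 2 * 2 - 2 * fit$fits$ARD$logL, tolerance = 1e-12)
  }
})

test_that("a constant character is flagged degenerate at the rate floor", {
  tr <- cherry4()
  fit <- fit_mk(tr, c(a = 0L, b = 0L, c = 0L, d = 0L), k = 2)
  expect_true(fit$degenerate)
  expect_lt(fit$rates[1], 1e-6)
})

test_that("tip pruning keeps path lengths intact", {
  tr <- cherry4()
  cs <- tiny_schema()
  toks <- matrix(c("0", "0",
                   "?", "1",
                   "1", "2",
                   "0", "?"), nrow = 4, byrow = TRUE,
                 dimnames = list(c("a", "b", "c", "d"), c("c1", "c2")))
  tm <- trait_matrix(toks, cs)
  pr <- prune_for_character(tr, tm, "c1")
  expect_setequal(pr$tree$tip.label, c("a", "c", "d"))
  expect_setequal(pr$dropped, "b")
  # dropping one tip of a cherry extends the sibling's branch to the
  # grandparent: a's root-to-tip depth is preserved
  depths <- ape::node.depth.edgelength(pr$tree)
  expect_equal(unname(depths[match("a", pr$tree$tip.label)]), 2)
  # no unusable tips -> identical tree
  pr2 <- prune_for_character(tr, tm, "c2")
  expect_setequal(pr2$tree$tip.label, c("a", "b", "c"))
  pr_all <- prune_for_character(
    tr, trait_matrix(matrix("0", 4, 2,
                            dimnames = list(c("a", "b", "c", "d"),
                                            c("c1", "c2"))), cs), "c1")
  expect_identical(ape::Ntip(pr_all$tree), 4L)
  expect_error(prune_for_character(
    tr, trait_matrix(matrix("?", 4, 2,
                            dimnames = list(c("a", "b", "c", "d"),
                                            c("c1", "c2"))), cs), "c1"),
    "fewer than two")
})

test_that("marginal node probabilities match brute-force enumeration", {
  # exact marginal: restrict the enumeration oracle to each value of one
  # internal node and normalize
  oracle_marginal <- function(tree, tips, k, Q, node) {
    ntip <- length(tree$tip.label)
    nnode <- tree$Nnode
    P <- lapply(seq_len(nrow(tree$edge)), function(e)
      ape::matexpo(Q * tree$edge.length[e]))
    grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nnode)))
    mass <- numeric(k)
    for (r in seq_len(nrow(grid))) {
      assign_ <- grid[r, ]
      lik <- (1 / k)  # uniform root prior on assign_[1]
      lik <- lik * prod(vapply(seq_len(nrow(tree$edge)), function(e) {
        par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
        sp <- assign_[par - ntip]
        if (ch <= ntip) {
          s <- tips[[tree$tip.label[ch]]]
          if (is.na(s)) 1 else P[[e]][sp, s + 1]
        } else P[[e]][sp, assign_[ch - ntip]]
      }, numeric(1)))
      st <- assign_[node - ntip]
      mass[st] <- mass[st] + lik
    }
    mass / sum(mass)
  }
  set.seed(23)
  tr <- ape::rtree(5)
  tips <- setNames(sample(0:1, 5, replace = TRUE), tr$tip.label)
  q <- 0.4
  Q <- matrix(c(-q, q, q, -q), 2)
  marg <- floradisp:::mk_marginal(tr, tips, Q)
  for (node in 6:9) {
    expect_equal(unname(marg[node, ]),
                 oracle_marginal(tr, tips, 2, Q, node), tolerance = 1e-10)
  }
  # invariance of root marginals to tip ordering
  perm <- sample(names(tips))
  marg2 <- floradisp:::mk_marginal(tr, tips[perm], Q)
  expect_equal(marg2[6, ], marg[6, ], tolerance = 1e-12)
})

test_that("stochastic node sampling converges to marginal probabilities", {
  set.seed(5)
  tr <- ape::rtree(10)
  tips <- setNames(sample(0:1, 10, replace = TRUE), tr$tip.label)
  fit <- fit_mk(tr, tips, k = 2, models = "ER")
  sm <- stochastic_map(tr, tips, fit, n_sims = 2000, seed = 8)
  expect_true(all(abs(rowSums(sm$node_probs) - 1) < 1e-9))
  expect_lt(max(abs(sm$node_probs - sm$marginal)), 0.03)
  # determinism
  sm2 <- stochastic_map(tr, tips, fit, n_sims = 50, seed = 8)
  sm3 <- stochastic_map(tr, tips, fit, n_sims = 50, seed = 8)
  expect_identical(sm2$node_probs, sm3$node_probs)
})

test_that("a zero-length terminal branch pins the parent draw to the tip", {
  tr <- ape::read.tree(text = "((a:0.0,b:1):1,c:1);")
  fit_q <- matrix(c(-0.5, 0.5, 0.5, -0.5), 2)
  sm <- stochastic_map(tr, c(a = 1L, b = 0L, c = 0L), fit_q,
                       n_sims = 300, seed = 4)
  # parent of the zero-length branch is the second internal node (node 5)
  expect_equal(unname(sm$node_probs["5", "state1"]), 1)
})

test_that("ancestral combinations assemble argmax states with tie logging", {
  sim <- generate_tree_with_characters(20, q = 0.01, seed = 12)
  ntip <- length(sim$tree$tip.label)
  nodes <- list(root = ntip + 1L, inner = ntip + 2L)
  anc <- ancestral_combinations(sim$tree, sim$matrix, nodes,
                                n_sims = 60, seed = 31)
  expect_identical(rownames(anc$matrix$cells), c("root", "inner"))
  expect_true(all(anc$matrix$taxa$status == "ancestor"))
  # every cell is a valid token (argmax state or missing on tie/absence)
  expect_silent(floradisp:::validate_cells(anc$matrix))
  # appended ancestors flow into the distance matrix
  res <- resolve_polymorphism(sim$matrix, seed = 1)
  comb <- rbind_matrices(res, anc$matrix)
  dm <- build_distance_matrix(comb)
  expect_equal(nrow(dm$D) + nrow(dm$dropped), ntip + 2L)
  # ties are logged as missing cells
  if (!is.null(anc$ties)) {
    for (i in seq_len(nrow(anc$ties)))
      expect_identical(
        anc$matrix$cells[anc$ties$node[i], anc$ties$character[i]], "?")
  }
})

test_that("deep-node state recovery improves with tip count", {
  score <- function(n_tips, seed) {
    sim <- generate_tree_with_characters(n_tips, q = 0.005, seed = seed)
    tm <- sim$matrix
    ids <- names(tm$schema$characters)[1:6]
    ntip <- length(sim$tree$tip.label)
    hits <- 0; tot <- 0
    for (cid in ids) {
      pr <- prune_for_character(sim$tree, tm, cid)
      k <- tm$schema$characters[[cid]]$n_states
      fit <- fit_mk(pr$tree, pr$tip_states, k = k, models = "ER")
      marg <- floradisp:::mk_marginal(pr$tree, pr$tip_states, fit$Q)
      root_p <- length(pr$tree$tip.label) + 1
      truth <- sim$node_states[as.character(ntip + 1L), cid]
      est <- which.max(marg[root_p, ]) - 1L
      hits <- hits + (est == truth); tot <- tot + 1
    }
    hits / tot
  }
  small <- mean(vapply(1:3, function(s) score(8, 100 + s), numeric(1)))
  large <- mean(vapply(1:3, function(s) score(60, 200 + s), numeric(1)))
  expect_gte(large, small - 0.2)  # allow sampling noise; trend not inverted
})
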