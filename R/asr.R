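# Mk-model ancestral state reconstruction: Felsenstein pruning likelihood
# for the k-state continuous-time Markov model (ER: one rate; ARD: k(k-1)
# free rates), ML fitting with AIC model choice, marginal node
# probabilities by the standard two-pass algorithm, stochastic node
# sampling (exact backward draws from the joint conditional distribution),
# and assembly of most-probable ancestral combinations as matrix rows.
#
# Root prior is uniform (1/k) throughout, configurable to the stationary
# distribution of the fitted generator.

# generator matrix from parameter vector: ER length-1, ARD length k(k-1)
# (row-major off-diagonal order)
mk_q_matrix <- function(rates, k, model = c("ER", "ARD")) {
  model <- match.arg(model)
  Q <- matrix(0, k, k)
  if (model == "ER") {
    stopifnot(length(rates) == 1)
    Q[] <- rates
  } else {
    stopifnot(length(rates) == k * (k - 1))
    Q[row(Q) != col(Q)] <- 0  # fill row-major below
    idx <- 1L
    for (i in seq_len(k)) for (j in seq_len(k)) if (i != j) {
      Q[i, j] <- rates[idx]; idx <- idx + 1L
    }
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

# transition probability matrix exp(Q t); ape's matexpo is a fast
# eigen-based exponential suited to small dense generators
mk_pmat <- function(Q, t) {
  P <- ape::matexpo(Q * t)
  # guard tiny negative round-off
  P[P < 0] <- 0
  P / rowSums(P)
}

# reorder tree edges so children precede parents (pruning order)
postorder_edges <- function(tree) ape::reorder.phylo(tree, "postorder")

# conditional likelihood table: rows = nodes (1..Ntip internal indexing of
# ape), cols = states; tips one-hot (or all-ones if state NA)
mk_down_pass <- function(tree, tip_states, Q) {
  k <- nrow(Q)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  L <- matrix(1, ntip + nnode, k)
  for (i in seq_len(ntip)) {
    s <- tip_states[[tree$tip.label[i]]]
    if (!is.na(s)) { L[i, ] <- 0; L[i, s + 1L] <- 1 }
  }
  tr <- postorder_edges(tree)
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    P <- mk_pmat(Q, tr$edge.length[e])
    L[parent, ] <- L[parent, ] * as.vector(P %*% L[child, ])
  }
  L
}

#' Mk-model log-likelihood by Felsenstein pruning
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param tip_states Named integer vector of state codes `0..k-1` (names =
#'   tip labels; `NA` = ambiguous tip).
#' @param k Number of states.
#' @param rates Rate parameters (ER: one value; ARD: `k(k-1)` values,
#'   row-major off-diagonal order).
#' @param model `"ER"` or `"ARD"`.
#' @param root_prior `"uniform"` (1/k, default) or `"stationary"`.
#' @return Log-likelihood (numeric scalar).
#' @export
mk_loglik <- function(tree, tip_states, k, rates, model = c("ER", "ARD"),
                      root_prior = c("uniform", "stationary")) {
  model <- match.arg(model)
  root_prior <- match.arg(root_prior)
  if (any(rates < 0)) stop("rates must be non-negative")
  Q <- mk_q_matrix(rates, k, model)
  L <- mk_down_pass(tree, tip_states, Q)
  root <- length(tree$tip.label) + 1L
  pi <- mk_root_prior(Q, root_prior)
  ll <- sum(pi * L[root, ])
  if (!is.finite(ll) || ll <= 0) return(-Inf)
  log(ll)
}

mk_root_prior <- function(Q, root_prior) {
  k <- nrow(Q)
  if (root_prior == "uniform") return(rep(1 / k, k))
  # stationary distribution: left null vector of Q
  ev <- eigen(t(Q))
  v <- abs(Re(ev$vectors[, which.min(abs(Re(ev$values)))]))
  v / sum(v)
}

#' Fit ER and ARD Mk models by maximum likelihood, choose by AIC
#'
#' Bounded quasi-Newton optimization (`L-BFGS-B` on log rates) from several
#' starting values. Returns both fits and the AIC-preferred one; a constant
#' character is flagged degenerate (rate at the lower boundary).
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param tip_states Named integer state vector (`0..k-1`, `NA` ambiguous).
#' @param k Number of states (default: inferred from the data).
#' @param n_starts Optimizer restarts per model.
#' @param root_prior Passed to [mk_loglik()].
#' @param models Candidate models to fit (default both ER and ARD).
#' @return Object of class `mk_fit`: `model`, `rates`, `Q`, `logL`, `AIC`,
#'   `k`, `fits` (fitted candidates), `degenerate`.
#' @export
fit_mk <- function(tree, tip_states, k = NULL, n_starts = 3,
                   root_prior = "uniform", models = c("ER", "ARD")) {
  models <- match.arg(models, several.ok = TRUE)
  obs <- tip_states[!is.na(tip_states)]
  if (is.null(k)) k <- max(obs) + 1L
  degenerate <- length(unique(obs)) < 2
  depth <- max(ape::node.depth.edgelength(tree))
  init_rates <- c(0.5, 0.05, 2) / max(depth, .Machine$double.eps)
  one_fit <- function(model, inits) {
    np <- if (model == "ER") 1L else k * (k - 1L)
    if (degenerate) {
      rates <- rep(1e-8, np)
      ll <- mk_loglik(tree, tip_states, k, rates, model, root_prior)
      return(list(model = model, rates = rates, logL = ll,
                  AIC = 2 * np - 2 * ll, converged = TRUE))
    }
    nll <- function(lr) {
      v <- -mk_loglik(tree, tip_states, k, exp(lr), model, root_prior)
      if (!is.finite(v)) 1e10 else v
    }
    best <- NULL
    for (r0 in inits) {
      o <- try(stats::optim(rep(log(r0), np), nll, method = "L-BFGS-B",
                            lower = log(1e-9), upper = log(1e4)),
               silent = TRUE)
      if (inherits(o, "try-error")) next
      if (is.null(best) || o$value < best$value) best <- o
    }
    if (is.null(best)) stop("Mk optimizer failed in all restarts (", model, ")")
    list(model = model, rates = exp(best$par), logL = -best$value,
         AIC = 2 * np + 2 * best$value, converged = best$convergence == 0)
  }
  fits <- list()
  if ("ER" %in% models)
    fits$ER <- one_fit("ER", init_rates[seq_len(min(n_starts, length(init_rates)))])
  if ("ARD" %in% models) {
    # warm-start the many-parameter ARD model from the fitted ER rate
    ard_init <- if (!is.null(fits$ER)) max(fits$ER$rates[1], 1e-8)
                else init_rates[1]
    fits$ARD <- one_fit("ARD", ard_init)
  }
  aics <- vapply(fits, `[[`, numeric(1), "AIC")
  chosen <- fits[[which.min(aics)]]
  structure(list(model = chosen$model, rates = chosen$rates,
                 Q = mk_q_matrix(chosen$rates, k, chosen$model),
                 logL = chosen$logL, AIC = chosen$AIC, k = k,
                 root_prior = root_prior,
                 fits = fits,
                 degenerate = degenerate),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("mk_fit: %s model, k = %d, logL = %.4f, AIC = %.2f%s\n",
              x$model, x$k, x$logL, x$AIC,
              if (x$degenerate) " (degenerate: constant character)" else ""))
  invisible(x)
}

#' Drop unusable tips before per-character ASR
#'
#' Removes tips whose cell for the focal character is missing, inapplicable
#' or polymorphic; `ape::drop.tip` suppresses the resulting unbranched
#' nodes and sums branch lengths through them.
#'
#' @param tree Rooted `phylo`.
#' @param tm A [trait_matrix()].
#' @param character_id Character (column) id.
#' @return List `tree` (pruned), `tip_states` (named integer vector),
#'   `dropped` (tip names removed).
#' @export
prune_for_character <- function(tree, tm, character_id) {
  j <- match(character_id, char_ids(tm$schema))
  if (is.na(j)) stop("unknown character: ", character_id)
  toks <- tm$cells[, j]
  usable <- vapply(toks, function(tok) {
    cell <- parse_token(tok)
    cell$kind == "observed" && length(cell$states) == 1L
  }, logical(1))
  names(usable) <- rownames(tm$cells)
  in_tree <- tree$tip.label[tree$tip.label %in% names(usable)]
  keep <- in_tree[usable[in_tree]]
  drop <- setdiff(tree$tip.label, keep)
  if (length(keep) < 2) stop("fewer than two usable tips for ", character_id)
  pruned <- if (length(drop)) ape::drop.tip(tree, drop) else tree
  states <- vapply(pruned$tip.label, function(tx)
    parse_token(tm$cells[tx, j])$states[1], integer(1))
  list(tree = pruned, tip_states = states, dropped = drop)
}

# up-pass marginal probabilities for every internal node (standard
# two-pass: conditional likelihoods below x partial likelihood of the rest
# of the tree), uniform or stationary root prior
mk_marginal <- function(tree, tip_states, Q, root_prior = "uniform") {
  k <- nrow(Q)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  L <- mk_down_pass(tree, tip_states, Q)
  pi <- mk_root_prior(Q, root_prior)
  # U[n, ] = likelihood of data outside the subtree of n, seen from n
  U <- matrix(NA_real_, ntip + nnode, k)
  root <- ntip + 1L
  U[root, ] <- pi
  tr <- postorder_edges(tree)
  edges <- tr$edge[rev(seq_len(nrow(tr$edge))), , drop = FALSE]  # preorder
  elen <- tr$edge.length[rev(seq_len(nrow(tr$edge)))]
  children_of <- split(seq_len(nrow(tr$edge)), tr$edge[, 1])
  for (e in seq_len(nrow(edges))) {
    parent <- edges[e, 1]; child <- edges[e, 2]
    P <- mk_pmat(Q, elen[e])
    # parent's message to child: U[parent] times siblings' contributions
    sib_edges <- children_of[[as.character(parent)]]
    msg <- U[parent, ]
    for (se in sib_edges) {
      sc <- tr$edge[se, 2]
      if (sc == child) next
      Ps <- mk_pmat(Q, tr$edge.length[se])
      msg <- msg * as.vector(Ps %*% L[sc, ])
    }
    U[child, ] <- as.vector(t(P) %*% msg)
  }
  post <- L * U
  post / rowSums(post)
}

#' Stochastic sampling of ancestral node states
#'
#' Samples joint node-state configurations conditional on the tip data and
#' the fitted generator: the root is drawn from its conditional
#' distribution, then each child node from `P(t)` weighted by its
#' conditional likelihoods (exact backward draws — no discretization). Node
#' state probabilities are the frequencies across simulations.
#'
#' @param tree Rooted `phylo`.
#' @param tip_states Named integer state vector.
#' @param fit An `mk_fit` (or a generator matrix via `Q`).
#' @param n_sims Number of simulations (default 500).
#' @param seed Integer seed.
#' @return Object of class `asr_result`: `node_probs` (node x state matrix
#'   of sampled frequencies), `marginal` (analytic marginal probabilities),
#'   `n_sims`, `k`, node numbering as in `ape` (`Ntip+1` = root).
#' @export
stochastic_map <- function(tree, tip_states, fit, n_sims = 500, seed = NULL) {
  Q <- if (inherits(fit, "mk_fit")) fit$Q else fit
  root_prior <- if (inherits(fit, "mk_fit")) fit$root_prior else "uniform"
  k <- nrow(Q)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  L <- mk_down_pass(tree, tip_states, Q)
  pi <- mk_root_prior(Q, root_prior)
  tr <- postorder_edges(tree)
  pre <- rev(seq_len(nrow(tr$edge)))  # preorder edge sequence
  Pmats <- lapply(seq_len(nrow(tr$edge)), function(e)
    mk_pmat(Q, tr$edge.length[e]))
  root <- ntip + 1L
  counts <- matrix(0L, nnode, k)
  with_seed(seed, {
    for (s in seq_len(n_sims)) {
      state <- integer(ntip + nnode)
      w <- pi * L[root, ]
      state[root] <- sample.int(k, 1, prob = w)
      for (e in pre) {
        parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
        w <- Pmats[[e]][state[parent], ] * L[child, ]
        state[child] <- sample.int(k, 1, prob = w)
      }
      nodes <- (ntip + 1L):(ntip + nnode)
      counts[cbind(nodes - ntip, state[nodes])] <-
        counts[cbind(nodes - ntip, state[nodes])] + 1L
    }
  })
  node_probs <- counts / n_sims
  rownames(node_probs) <- as.character((ntip + 1L):(ntip + nnode))
  colnames(node_probs) <- paste0("state", 0:(k - 1))
  marg <- mk_marginal(tree, tip_states, Q, root_prior)
  marg <- marg[(ntip + 1L):(ntip + nnode), , drop = FALSE]
  dimnames(marg) <- dimnames(node_probs)
  structure(list(node_probs = node_probs, marginal = marg,
                 n_sims = n_sims, k = k, ntip = ntip),
            class = "asr_result")
}

#' Reconstruct ancestral combinations for named nodes across all characters
#'
#' Runs per-character tip pruning, ER/ARD ML fitting with AIC choice, and
#' stochastic node sampling, then assembles for each requested node the
#' most probable state per character. A character whose probabilities tie
#' at the top, or whose pruned tree lost the node, yields a missing cell.
#'
#' @param tree Rooted `phylo` whose tips match matrix taxa.
#' @param tm A [trait_matrix()] with polymorphism unresolved (polymorphic
#'   tips are dropped per character).
#' @param nodes Named list/vector: node numbers (ape numbering on the full
#'   tree) or internal-node labels; names become ancestor row names.
#' @param n_sims Simulations per character.
#' @param seed Integer seed.
#' @param source `"sampled"` (stochastic-map frequencies, default) or
#'   `"marginal"` (analytic marginals).
#' @return List: `matrix` (a [trait_matrix()] of ancestor rows), `detail`
#'   (long data frame node x character x state probabilities), `fits`
#'   (per-character `mk_fit`), `ties` (tie log).
#' @export
ancestral_combinations <- function(tree, tm, nodes, n_sims = 500,
                                   seed = NULL, source = c("sampled", "marginal")) {
  source <- match.arg(source)
  node_ids <- resolve_nodes(tree, nodes)
  ids <- char_ids(tm$schema)
  cells <- matrix(TOK_MISSING, nrow = length(node_ids), ncol = length(ids),
                  dimnames = list(names(node_ids), ids))
  detail <- list(); fits <- list(); ties <- list()
  for (ci in seq_along(ids)) {
    cid <- ids[ci]
    pr <- try(prune_for_character(tree, tm, cid), silent = TRUE)
    if (inherits(pr, "try-error")) next
    k <- tm$schema$characters[[ci]]$n_states
    fit <- fit_mk(pr$tree, pr$tip_states, k = k)
    fits[[cid]] <- fit
    sm <- stochastic_map(pr$tree, pr$tip_states, fit, n_sims = n_sims,
                         seed = if (is.null(seed)) NULL else derive_seed(seed, ci))
    probs <- if (source == "sampled") sm$node_probs else sm$marginal
    # map full-tree nodes onto pruned-tree nodes via shared tip descendants
    map <- match_nodes(tree, pr$tree, node_ids)
    for (ni in seq_along(node_ids)) {
      pn <- map[ni]
      if (is.na(pn)) next  # node lost in pruning -> missing cell
      p <- probs[as.character(pn), ]
      top <- which(p == max(p))
      detail[[length(detail) + 1]] <- data.frame(
        node = names(node_ids)[ni], character = cid,
        state = 0:(k - 1), probability = unname(p),
        stringsAsFactors = FALSE)
      if (length(top) > 1) {
        ties[[length(ties) + 1]] <- data.frame(
          node = names(node_ids)[ni], character = cid,
          tied_states = paste(top - 1, collapse = "&"),
          stringsAsFactors = FALSE)
      } else {
        cells[ni, ci] <- as.character(top - 1L)
      }
    }
  }
  taxa <- data.frame(name = rownames(cells), status = "ancestor",
                     group = NA_character_, max_ma = NA_real_,
                     min_ma = NA_real_, stringsAsFactors = FALSE)
  list(matrix = trait_matrix(cells, tm$schema, taxa),
       detail = if (length(detail)) do.call(rbind, detail) else NULL,
       fits = fits,
       ties = if (length(ties)) do.call(rbind, ties) else NULL)
}

# node spec -> named vector of node numbers on the full tree
resolve_nodes <- function(tree, nodes) {
  ntip <- length(tree$tip.label)
  if (is.null(names(nodes)))
    names(nodes) <- paste0("node", unlist(nodes))
  out <- integer(length(nodes))
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    if (is.character(nd)) {
      hit <- match(nd, tree$node.label)
      if (is.na(hit)) stop("unknown node label: ", nd)
      out[i] <- ntip + hit
    } else out[i] <- as.integer(nd)
  }
  names(out) <- names(nodes)
  out
}

# For each full-tree node, find the pruned-tree node with the same set of
# surviving tip descendants (NA if the clade collapsed).
match_nodes <- function(full, pruned, node_ids) {
  ntip_f <- length(full$tip.label)
  ntip_p <- length(pruned$tip.label)
  desc_f <- lapply(node_ids, function(n)
    intersect(tip_descendants(full, n), pruned$tip.label))
  out <- rep(NA_integer_, length(node_ids))
  pn_desc <- lapply((ntip_p + 1L):(ntip_p + pruned$Nnode), function(n)
    tip_descendants(pruned, n))
  for (i in seq_along(node_ids)) {
    want <- sort(desc_f[[i]])
    if (length(want) < 2) next
    for (j in seq_along(pn_desc)) {
      if (identical(sort(pn_desc[[j]]), want)) {
        out[i] <- ntip_p + j
        break
      }
    }
  }
  out
}

tip_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  tr <- postorder_edges(tree)
  # iterative descent
  todo <- node
  tips <- character(0)
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  while (length(todo)) {
    n <- todo[[1]]; todo <- todo[-1]
    ch <- kids[[as.character(n)]]
    for (c in ch) {
      if (c <= ntip) tips <- c(tips, tree$tip.label[c])
      else todo <- c(todo, c)
    }
  }
  tips
}
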