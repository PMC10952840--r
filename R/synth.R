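# Synthetic-data generator: group-structured categorical matrices with
# missing/inapplicable/polymorphic cells and fossil age ranges, and
# birth-death trees with Mk-evolved characters plus their true ancestral
# states. Defaults reproduce the composition of the floral dataset the
# pipeline is designed for: 30 characters (17/8/3/2 of 2/3/4/5 states),
# ~32% missing+inapplicable cells among extant taxa, ~36% among fossils,
# ~3% / ~2% polymorphic cells, fossil ages spanning 145-0 Ma.

#' Configuration for the synthetic matrix generator
#'
#' Per group and character, a state-frequency profile is drawn from a
#' Dirichlet distribution; `divergence` mixes each group's profile with a
#' group-specific preferred state (0 = exchangeable groups, 1 = each group
#' nearly fixed for its own state), which directly controls between-group
#' distance. The schema's constraint rules force inapplicable cells from
#' the drawn states; missing cells are then overlaid so that
#' `missing_rate` is the expected total missing + inapplicable proportion,
#' and a polymorphic mask is applied to observed cells.
#'
#' @param n_groups Number of groups.
#' @param taxa_per_group Taxa per group (recycled; each >= 3).
#' @param schema A [character_set()] (default [floral_schema()]).
#' @param alpha Dirichlet concentration of state-frequency profiles.
#' @param divergence Between-group divergence in `[0, 1]`.
#' @param missing_rate Target total proportion of missing plus
#'   inapplicable cells.
#' @param polymorphic_rate Probability an observed multi-draw cell is
#'   polymorphic.
#' @param fossil_fraction Fraction of taxa flagged fossil with an age range.
#' @param age_max_ma,age_min_ma Span from which fossil ages are drawn.
#' @param seed Integer seed.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_groups = 4, taxa_per_group = 30,
                         schema = floral_schema(), alpha = 1,
                         divergence = 0.5, missing_rate = 0.32,
                         polymorphic_rate = 0.03, fossil_fraction = 0,
                         age_max_ma = 145, age_min_ma = 0, seed = NULL) {
  stopifnot(n_groups >= 1, all(taxa_per_group >= 3),
            missing_rate >= 0, missing_rate <= 1,
            polymorphic_rate >= 0, polymorphic_rate <= 1,
            divergence >= 0, divergence <= 1,
            fossil_fraction >= 0, fossil_fraction <= 1)
  structure(list(n_groups = n_groups,
                 taxa_per_group = rep_len(taxa_per_group, n_groups),
                 schema = schema, alpha = alpha, divergence = divergence,
                 missing_rate = missing_rate,
                 polymorphic_rate = polymorphic_rate,
                 fossil_fraction = fossil_fraction,
                 age_max_ma = age_max_ma, age_min_ma = age_min_ma,
                 seed = seed),
            class = "synth_config")
}

rdirichlet1 <- function(alpha_vec) {
  g <- stats::rgamma(length(alpha_vec), shape = alpha_vec, rate = 1)
  if (all(g == 0)) g[1] <- 1
  g / sum(g)
}

#' Generate a synthetic trait matrix with known group structure
#'
#' @param cfg A [synth_config()].
#' @return List: `matrix` (a [trait_matrix()]), `truth` (per-group,
#'   per-character state-frequency profiles and the mask rates actually
#'   realized).
#' @export
generate_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  cs <- cfg$schema
  ks <- n_states(cs)
  p <- length(ks)
  n <- sum(cfg$taxa_per_group)
  with_seed(cfg$seed, {
    group_of <- rep(paste0("G", seq_len(cfg$n_groups)), cfg$taxa_per_group)
    # one shared base profile per character: at divergence 0 all groups
    # draw from the same distribution (exchangeable); divergence mixes in
    # a group-specific preferred state
    base <- lapply(seq_len(p), function(j) rdirichlet1(rep(cfg$alpha, ks[j])))
    profiles <- vector("list", cfg$n_groups)
    codes <- matrix(NA_integer_, n, p)
    for (g in seq_len(cfg$n_groups)) {
      prof <- vector("list", p)
      for (j in seq_len(p)) {
        pref <- ((g - 1L) %% ks[j]) + 1L  # group's preferred state
        point <- rep(0, ks[j]); point[pref] <- 1
        prof[[j]] <- (1 - cfg$divergence) * base[[j]] + cfg$divergence * point
      }
      profiles[[g]] <- prof
      rows <- which(group_of == paste0("G", g))
      for (j in seq_len(p)) {
        codes[rows, j] <- sample.int(ks[j], length(rows), replace = TRUE,
                                     prob = prof[[j]]) - 1L
      }
    }
    toks <- matrix(as.character(codes), n, p)
    colnames(toks) <- char_ids(cs)
    # constraint rules force inapplicable cells first; missing cells are
    # then added so that missing_rate is the expected TOTAL proportion of
    # missing + inapplicable cells
    for (r in cs$constraints) {
      trig <- toks[, r$trigger_char] == as.character(r$trigger_state)
      toks[trig, r$consequences] <- TOK_INAPP
    }
    inapp <- toks == TOK_INAPP
    f_inapp <- mean(inapp)
    p_miss <- if (f_inapp >= cfg$missing_rate) 0
              else (cfg$missing_rate - f_inapp) / (1 - f_inapp)
    miss_mask <- matrix(stats::runif(n * p) < p_miss, n, p) & !inapp
    toks[miss_mask] <- TOK_MISSING
    # polymorphic overlay on the surviving observed cells, with the rate
    # adjusted so polymorphic_rate is the expected share of ALL cells
    obs_frac <- mean(!inapp & !miss_mask)
    p_poly <- min(1, cfg$polymorphic_rate / max(obs_frac, 1e-12))
    poly_mask <- matrix(stats::runif(n * p) < p_poly, n, p) &
      !inapp & !miss_mask
    for (idx in which(poly_mask)) {
      j <- ((idx - 1L) %/% n) + 1L
      s1 <- codes[idx]
      s2 <- sample(setdiff(0:(ks[j] - 1L), s1), 1L)
      toks[idx] <- paste(sort(c(s1, s2)), collapse = TOK_POLY_SEP)
    }
    names_ <- sprintf("tax%04d", seq_len(n))
    rownames(toks) <- names_
    is_fossil <- stats::runif(n) < cfg$fossil_fraction
    max_ma <- rep(NA_real_, n); min_ma <- rep(NA_real_, n)
    if (any(is_fossil)) {
      # age midpoint uniform in span; range width log-uniform in [1, 20] Myr
      mid <- stats::runif(sum(is_fossil), cfg$age_min_ma, cfg$age_max_ma)
      width <- exp(stats::runif(sum(is_fossil), log(1), log(20)))
      max_ma[is_fossil] <- pmin(mid + width / 2, cfg$age_max_ma)
      min_ma[is_fossil] <- pmax(mid - width / 2, 0)
    }
    taxa <- data.frame(name = names_,
                       status = ifelse(is_fossil, "fossil", "extant"),
                       group = group_of, max_ma = max_ma, min_ma = min_ma,
                       stringsAsFactors = FALSE)
    tm <- trait_matrix(toks, cs, taxa)
    list(matrix = tm,
         truth = list(profiles = profiles, group_of = group_of,
                      realized_missing = mean(toks == TOK_MISSING |
                                                toks == TOK_INAPP),
                      realized_polymorphic = mean(grepl(TOK_POLY_SEP, toks,
                                                        fixed = TRUE))))
  })
}

#' Simulate a dated tree with Mk-evolved characters and true node states
#'
#' A birth-death tree is simulated to the target tip count and rescaled to
#' `root_age`; each character then evolves under the true ER Mk process from
#' a uniformly drawn root state, recording every internal-node state for
#' recovery scoring.
#'
#' @param n_tips Number of tips.
#' @param schema A [character_set()]; default a small binary/multistate set
#'   via [floral_schema()].
#' @param q True ER rate (events per Myr per off-diagonal cell).
#' @param birth,death Birth-death rates for the tree shape.
#' @param root_age Root age (Myr; tree rescaled so max depth = root_age).
#' @param seed Integer seed.
#' @return List: `tree` (`phylo`, ultrametric), `matrix` (tip
#'   [trait_matrix()]), `node_states` (node x character true states),
#'   `q` (true rate).
#' @export
generate_tree_with_characters <- function(n_tips, schema = floral_schema(),
                                          q = 0.01, birth = 0.1, death = 0,
                                          root_age = 140, seed = NULL) {
  ks <- n_states(schema)
  p <- length(ks)
  with_seed(seed, {
    tree <- ape::rphylo(n_tips, birth = birth, death = death)
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length * root_age / depth
    ntip <- length(tree$tip.label)
    nnode <- tree$Nnode
    tree$tip.label <- sprintf("tax%04d", seq_len(ntip))
    tr <- postorder_edges(tree)
    pre <- rev(seq_len(nrow(tr$edge)))
    states <- matrix(NA_integer_, ntip + nnode, p)
    for (j in seq_len(p)) {
      k <- ks[j]
      Q <- mk_q_matrix(q, k, "ER")
      root <- ntip + 1L
      states[root, j] <- sample.int(k, 1) - 1L
      for (e in pre) {
        parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
        P <- mk_pmat(Q, tr$edge.length[e])
        states[child, j] <- sample.int(k, 1,
                                       prob = P[states[parent, j] + 1L, ]) - 1L
      }
    }
    toks <- matrix(as.character(states[seq_len(ntip), , drop = FALSE]),
                   ntip, p, dimnames = list(tree$tip.label, char_ids(schema)))
    tm <- trait_matrix(toks, schema)
    node_states <- states[(ntip + 1L):(ntip + nnode), , drop = FALSE]
    rownames(node_states) <- as.character((ntip + 1L):(ntip + nnode))
    colnames(node_states) <- char_ids(schema)
    list(tree = tree, matrix = tm, node_states = node_states, q = q)
  })
}

#' Synthetic study-scale dataset emulating the floral analysis conditions
#'
#' Convenience wrapper: 1201 extant taxa in 11 groups plus 121 fossils,
#' 30 characters, ~32%/36% missing+inapplicable and ~3%/2% polymorphic
#' cells, fossil ages spanning 145 to 2.6 Ma.
#'
#' @param seed Integer seed.
#' @param n_extant,n_fossil Taxon counts (defaults 1201, 121).
#' @param n_groups Number of extant groups (default 11).
#' @return List as in [generate_matrix()], extant and fossil rows combined.
#' @export
generate_study_dataset <- function(seed = NULL, n_extant = 1201,
                                   n_fossil = 121, n_groups = 11) {
  per <- diff(round(seq(0, n_extant, length.out = n_groups + 1)))
  cfg_e <- synth_config(n_groups = n_groups, taxa_per_group = pmax(per, 3),
                        divergence = 0.45, missing_rate = 0.32,
                        polymorphic_rate = 0.03,
                        seed = if (is.null(seed)) NULL else derive_seed(seed, 1))
  ext <- generate_matrix(cfg_e)
  cfg_f <- synth_config(n_groups = 3, taxa_per_group =
                          pmax(diff(round(seq(0, n_fossil, length.out = 4))), 3),
                        divergence = 0.55, missing_rate = 0.36,
                        polymorphic_rate = 0.02, fossil_fraction = 1,
                        age_max_ma = 145, age_min_ma = 2.6,
                        seed = if (is.null(seed)) NULL else derive_seed(seed, 2))
  fos <- generate_matrix(cfg_f)
  fos$matrix$taxa$name <- sub("^tax", "fos", fos$matrix$taxa$name)
  rownames(fos$matrix$cells) <- fos$matrix$taxa$name
  fos$matrix$taxa$group <- NA_character_
  comb <- rbind_matrices(ext$matrix, fos$matrix)
  list(matrix = comb, extant_truth = ext$truth, fossil_truth = fos$truth)
}
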