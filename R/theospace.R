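# Theoretical morphospace: exact counting and constrained uniform sampling
# of state combinations.

# Minimal exact non-negative integer arithmetic on base-1e4 digit vectors
# (least significant first). Products of per-character state counts exceed
# 2^53, so double precision cannot hold them exactly.
big_from_int <- function(x) {
  x <- as.integer(x)
  stopifnot(x >= 0L)
  if (x == 0L) return(0L)
  d <- integer(0)
  while (x > 0L) { d <- c(d, x %% 10000L); x <- x %/% 10000L }
  d
}

big_mul_small <- function(d, m) {
  m <- as.integer(m)
  carry <- 0
  out <- numeric(length(d))
  for (i in seq_along(d)) {
    v <- d[i] * m + carry
    out[i] <- v %% 10000
    carry <- v %/% 10000
  }
  while (carry > 0) { out <- c(out, carry %% 10000); carry <- carry %/% 10000 }
  as.integer(out)
}

big_to_string <- function(d) {
  n <- length(d)
  paste0(d[n], paste(sprintf("%04d", rev(d[-n])), collapse = ""))
}

#' Exact size of the unconstrained theoretical morphospace
#'
#' The number of state combinations is the product of the per-character
#' state counts. Computed in exact integer arithmetic (the 30-character
#' floral schema yields about 1.38e12; larger schemas overflow doubles).
#'
#' @param cs A [character_set()].
#' @return List with `count` (exact decimal string) and `count_num`
#'   (numeric, exact only below 2^53).
#' @export
count_combinations <- function(cs) {
  ks <- n_states(cs)
  if (!length(ks)) stop("empty character set")
  acc <- big_from_int(1L)
  for (k in ks) acc <- big_mul_small(acc, k)
  s <- big_to_string(acc)
  structure(list(count = s, count_num = as.numeric(s)),
            class = "combination_count")
}

#' @export
print.combination_count <- function(x, ...) {
  cat("theoretical combinations:", x$count,
      sprintf("(~%.3g)\n", x$count_num))
  invisible(x)
}

# Apply constraint rules to an integer state vector: triggered consequence
# characters are set NA (inapplicable). Returns NULL if the row is
# internally impossible (a consequence character carries an observed state
# required by another rule — cannot happen with acyclic rules, kept for
# safety).
apply_constraints <- function(states, cs) {
  inapp <- rep(FALSE, length(states))
  names(inapp) <- char_ids(cs)
  for (r in cs$constraints) {
    tv <- states[[r$trigger_char]]
    if (!is.na(tv) && tv == r$trigger_state) inapp[r$consequences] <- TRUE
  }
  states[inapp] <- NA_integer_
  states
}

# TRUE if an already-masked row satisfies every rule (no observed state on
# a consequence character whose trigger fires).
satisfies_constraints <- function(states, cs) {
  for (r in cs$constraints) {
    tv <- states[[r$trigger_char]]
    if (!is.na(tv) && tv == r$trigger_state &&
        any(!is.na(states[r$consequences]))) return(FALSE)
  }
  TRUE
}

#' Sample distinct theoretical combinations under applicability constraints
#'
#' Draws each character's state uniformly and independently, applies the
#' constraint rules (triggered consequence characters become inapplicable,
#' treated as missing downstream), and rejects duplicate rows until `n`
#' distinct combinations are collected. Sampling is uniform over raw
#' combinations before constraint masking.
#'
#' @param cs A [character_set()].
#' @param n Number of combinations (distinct rows) to draw.
#' @param seed Integer seed.
#' @param max_tries Rejection watchdog: give up after this many draws
#'   (default `1000 * n`), which detects `n` exceeding the constrained
#'   space size on small schemas.
#' @return A [trait_matrix()] of `n` theoretical rows named `theo0001`, ...
#' @export
sample_theoretical <- function(cs, n, seed = NULL, max_tries = NULL) {
  stopifnot(n >= 1)
  ks <- n_states(cs)
  p <- length(ks)
  if (is.null(max_tries)) max_tries <- 1000 * n
  with_seed(seed, {
    seen <- new.env(hash = TRUE, parent = emptyenv())
    rows <- matrix(NA_integer_, nrow = n, ncol = p)
    got <- 0L
    tries <- 0L
    while (got < n) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("rejection watchdog: could not draw ", n,
             " distinct constraint-satisfying combinations (space too small?)")
      draw <- vapply(ks, function(k) sample.int(k, 1L) - 1L, integer(1))
      names(draw) <- char_ids(cs)
      draw <- apply_constraints(draw, cs)
      key <- paste(ifelse(is.na(draw), "-", draw), collapse = ",")
      if (!is.null(seen[[key]])) next
      assign(key, TRUE, envir = seen)
      got <- got + 1L
      rows[got, ] <- draw
    }
    toks <- matrix(ifelse(is.na(rows), TOK_INAPP, as.character(rows)),
                   nrow = n, dimnames = list(
                     sprintf("theo%04d", seq_len(n)), char_ids(cs)))
    taxa <- data.frame(name = rownames(toks), status = "theoretical",
                       group = NA_character_, max_ma = NA_real_,
                       min_ma = NA_real_, stringsAsFactors = FALSE)
    trait_matrix(toks, cs, taxa)
  })
}

#' Bind trait matrices that share a schema (row-wise)
#'
#' Used to append theoretical combinations or ancestral-combination rows to
#' an empirical matrix before computing distances.
#'
#' @param ... [trait_matrix()] objects over the same character set.
#' @return A combined [trait_matrix()].
#' @export
rbind_matrices <- function(...) {
  tms <- list(...)
  stopifnot(length(tms) >= 1)
  ids <- char_ids(tms[[1]]$schema)
  for (tm in tms)
    if (!identical(char_ids(tm$schema), ids))
      stop("trait matrices use different schemas")
  cells <- do.call(rbind, lapply(tms, `[[`, "cells"))
  taxa <- do.call(rbind, lapply(tms, function(tm)
    tm$taxa[, c("name", "status", "group", "max_ma", "min_ma")]))
  trait_matrix(cells, tms[[1]]$schema, taxa)
}
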