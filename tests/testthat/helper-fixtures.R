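# Small schemas and matrices built in code, shared across test files.

# two characters: c1 unordered binary, c2 ordered 3-state
tiny_schema <- function() {
  character_set(list(
    character_def("c1", "binary unordered", 2, FALSE, "flower"),
    character_def("c2", "ordered three-state", 3, TRUE, "perianth")))
}

# mixed 8-character schema used by the distance oracle tests
mixed_schema <- function() {
  character_set(list(
    character_def("u2a", n_states = 2, ordered = FALSE, organ_block = "flower"),
    character_def("u2b", n_states = 2, ordered = FALSE, organ_block = "perianth"),
    character_def("o3a", n_states = 3, ordered = TRUE, organ_block = "perianth"),
    character_def("u3a", n_states = 3, ordered = FALSE, organ_block = "androecium"),
    character_def("o4a", n_states = 4, ordered = TRUE, organ_block = "androecium"),
    character_def("u4a", n_states = 4, ordered = FALSE, organ_block = "gynoecium"),
    character_def("o5a", n_states = 5, ordered = TRUE, organ_block = "gynoecium"),
    character_def("u5a", n_states = 5, ordered = FALSE, organ_block = "pollen")))
}

# random token matrix over mixed_schema with missing/inapplicable holes
random_matrix <- function(n_taxa, missing_rate = 0.2, seed = 1) {
  cs <- mixed_schema()
  ks <- vapply(cs$characters, `[[`, integer(1), "n_states")
  set.seed(seed)
  toks <- sapply(ks, function(k)
    as.character(sample(0:(k - 1), n_taxa, replace = TRUE)))
  toks <- matrix(toks, nrow = n_taxa)
  holes <- matrix(runif(length(toks)) < missing_rate, nrow = n_taxa)
  toks[holes] <- ifelse(runif(sum(holes)) < 0.5, "?", "-")
  colnames(toks) <- names(cs$characters)
  rownames(toks) <- sprintf("t%02d", seq_len(n_taxa))
  trait_matrix(toks, cs)
}

# independent brute-force mean character difference (double loop, no
# package distance code)
oracle_distance_matrix <- function(tm) {
  ks <- vapply(tm$schema$characters, `[[`, integer(1), "n_states")
  ord <- vapply(tm$schema$characters, `[[`, logical(1), "ordered")
  n <- nrow(tm$cells)
  codes <- suppressWarnings(matrix(as.integer(tm$cells), nrow = n))
  D <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- 0; cnt <- 0
    for (c in seq_along(ks)) {
      a <- codes[i, c]; b <- codes[j, c]
      if (is.na(a) || is.na(b)) next
      d <- if (ord[c]) abs(a - b) / (ks[c] - 1) else as.numeric(a != b)
      acc <- acc + d; cnt <- cnt + 1
    }
    D[i, j] <- if (cnt > 0) acc / cnt else NA_real_
  }
  diag(D) <- 0
  dimnames(D) <- dimnames(tm$cells)[c(1, 1)]
  D
}

# distance matrix object from an explicit symmetric matrix
dist_from_matrix <- function(D, status = "extant") {
  taxa <- data.frame(name = rownames(D), status = status,
                     group = NA_character_, max_ma = NA_real_,
                     min_ma = NA_real_, stringsAsFactors = FALSE)
  structure(list(D = D, comparable = 0 * D + 1, taxa = taxa,
                 dropped = data.frame(taxon = character(0),
                                      reason = character(0))),
            class = "mcd_dist")
}
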