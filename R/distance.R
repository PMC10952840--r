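# Mean character difference (Gower-type distance for mixed ordered and
# unordered categorical characters). Per character: unordered characters
# contribute 0/1 mismatches; ordered characters contribute |code_i -
# code_j|/(k-1), so every character's contribution lies in [0, 1] and so
# does the mean. Characters missing or inapplicable on either side are not
# comparable and are left out of the mean; a pair with zero comparable
# characters has an undefined distance.

#' Per-character dissimilarity between two cells
#'
#' @param state_i,state_j Integer state codes (or `NA` for a missing or
#'   inapplicable cell).
#' @param chardef A [character_def()].
#' @return Dissimilarity in `[0, 1]`, or `NA` if not comparable.
#' @export
char_distance <- function(state_i, state_j, chardef) {
  if (is.na(state_i) || is.na(state_j)) return(NA_real_)
  if (chardef$ordered) {
    abs(state_i - state_j) / (chardef$n_states - 1)
  } else {
    as.numeric(state_i != state_j)
  }
}

#' Mean character difference between two taxa
#'
#' The average of per-character dissimilarities over all characters observed
#' in both taxa. Undefined (`NA`) when the two taxa share no observed
#' character.
#'
#' @param row_i,row_j Integer state-code vectors (NA = missing/inapplicable).
#' @param schema A [character_set()].
#' @return A number in `[0, 1]` or `NA`.
#' @export
mean_character_difference <- function(row_i, row_j, schema) {
  d <- mapply(char_distance, row_i, row_j, schema$characters)
  if (all(is.na(d))) return(NA_real_)
  mean(d, na.rm = TRUE)
}

#' Pairwise mean-character-difference matrix
#'
#' Computes all pairwise distances, then (under `drop_policy =
#' "greedy_undefined"`) iteratively removes the taxon involved in the most
#' undefined pairs — ties broken alphabetically — until the matrix is fully
#' defined. Removals are logged in `$dropped`.
#'
#' @param tm A [trait_matrix()] with polymorphism already resolved.
#' @param drop_policy `"greedy_undefined"` (default) or `"none"`.
#' @return An object of class `mcd_dist`: list with `D` (symmetric numeric
#'   matrix), `comparable` (characters compared per pair), `taxa` (metadata
#'   of retained taxa), `dropped` (data frame of removed taxa).
#' @export
build_distance_matrix <- function(tm, drop_policy = c("greedy_undefined", "none")) {
  drop_policy <- match.arg(drop_policy)
  codes <- as_state_codes(tm)
  n <- nrow(codes)
  if (n < 2L) stop("need at least two taxa to build a distance matrix")
  ids <- rownames(codes)
  kk <- n_states(tm$schema)
  ord <- vapply(tm$schema$characters, `[[`, logical(1), "ordered")

  Dsum <- matrix(0, n, n)
  Cnt <- matrix(0L, n, n)
  for (j in seq_len(ncol(codes))) {
    x <- codes[, j]
    obs <- !is.na(x)
    if (sum(obs) < 2L) next
    xo <- x[obs]
    dj <- if (ord[j]) abs(outer(xo, xo, "-")) / (kk[j] - 1L)
          else 1 * outer(xo, xo, "!=")
    Dsum[obs, obs] <- Dsum[obs, obs] + dj
    Cnt[obs, obs] <- Cnt[obs, obs] + 1L
  }
  D <- ifelse(Cnt > 0L, Dsum / pmax(Cnt, 1L), NA_real_)
  diag(D) <- 0
  dimnames(D) <- list(ids, ids)
  dimnames(Cnt) <- list(ids, ids)

  dropped <- data.frame(taxon = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  if (drop_policy == "greedy_undefined") {
    repeat {
      undef <- is.na(D)
      diag(undef) <- FALSE
      if (!any(undef)) break
      cnt_undef <- rowSums(undef)
      worst <- names(cnt_undef)[cnt_undef == max(cnt_undef)]
      victim <- sort(worst)[1L]
      dropped <- rbind(dropped, data.frame(
        taxon = victim,
        reason = sprintf("undefined distance to %d taxa", max(cnt_undef)),
        stringsAsFactors = FALSE))
      keep <- rownames(D) != victim
      D <- D[keep, keep, drop = FALSE]
      Cnt <- Cnt[keep, keep, drop = FALSE]
      if (nrow(D) < 2L)
        stop("fewer than two taxa remain after dropping undefined pairs")
    }
  }
  taxa <- tm$taxa[match(rownames(D), tm$taxa$name), , drop = FALSE]
  rownames(taxa) <- NULL
  structure(list(D = D, comparable = Cnt, taxa = taxa, dropped = dropped),
            class = "mcd_dist")
}

#' @export
print.mcd_dist <- function(x, ...) {
  cat("mcd_dist:", nrow(x$D), "taxa;", nrow(x$dropped), "dropped\n")
  if (nrow(x$D) > 1) {
    v <- x$D[upper.tri(x$D)]
    cat(sprintf("  D range [%.3f, %.3f], mean %.3f\n",
                min(v), max(v), mean(v)))
  }
  invisible(x)
}

#' @export
as.dist.mcd_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$D, diag = diag, upper = upper)
}

#' Write a distance matrix and its drop log to CSV
#'
#' @param dm An `mcd_dist` object.
#' @param path Output CSV path for the taxon-labelled square matrix.
#' @param drop_log_path Optional path for the drop log.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path, drop_log_path = NULL) {
  df <- data.frame(taxon = rownames(dm$D), dm$D,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(drop_log_path))
    utils::write.csv(dm$dropped, drop_log_path, row.names = FALSE)
  invisible(path)
}

# Subset an mcd_dist to a set of taxon names (used by group metrics).
subset_dist <- function(dm, taxa) {
  idx <- match(taxa, rownames(dm$D))
  if (anyNA(idx)) stop("taxa absent from distance matrix: ",
                       paste(taxa[is.na(idx)], collapse = ", "))
  structure(list(D = dm$D[idx, idx, drop = FALSE],
                 comparable = dm$comparable[idx, idx, drop = FALSE],
                 taxa = dm$taxa[idx, , drop = FALSE],
                 dropped = dm$dropped),
            class = "mcd_dist")
}
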