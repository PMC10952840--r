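# Disparity metrics over a mean-character-difference matrix: per-group mean
# and maximum pairwise distance, rarefaction, partial contribution to total
# disparity (Ddelta), per-taxon eccentricity, and stratigraphic time-bin
# assignment for disparity-through-time analyses.

#' Stratigraphic time bins
#'
#' Default bins: Early Cretaceous (145-100.5 Ma), Late Cretaceous
#' (100.5-66 Ma), Paleogene (66-23.03 Ma); the Neogene (23.03-2.58 Ma) is
#' flagged excluded (too few well-described fossil flowers) and extant taxa
#' are pooled in a "living" bin.
#'
#' @return Data frame with columns `name`, `max_ma`, `min_ma`, `excluded`.
#' @export
default_time_bins <- function() {
  data.frame(
    name = c("Early Cretaceous", "Late Cretaceous", "Paleogene", "Neogene"),
    max_ma = c(145, 100.5, 66, 23.03),
    min_ma = c(100.5, 66, 23.03, 2.58),
    excluded = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

#' Assign taxa to stratigraphic time bins
#'
#' Fossils are binned by the midpoint of their age range: the bin whose
#' interval `(min_ma, max_ma]` contains the midpoint. Fossils falling in an
#' excluded bin get `NA` with `excluded = TRUE`. Extant taxa are assigned
#' the `"living"` bin.
#'
#' @param taxa Taxon metadata data frame (`name`, `status`, `max_ma`,
#'   `min_ma`), e.g. `tm$taxa` or `dm$taxa`.
#' @param bins Time-bin data frame as in [default_time_bins()].
#' @return Data frame `name`, `bin`, `excluded`, `midpoint_ma`.
#' @export
assign_time_bins <- function(taxa, bins = default_time_bins()) {
  if (any(bins$max_ma <= bins$min_ma)) stop("time bins must have max_ma > min_ma")
  o <- order(bins$max_ma, decreasing = TRUE)
  b <- bins[o, ]
  if (any(utils::head(b$min_ma, -1) < utils::tail(b$max_ma, -1)))
    stop("time bins overlap")
  out <- data.frame(name = taxa$name, bin = NA_character_, excluded = FALSE,
                    midpoint_ma = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(taxa))) {
    if (taxa$status[i] == "extant") {
      out$bin[i] <- "living"; out$midpoint_ma[i] <- 0
    } else if (taxa$status[i] == "fossil") {
      if (is.na(taxa$max_ma[i]) || is.na(taxa$min_ma[i]))
        stop("fossil without age range: ", taxa$name[i])
      mid <- (taxa$max_ma[i] + taxa$min_ma[i]) / 2
      out$midpoint_ma[i] <- mid
      hit <- which(mid <= b$max_ma & mid > b$min_ma)
      if (length(hit) == 1L) {
        if (b$excluded[hit]) out$excluded[i] <- TRUE
        else out$bin[i] <- b$name[hit]
      } else out$excluded[i] <- TRUE  # outside all bins
    }
    # theoretical/ancestor rows stay unbinned
  }
  out
}

# within-group pairwise distances (upper triangle, each unordered pair once)
group_pairs <- function(dm, members) {
  sub <- dm$D[members, members, drop = FALSE]
  sub[upper.tri(sub)]
}

#' Per-group disparity: mean, SD and maximum pairwise distance
#'
#' For each group, `meanD` (mean of the C(n,2) within-group pairwise
#' distances — the density of the group in morphospace), `sdD` (their SD)
#' and `maxD` (their maximum — the group's range). `Dtot` is `meanD` of
#' the pooled reference set.
#'
#' @param dm An `mcd_dist` object.
#' @param groups Named character vector or factor of group labels (names =
#'   taxon names), or a data frame with `name` and `group`/`bin` columns.
#'   Taxa with `NA` labels are ignored.
#' @return Object of class `disparity_report`: data frame with one row per
#'   group plus attribute `Dtot`.
#' @export
group_disparity <- function(dm, groups) {
  labs <- normalize_groups(dm, groups)
  keep <- !is.na(labs)
  tab <- table(labs[keep])
  if (any(tab < 2)) stop("group(s) with fewer than two taxa: ",
                         paste(names(tab)[tab < 2], collapse = ", "))
  rows <- lapply(sort(names(tab)), function(g) {
    v <- group_pairs(dm, names(labs)[!is.na(labs) & labs == g])
    data.frame(group = g, n = as.integer(tab[[g]]), meanD = mean(v),
               sdD = stats::sd(v), maxD = max(v), stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  all_v <- group_pairs(dm, names(labs)[keep])
  attr(rep, "Dtot") <- mean(all_v)
  class(rep) <- c("disparity_report", "data.frame")
  rep
}

#' @export
print.disparity_report <- function(x, ...) {
  cat("disparity_report (Dtot =", round(attr(x, "Dtot"), 4), ")\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

# Accept several shapes of group specification; returns named label vector
# aligned with the distance matrix, NA for unlabelled taxa.
normalize_groups <- function(dm, groups) {
  taxa <- rownames(dm$D)
  if (is.data.frame(groups)) {
    lab_col <- intersect(c("group", "bin"), names(groups))[1]
    if (is.na(lab_col)) stop("groups data frame needs a 'group' or 'bin' column")
    labs <- groups[[lab_col]][match(taxa, groups$name)]
  } else if (!is.null(names(groups))) {
    labs <- unname(groups[taxa])
  } else if (length(groups) == length(taxa)) {
    labs <- as.character(groups)
  } else stop("cannot align group labels with distance matrix taxa")
  labs <- as.character(labs)
  names(labs) <- taxa
  labs
}

#' Rarefied disparity distributions
#'
#' Subsamples `n_rarefied` taxa without replacement from each group,
#' recomputes the distance matrix on the subsample from the trait data, and
#' evaluates the metric; repeated `reps` times. Default `n_rarefied` is the
#' smallest group size minus one. Removes the sample-size sensitivity of
#' `meanD` and especially `maxD` when groups differ widely in size.
#'
#' @param tm A [trait_matrix()] (polymorphism resolved) holding every taxon
#'   in `groups`.
#' @param groups Group labels as in [group_disparity()].
#' @param metric `"meanD"` or `"maxD"`.
#' @param reps Number of replicates (default 1000).
#' @param n_rarefied Subsample size; default `min(group size) - 1`.
#' @param seed Integer seed.
#' @return Long data frame `group`, `replicate`, `value`.
#' @export
rarefy_disparity <- function(tm, groups, metric = c("meanD", "maxD"),
                             reps = 1000, n_rarefied = NULL, seed = NULL) {
  metric <- match.arg(metric)
  dm0 <- build_distance_matrix(tm, drop_policy = "greedy_undefined")
  labs <- normalize_groups(dm0, groups)
  labs <- labs[!is.na(labs)]
  tab <- table(labs)
  if (min(tab) < 3) stop("smallest group must have at least 3 taxa to rarefy")
  if (is.null(n_rarefied)) n_rarefied <- min(tab) - 1L
  if (any(tab < n_rarefied)) stop("n_rarefied exceeds a group's size")
  gnames <- sort(names(tab))
  fun <- if (metric == "meanD") mean else max
  with_seed(seed, {
    out <- vector("list", length(gnames))
    names(out) <- gnames
    for (g in gnames) {
      members <- names(labs)[labs == g]
      vals <- numeric(reps)
      for (r in seq_len(reps)) {
        sub <- if (length(members) == n_rarefied) members
               else sample(members, n_rarefied)
        idx <- match(sub, rownames(tm$cells))
        sub_tm <- trait_matrix(tm$cells[idx, , drop = FALSE], tm$schema,
                               tm$taxa[idx, , drop = FALSE])
        dms <- build_distance_matrix(sub_tm, drop_policy = "greedy_undefined")
        vals[r] <- fun(dms$D[upper.tri(dms$D)])
      }
      out[[g]] <- data.frame(group = g, replicate = seq_len(reps),
                             value = vals, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Partial contribution of a group to total disparity (Ddelta)
#'
#' `Ddelta_i = Dtot - meanD(dataset without group i)`: positive when the
#' group's presence raises the dataset's mean pairwise distance, negative
#' when it lowers it; the magnitude is the size of the contribution.
#'
#' @param dm An `mcd_dist` object.
#' @param groups Group labels as in [group_disparity()].
#' @param target_group Label of the group whose contribution is measured.
#' @param sign `"contribution"` (default, `Dtot - meanD_without`) or
#'   `"difference"` (the reverse sign).
#' @return A single signed number.
#' @export
ddelta <- function(dm, groups, target_group,
                   sign = c("contribution", "difference")) {
  sign <- match.arg(sign)
  labs <- normalize_groups(dm, groups)
  keep <- !is.na(labs)
  if (!target_group %in% labs[keep]) stop("unknown group: ", target_group)
  all_taxa <- names(labs)[keep]
  rest <- names(labs)[keep & labs != target_group]
  if (length(rest) < 2)
    stop("removing group '", target_group, "' leaves fewer than two taxa")
  Dtot <- mean(group_pairs(dm, all_taxa))
  Dwithout <- mean(group_pairs(dm, rest))
  d <- Dtot - Dwithout
  if (sign == "difference") d <- -d
  d
}

#' Per-taxon eccentricity
#'
#' A taxon's mean distance to all other taxa of the reference set (the
#' average of its row of the distance matrix); high values mark
#' morphological outliers at the edge of the occupied morphospace.
#'
#' @param dm An `mcd_dist` object.
#' @param reference Optional character vector of taxon names (default: all
#'   taxa in `dm`).
#' @return Data frame `taxon`, `eccentricity`, `rank`, sorted descending.
#' @export
eccentricity <- function(dm, reference = NULL) {
  taxa <- reference %||% rownames(dm$D)
  if (length(taxa) < 2) stop("reference needs at least two taxa")
  sub <- dm$D[taxa, taxa, drop = FALSE]
  ecc <- rowSums(sub) / (length(taxa) - 1)
  out <- data.frame(taxon = taxa, eccentricity = unname(ecc),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$eccentricity, out$taxon), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
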