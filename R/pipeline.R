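# Configuration-driven orchestration of the three analyses: disparity
# through time (fossil time bins + living pool), disparity among living
# groups, and ancestor placement in the morphospace. Each run resolves
# polymorphism once, builds the distance matrix, computes disparity
# metrics, ordinates, runs the group statistics, and writes artifacts plus
# a manifest capturing seeds and drop logs.

#' Read a pipeline run configuration from YAML
#'
#' Recognized keys: `matrix_file`, `schema_file`, `constraints_file`,
#' `groups_file`, `tree_file`, `analyses` (subset of `dtt`, `groups`,
#' `ancestors`), `excluded_groups`, `theoretical_n`, `rarefaction_reps`,
#' `n_permutations`, `seed`, `output_dir`, `time_bins` (list of name /
#' max_ma / min_ma / excluded).
#'
#' @param path YAML file path.
#' @return List of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(analyses = c("dtt", "groups"), excluded_groups = character(0),
                   theoretical_n = 2000, rarefaction_reps = 1000,
                   n_permutations = 9999, seed = 1L, output_dir = ".",
                   ancestor_nodes = NULL, n_sims = 500)
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  for (f in c("matrix_file", "schema_file", "constraints_file", "groups_file",
              "tree_file")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("configured file does not exist: ", cfg[[f]])
  }
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' @param config A `run_config` (from [read_run_config()]) or a list with
#'   the same fields; alternatively pass `tm` directly.
#' @param tm Optional [trait_matrix()] (overrides `matrix_file`).
#' @param tree Optional `phylo` for the ancestor analysis.
#' @return List of class `run_result` with per-analysis results and the
#'   manifest; artifacts are written under `config$output_dir` when it is
#'   set.
#' @export
run_pipeline <- function(config, tm = NULL, tree = NULL) {
  cfg <- config
  if (is.null(tm)) {
    schema <- read_schema(cfg$schema_file, cfg$constraints_file)
    tm <- read_matrix(cfg$matrix_file, schema, cfg$groups_file)
  }
  if (is.null(tree) && !is.null(cfg$tree_file))
    tree <- ape::read.tree(cfg$tree_file)
  seed <- cfg$seed %||% 1L
  out_dir <- cfg$output_dir
  write_out <- !is.null(out_dir)
  if (write_out) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, analyses = cfg$analyses,
                   n_taxa = nrow(tm$cells), n_characters = ncol(tm$cells),
                   excluded_groups = cfg$excluded_groups, stages = list())
  results <- list()

  log_stage <- function(name, before, after, note = "") {
    manifest$stages[[name]] <<- list(rows_before = before, rows_after = after,
                                     note = note)
  }

  # ancestors are reconstructed on the unresolved matrix (polymorphic tips
  # dropped per character), then appended before distances
  anc <- NULL
  if ("ancestors" %in% cfg$analyses && !is.null(tree)) {
    nodes <- cfg$ancestor_nodes %||%
      stats::setNames(list(length(tree$tip.label) + 1L), "root")
    anc <- ancestral_combinations(tree, tm, nodes,
                                  n_sims = cfg$n_sims %||% 500,
                                  seed = derive_seed(seed, 901))
    results$ancestors <- anc
    log_stage("ancestors", length(nodes), nrow(anc$matrix$cells))
  }

  res <- resolve_polymorphism(tm, seed = derive_seed(seed, 11))
  audit <- list(all = audit_missing(tm),
                extant = if (any(tm$taxa$status == "extant"))
                  audit_missing(tm, "extant") else NULL,
                fossil = if (any(tm$taxa$status == "fossil"))
                  audit_missing(tm, "fossil") else NULL)
  results$audit <- audit

  theo <- NULL
  if (!is.null(cfg$theoretical_n) && cfg$theoretical_n > 0) {
    theo <- sample_theoretical(tm$schema, cfg$theoretical_n,
                               seed = derive_seed(seed, 21))
    log_stage("theoretical", cfg$theoretical_n, nrow(theo$cells))
  }

  combined <- res
  if (!is.null(anc)) combined <- rbind_matrices(combined, anc$matrix)
  empirical_dm <- build_distance_matrix(combined)
  log_stage("distance_empirical", nrow(combined$cells), nrow(empirical_dm$D),
            sprintf("%d taxa dropped (undefined pairs)",
                    nrow(empirical_dm$dropped)))
  results$distance <- empirical_dm

  if (!is.null(theo)) {
    with_theo <- rbind_matrices(combined, theo)
    full_dm <- build_distance_matrix(with_theo)
    ord <- nmds_ordination(full_dm, k = 2, n_starts = cfg$n_starts %||% 20,
                           seed = derive_seed(seed, 31))
  } else {
    full_dm <- empirical_dm
    ord <- nmds_ordination(full_dm, k = 2, n_starts = cfg$n_starts %||% 20,
                           seed = derive_seed(seed, 31))
  }
  results$ordination <- ord

  if ("dtt" %in% cfg$analyses && any(empirical_dm$taxa$status == "fossil")) {
    bins <- if (!is.null(cfg$time_bins))
      do.call(rbind, lapply(cfg$time_bins, as.data.frame))
    else default_time_bins()
    binning <- assign_time_bins(empirical_dm$taxa, bins)
    bin_labels <- stats::setNames(binning$bin, binning$name)
    bin_labels <- drop_small_groups(bin_labels)
    dtt_disp <- group_disparity(empirical_dm, bin_labels)
    kw_in <- split_pairs_by_group(empirical_dm, bin_labels)
    dtt_kw <- kruskal_wallis(kw_in)
    dtt_perm <- permanova(empirical_dm, bin_labels,
                          n_permutations = cfg$n_permutations,
                          seed = derive_seed(seed, 41))
    results$dtt <- list(bins = binning, disparity = dtt_disp, kw = dtt_kw,
                        permanova = dtt_perm,
                        excluded = binning$name[binning$excluded])
    log_stage("dtt", nrow(binning), sum(!is.na(binning$bin)),
              sprintf("%d fossils excluded by bin rules", sum(binning$excluded)))
  }

  if ("groups" %in% cfg$analyses) {
    labs <- stats::setNames(empirical_dm$taxa$group, empirical_dm$taxa$name)
    labs[empirical_dm$taxa$status != "extant"] <- NA
    labs[labs %in% cfg$excluded_groups] <- NA
    labs <- drop_small_groups(labs)
    if (length(unique(stats::na.omit(labs))) >= 2) {
      grp_disp <- group_disparity(empirical_dm, labs)
      grp_kw <- kruskal_wallis(split_pairs_by_group(empirical_dm, labs))
      grp_perm <- permanova(empirical_dm, labs,
                            n_permutations = cfg$n_permutations,
                            seed = derive_seed(seed, 51))
      grp_pair <- pairwise_permanova(empirical_dm, labs,
                                     n_permutations =
                                       min(cfg$n_permutations, 999),
                                     seed = derive_seed(seed, 61))
      dd <- vapply(grp_disp$group, function(g)
        ddelta(empirical_dm, labs, g), numeric(1))
      grp_disp$Ddelta <- dd
      ecc <- eccentricity(empirical_dm,
                          reference = empirical_dm$taxa$name[
                            empirical_dm$taxa$status == "extant"])
      cors <- if (nrow(grp_disp) >= 3)
        list(meanD_vs_Ddelta = pearson_test(grp_disp$meanD, grp_disp$Ddelta))
      else list()
      results$groups <- list(disparity = grp_disp, kw = grp_kw,
                             permanova = grp_perm, pairwise = grp_pair,
                             eccentricity = ecc, correlations = cors)
      log_stage("groups", length(labs), sum(!is.na(labs)))
    }
  }

  if (write_out) {
    write_matrix(res, file.path(out_dir, "matrix_resolved.csv"))
    write_distance_matrix(empirical_dm,
                          file.path(out_dir, "distance_matrix.csv"),
                          file.path(out_dir, "distance_drop_log.csv"))
    write_ordination(ord, file.path(out_dir, "ordination_coordinates.csv"),
                     file.path(out_dir, "ordination_diagnostics.json"))
    if (!is.null(results$dtt))
      utils::write.csv(results$dtt$disparity,
                       file.path(out_dir, "dtt_disparity.csv"),
                       row.names = FALSE)
    if (!is.null(results$groups)) {
      utils::write.csv(results$groups$disparity,
                       file.path(out_dir, "group_disparity.csv"),
                       row.names = FALSE)
      utils::write.csv(results$groups$eccentricity,
                       file.path(out_dir, "eccentricity.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  results$manifest <- manifest
  structure(results, class = "run_result")
}

# groups with fewer than two members cannot contribute pairwise distances
drop_small_groups <- function(labs, min_size = 2L) {
  tab <- table(labs)
  labs[labs %in% names(tab)[tab < min_size]] <- NA
  labs
}

#' Within-group pairwise distances, split by group
#'
#' Collects, for each group, the vector of pairwise distances among its
#' members (each unordered pair once) — the input convention for
#' [kruskal_wallis()] on disparity data.
#'
#' @param dm An `mcd_dist` object.
#' @param labels Group labels as in [group_disparity()].
#' @return Named list of numeric vectors, one per group.
#' @export
split_pairs_by_group <- function(dm, labels) {
  labs <- normalize_groups(dm, labels)
  gl <- sort(unique(labs[!is.na(labs)]))
  out <- lapply(gl, function(g)
    group_pairs(dm, names(labs)[!is.na(labs) & labs == g]))
  names(out) <- gl
  out[lengths(out) > 0]
}

#' @export
print.run_result <- function(x, ...) {
  cat("run_result with components:",
      paste(setdiff(names(x), "manifest"), collapse = ", "), "\n")
  invisible(x)
}
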