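#' Define a single categorical character
#'
#' A character is a column of the trait matrix: a small set of discrete
#' states coded as contiguous integers starting at 0. Ordered characters
#' (e.g. organ counts binned into ranked classes) use the code as the rank,
#' so their per-character dissimilarity is graded; unordered characters
#' contribute 0/1 mismatches.
#'
#' @param id Short unique identifier (used as the matrix column name).
#' @param label Free-text description.
#' @param n_states Number of states `k` (>= 2); codes are `0:(k-1)`.
#' @param ordered Logical; if `TRUE` the state code is a rank.
#' @param organ_block One of `"flower"`, `"perianth"`, `"androecium"`,
#'   `"gynoecium"`, `"pollen"` — the floral module the character describes.
#' @param state_labels Optional character vector of length `n_states`.
#' @return An object of class `character_def`.
#' @export
character_def <- function(id, label = id, n_states, ordered = FALSE,
                          organ_block = c("flower", "perianth", "androecium",
                                          "gynoecium", "pollen"),
                          state_labels = NULL) {
  organ_block <- match.arg(organ_block)
  n_states <- as.integer(n_states)
  if (is.na(n_states) || n_states < 2L)
    stop("a character needs at least two states: ", id)
  if (is.null(state_labels)) state_labels <- paste0("state", 0:(n_states - 1L))
  if (length(state_labels) != n_states)
    stop("state_labels length must equal n_states for character ", id)
  structure(
    list(id = as.character(id), label = as.character(label),
         n_states = n_states, states = 0:(n_states - 1L),
         ordered = isTRUE(ordered), organ_block = organ_block,
         state_labels = as.character(state_labels)),
    class = "character_def")
}

#' Assemble a character set (schema) with applicability constraints
#'
#' @param characters List of [character_def()] objects with unique ids.
#' @param constraints Optional list of [constraint_rule()] objects.
#' @return An object of class `character_set`.
#' @export
character_set <- function(characters, constraints = list()) {
  ids <- vapply(characters, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate character ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  names(characters) <- ids
  cs <- structure(list(characters = characters, constraints = list()),
                  class = "character_set")
  if (length(constraints)) {
    for (r in constraints) cs <- add_constraint(cs, r)
  }
  cs
}

#' Applicability constraint: a trigger state forces other characters
#' to be inapplicable
#'
#' E.g. "perianth absent" makes perianth phyllotaxis, merism, fusion, and
#' differentiation inapplicable. Inapplicable cells are treated as missing
#' data in distance computations.
#'
#' @param trigger_char Character id whose state triggers the rule.
#' @param trigger_state Integer state code of the trigger.
#' @param consequences Character ids forced inapplicable when triggered.
#' @return An object of class `constraint_rule`.
#' @export
constraint_rule <- function(trigger_char, trigger_state, consequences) {
  if (trigger_char %in% consequences)
    stop("a constraint cannot make its own trigger inapplicable: ", trigger_char)
  structure(list(trigger_char = as.character(trigger_char),
                 trigger_state = as.integer(trigger_state),
                 consequences = as.character(consequences)),
            class = "constraint_rule")
}

add_constraint <- function(cs, rule) {
  stopifnot(inherits(cs, "character_set"), inherits(rule, "constraint_rule"))
  ids <- names(cs$characters)
  unknown <- setdiff(c(rule$trigger_char, rule$consequences), ids)
  if (length(unknown)) stop("constraint refers to unknown characters: ",
                            paste(unknown, collapse = ", "))
  if (!rule$trigger_state %in% cs$characters[[rule$trigger_char]]$states)
    stop("trigger state ", rule$trigger_state, " not a state of ",
         rule$trigger_char)
  # no cyclic triggering: a consequence character may not itself trigger a
  # rule whose consequences reach back to this trigger
  trig_of <- vapply(cs$constraints, `[[`, character(1), "trigger_char")
  for (r in cs$constraints) {
    if (rule$trigger_char %in% r$consequences && r$trigger_char %in% rule$consequences)
      stop("cyclic triggering between constraints on ", rule$trigger_char,
           " and ", r$trigger_char)
  }
  cs$constraints <- c(cs$constraints, list(rule))
  cs
}

#' @export
print.character_set <- function(x, ...) {
  k <- vapply(x$characters, `[[`, integer(1), "n_states")
  cat("character_set:", length(k), "characters (",
      paste(table(k), "x", names(table(k)), "-state", collapse = ", ", sep = ""),
      ")\n", sep = " ")
  cat(" ", sum(vapply(x$characters, `[[`, logical(1), "ordered")),
      "ordered;", length(x$constraints), "constraint rule(s)\n")
  invisible(x)
}

n_states <- function(cs) vapply(cs$characters, `[[`, integer(1), "n_states")
char_ids <- function(cs) names(cs$characters)

#' The 30-character floral organization schema
#'
#' Builds the default schema used throughout the package: 30 categorical
#' characters describing floral structure (Bauplan) — one for the whole
#' flower, eight for the perianth, eleven for the androecium, eight for the
#' gynoecium and two for pollen; 17 binary, 8 three-state, 3 four-state and
#' 2 five-state characters. Count-like characters (merism, whorl numbers,
#' stamen and carpel number classes, ovary position) are ordered. Two
#' applicability rules are bundled: an absent perianth makes the perianth
#' characters and stamen-perianth fusion inapplicable, and a single carpel
#' makes carpel fusion inapplicable.
#'
#' @return A [character_set()] with 30 characters and 2 constraint rules.
#' @export
floral_schema <- function() {
  ch <- list(
    # whole flower
    character_def("flw_sex", "Flower sex", 2, FALSE, "flower",
                  c("bisexual", "unisexual")),
    # perianth
    character_def("per_presence", "Perianth presence", 2, FALSE, "perianth",
                  c("absent", "present")),
    character_def("per_phyllotaxis", "Perianth phyllotaxis", 3, FALSE, "perianth",
                  c("spiral", "whorled", "irregular")),
    character_def("per_merism", "Perianth merism", 5, TRUE, "perianth",
                  c("dimerous", "trimerous", "tetramerous", "pentamerous",
                    "polymerous")),
    character_def("per_whorls", "Number of perianth whorls/series", 4, TRUE,
                  "perianth", c("one", "two", "three", "more than three")),
    character_def("per_differentiation", "Perianth differentiation", 3, FALSE,
                  "perianth", c("undifferentiated", "sepals and petals",
                                "graded")),
    character_def("per_fusion", "Perianth fusion", 2, FALSE, "perianth",
                  c("free", "fused")),
    character_def("per_symmetry", "Floral (perianth) symmetry", 3, FALSE,
                  "perianth", c("actinomorphic", "zygomorphic", "asymmetric")),
    character_def("per_petaloidy", "Petaloid organs present", 2, FALSE,
                  "perianth", c("no", "yes")),
    # androecium
    character_def("and_stamen_number", "Stamen number class", 5, TRUE,
                  "androecium", c("one", "2-5", "6-10", "11-20", "more than 20")),
    character_def("and_phyllotaxis", "Androecium phyllotaxis", 3, FALSE,
                  "androecium", c("spiral", "whorled", "irregular")),
    character_def("and_merism", "Androecium merism class", 4, TRUE,
                  "androecium", c("dimerous", "trimerous", "tetra-pentamerous",
                                  "polymerous")),
    character_def("and_whorls", "Number of androecium whorls", 4, TRUE,
                  "androecium", c("one", "two", "three", "more than three")),
    character_def("and_stamen_fusion", "Fusion of stamens", 2, FALSE,
                  "androecium", c("free", "fused")),
    character_def("and_per_fusion", "Stamen-perianth fusion", 2, FALSE,
                  "androecium", c("free", "fused")),
    character_def("and_anther_attachment", "Anther attachment", 2, FALSE,
                  "androecium", c("basifixed", "dorsifixed")),
    character_def("and_anther_dehiscence", "Anther dehiscence", 3, FALSE,
                  "androecium", c("longitudinal slits", "valvate", "poricidal")),
    character_def("and_anther_orientation", "Anther orientation", 2, FALSE,
                  "androecium", c("introrse", "extrorse")),
    character_def("and_staminodes", "Staminodes present", 2, FALSE,
                  "androecium", c("no", "yes")),
    character_def("and_filament", "Filament differentiation", 2, FALSE,
                  "androecium", c("undifferentiated", "distinct filament")),
    # gynoecium
    character_def("gyn_carpel_number", "Carpel number class", 3, TRUE,
                  "gynoecium", c("one", "2-5", "more than 5")),
    character_def("gyn_fusion", "Carpel fusion", 3, FALSE, "gynoecium",
                  c("apocarpous", "partly syncarpous", "fully syncarpous")),
    character_def("gyn_ovary_position", "Ovary position", 3, TRUE, "gynoecium",
                  c("superior", "half-inferior", "inferior")),
    character_def("gyn_style", "Style differentiation", 2, FALSE, "gynoecium",
                  c("undifferentiated", "differentiated")),
    character_def("gyn_phyllotaxis", "Gynoecium phyllotaxis", 2, FALSE,
                  "gynoecium", c("spiral", "whorled")),
    character_def("gyn_ovule_number", "Ovules per carpel", 2, FALSE,
                  "gynoecium", c("one", "several")),
    character_def("gyn_sealing", "Carpel sealing", 2, FALSE, "gynoecium",
                  c("by secretion", "postgenital fusion")),
    character_def("gyn_stigma", "Stigma extent", 2, FALSE, "gynoecium",
                  c("restricted", "extended")),
    # pollen
    character_def("pol_apertures", "Pollen aperture number", 2, FALSE, "pollen",
                  c("up to one", "two or more")),
    character_def("pol_tectum", "Pollen tectum", 2, FALSE, "pollen",
                  c("continuous/microperforate", "perforate/reticulate"))
  )
  rules <- list(
    constraint_rule("per_presence", 0L,
                    c("per_phyllotaxis", "per_merism", "per_whorls",
                      "per_differentiation", "per_fusion", "per_symmetry",
                      "per_petaloidy", "and_per_fusion")),
    constraint_rule("gyn_carpel_number", 0L, "gyn_fusion")
  )
  character_set(ch, rules)
}

#' Read a character schema from CSV
#'
#' Columns: `id`, `label`, `n_states`, `ordered` (TRUE/FALSE), `organ_block`,
#' optional `state_labels` (state names separated by `|`).
#'
#' @param path CSV file path.
#' @param constraints_path Optional constraints CSV with columns
#'   `trigger_char`, `trigger_state`, `consequences` (ids separated by `|`).
#' @return A [character_set()].
#' @export
read_schema <- function(path, constraints_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "label", "n_states", "ordered", "organ_block")
  if (!all(need %in% names(df)))
    stop("schema CSV must have columns: ", paste(need, collapse = ", "))
  chars <- lapply(seq_len(nrow(df)), function(i) {
    sl <- NULL
    if ("state_labels" %in% names(df) && nzchar(df$state_labels[i]))
      sl <- strsplit(df$state_labels[i], "|", fixed = TRUE)[[1]]
    character_def(df$id[i], df$label[i], df$n_states[i],
                  as.logical(df$ordered[i]), df$organ_block[i], sl)
  })
  rules <- list()
  if (!is.null(constraints_path)) {
    rc <- utils::read.csv(constraints_path, stringsAsFactors = FALSE)
    rules <- lapply(seq_len(nrow(rc)), function(i)
      constraint_rule(rc$trigger_char[i], rc$trigger_state[i],
                      strsplit(rc$consequences[i], "|", fixed = TRUE)[[1]]))
  }
  character_set(chars, rules)
}

#' Write a character schema (and its constraints) to CSV
#'
#' @param cs A [character_set()].
#' @param path Output CSV path for the characters.
#' @param constraints_path Optional output path for the constraint rules.
#' @return `path`, invisibly.
#' @export
write_schema <- function(cs, path, constraints_path = NULL) {
  df <- data.frame(
    id = char_ids(cs),
    label = vapply(cs$characters, `[[`, character(1), "label"),
    n_states = n_states(cs),
    ordered = vapply(cs$characters, `[[`, logical(1), "ordered"),
    organ_block = vapply(cs$characters, `[[`, character(1), "organ_block"),
    state_labels = vapply(cs$characters, function(ch)
      paste(ch$state_labels, collapse = "|"), character(1)),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(constraints_path)) {
    rc <- data.frame(
      trigger_char = vapply(cs$constraints, `[[`, character(1), "trigger_char"),
      trigger_state = vapply(cs$constraints, `[[`, integer(1), "trigger_state"),
      consequences = vapply(cs$constraints, function(r)
        paste(r$consequences, collapse = "|"), character(1)),
      stringsAsFactors = FALSE)
    utils::write.csv(rc, constraints_path, row.names = FALSE)
  }
  invisible(path)
}
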