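# Trait matrix data model.
#
# Cells are stored as character tokens: an integer code ("2"), a polymorphic
# set joined by "&" ("0&2"), "?" for missing, "-" for inapplicable. The token
# form preserves the missing/inapplicable distinction; distance computations
# pool the two (both mean "cannot compare") via as_state_codes().

TOK_MISSING <- "?"
TOK_INAPP <- "-"
TOK_POLY_SEP <- "&"

#' Construct a validated trait matrix
#'
#' @param cells Character matrix of cell tokens (rows = taxa, columns =
#'   character ids). Tokens: an integer state code, `"a&b"` for polymorphic
#'   cells, `"?"` missing, `"-"` inapplicable.
#' @param schema A [character_set()] whose character ids match the columns.
#' @param taxa Data frame with columns `name`, `status` (one of `"extant"`,
#'   `"fossil"`, `"theoretical"`, `"ancestor"`), and optionally `group`,
#'   `max_ma`, `min_ma`. Defaults to all-extant taxa named by the rownames.
#' @return An object of class `trait_matrix`.
#' @export
trait_matrix <- function(cells, schema, taxa = NULL) {
  stopifnot(inherits(schema, "character_set"), is.matrix(cells))
  cells <- apply(cells, c(1, 2), as.character)
  ids <- char_ids(schema)
  if (ncol(cells) != length(ids))
    stop("matrix has ", ncol(cells), " columns but schema declares ",
         length(ids), " characters")
  if (is.null(colnames(cells))) colnames(cells) <- ids
  if (!identical(colnames(cells), ids))
    stop("matrix column names do not match schema character ids")
  if (is.null(taxa)) {
    if (is.null(rownames(cells)))
      rownames(cells) <- paste0("t", seq_len(nrow(cells)))
    taxa <- data.frame(name = rownames(cells), status = "extant",
                       group = NA_character_, max_ma = NA_real_,
                       min_ma = NA_real_, stringsAsFactors = FALSE)
  }
  taxa <- as.data.frame(taxa, stringsAsFactors = FALSE)
  if (!"name" %in% names(taxa)) stop("taxa table needs a 'name' column")
  if (!"status" %in% names(taxa)) taxa$status <- "extant"
  for (col in c("group")) if (!col %in% names(taxa)) taxa[[col]] <- NA_character_
  for (col in c("max_ma", "min_ma")) if (!col %in% names(taxa)) taxa[[col]] <- NA_real_
  if (anyDuplicated(taxa$name))
    stop("duplicate taxon names: ",
         paste(unique(taxa$name[duplicated(taxa$name)]), collapse = ", "))
  if (nrow(taxa) != nrow(cells))
    stop("taxa table (", nrow(taxa), ") and matrix (", nrow(cells),
         ") disagree on the number of taxa")
  bad_status <- setdiff(taxa$status, c("extant", "fossil", "theoretical", "ancestor"))
  if (length(bad_status)) stop("unknown taxon status: ",
                               paste(bad_status, collapse = ", "))
  foss <- taxa$status == "fossil"
  if (any(foss & (is.na(taxa$max_ma) | is.na(taxa$min_ma))))
    stop("fossil taxa must carry an age range (max_ma, min_ma)")
  if (any(foss & (taxa$max_ma < taxa$min_ma | taxa$min_ma < 0)))
    stop("fossil age ranges must satisfy max_ma >= min_ma >= 0")
  rownames(cells) <- taxa$name
  tm <- structure(list(cells = cells, schema = schema, taxa = taxa),
                  class = "trait_matrix")
  validate_cells(tm)
  tm
}

parse_token <- function(tok) {
  # returns list(kind, states); states integer(0) for missing/inapplicable
  if (is.na(tok) || tok == TOK_MISSING) return(list(kind = "missing", states = integer(0)))
  if (tok == TOK_INAPP) return(list(kind = "inapplicable", states = integer(0)))
  parts <- strsplit(tok, TOK_POLY_SEP, fixed = TRUE)[[1]]
  st <- suppressWarnings(as.integer(parts))
  if (any(is.na(st))) stop("unparseable cell token: '", tok, "'")
  if (anyDuplicated(st)) stop("duplicated state in polymorphic token: '", tok, "'")
  list(kind = "observed", states = sort(st))
}

validate_cells <- function(tm) {
  ids <- char_ids(tm$schema)
  for (j in seq_along(ids)) {
    k <- tm$schema$characters[[j]]$n_states
    toks <- tm$cells[, j]
    for (i in seq_along(toks)) {
      cell <- parse_token(toks[i])
      if (cell$kind == "observed" &&
          (any(cell$states < 0L) || any(cell$states >= k)))
        stop("taxon '", rownames(tm$cells)[i], "', character '", ids[j],
             "': state outside declared set 0..", k - 1L,
             " (token '", toks[i], "')")
    }
  }
  invisible(tm)
}

#' @export
print.trait_matrix <- function(x, ...) {
  st <- table(x$taxa$status)
  cat("trait_matrix: ", nrow(x$cells), " taxa x ", ncol(x$cells),
      " characters (", paste(st, names(st), collapse = ", "), ")\n", sep = "")
  a <- audit_missing(x)
  cat(sprintf("  missing+inapplicable %.1f%%, polymorphic %.1f%%\n",
              100 * a$prop_missing_inapplicable, 100 * a$prop_polymorphic))
  invisible(x)
}

#' @export
dim.trait_matrix <- function(x) dim(x$cells)

#' Read a trait matrix from CSV files
#'
#' The matrix CSV has a `taxon` first column and one column per character,
#' with cell tokens as in [trait_matrix()]. The optional groups CSV carries
#' the taxon metadata (`taxon`, `group`, `status`, `max_Ma`, `min_Ma`).
#'
#' @param matrix_file Matrix CSV path.
#' @param schema Either a [character_set()] or the path of a schema CSV.
#' @param groups_file Optional groups CSV path.
#' @return A validated [trait_matrix()].
#' @export
read_matrix <- function(matrix_file, schema, groups_file = NULL) {
  if (!inherits(schema, "character_set")) schema <- read_schema(schema)
  df <- utils::read.csv(matrix_file, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  if (names(df)[1] != "taxon")
    stop("matrix CSV must have a leading 'taxon' column")
  cells <- as.matrix(df[, -1, drop = FALSE])
  rownames(cells) <- df$taxon
  taxa <- NULL
  if (!is.null(groups_file)) {
    g <- utils::read.csv(groups_file, stringsAsFactors = FALSE)
    names(g) <- sub("^max_Ma$", "max_ma", sub("^min_Ma$", "min_ma", names(g)))
    m <- match(df$taxon, g$taxon)
    if (anyNA(m)) stop("taxa absent from groups file: ",
                       paste(df$taxon[is.na(m)][1:min(5, sum(is.na(m)))],
                             collapse = ", "))
    taxa <- data.frame(name = df$taxon,
                       status = g$status[m] %||% "extant",
                       group = if ("group" %in% names(g)) g$group[m] else NA_character_,
                       max_ma = if ("max_ma" %in% names(g)) as.numeric(g$max_ma[m]) else NA_real_,
                       min_ma = if ("min_ma" %in% names(g)) as.numeric(g$min_ma[m]) else NA_real_,
                       stringsAsFactors = FALSE)
  }
  trait_matrix(cells, schema, taxa)
}

#' Write a trait matrix (and taxon metadata) to CSV
#'
#' @param tm A [trait_matrix()].
#' @param matrix_file Output matrix CSV path.
#' @param groups_file Optional output path for the taxon metadata.
#' @return `matrix_file`, invisibly.
#' @export
write_matrix <- function(tm, matrix_file, groups_file = NULL) {
  df <- data.frame(taxon = rownames(tm$cells), tm$cells,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, matrix_file, row.names = FALSE)
  if (!is.null(groups_file)) {
    g <- tm$taxa
    names(g)[names(g) == "name"] <- "taxon"
    utils::write.csv(g, groups_file, row.names = FALSE)
  }
  invisible(matrix_file)
}

#' Read a morphology matrix from a NEXUS file (read-only)
#'
#' Maps the NEXUS missing symbol to missing (`"?"`) and the gap symbol to
#' inapplicable (`"-"`). Polymorphisms in `{}`/`()` notation are joined with
#' `"&"` when `ape` exposes them as multi-state vectors.
#'
#' @param path NEXUS file path.
#' @param schema A [character_set()] describing the characters.
#' @return A validated [trait_matrix()].
#' @export
read_nexus_matrix <- function(path, schema) {
  dat <- ape::read.nexus.data(path)
  toks <- vapply(dat, function(x)
    vapply(x, function(cell) {
      cell <- tolower(paste(cell, collapse = TOK_POLY_SEP))
      if (cell %in% c("?", "n")) TOK_MISSING
      else if (cell == "-") TOK_INAPP
      else cell
    }, character(1)), character(length(dat[[1]])))
  cells <- t(toks)
  colnames(cells) <- char_ids(schema)
  trait_matrix(cells, schema)
}

#' Resolve polymorphic cells by uniform random choice
#'
#' Every polymorphic cell is replaced by one of its states drawn with equal
#' probability; monomorphic, missing and inapplicable cells are untouched.
#' Drawn once per analysis run — downstream metrics share one resolution.
#'
#' @param tm A [trait_matrix()].
#' @param seed Integer seed making the resolution reproducible.
#' @return A [trait_matrix()] with no polymorphic cells.
#' @export
resolve_polymorphism <- function(tm, seed = NULL) {
  cells <- tm$cells
  poly <- which(grepl(TOK_POLY_SEP, cells, fixed = TRUE))
  if (length(poly)) {
    with_seed(seed, {
      cells[poly] <- vapply(cells[poly], function(tok) {
        st <- parse_token(tok)$states
        as.character(st[sample.int(length(st), 1L)])
      }, character(1))
    })
  }
  tm$cells <- cells
  tm
}

#' Audit missing, inapplicable and polymorphic cells
#'
#' Missing and inapplicable cells are pooled (both are unusable in distance
#' computations); polymorphic cells are counted separately. Proportions are
#' exact rational counts over `|subset| * |characters|` cells.
#'
#' @param tm A [trait_matrix()].
#' @param status Optional status filter, e.g. `"extant"` or `"fossil"`;
#'   `NULL` audits all taxa.
#' @return List with cell counts and proportions.
#' @export
audit_missing <- function(tm, status = NULL) {
  keep <- if (is.null(status)) rep(TRUE, nrow(tm$cells))
          else tm$taxa$status %in% status
  if (!any(keep)) stop("empty taxon subset in audit")
  cells <- tm$cells[keep, , drop = FALSE]
  n <- length(cells)
  n_missing <- sum(cells == TOK_MISSING)
  n_inapp <- sum(cells == TOK_INAPP)
  n_poly <- sum(grepl(TOK_POLY_SEP, cells, fixed = TRUE))
  list(n_taxa = sum(keep), n_characters = ncol(cells), n_cells = n,
       n_missing = n_missing, n_inapplicable = n_inapp,
       n_missing_inapplicable = n_missing + n_inapp,
       n_polymorphic = n_poly,
       n_observed = n - n_missing - n_inapp,
       prop_missing_inapplicable = (n_missing + n_inapp) / n,
       prop_polymorphic = n_poly / n)
}

# Integer state codes with NA for missing/inapplicable; errors on
# unresolved polymorphism. The working representation for distances.
as_state_codes <- function(tm) {
  if (any(grepl(TOK_POLY_SEP, tm$cells, fixed = TRUE)))
    stop("matrix still contains polymorphic cells; run resolve_polymorphism()")
  codes <- suppressWarnings(
    matrix(as.integer(tm$cells), nrow = nrow(tm$cells),
           dimnames = dimnames(tm$cells)))
  codes
}
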