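#' Compound descriptor tables
#'
#' A compound table is a tibble with one row per compound: a `compound_id`
#' character column followed by numeric columns. Every numeric column carries a
#' role — `"descriptor"` (a molecular descriptor usable as a model input),
#' `"target"` (a quantity to be predicted, e.g. a tissue's log10 Kt:p or
#' log10 Vss), or `"predicted_ktp"` (a tissue partition coefficient predicted
#' by a phase-1 model and re-used as a model input). Roles live in the
#' `"roles"` attribute, so the CSV representation stays plain. Missing values
#' are `NA` and are first-class: the tissue Kt:p targets are mostly missing by
#' design.
#'
#' @param data A data frame with a `compound_id` column (or one supplied via
#'   row names) and numeric measurement columns.
#' @param targets Character vector of column names holding targets.
#' @param predicted_ktp Character vector of columns holding predicted log Kt:p
#'   values; all remaining numeric columns get the descriptor role.
#' @return A `compound_table` (a tibble subclass).
#' @export
compound_table <- function(data, targets = character(), predicted_ktp = character()) {
  data <- tibble::as_tibble(data)
  if (!"compound_id" %in% names(data)) {
    abort("`data` must contain a `compound_id` column.")
  }
  data$compound_id <- as.character(data$compound_id)
  dup <- data$compound_id[duplicated(data$compound_id)]
  if (length(dup)) {
    abort(paste0("Duplicated compound ids: ", paste(unique(dup), collapse = ", ")))
  }
  value_cols <- setdiff(names(data), "compound_id")
  if (anyDuplicated(names(data))) {
    abort("Column names must be unique.")
  }
  bad <- value_cols[!vapply(data[value_cols], is.numeric, logical(1))]
  if (length(bad)) {
    abort(paste0("Non-numeric columns: ", paste(bad, collapse = ", ")))
  }
  missing_roles <- setdiff(c(targets, predicted_ktp), value_cols)
  if (length(missing_roles)) {
    abort(paste0("Role assigned to absent columns: ",
                 paste(missing_roles, collapse = ", ")))
  }
  if (length(intersect(targets, predicted_ktp))) {
    abort("A column cannot be both a target and a predicted Kt:p descriptor.")
  }
  roles <- setNames(rep("descriptor", length(value_cols)), value_cols)
  roles[targets] <- "target"
  roles[predicted_ktp] <- "predicted_ktp"
  new_compound_table(data, roles)
}

new_compound_table <- function(data, roles) {
  attr(data, "roles") <- roles
  class(data) <- unique(c("compound_table", class(data)))
  data
}

#' @export
`[.compound_table` <- function(x, ...) {
  roles <- attr(x, "roles")
  out <- NextMethod()
  if (is.data.frame(out)) {
    out <- new_compound_table(out, roles[intersect(names(out), names(roles))])
  }
  out
}

#' Column roles of a compound table
#'
#' @param table A [compound_table()].
#' @return `col_roles()` returns the named role vector; the `*_names()`
#'   helpers return the column names in each role. `feature_names()` returns
#'   the columns usable as model inputs (descriptors plus predicted Kt:p).
#' @export
col_roles <- function(table) {
  roles <- attr(table, "roles")
  if (is.null(roles)) {
    value_cols <- setdiff(names(table), "compound_id")
    roles <- setNames(rep("descriptor", length(value_cols)), value_cols)
  }
  roles[intersect(names(table), names(roles))]
}

#' @rdname col_roles
#' @export
descriptor_names <- function(table) {
  roles <- col_roles(table)
  names(roles)[roles == "descriptor"]
}

#' @rdname col_roles
#' @export
target_names <- function(table) {
  roles <- col_roles(table)
  names(roles)[roles == "target"]
}

#' @rdname col_roles
#' @export
predicted_ktp_names <- function(table) {
  roles <- col_roles(table)
  names(roles)[roles == "predicted_ktp"]
}

#' @rdname col_roles
#' @export
feature_names <- function(table) {
  roles <- col_roles(table)
  names(roles)[roles %in% c("descriptor", "predicted_ktp")]
}

# Numeric matrix of model-input columns, rownames = compound ids.
feature_matrix <- function(table, features = feature_names(table)) {
  m <- as.matrix(as.data.frame(table[features], check.names = FALSE))
  rownames(m) <- table$compound_id
  m
}

#' Read a compound table from CSV
#'
#' The first column must hold unique compound identifiers; every other column
#' must be numeric. Empty cells and the `missing` sentinels are read as `NA`.
#' Column roles are not stored in the CSV; name the target columns here (or
#' pass a roles sidecar written by [write_compound_table()]).
#'
#' @param path Path to a CSV file with a header row.
#' @param targets Character vector of target column names.
#' @param predicted_ktp Character vector of predicted-Kt:p column names.
#' @param roles_path Optional JSON sidecar with the role map (overrides
#'   `targets`/`predicted_ktp`).
#' @param missing Strings treated as missing, besides the empty cell.
#' @return A [compound_table()].
#' @export
read_compound_table <- function(path, targets = character(),
                                predicted_ktp = character(),
                                roles_path = NULL, missing = c("", "NA")) {
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                                  name_repair = "minimal"))
  spec <- readr::cols(readr::col_character())
  spec$default <- readr::col_double()
  raw <- suppressWarnings(
    readr::read_csv(path, col_types = spec, na = missing,
                    show_col_types = FALSE, name_repair = "minimal"))
  probs <- readr::problems(raw)
  if (nrow(probs)) {
    p1 <- probs[1, ]
    abort(sprintf(
      "Non-numeric cell in %s at row %d, column '%s' (expected %s, got '%s').",
      path, p1$row - 1L, header[p1$col], p1$expected, p1$actual))
  }
  names(raw)[1] <- "compound_id"
  if (!is.null(roles_path)) {
    roles <- unlist(jsonlite::read_json(roles_path))
    targets <- names(roles)[roles == "target"]
    predicted_ktp <- names(roles)[roles == "predicted_ktp"]
  }
  compound_table(raw, targets = targets, predicted_ktp = predicted_ktp)
}

#' Write a compound table to CSV
#'
#' Missing values become empty cells; the result reads back identically with
#' [read_compound_table()]. When `roles_path` is given, the role map is
#' written as a JSON sidecar so the round trip also preserves roles.
#'
#' @param table A [compound_table()].
#' @param path Output CSV path.
#' @param roles_path Optional path for the JSON role sidecar.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(table, path, roles_path = NULL) {
  readr::write_csv(tibble::as_tibble(as.data.frame(table, check.names = FALSE)),
                   path, na = "")
  if (!is.null(roles_path)) {
    jsonlite::write_json(as.list(col_roles(table)), roles_path,
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Split a compound table into model-selection and external sets
#'
#' Uniformly random, seeded, disjoint and exhaustive partition — the
#' 402-compound model-selection / 202-compound external-validation design used
#' for the Vss-target data. External compounds must never influence fitting or
#' model selection.
#'
#' @param table A [compound_table()].
#' @param n_model_selection,n_external Sizes of the two parts; they must sum
#'   to `nrow(table)`.
#' @param seed Integer seed making the partition reproducible.
#' @return A list with elements `model_selection` and `external`.
#' @export
split_holdout <- function(table, n_model_selection, n_external, seed = 1L) {
  n <- nrow(table)
  if (n_model_selection + n_external != n) {
    abort(sprintf("Split sizes (%d + %d) must sum to the table size (%d).",
                  n_model_selection, n_external, n))
  }
  idx <- with_local_seed(seed, sample.int(n, n_model_selection))
  roles <- col_roles(table)
  list(
    model_selection = new_compound_table(table[sort(idx), , drop = FALSE], roles),
    external = new_compound_table(table[setdiff(seq_len(n), idx), , drop = FALSE], roles)
  )
}

#' Merge predicted log Kt:p columns into a compound table
#'
#' Adds the phase-1 model outputs as new columns with role `predicted_ktp`, so
#' phase-2 learners can use them as descriptors alongside the molecular
#' descriptors.
#'
#' @param table A [compound_table()].
#' @param predictions A data frame or named list of numeric columns aligned
#'   with the table rows (an optional `compound_id` column is checked against
#'   the table and dropped).
#' @return A new [compound_table()] with the added columns.
#' @export
merge_predicted_ktp <- function(table, predictions) {
  predictions <- tibble::as_tibble(predictions)
  if ("compound_id" %in% names(predictions)) {
    if (!identical(as.character(predictions$compound_id), table$compound_id)) {
      abort("`predictions` compound ids do not align with the table.")
    }
    predictions$compound_id <- NULL
  }
  if (ncol(predictions) == 0L) {
    return(table)
  }
  if (nrow(predictions) != nrow(table)) {
    abort(sprintf("`predictions` has %d rows but the table has %d.",
                  nrow(predictions), nrow(table)))
  }
  clash <- intersect(names(predictions), names(table))
  if (length(clash)) {
    abort(paste0("Prediction columns collide with existing columns: ",
                 paste(clash, collapse = ", ")))
  }
  out <- dplyr::bind_cols(tibble::as_tibble(as.data.frame(table, check.names = FALSE)),
                          predictions)
  roles <- c(col_roles(table),
             setNames(rep("predicted_ktp", ncol(predictions)), names(predictions)))
  new_compound_table(out, roles)
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}
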