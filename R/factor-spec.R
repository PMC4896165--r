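#' Describe a set of categorical factors
#'
#' A factor specification records the factor (covariate) labels and the number
#' of categories of each. Levels are always integer coded `0, ..., M_p - 1`
#' in data supplied to or returned by the package.
#'
#' @param names Character vector of unique factor labels.
#' @param levels Integer vector of category counts, each at least 2. Recycled
#'   to `length(names)` if a single value is given.
#'
#' @return An object of class `factor_spec`: a named integer vector of level
#'   counts.
#' @examples
#' factor_spec(LETTERS[1:6], 3)
#' @export
factor_spec <- function(names, levels) {
  names <- as.character(names)
  if (anyDuplicated(names)) abort("factor names must be unique")
  if (length(levels) == 1L) levels <- rep(levels, length(names))
  levels <- as.integer(levels)
  if (length(levels) != length(names)) {
    abort("`levels` must have length 1 or length(names)")
  }
  if (any(is.na(levels)) || any(levels < 2L)) {
    abort("every factor needs at least 2 levels")
  }
  structure(setNames(levels, names), class = "factor_spec")
}

#' @export
print.factor_spec <- function(x, ...) {
  cat("<factor_spec> ", length(x), " factors, ",
      format(count_cells(x), big.mark = ","), " cells\n", sep = "")
  print(setNames(as.integer(x), names(x)))
  invisible(x)
}

#' @export
`[.factor_spec` <- function(x, i) {
  structure(NextMethod(), class = "factor_spec")
}

is_factor_spec <- function(x) inherits(x, "factor_spec")

#' Infer a factor specification from integer-coded data
#'
#' Assumes every level `0..M_p - 1` is observed at least once, which holds for
#' all but tiny samples.
#'
#' @param data Data frame of integer-coded covariates (levels from 0).
#' @return A [factor_spec()].
#' @export
infer_spec <- function(data) {
  data <- as.data.frame(data)
  check_levels(data)
  factor_spec(names(data), vapply(data, function(x) as.integer(max(x)) + 1L,
                                  integer(1)))
}

check_levels <- function(data, spec = NULL) {
  for (j in seq_along(data)) {
    x <- data[[j]]
    if (!is.numeric(x) || any(x != floor(x)) || any(is.na(x))) {
      abort(paste0("column '", names(data)[j],
                   "' must contain non-missing integer levels"))
    }
    if (any(x < 0)) abort(paste0("column '", names(data)[j],
                                 "' has negative levels; coding starts at 0"))
    if (!is.null(spec) && any(x >= spec[[names(data)[j]]])) {
      bad <- which(x >= spec[[names(data)[j]]])[1]
      abort(paste0("column '", names(data)[j], "', row ", bad,
                   ": level out of range for spec"))
    }
  }
  invisible(data)
}

#' Enumerate the cells of a contingency table
#'
#' Cells are listed in the package's canonical order: the last factor varies
#' fastest (row-major over levels).
#'
#' @param spec A [factor_spec()].
#' @return A tibble with one integer column per factor and one row per cell.
#' @export
cell_grid <- function(spec) {
  stopifnot(is_factor_spec(spec))
  g <- expand.grid(rev(lapply(as.integer(spec), function(m) 0:(m - 1L))),
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, rev(seq_along(g)), drop = FALSE]
  names(g) <- names(spec)
  tibble::as_tibble(g)
}

#' Assemble or validate a contingency table
#'
#' Takes a long-format table (one integer level column per factor plus a
#' `count` column), completes missing cells with zeros (with a warning), and
#' returns the table in canonical cell order with the spec attached.
#'
#' @param data Long-format data frame: one column per factor plus `count`.
#' @param spec A [factor_spec()]; inferred from the data when `NULL`.
#' @return A tibble of class `contingency_tbl` with attribute `spec`.
#' @export
contingency_table <- function(data, spec = NULL) {
  data <- tibble::as_tibble(data)
  if (!"count" %in% names(data)) abort("table needs a `count` column")
  counts <- data$count
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    abort("cell counts must be non-negative integers")
  }
  vars <- data[setdiff(names(data), "count")]
  if (is.null(spec)) spec <- infer_spec(vars) else check_levels(vars, spec)
  vars <- vars[names(spec)]
  idx <- cell_index(vars, spec)
  if (anyDuplicated(idx)) abort("duplicate cells in contingency table")
  full <- numeric(count_cells(spec))
  full[idx] <- counts
  if (length(idx) < length(full)) {
    warn(paste0(length(full) - length(idx),
                " cells absent from input; filled with zero counts"))
  }
  out <- cell_grid(spec)
  out$count <- full
  structure(out, spec = spec, class = c("contingency_tbl", class(out)))
}

# canonical cell index (1-based) of level combinations, last factor fastest
cell_index <- function(vars, spec) {
  P <- length(spec)
  idx <- rep(0, nrow(vars))
  for (p in seq_len(P)) idx <- idx * spec[[p]] + vars[[p]]
  as.integer(idx + 1)
}

#' Tally subject-level covariate data into a contingency table
#'
#' @param data Data frame of integer-coded covariates, one row per subject.
#' @param spec A [factor_spec()]; inferred when `NULL`.
#' @return A `contingency_tbl` (see [contingency_table()]).
#' @export
as_contingency <- function(data, spec = NULL) {
  data <- tibble::as_tibble(data)
  if (is.null(spec)) spec <- infer_spec(data) else check_levels(data, spec)
  data <- data[names(spec)]
  idx <- cell_index(data, spec)
  full <- tabulate(idx, count_cells(spec))
  out <- cell_grid(spec)
  out$count <- as.numeric(full)
  structure(out, spec = spec, class = c("contingency_tbl", class(out)))
}

#' @export
print.contingency_tbl <- function(x, ...) {
  spec <- attr(x, "spec")
  cat("<contingency_tbl> ", length(spec), " factors, ", nrow(x), " cells, n = ",
      format(sum(x$count), big.mark = ","), "\n", sep = "")
  NextMethod()
}

table_spec <- function(table) {
  spec <- attr(table, "spec")
  if (is.null(spec)) abort("contingency table lacks a factor spec; use contingency_table()")
  spec
}

cell_counts <- function(table) as.numeric(table$count)
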