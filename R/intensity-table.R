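#' Feature-by-sample intensity table with a two-group design
#'
#' The central container of the quantification workflow: a numeric matrix of
#' strictly positive intensities (arbitrary units) with features in rows and
#' samples in columns, plus a group label (`"control"` or `"case"`) per
#' sample. Missing values are `NA` and are propagated, never imputed.
#'
#' @param values Numeric matrix, features x samples, with unique non-empty
#'   rownames (feature ids) and colnames (sample ids). Present values must be
#'   strictly positive; missing cells are `NA`.
#' @param group Character vector of length `ncol(values)` with entries
#'   `"control"` or `"case"`; at least two samples per group.
#' @return An object of class `intensity_table`: a list with elements
#'   `values` (the matrix) and `group` (named character vector keyed by
#'   sample id).
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), nrow = 2,
#'             dimnames = list(c("f1", "f2"), c("c1", "c2", "m1", "m2")))
#' tab <- intensity_table(m, c("control", "control", "case", "case"))
#' @export
intensity_table <- function(values, group) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_validation("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)) ||
      any(!nzchar(rownames(values)))) {
    stop_validation("feature ids (rownames) must be unique and non-empty")
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop_validation("sample ids (colnames) must be unique")
  }
  if (length(group) != ncol(values)) {
    stop_validation("'group' must have one label per sample column")
  }
  group <- as.character(group)
  if (!all(group %in% c("control", "case"))) {
    stop_validation("group labels must be 'control' or 'case'")
  }
  if (sum(group == "control") < 2L || sum(group == "case") < 2L) {
    stop_validation("each group needs at least 2 samples")
  }
  if (any(values[!is.na(values)] <= 0)) {
    stop_validation("all present intensities must be > 0")
  }
  structure(list(values = values, group = setNames(group, colnames(values))),
            class = "intensity_table")
}

#' @export
print.intensity_table <- function(x, ...) {
  cat(sprintf("intensity_table: %d features x %d samples (%d control, %d case)\n",
              nrow(x$values), ncol(x$values),
              sum(x$group == "control"), sum(x$group == "case")))
  cat(sprintf("missing cells: %d (%.1f%%)\n", sum(is.na(x$values)),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.intensity_table <- function(x) dim(x$values)

## Replace the value matrix, keeping the design.
set_values <- function(tab, values) {
  tab$values <- values
  tab
}

group_columns <- function(tab, which) {
  tab$values[, tab$group == which, drop = FALSE]
}
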