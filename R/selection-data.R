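#' Assemble a selection dataset
#'
#' Bundles the ingredients of a sample-selection analysis: an outcome that is
#' only observed for a subset of individuals, the design matrix of its
#' regression model, and the design matrix of the selection model, which must
#' contain at least one instrument for selection (a column associated with
#' selection but excluded from the outcome model).
#'
#' @param outcome Numeric vector of length n.  Entries for non-selected
#'   individuals may be `NA`; they are never used.
#' @param outcome_design n x p numeric matrix for the outcome regression,
#'   including an intercept column.
#' @param selection_design n x q numeric matrix for the selection model,
#'   including an intercept and the instrument(s) for selection.  Must be
#'   fully observed.
#' @param selected Logical or 0/1 vector of length n; `TRUE`/1 where the
#'   outcome is observed.  Defaults to `!is.na(outcome)`.
#' @param family Outcome family: `"linear"`, `"logistic"` or `"poisson"`.
#'
#' @return An object of class `"selection_data"`: a list with components
#'   `outcome`, `outcome_design`, `selection_design`, `selected`, `family`,
#'   and `n`.
#' @examples
#' set.seed(1)
#' n <- 200
#' z <- rnorm(n); x <- rnorm(n)
#' y <- 1 + 0.5 * x + rnorm(n)
#' r <- runif(n) < plogis(0.3 * x + 0.5 * z)
#' y[!r] <- NA
#' d <- selection_data(y, cbind(1, x = x), cbind(1, x = x, z = z))
#' @export
selection_data <- function(outcome, outcome_design, selection_design,
                           selected = NULL, family = c("linear", "logistic",
                                                       "poisson")) {
  family <- match.arg(family)
  outcome_design <- as.matrix(outcome_design)
  selection_design <- as.matrix(selection_design)
  n <- length(outcome)
  if (is.null(selected)) selected <- !is.na(outcome)
  selected <- as.logical(selected)
  if (nrow(outcome_design) != n || nrow(selection_design) != n ||
      length(selected) != n)
    stop("outcome, designs and selection indicator must have matching rows")
  if (anyNA(selection_design))
    stop("selection_design must be fully observed (the instrument for ",
         "selection must be measured for every individual)")
  if (anyNA(outcome_design))
    stop("outcome_design must be fully observed")
  if (anyNA(selected))
    stop("selection indicator contains NA")
  if (any(selected & is.na(outcome)))
    stop("outcome must be observed for every selected individual")
  if (n < ncol(outcome_design) + ncol(selection_design))
    stop("too few rows for the number of model columns")
  colnames(outcome_design) <- .fill_names(colnames(outcome_design),
                                          "x", ncol(outcome_design))
  colnames(selection_design) <- .fill_names(colnames(selection_design),
                                            "w", ncol(selection_design))
  structure(list(outcome = as.numeric(outcome),
                 outcome_design = outcome_design,
                 selection_design = selection_design,
                 selected = selected, family = family, n = n),
            class = "selection_data")
}

## default names for unnamed design columns; a leading constant column is
## recognized as the intercept
.fill_names <- function(nms, stem, k) {
  if (is.null(nms)) nms <- rep("", k)
  blank <- !nzchar(nms)
  nms[blank] <- paste0(stem, which(blank))
  nms
}

#' @export
print.selection_data <- function(x, ...) {
  cat("Selection dataset: n =", x$n, "(", sum(x$selected), "selected,",
      sprintf("%.1f%%", 100 * mean(x$selected)), ")\n")
  cat("Outcome family:", x$family, "\n")
  cat("Outcome design:", paste(colnames(x$outcome_design), collapse = ", "),
      "\nSelection design:",
      paste(colnames(x$selection_design), collapse = ", "), "\n")
  invisible(x)
}
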