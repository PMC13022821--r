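#' Read individual-level data from delimited text
#'
#' Reads a delimited text file (comma or tab, auto-detected from the
#' header line) with one row per individual and maps its columns onto the
#' roles of a selection analysis.  Missing outcome/exposure cells may be
#' empty fields or `NA`; the selection indicator, if not supplied, is
#' derived from missingness of the partially observed variable(s).  The
#' instrument for selection must be observed for every row.
#'
#' @param path Path to the file (header required).
#' @param roles Named list mapping roles to column names:
#'   `outcome` (required), `covariates` (character vector, optional),
#'   `selection_instrument` (required for any adjusted analysis),
#'   `selected` (optional), and for MR data `exposure` and
#'   `instruments` (character vector).
#' @return A [selection_data] object, or an [mr_data] object when
#'   `exposure` and `instruments` roles are present.
#' @export
read_individual_data <- function(path, roles) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("", "NA"), check.names = FALSE)
  need <- function(role) {
    cols <- roles[[role]]
    missing_cols <- setdiff(cols, names(df))
    if (length(missing_cols))
      stop("read_individual_data: role '", role, "' names absent column(s) ",
           paste(missing_cols, collapse = ", "))
    for (cn in cols)
      if (!is.numeric(df[[cn]]))
        stop("read_individual_data: non-numeric values in column '", cn,
             "' (role '", role, "')")
    cols
  }
  if (is.null(roles$outcome)) stop("roles$outcome is required")
  ycol <- need("outcome")
  y <- df[[ycol]]
  z <- NULL
  if (!is.null(roles$selection_instrument)) {
    zcol <- need("selection_instrument")
    z <- df[[zcol]]
    if (anyNA(z))
      stop("instrument for selection column '", zcol, "' contains missing ",
           "values; it must be observed for all individuals")
  }
  sel <- if (!is.null(roles$selected)) {
    as.logical(df[[need("selected")]])
  } else NULL

  if (!is.null(roles$instruments) && !is.null(roles$exposure)) {
    gcols <- need("instruments")
    xcol <- need("exposure")
    if (is.null(z)) stop("MR data require a selection_instrument role")
    d <- mr_data(as.matrix(df[gcols]), df[[xcol]], y, z, selected = sel)
    message("read ", d$n, " rows; missing exposure ",
            sum(is.na(d$exposure)), ", missing outcome ",
            sum(is.na(d$outcome)))
    return(d)
  }

  xcols <- if (!is.null(roles$covariates)) need("covariates") else character()
  X <- cbind(`(Intercept)` = 1, as.matrix(df[xcols]))
  W <- if (!is.null(z)) cbind(X, z = z) else X
  if (is.null(sel)) sel <- !is.na(y)
  d <- selection_data(y, X, W, selected = sel)
  message("read ", d$n, " rows; ", sum(!d$selected), " missing outcomes (",
          sprintf("%.1f%%", 100 * mean(!d$selected)), ")")
  d
}

#' Write a dataset to delimited text
#'
#' Inverse of [read_individual_data] for simulated datasets; masked cells
#' are written as empty fields.  Values are written with 15 significant
#' digits so a write-read round trip is lossless at that precision.
#'
#' @param data A [selection_data] or [mr_data] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_individual_data <- function(data, path) {
  if (inherits(data, "mr_data")) {
    df <- data.frame(data$instruments, x = data$exposure,
                     y = data$outcome, z = data$selection_instrument,
                     r = as.integer(data$selected), check.names = FALSE)
  } else {
    X <- data$outcome_design
    keep <- colnames(X) != "(Intercept)"
    W <- data$selection_design
    extra <- setdiff(colnames(W), c(colnames(X), "(Intercept)"))
    df <- data.frame(X[, keep, drop = FALSE],
                     W[, extra, drop = FALSE],
                     y = data$outcome,
                     r = as.integer(data$selected), check.names = FALSE)
  }
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(col) {
    out <- formatC(col, format = "g", digits = 15)
    out[is.na(col)] <- ""
    out
  })
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Serialize a fitted model to JSON
#'
#' Writes the coefficients, standard errors and nuisance parameters of a
#' `heckman_fit`, `ttw_fit`, `reg_fit` or `mr_estimate` to a JSON file (or
#' returns the JSON string when `path` is `NULL`).
#'
#' @param fit A fitted object from this package.
#' @param path Output path, or `NULL` to return the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @export
fit_to_json <- function(fit, path = NULL) {
  obj <- if (inherits(fit, "heckman_fit")) {
    list(model = "heckman", method = fit$method,
         beta = as.list(fit$beta), beta_se = as.list(
           stats::setNames(fit$beta_se, names(fit$beta))),
         gamma = as.list(fit$gamma), rho = fit$rho, sigma1 = fit$sigma1,
         rho_sigma = fit$rho_sigma, loglik = fit$loglik,
         n = fit$n, n_selected = fit$n_selected)
  } else if (inherits(fit, "ttw_fit")) {
    list(model = "ttw", mode = fit$mode, family = fit$family,
         beta = as.list(fit$beta), beta_se = as.list(
           stats::setNames(fit$beta_se, names(fit$beta))),
         eta = as.list(fit$eta), alpha_prop = as.list(fit$alpha_prop),
         sigma2 = fit$sigma2, loglik = fit$loglik,
         n = fit$n, n_selected = fit$n_selected)
  } else if (inherits(fit, "reg_fit")) {
    list(model = "glm", family = fit$family, beta = as.list(fit$beta),
         beta_se = as.list(stats::setNames(fit$beta_se, names(fit$beta))),
         n_used = fit$n_used)
  } else if (inherits(fit, "mr_estimate")) {
    list(model = "mr", method = fit$method, theta = fit$theta,
         theta_se = fit$theta_se, ci95 = fit$ci95,
         adjustment = as.list(fit$adjustment), n_boot = fit$n_boot)
  } else stop("fit_to_json: unsupported object")
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read and write per-variant summary statistics
#'
#' Delimited text with header columns `variant`, `beta_x`, `se_x`,
#' `beta_y`, `se_y`.
#'
#' @param path File path.
#' @return `read_summary_stats`: an `"mr_sumstats"` data frame.
#' @export
read_summary_stats <- function(path) {
  df <- utils::read.csv(path)
  need <- c("variant", "beta_x", "se_x", "beta_y", "se_y")
  if (!all(need %in% names(df)))
    stop("summary statistics file must have columns ",
         paste(need, collapse = ", "))
  if (any(df$se_x <= 0) || any(df$se_y <= 0))
    stop("summary statistics standard errors must be positive")
  attr(df, "two_sample") <- TRUE
  class(df) <- c("mr_sumstats", "data.frame")
  df
}

#' @rdname read_summary_stats
#' @param stats An `"mr_sumstats"` data frame.
#' @export
write_summary_stats <- function(stats, path) {
  utils::write.csv(as.data.frame(stats), path, row.names = FALSE)
  invisible(path)
}
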