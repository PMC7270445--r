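new_model_fit <- function(terms, n_used, adjustment_set = character(),
                          rss = NA_real_, df_resid = NA_integer_,
                          converged = TRUE, kind = "linear") {
  structure(list(terms = terms, n_used = n_used,
                 adjustment_set = adjustment_set, rss = rss,
                 df_resid = df_resid, converged = converged, kind = kind),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("<model_fit:", x$kind, "> n =", x$n_used,
      if (!x$converged) "(NOT converged)", "\n")
  print(x$terms)
  invisible(x)
}

#' Extract the coefficient table of a model fit
#'
#' @param fit A `model_fit`.
#' @return Tibble with columns `term`, `beta`, `se`, `stat`, `p`.
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, "model_fit"))
  fit$terms
}

# Design-matrix plumbing shared by the fitters: drop incomplete rows, add
# an intercept, and fail loudly (naming the aliased columns) on rank
# deficiency rather than silently dropping terms.
prepare_design <- function(y, X) {
  if (is.null(X)) X <- matrix(numeric(0), nrow = length(y), ncol = 0L)
  X <- as.matrix(X)
  if (ncol(X) > 0L && is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  keep <- if (ncol(X) > 0L) stats::complete.cases(y, X) else !is.na(y)
  y <- y[keep]
  X <- X[keep, , drop = FALSE]
  Xi <- cbind(`(Intercept)` = 1, X)
  n <- length(y)
  if (n <= ncol(Xi)) {
    stop("too few complete cases (", n, ") for ", ncol(Xi), " coefficients",
         call. = FALSE)
  }
  qrx <- qr(Xi)
  if (qrx$rank < ncol(Xi)) {
    aliased <- colnames(Xi)[qrx$pivot[(qrx$rank + 1L):ncol(Xi)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  list(y = y, X = Xi, n = n)
}

#' Fit a linear model by least squares
#'
#' Covariate-adjusted general linear model used throughout the association
#' stages. Incomplete rows are dropped (complete-case), an intercept is
#' always included, standard errors come from the unbiased residual
#' variance, and p-values are two-sided t tests.
#'
#' @param y Numeric outcome vector.
#' @param X Numeric matrix or data frame of predictors (no intercept
#'   column; one is added).
#' @param adjustment_set Names of the columns of `X` that are confounder
#'   adjustments rather than exposures of interest (recorded, not treated
#'   differently).
#' @return A `model_fit` with the coefficient table, `n_used`, residual
#'   sum of squares and residual degrees of freedom.
#' @export
fit_linear <- function(y, X, adjustment_set = character()) {
  d <- prepare_design(y, X)
  fit <- stats::lm.fit(d$X, d$y)
  beta <- fit$coefficients
  rss <- sum(fit$residuals^2)
  df_resid <- d$n - ncol(d$X)
  sigma2 <- rss / df_resid
  R <- qr.R(fit$qr)
  xtx_inv <- chol2inv(R)
  se <- sqrt(sigma2 * diag(xtx_inv))
  tstat <- beta / se
  p <- 2 * stats::pt(abs(tstat), df = df_resid, lower.tail = FALSE)
  new_model_fit(
    tibble::tibble(term = colnames(d$X), beta = unname(beta),
                   se = unname(se), stat = unname(tstat), p = unname(p)),
    n_used = d$n, adjustment_set = adjustment_set,
    rss = rss, df_resid = df_resid, kind = "linear")
}

# F-test comparing nested linear fits (reduced within full); used for
# multi-level factor effects where a single t row is not the right test.
ftest_nested <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "model_fit"), inherits(fit_reduced, "model_fit"))
  df1 <- fit_reduced$df_resid - fit_full$df_resid
  if (df1 <= 0) stop("models are not nested", call. = FALSE)
  f <- ((fit_reduced$rss - fit_full$rss) / df1) /
    (fit_full$rss / fit_full$df_resid)
  list(f = f, df1 = df1, df2 = fit_full$df_resid,
       p = stats::pf(f, df1, fit_full$df_resid, lower.tail = FALSE))
}

#' Fit a logistic regression
#'
#' Binomial GLM with logit link fitted by iteratively reweighted least
#' squares, Wald standard errors and two-sided z p-values. Complete
#' separation is flagged (`converged = FALSE`) rather than silently
#' reported as a finite estimate.
#'
#' @param y Binary outcome: logical, 0/1 numeric, or two-level factor
#'   (second level = event).
#' @param X Predictor matrix or data frame (intercept added).
#' @inheritParams fit_linear
#' @return A `model_fit` (kind `"logistic"`).
#' @export
fit_logistic <- function(y, X, adjustment_set = character()) {
  if (is.factor(y)) {
    if (nlevels(y) != 2L) stop("factor outcome must have 2 levels", call. = FALSE)
    y <- as.integer(y) - 1L
  }
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1) | is.na(y))) {
    stop("logistic outcome must be binary", call. = FALSE)
  }
  d <- prepare_design(y, X)
  if (length(unique(d$y)) < 2L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm.fit(d$X, d$y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-14, maxit = 100)))
  beta <- fit$coefficients
  # Wald covariance (X' W X)^{-1} from the final IRLS weights
  w <- fit$weights
  xtwx <- crossprod(d$X * sqrt(w))
  vcov <- tryCatch(chol2inv(chol(xtwx)), error = function(e) {
    matrix(NA_real_, ncol(d$X), ncol(d$X))
  })
  se <- sqrt(diag(vcov))
  z <- beta / se
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  mu <- fit$fitted.values
  separated <- any(mu < 1e-8 | mu > 1 - 1e-8) && max(abs(beta), na.rm = TRUE) > 12
  new_model_fit(
    tibble::tibble(term = colnames(d$X), beta = unname(beta),
                   se = unname(se), stat = unname(z), p = unname(p)),
    n_used = d$n, adjustment_set = adjustment_set,
    converged = fit$converged && !separated, kind = "logistic")
}

#' One-vs-reference multinomial logistic regression
#'
#' Decomposes a multi-level categorical outcome into one binary logistic
#' fit per non-reference level versus the reference level. This keeps
#' every reported contrast available and collapses exactly to
#' [fit_logistic()] for a two-level outcome; it is an approximation to the
#' joint softmax likelihood (each contrast conditions on membership in its
#' own pair of levels).
#'
#' @param y Factor outcome with at least 2 levels.
#' @param X Predictor matrix or data frame.
#' @param reference Reference level; defaults to the first level of `y`.
#' @inheritParams fit_linear
#' @return Named list of `model_fit`s, one per non-reference level.
#' @export
fit_multinomial <- function(y, X, reference = NULL,
                            adjustment_set = character()) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("outcome needs at least 2 levels", call. = FALSE)
  reference <- reference %||% levels(y)[1]
  if (!reference %in% levels(y)) stop("unknown reference level", call. = FALSE)
  other <- setdiff(levels(y), reference)
  X <- as.matrix(X)
  fits <- lapply(other, function(lev) {
    keep <- y %in% c(reference, lev)
    fit_logistic(as.integer(y[keep] == lev), X[keep, , drop = FALSE],
                 adjustment_set = adjustment_set)
  })
  stats::setNames(fits, other)
}

#' Gene-environment interaction model
#'
#' Linear model for a continuous outcome with GRS and 25(OH)D main effects,
#' their product term, and covariate adjustments; the product-term row is
#' returned prominently as `$interaction`. The GRS enters as the continuous
#' risk-allele count by default; passing a dichotomized group (factor or
#' 0/1) reproduces the stratified-display coding.
#'
#' @param outcome Continuous outcome (e.g. head circumference, cm).
#' @param grs Genetic risk score: numeric count, or 2-level factor/binary.
#' @param exposure Serum 25(OH)D (ng/mL) at the chosen trimester.
#' @param covariates Optional data frame / matrix of adjustment covariates.
#' @return A `model_fit` with an extra `$interaction` element (the
#'   product-term row of the coefficient table).
#' @export
interaction_fit <- function(outcome, grs, exposure, covariates = NULL) {
  if (is.factor(grs)) grs <- as.integer(grs) - 1L
  if (is.logical(grs)) grs <- as.integer(grs)
  X <- cbind(grs = as.numeric(grs), exposure = as.numeric(exposure),
             `grs:exposure` = as.numeric(grs) * as.numeric(exposure))
  adj <- character()
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    adj <- colnames(covariates)
    X <- cbind(X, covariates)
  }
  fit <- fit_linear(outcome, X, adjustment_set = adj)
  fit$interaction <- fit$terms[fit$terms$term == "grs:exposure", ]
  fit
}
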