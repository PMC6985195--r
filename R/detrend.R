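#' Select temporal predictors for one symptom by LASSO
#'
#' Fits an L1-penalized regression of a symptom series on the standardized
#' temporal basis over a log-spaced penalty path (via \pkg{glmnet}) and
#' returns the columns with non-zero coefficients at the cross-validated
#' penalty. Any subset of the seven columns may be retained: no hierarchy is
#' imposed between trends and cycles. The series is standardized internally
#' so the penalty treats all columns comparably.
#'
#' @param y numeric symptom series, complete cases aligned with `X`.
#' @param X standardized basis matrix (from [standardize_basis()]).
#' @param cv_folds number of cross-validation folds (default 10).
#' @param seed integer seed controlling the fold assignment.
#' @param rule penalty choice: `"min"` (default) picks the CV-minimum
#'   penalty; `"1se"` picks the sparsest model within one standard error of
#'   the minimum.
#' @param cv_type `"shuffle"` (default) assigns folds by seeded random
#'   shuffle; `"blocks"` uses contiguous time blocks, which is more robust
#'   to autocorrelation.
#' @return list with `retained` (character vector of column names, possibly
#'   empty), `lambda` (selected penalty) and `cv_fallback` (`TRUE` if CV was
#'   degenerate and BIC selection was used instead).
#' @export
select_temporal_predictors <- function(y, X, cv_folds = 10L, seed = 1L,
                                       rule = c("min", "1se"),
                                       cv_type = c("shuffle", "blocks")) {
  rule <- match.arg(rule)
  cv_type <- match.arg(cv_type)
  n <- length(y)
  if (n != nrow(X)) stop("y and X must have the same number of rows")
  if (n < 10L) stop("need at least 10 observations, got ", n)
  if (sd(y) == 0) stop("zero-variance series; screen endorsement first")
  ys <- (y - mean(y)) / sd(y)

  foldid <- if (cv_type == "shuffle") {
    with_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
  } else {
    sort(rep_len(seq_len(cv_folds), n)) # contiguous blocks in time order
  }

  fit <- tryCatch({
    cv <- glmnet::cv.glmnet(X, ys, foldid = foldid, standardize = FALSE,
                            family = "gaussian")
    lam <- if (rule == "1se") cv$lambda.1se else cv$lambda.min
    cf <- as.matrix(coef(cv, s = lam))[-1L, 1L]
    list(retained = names(cf)[cf != 0], lambda = lam, cv_fallback = FALSE)
  }, error = function(e) NULL)

  if (is.null(fit)) {
    warning("cross-validation degenerate; falling back to BIC selection")
    path <- glmnet::glmnet(X, ys, standardize = FALSE, family = "gaussian")
    pred <- predict(path, X)
    rss <- colSums((ys - pred)^2)
    bic <- n * log(rss / n) + path$df * log(n)
    k <- which.min(bic)
    cf <- as.matrix(coef(path))[-1L, k]
    fit <- list(retained = names(cf)[cf != 0], lambda = path$lambda[k],
                cv_fallback = TRUE)
  }
  fit
}

#' Refit retained temporal predictors by ordinary least squares
#'
#' Given the LASSO-retained columns, fits the unpenalized model and returns
#' coefficients, variance explained and residuals. With an empty retained
#' set only the intercept is fitted: R-squared is recorded as 0 and the
#' residuals are the mean-centered series.
#'
#' @param y numeric symptom series.
#' @param X standardized basis matrix.
#' @param retained character vector of retained column names (may be empty).
#' @param symptom optional label carried into the result.
#' @param lambda optional selected penalty carried into the result.
#' @return An object of class `"detrend_fit"`: list with `symptom`,
#'   `retained`, `beta` (named, including `(Intercept)`), `r_squared`,
#'   `residuals`, `fitted`, `lambda`, `n_obs`.
#' @export
refit_ols <- function(y, X, retained = character(0), symptom = NA_character_,
                      lambda = NA_real_) {
  n <- length(y)
  if (length(retained)) {
    if (!all(retained %in% colnames(X)))
      stop("retained column(s) absent from basis: ",
           paste(setdiff(retained, colnames(X)), collapse = ", "))
    Xr <- X[, retained, drop = FALSE]
    fit <- lm(y ~ Xr)
    cf <- coef(fit)
    names(cf) <- c("(Intercept)", retained)
    if (anyNA(cf)) {
      drop_cols <- retained[is.na(cf[-1L])]
      warning("dropping linearly dependent column(s): ",
              paste(drop_cols, collapse = ", "))
      return(refit_ols(y, X, setdiff(retained, drop_cols), symptom, lambda))
    }
    res <- residuals(fit)
    sst <- sum((y - mean(y))^2)
    r2 <- 1 - sum(res^2) / sst
  } else {
    cf <- c("(Intercept)" = mean(y))
    res <- y - mean(y)
    r2 <- 0
  }
  structure(list(symptom = symptom, retained = retained, beta = cf,
                 r_squared = r2, residuals = as.numeric(res),
                 fitted = y - as.numeric(res), lambda = lambda, n_obs = n),
            class = "detrend_fit")
}

#' @export
print.detrend_fit <- function(x, ...) {
  cat("Detrend fit", if (!is.na(x$symptom)) paste0("[", x$symptom, "]"),
      ": R^2 =", sprintf("%.2f", x$r_squared), "\n")
  cat("  retained:",
      if (length(x$retained)) paste(x$retained, collapse = ", ") else
        "(none)", "\n")
  invisible(x)
}

#' Detrend every endorsed symptom of one person
#'
#' Runs LASSO selection and OLS refitting symptom by symptom on the
#' complete-case rows, producing one [refit_ols()] result per endorsed
#' symptom. Each symptom draws its CV fold seed deterministically from
#' `seed`, so results are reproducible across runs and invariant to symptom
#' order.
#'
#' @param Y complete-case ratings matrix (rows aligned with `X`).
#' @param X standardized basis matrix.
#' @param seed master seed for fold assignment.
#' @param ... passed to [select_temporal_predictors()].
#' @return named list of `"detrend_fit"` objects, one per column of `Y`.
#' @export
detrend_symptoms <- function(Y, X, seed = 1L, ...) {
  syms <- colnames(Y)
  seeds <- derive_seeds(seed, length(syms))
  names(seeds) <- syms
  out <- lapply(syms, function(s) {
    sel <- tryCatch(
      select_temporal_predictors(Y[, s], X, seed = seeds[[s]], ...),
      error = function(e) stop("symptom ", s, ": ", conditionMessage(e),
                               call. = FALSE))
    refit_ols(Y[, s], X, sel$retained, symptom = s, lambda = sel$lambda)
  })
  names(out) <- syms
  out
}

# Cell states for the variance-explained grid
.cell_not_endorsed <- -1  # rendered as an en-dash
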