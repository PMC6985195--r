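#' Correlation matrix for network estimation
#'
#' @param Y numeric matrix, complete cases, each column non-constant.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(Y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  Y <- as.matrix(Y)
  if (anyNA(Y)) stop("Y must be complete cases")
  sds <- apply(Y, 2L, sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(Y)[sds == 0], collapse = ", "))
  if (nrow(Y) < ncol(Y))
    warning("fewer observations (", nrow(Y), ") than variables (", ncol(Y),
            "); estimates rely on regularization")
  S <- cor(Y, method = method)
  0.5 * (S + t(S))
}

#' Solve the graphical lasso at one penalty
#'
#' Maximizes `log det(Theta) - tr(S Theta) - lam * sum_(i!=j) |theta_ij|`
#' over positive-definite precision matrices (diagonal unpenalized) by block
#' coordinate descent. Warm starts accelerate penalty paths.
#'
#' @param S symmetric correlation matrix with unit diagonal. A matrix that
#'   is not positive semidefinite is repaired to the nearest PSD matrix
#'   (eigenvalue clipping) with a warning.
#' @param lam non-negative penalty.
#' @param tol convergence tolerance on the working covariance (relative to
#'   the mean absolute off-diagonal of `S`).
#' @param maxit maximum outer sweeps.
#' @param warm optional previous solution (list with `W`, `B`) to warm-start.
#' @param trace_objective record the penalized log-likelihood after each
#'   sweep.
#' @param penalty_weights optional symmetric matrix of relative per-edge
#'   penalty factors (effective penalty on edge ij is
#'   `lam * penalty_weights[i, j]`); 0 leaves an edge unpenalized. Default:
#'   uniform 1.
#' @return list with `Theta` (precision estimate), `W`, `B`, `objective`,
#'   `objective_trace`, `converged`, `iterations`.
#' @export
glasso_fit <- function(S, lam, tol = 1e-4, maxit = 200L, warm = NULL,
                       trace_objective = FALSE, penalty_weights = NULL) {
  if (!is_symmetric(S)) stop("S must be a symmetric matrix")
  if (lam < 0) stop("lam must be non-negative")
  if (is.null(penalty_weights)) {
    Lam <- matrix(lam, nrow(S), ncol(S))
  } else {
    if (!is_symmetric(penalty_weights) ||
        nrow(penalty_weights) != nrow(S) || any(penalty_weights < 0))
      stop("penalty_weights must be a symmetric non-negative matrix like S")
    Lam <- lam * penalty_weights
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    warning("S is not positive semidefinite; repairing by eigenvalue clipping")
    e <- eigen(S, symmetric = TRUE)
    S <- e$vectors %*% diag(pmax(e$values, 1e-8)) %*% t(e$vectors)
    d <- sqrt(diag(S))
    S <- S / tcrossprod(d)
    S <- 0.5 * (S + t(S))
  }
  fit <- glasso_cpp(S, Lam, tol, as.integer(maxit),
                    warm$W, warm$B, trace_objective)
  if (!fit$converged)
    stop("graphical lasso did not converge in ", maxit,
         " sweeps (lam = ", signif(lam, 4), ")")
  dimnames(fit$Theta) <- dimnames(S)
  fit
}

# Extended BIC for a glasso solution.
# -2 * loglik + E*log(n) + 4*gamma*E*log(p), with
# loglik = (n/2) * (log det Theta - tr(S Theta)).
ebic_score <- function(Theta, S, n, gamma) {
  p <- ncol(S)
  ld <- determinant(Theta, logarithm = TRUE)
  if (ld$sign <= 0) return(Inf)
  ll <- (n / 2) * (as.numeric(ld$modulus) - sum(S * Theta))
  E <- sum(abs(Theta[upper.tri(Theta)]) > 1e-10)
  -2 * ll + E * log(n) + 4 * gamma * E * log(p)
}

# Theta -> partial correlation matrix: w_ij = -theta_ij / sqrt(theta_ii theta_jj)
partial_correlations <- function(Theta) {
  d <- sqrt(diag(Theta))
  W <- -Theta / tcrossprod(d)
  diag(W) <- 0
  W[abs(W) < 1e-12] <- 0
  W <- 0.5 * (W + t(W))
  pmin(pmax(W, -1), 1)
}

#' Estimate a sparse partial-correlation network
#'
#' Gaussian graphical model estimation: evaluates the graphical lasso along
#' a log-spaced penalty path (default 100 values from `lambda_max`, the
#' largest absolute off-diagonal correlation, down to
#' `lambda_min_ratio * lambda_max`), scores every solution by the extended
#' BIC with hyperparameter `gamma`, and reports the minimizer as a
#' partial-correlation weight matrix.
#'
#' @param Y complete-case data matrix (n x p, p >= 2), or `NULL` if `S` and
#'   `n_obs` are given directly.
#' @param kinds node kinds, `"symptom"` or `"temporal"`, recycled to p.
#' @param gamma EBIC hyperparameter in `[0, 1]`; 0 is plain BIC. Default 0.5.
#' @param nlambda path length (default 100).
#' @param lambda_min_ratio ratio of smallest to largest penalty (default 0.01).
#' @param method correlation method, see [correlation_matrix()].
#' @param S optional precomputed correlation matrix (overrides `Y`).
#' @param n_obs number of observations behind `S` (required with `S`).
#' @param penalty_weights optional relative per-edge penalty factors, see
#'   [glasso_fit()]; the path's `lambda_max` is taken over penalized
#'   entries only.
#' @param tol,maxit solver controls, see [glasso_fit()].
#' @return An object of class `"ggm"`: list with `nodes`, `kinds`, `W`
#'   (partial correlations, symmetric, zero diagonal), `Theta`, `S`,
#'   `lambda_path`, `ebic`, `selected_lambda`, `selected_index`, `gamma`,
#'   `n_obs`, `edges` (data frame of non-zero edges), `uninterpretable`.
#' @examples
#' set.seed(1)
#' Y <- matrix(rnorm(300), 100, 3)
#' Y[, 2] <- Y[, 1] + rnorm(100, sd = 0.7)
#' fit_ggm(Y)
#' @export
fit_ggm <- function(Y = NULL, kinds = "symptom", gamma = 0.5, nlambda = 100L,
                    lambda_min_ratio = 0.01,
                    method = c("pearson", "spearman"),
                    S = NULL, n_obs = NULL, penalty_weights = NULL,
                    tol = 1e-4, maxit = 200L) {
  if (is.null(S)) {
    Y <- as.matrix(Y)
    if (ncol(Y) < 2L) stop("need at least 2 columns")
    S <- correlation_matrix(Y, method = match.arg(method))
    n_obs <- nrow(Y)
  } else {
    if (is.null(n_obs)) stop("n_obs is required when S is supplied")
  }
  p <- ncol(S)
  nodes <- colnames(S) %||% paste0("V", seq_len(p))
  kinds <- rep_len(kinds, p)

  pen_ut <- if (is.null(penalty_weights)) upper.tri(S) else
    upper.tri(S) & penalty_weights > 0
  lam_max <- if (any(pen_ut)) max(abs(S[pen_ut])) else 1e-12
  if (lam_max < 1e-12) lam_max <- 1e-12
  lambda_path <- exp(seq(log(lam_max), log(lambda_min_ratio * lam_max),
                         length.out = nlambda))

  fits <- vector("list", nlambda)
  warm <- NULL
  for (k in seq_len(nlambda)) {
    fits[[k]] <- glasso_fit(S, lambda_path[k], tol = tol, maxit = maxit,
                            warm = warm, penalty_weights = penalty_weights)
    warm <- fits[[k]]
  }
  ebic <- vapply(fits, function(f) ebic_score(f$Theta, S, n_obs, gamma),
                 numeric(1))
  k_sel <- which.min(ebic)
  Theta <- fits[[k_sel]]$Theta
  W <- partial_correlations(Theta)
  dimnames(W) <- dimnames(Theta) <- list(nodes, nodes)

  ut <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  edges <- data.frame(node_a = nodes[ut[, 1L]], node_b = nodes[ut[, 2L]],
                      weight = W[ut],
                      kind_a = kinds[ut[, 1L]], kind_b = kinds[ut[, 2L]],
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, kinds = kinds, W = W, Theta = Theta, S = S,
                 lambda_path = lambda_path, ebic = ebic,
                 selected_lambda = lambda_path[k_sel],
                 selected_index = k_sel, gamma = gamma, n_obs = n_obs,
                 edges = edges, uninterpretable = p < 3L),
            class = "ggm")
}

#' @export
print.ggm <- function(x, ...) {
  n_sym <- sum(x$kinds == "symptom")
  cat("Sparse partial-correlation network:", length(x$nodes), "nodes (",
      n_sym, "symptom,", length(x$nodes) - n_sym, "temporal ),",
      nrow(x$edges), "edges\n")
  cat("  lambda =", signif(x$selected_lambda, 4), "(EBIC gamma =", x$gamma,
      "), n =", x$n_obs, "\n")
  if (x$uninterpretable)
    cat("  note: fewer than 3 nodes; centrality is not interpretable\n")
  invisible(x)
}

#' Count edges of a network by node-kind pair
#' @param net a `"ggm"`.
#' @return named integer vector with counts of symptom-symptom,
#'   symptom-temporal and temporal-temporal edges.
#' @export
edge_counts <- function(net) {
  stopifnot(inherits(net, "ggm"))
  e <- net$edges
  kinds <- apply(cbind(e$kind_a, e$kind_b), 1L,
                 function(k) paste(sort(k), collapse = "-"))
  c(`symptom-symptom` = sum(kinds == "symptom-symptom"),
    `symptom-temporal` = sum(kinds == "symptom-temporal"),
    `temporal-temporal` = sum(kinds == "temporal-temporal"))
}

#' Network with temporal variables embedded as nodes
#'
#' The first nonstationarity-handling approach: the seven standardized
#' temporal columns enter the network alongside the endorsed symptoms, so
#' nonstationary variation is partialed out of every symptom-symptom edge,
#' and symptom-temporal edges surface trends or cycles in each symptom.
#'
#' @param Y complete-case ratings matrix of endorsed symptoms.
#' @param basis standardized [temporal_basis()] aligned to the same rows.
#' @param penalize_temporal if `FALSE`, every edge involving a temporal
#'   node (symptom-temporal and temporal-temporal) is left unpenalized and
#'   only symptom-symptom edges are on the penalty path, so conditioning on
#'   time is not shrunk. With a uniform penalty the nearly collinear trend
#'   columns produce huge likelihood gains at small penalties, dragging the
#'   EBIC selection down and letting sampling-noise edges between symptoms
#'   survive; this flag is the sensitivity analysis that isolates genuine
#'   symptom-symptom covariation. Default `TRUE` (uniform penalty).
#' @param ... passed to [fit_ggm()].
#' @return a `"ggm"` over symptom + temporal nodes.
#' @export
embedded_network <- function(Y, basis, penalize_temporal = TRUE, ...) {
  stopifnot(inherits(basis, "temporal_basis"))
  if (!basis$standardized) basis <- standardize_basis(basis)
  if (nrow(Y) != nrow(basis$X))
    stop("ratings and basis must have the same rows")
  Z <- cbind(Y, basis$X)
  kinds <- c(rep("symptom", ncol(Y)), rep("temporal", ncol(basis$X)))
  pw <- NULL
  if (!penalize_temporal) {
    pw <- matrix(1, ncol(Z), ncol(Z))
    pw[kinds == "temporal", ] <- 0
    pw[, kinds == "temporal"] <- 0
  }
  fit_ggm(Z, kinds = kinds, penalty_weights = pw, ...)
}

#' Network over detrended residuals
#'
#' The second approach: symptoms are individually detrended (LASSO-selected
#' temporal predictors, OLS refit) and the network is estimated on the
#' residuals, so all variance attributable to trends and cycles is removed
#' before edges are estimated. With fewer than 2 residual series a
#' degenerate empty network is returned, flagged uninterpretable; with
#' exactly 2 nodes the network is estimated but its centrality is flagged
#' uninterpretable.
#'
#' @param detrended named list of `"detrend_fit"` objects on identical rows.
#' @param ... passed to [fit_ggm()].
#' @return a `"ggm"` over residual symptom nodes.
#' @export
residual_network <- function(detrended, ...) {
  stopifnot(length(detrended) >= 1L,
            all(vapply(detrended, inherits, TRUE, "detrend_fit")))
  R <- vapply(detrended, `[[`, numeric(detrended[[1L]]$n_obs), "residuals")
  colnames(R) <- unname(vapply(detrended, `[[`, character(1), "symptom"))
  if (ncol(R) < 2L) {
    p <- ncol(R)
    W <- matrix(0, p, p, dimnames = list(colnames(R), colnames(R)))
    return(structure(list(nodes = colnames(R), kinds = rep("symptom", p),
                          W = W, Theta = W, S = W, lambda_path = numeric(0),
                          ebic = numeric(0), selected_lambda = NA_real_,
                          selected_index = NA_integer_, gamma = NA_real_,
                          n_obs = nrow(R),
                          edges = data.frame(node_a = character(0),
                                             node_b = character(0),
                                             weight = numeric(0),
                                             kind_a = character(0),
                                             kind_b = character(0)),
                          uninterpretable = TRUE),
                     class = "ggm"))
  }
  fit_ggm(R, kinds = "symptom", ...)
}
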