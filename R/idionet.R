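#' Control parameters for person-specific network analysis
#'
#' @param min_nonzero,min_sd endorsement screen thresholds, see
#'   [screen_endorsement()].
#' @param min_rows minimum complete-case rows required for fitting.
#' @param cv_folds,lambda_rule,cv_type LASSO selection controls, see
#'   [select_temporal_predictors()].
#' @param gamma,nlambda,lambda_min_ratio,cor_method network estimation
#'   controls, see [fit_ggm()].
#' @param ei_order expected-influence order (1 or 2), see
#'   [compute_centrality()].
#' @param seed master seed; all randomness (CV fold assignment) derives
#'   from it.
#' @return a list of class `"idionet_control"`.
#' @export
idionet_control <- function(min_nonzero = 3L, min_sd = 0.1, min_rows = 10L,
                            cv_folds = 10L, lambda_rule = "min",
                            cv_type = "shuffle", gamma = 0.5,
                            nlambda = 100L, lambda_min_ratio = 0.01,
                            cor_method = "pearson", ei_order = 1L,
                            seed = 1L) {
  structure(list(min_nonzero = min_nonzero, min_sd = min_sd,
                 min_rows = min_rows, cv_folds = cv_folds,
                 lambda_rule = lambda_rule, cv_type = cv_type,
                 gamma = gamma, nlambda = nlambda,
                 lambda_min_ratio = lambda_min_ratio,
                 cor_method = cor_method, ei_order = ei_order, seed = seed),
            class = "idionet_control")
}

#' Fit person-specific symptom network models
#'
#' The full idiographic analysis of one person's EMA series. Symptoms are
#' first screened for endorsement; prompts with any missing rating among the
#' endorsed symptoms are dropped (listwise), so every later stage sees
#' identical rows. Nonstationarity is then handled in two parallel ways:
#'
#' * **Temporal-embedded network** ("raw"): the seven standardized temporal
#'   predictors (linear/quadratic/cubic trends, 24-h and 12-h sine/cosine
#'   pairs) join the endorsed symptoms as nodes of one regularized
#'   partial-correlation network. Symptom-symptom edges are thereby
#'   conditioned on time, and symptom-temporal edges expose trends and
#'   cycles in individual symptoms.
#' * **Detrended residual network**: each symptom is regressed on
#'   LASSO-selected temporal predictors (OLS refit); the residuals --
#'   the stationary variation -- form a symptoms-only network.
#'
#' Both networks are Gaussian graphical models estimated by graphical lasso
#' with EBIC model selection; strength and expected-influence centrality and
#' a raw-versus-detrended comparison complete the analysis.
#'
#' @param data an [ema_dataset()] (or long data frame / CSV path accepted by
#'   [read_ema_csv()] conventions: columns person_id, timestamp, symptom,
#'   rating).
#' @param control an [idionet_control()].
#' @return An object of class `"idionet"` with components `person_id`,
#'   `endorsement`, `data` (complete-case dataset used), `basis`
#'   (standardized), `network_raw`, `detrend` (list of per-symptom fits),
#'   `network_detrended`, `centrality_raw`, `centrality_detrended`,
#'   `comparison`, `r_squared` (named per endorsed symptom), `control`,
#'   `call`.
#' @examples
#' gt <- ground_truth(symptoms = c("Headache", "Fatigue", "Foggy"),
#'                    target_r2 = c(0.4, 0.3, 0), missing_rate = 0.1,
#'                    Omega = chain_precision(3, 0.3))
#' ds <- simulate_person(gt, seed = 7)
#' fit <- idionet(ds)
#' fit
#' coef(fit)[1:3, 1:3]
#' @export
idionet <- function(data, control = idionet_control()) {
  cl <- match.call()
  if (is.character(data) && length(data) == 1L)
    data <- read_ema_csv(data)
  if (is.data.frame(data)) {
    tmp <- tempfile(fileext = ".csv")
    on.exit(unlink(tmp), add = TRUE)
    write.csv(data, tmp, row.names = FALSE, na = "", quote = FALSE)
    data <- read_ema_csv(tmp)
  }
  stopifnot(inherits(data, "ema_dataset"),
            inherits(control, "idionet_control"))

  screen <- screen_endorsement(data, control$min_nonzero, control$min_sd)
  endorsed <- endorsed_symptoms(screen)
  if (!length(endorsed))
    stop("no endorsed symptoms for person ", data$person_id)
  cc <- complete_cases_ema(data, endorsed, min_rows = control$min_rows)

  basis <- standardize_basis(temporal_basis(cc$timestamps))
  Y <- cc$ratings

  net_raw <- embedded_network(Y, basis, gamma = control$gamma,
                              nlambda = control$nlambda,
                              lambda_min_ratio = control$lambda_min_ratio,
                              method = control$cor_method)
  det <- detrend_symptoms(Y, basis$X, seed = control$seed,
                          cv_folds = control$cv_folds,
                          rule = control$lambda_rule,
                          cv_type = control$cv_type)
  net_det <- residual_network(det, gamma = control$gamma,
                              nlambda = control$nlambda,
                              lambda_min_ratio = control$lambda_min_ratio,
                              method = control$cor_method)
  cen_raw <- compute_centrality(net_raw, order = control$ei_order)
  cen_det <- compute_centrality(net_det, order = control$ei_order)
  cmp <- tryCatch(compare_centrality(cen_raw, cen_det),
                  error = function(e) NULL)
  r2 <- vapply(det, `[[`, numeric(1), "r_squared")

  structure(list(person_id = data$person_id, endorsement = screen,
                 data = cc, basis = basis, network_raw = net_raw,
                 detrend = det, network_detrended = net_det,
                 centrality_raw = cen_raw, centrality_detrended = cen_det,
                 comparison = cmp, r_squared = r2, control = control,
                 call = cl),
            class = "idionet")
}

#' @export
print.idionet <- function(x, ...) {
  cat("Person-specific symptom network model -- person", x$person_id, "\n")
  cat("  ", nrow(x$data$ratings), "complete prompts,",
      length(x$detrend), "endorsed symptoms (of",
      nrow(x$endorsement), ")\n")
  cat("  temporal-embedded network:", nrow(x$network_raw$edges),
      "edges over", length(x$network_raw$nodes), "nodes\n")
  cat("  detrended residual network:", nrow(x$network_detrended$edges),
      "edges over", length(x$network_detrended$nodes), "nodes",
      if (x$network_detrended$uninterpretable) "(uninterpretable)", "\n")
  cat("  mean variance explained by time:",
      sprintf("%.2f", mean(x$r_squared)), "\n")
  invisible(x)
}

#' @export
summary.idionet <- function(object, ...) {
  r2 <- sort(object$r_squared, decreasing = TRUE)
  top_raw <- rank_nodes(object$centrality_raw, "strength")
  top_det <- rank_nodes(object$centrality_detrended, "strength")
  out <- list(person_id = object$person_id,
              n_obs = nrow(object$data$ratings),
              response_rate = attr(object$endorsement, "response_rate"),
              endorsed = names(object$r_squared),
              not_endorsed = setdiff(object$endorsement$symptom,
                                     names(object$r_squared)),
              r_squared = r2,
              retained = lapply(object$detrend, `[[`, "retained"),
              edges_raw = edge_counts(object$network_raw),
              edges_detrended = nrow(object$network_detrended$edges),
              top_raw = head(top_raw, 5L), top_detrended = head(top_det, 5L),
              rank_correlation =
                if (!is.null(object$comparison))
                  attr(object$comparison, "rank_correlation") else NA_real_,
              uninterpretable = object$network_detrended$uninterpretable)
  class(out) <- "summary.idionet"
  out
}

#' @export
print.summary.idionet <- function(x, ...) {
  cat("Person", x$person_id, ":", x$n_obs, "complete prompts, response rate",
      sprintf("%.2f", x$response_rate), "\n\n")
  cat("Variance explained by temporal structure (R^2):\n")
  print(round(x$r_squared, 2))
  if (length(x$not_endorsed))
    cat("Not endorsed:", paste(x$not_endorsed, collapse = ", "), "\n")
  cat("\nTemporal-embedded network edges: ",
      paste(names(x$edges_raw), x$edges_raw, collapse = ", "), "\n")
  cat("Detrended network edges:", x$edges_detrended,
      if (x$uninterpretable) "(uninterpretable)", "\n")
  cat("Most central (raw):", paste(x$top_raw, collapse = ", "), "\n")
  cat("Most central (detrended):", paste(x$top_detrended, collapse = ", "),
      "\n")
  if (!is.na(x$rank_correlation))
    cat("Raw vs detrended rank correlation:",
        sprintf("%.2f", x$rank_correlation), "\n")
  invisible(x)
}

#' @export
coef.idionet <- function(object, network = c("detrended", "raw"), ...) {
  network <- match.arg(network)
  if (network == "detrended") object$network_detrended$W
  else object$network_raw$W
}

#' @export
residuals.idionet <- function(object, ...) {
  vapply(object$detrend, `[[`,
         numeric(object$detrend[[1L]]$n_obs), "residuals")
}

#' Fitted temporal trajectories for each endorsed symptom
#'
#' Evaluates every symptom's retained-temporal-predictor OLS model, either
#' at the fitted rows (default) or at new timestamps (the basis is rebuilt
#' with the stored anchor and standardization).
#'
#' @param object an `"idionet"` fit.
#' @param timestamps optional `POSIXct` vector of new prediction times.
#' @param ... unused.
#' @return matrix of fitted values (rows = times, columns = endorsed
#'   symptoms).
#' @export
predict.idionet <- function(object, timestamps = NULL, ...) {
  if (is.null(timestamps))
    return(vapply(object$detrend, `[[`,
                  numeric(object$detrend[[1L]]$n_obs), "fitted"))
  b <- object$basis
  raw <- temporal_basis(timestamps, anchor = b$anchor)
  keep <- names(b$center)
  Xn <- scale(raw$X[, keep, drop = FALSE], center = b$center,
              scale = b$scale)
  out <- vapply(object$detrend, function(d) {
    f <- rep(d$beta[["(Intercept)"]], length(timestamps))
    if (length(d$retained))
      f <- f + as.numeric(Xn[, d$retained, drop = FALSE] %*%
                            d$beta[d$retained])
    f
  }, numeric(length(timestamps)))
  out
}

#' Simulate new series from a fitted person-specific model
#'
#' Parametric bootstrap: fitted temporal trajectories plus multivariate
#' Gaussian noise with the empirical covariance of the detrend residuals,
#' rounded and clamped back to the 0-6 Likert scale.
#'
#' @param object an `"idionet"` fit.
#' @param nsim number of simulated datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return an [ema_dataset()], or a list of them if `nsim > 1`.
#' @export
simulate.idionet <- function(object, nsim = 1, seed = 1L, ...) {
  mu <- predict(object)
  R <- residuals(object)
  Sigma <- cov(R)
  # ridge for safety when residuals are near-degenerate
  ch <- chol(Sigma + diag(1e-8, ncol(Sigma)))
  n <- nrow(mu)
  seeds <- if (nsim > 1L) derive_seeds(seed, nsim) else seed
  sets <- lapply(seq_len(nsim), function(i) {
    lat <- with_seed(seeds[[i]],
                     mu + matrix(rnorm(n * ncol(mu)), n) %*% ch)
    ratings <- pmin(pmax(round(lat), .rating_min), .rating_max)
    colnames(ratings) <- colnames(mu)
    ema_dataset(paste0(object$person_id, "_sim", i), ratings,
                object$data$timestamps, object$data$schema,
                n_scheduled = object$data$n_scheduled)
  })
  if (nsim == 1L) sets[[1L]] else sets
}

#' Plot a fitted symptom network
#'
#' Draws the selected network on a circle layout: blue edges for positive
#' partial correlations, red for negative, width proportional to magnitude;
#' temporal nodes are drawn as squares.
#'
#' @param x an `"idionet"` fit or a `"ggm"`.
#' @param network which network to draw (for `"idionet"`).
#' @param min_weight hide edges below this absolute weight.
#' @param ... passed to [graphics::plot()].
#' @export
plot.idionet <- function(x, network = c("detrended", "raw"),
                         min_weight = 0, ...) {
  network <- match.arg(network)
  net <- if (network == "detrended") x$network_detrended else x$network_raw
  plot(net, min_weight = min_weight,
       main = paste0("Person ", x$person_id, " (", network, ")"), ...)
}

#' @rdname plot.idionet
#' @export
plot.ggm <- function(x, min_weight = 0, main = NULL, ...) {
  p <- length(x$nodes)
  theta <- seq(0, 2 * pi, length.out = p + 1L)[seq_len(p)]
  xs <- cos(theta); ys <- sin(theta)
  graphics::plot(NA, xlim = c(-1.35, 1.35), ylim = c(-1.35, 1.35),
                 axes = FALSE, xlab = "", ylab = "", asp = 1,
                 main = main %||% "Partial-correlation network", ...)
  e <- x$edges
  e <- e[abs(e$weight) >= min_weight, , drop = FALSE]
  if (nrow(e)) {
    ia <- match(e$node_a, x$nodes); ib <- match(e$node_b, x$nodes)
    graphics::segments(xs[ia], ys[ia], xs[ib], ys[ib],
                       col = ifelse(e$weight > 0, "#2166AC", "#B2182B"),
                       lwd = 0.5 + 6 * abs(e$weight))
  }
  graphics::points(xs, ys, pch = ifelse(x$kinds == "temporal", 22, 21),
                   bg = ifelse(x$kinds == "temporal", "grey85", "white"),
                   cex = 2.2)
  graphics::text(1.18 * xs, 1.18 * ys, x$nodes, cex = 0.7)
  invisible(x)
}
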