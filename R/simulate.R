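#' EMA sampling protocol configuration
#'
#' Describes the prompt schedule the generator emulates: 5 prompts per day
#' at 3-hour intervals for 20 days (100 scheduled prompts), one of three
#' preset schedules differing in their morning start time, and a 90-minute
#' response window.
#'
#' @param n_days days of measurement (default 20).
#' @param prompts_per_day prompts per day (default 5).
#' @param prompt_interval_hours hours between prompts within a day (default 3).
#' @param response_window_min minutes allowed to answer a prompt (default 90).
#' @param schedule one of `"early"`, `"mid"`, `"late"` (first prompt at
#'   8:00, 9:00 or 10:00).
#' @param start_date calendar date of day 1.
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(n_days = 20L, prompts_per_day = 5L,
                       prompt_interval_hours = 3,
                       response_window_min = 90,
                       schedule = c("early", "mid", "late"),
                       start_date = as.POSIXct("2024-01-01", tz = "UTC")) {
  schedule <- match.arg(schedule)
  structure(list(n_days = as.integer(n_days),
                 prompts_per_day = as.integer(prompts_per_day),
                 prompt_interval_hours = prompt_interval_hours,
                 response_window_min = response_window_min,
                 schedule = schedule,
                 start_hour = c(early = 8, mid = 9, late = 10)[[schedule]],
                 start_date = start_date),
            class = "sim_config")
}

#' Scheduled prompt timestamps for a protocol configuration
#' @param cfg a [sim_config()].
#' @return `POSIXct` vector of `n_days * prompts_per_day` scheduled prompt
#'   times.
#' @export
schedule_times <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  day <- rep(seq_len(cfg$n_days) - 1L, each = cfg$prompts_per_day)
  slot <- rep(seq_len(cfg$prompts_per_day) - 1L, times = cfg$n_days)
  hours <- cfg$start_hour + slot * cfg$prompt_interval_hours
  cfg$start_date + day * 86400 + hours * 3600
}

#' Ground truth for simulating one person's EMA series
#'
#' Specifies the latent data-generating process: per-symptom polynomial
#' recovery trends (on study time rescaled to `[0, 1]`), 24-h and 12-h
#' cycles with free amplitude and phase, a sparse precision matrix
#' governing the contemporaneous residual correlations, per-symptom
#' residual SDs, an endorsement mask, Likert thresholds and a missingness
#' rate.
#'
#' If `target_r2` is given, each symptom's deterministic temporal signal is
#' rescaled at simulation time so its population variance share over the
#' realized schedule equals the target.
#'
#' @param symptoms symptom labels (default: the 18-item schema).
#' @param endorsed labels of symptoms the person expresses; the rest rate 0
#'   throughout.
#' @param trend p x 3 matrix of linear/quadratic/cubic coefficients (latent
#'   units per unit of rescaled study time).
#' @param amp24,phase24,amp12,phase12 cycle amplitudes (latent units) and
#'   phases (radians), length p.
#' @param Omega p x p positive-definite precision matrix for the residual
#'   correlation structure (unit-diagonal partial-correlation scale).
#' @param noise_sd residual marginal SD per symptom (latent units).
#' @param missing_rate probability a whole prompt goes unanswered.
#' @param target_r2 optional per-symptom population R-squared in `[0, 1)`.
#' @param floor_shift upward shift of all Likert thresholds in latent-SD
#'   units; pushes mass into the 0 category, mimicking floor effects.
#' @param schema a [symptom_schema()] used for resulting datasets.
#' @return object of class `"ema_ground_truth"`.
#' @export
ground_truth <- function(symptoms = pcss_schema()$analysis_items,
                         endorsed = symptoms,
                         trend = NULL, amp24 = NULL, phase24 = NULL,
                         amp12 = NULL, phase12 = NULL,
                         Omega = NULL, noise_sd = NULL,
                         missing_rate = 0.27, target_r2 = NULL,
                         floor_shift = 0.25, schema = pcss_schema()) {
  p <- length(symptoms)
  if (!all(symptoms %in% schema$items))
    schema <- symptom_schema(symptoms)
  zero <- function(x, d) if (is.null(x)) d else x
  trend <- zero(trend, matrix(0, p, 3))
  if (is.vector(trend) && p == 1L) trend <- matrix(trend, 1L)
  stopifnot(nrow(trend) == p, ncol(trend) == 3L)
  amp24 <- rep_len(zero(amp24, 0), p)
  phase24 <- rep_len(zero(phase24, 0), p)
  amp12 <- rep_len(zero(amp12, 0), p)
  phase12 <- rep_len(zero(phase12, 0), p)
  Omega <- zero(Omega, diag(p))
  noise_sd <- rep_len(zero(noise_sd, 1), p)
  if (!is_symmetric(Omega) || nrow(Omega) != p)
    stop("Omega must be a symmetric p x p matrix")
  ev <- eigen(Omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("Omega must be positive definite")
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must be in [0, 1]")
  if (!is.null(target_r2)) {
    target_r2 <- rep_len(target_r2, p)
    if (any(target_r2 < 0 | target_r2 >= 1))
      stop("target_r2 entries must be in [0, 1)")
  }
  if (!all(endorsed %in% symptoms))
    stop("endorsed must be a subset of symptoms")
  # a symptom asked to carry temporal variance but given no signal shape
  # gets a default recovery trend plus diurnal cycle (scaled at simulation)
  if (!is.null(target_r2)) {
    flat <- rowSums(abs(trend)) == 0 & amp24 == 0 & amp12 == 0
    fix <- flat & target_r2 > 0
    trend[fix, 1L] <- -1
    amp24[fix] <- 0.5
  }
  structure(list(symptoms = symptoms, endorsed = endorsed, trend = trend,
                 amp24 = amp24, phase24 = phase24, amp12 = amp12,
                 phase12 = phase12, Omega = Omega, noise_sd = noise_sd,
                 missing_rate = missing_rate, target_r2 = target_r2,
                 floor_shift = floor_shift, schema = schema),
            class = "ema_ground_truth")
}

#' @export
print.ema_ground_truth <- function(x, ...) {
  cat("EMA ground truth:", length(x$symptoms), "symptoms (",
      length(x$endorsed), "endorsed ), missingness",
      sprintf("%.2f", x$missing_rate), "\n")
  invisible(x)
}

# Deterministic latent mean per symptom over given timestamps.
latent_means <- function(gt, timestamps) {
  t_h <- as.numeric(timestamps - timestamps[1L], units = "hours")
  u <- if (max(t_h) > 0) t_h / max(t_h) else t_h
  lt <- as.POSIXlt(timestamps)
  clock <- lt$hour + lt$min / 60 + lt$sec / 3600
  p <- length(gt$symptoms)
  M <- matrix(0, length(timestamps), p,
              dimnames = list(NULL, gt$symptoms))
  for (j in seq_len(p)) {
    M[, j] <- gt$trend[j, 1L] * u + gt$trend[j, 2L] * u^2 +
      gt$trend[j, 3L] * u^3 +
      gt$amp24[j] * sin(2 * pi * clock / 24 + gt$phase24[j]) +
      gt$amp12[j] * sin(2 * pi * clock / 12 + gt$phase12[j])
  }
  M
}

#' Simulate one person's EMA dataset from ground truth
#'
#' Latent value per scheduled prompt = deterministic mean (trends on
#' elapsed study time, cycles on clock time) + multivariate Gaussian
#' residual with correlation `cov2cor(solve(Omega))` scaled by `noise_sd`.
#' Latent values are cut into Likert 0-6 ratings by per-symptom thresholds
#' (equal-probability bins of the latent marginal, shifted up by
#' `floor_shift` SDs). Whole prompts go missing i.i.d. with probability
#' `missing_rate`; answered prompts are stamped with a response delay drawn
#' uniformly within the response window.
#'
#' @param gt an [ground_truth()].
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @param person_id identifier for the generated dataset.
#' @param likert discretize to Likert ratings (default `TRUE`); if `FALSE`
#'   the latent values are returned as-is (for estimator-level studies).
#' @return an [ema_dataset()] with attribute `"sim_meta"`: list with
#'   `population_r2` (per symptom, over the realized schedule),
#'   `response_rate`, `latent` (latent matrix), `ground_truth`, `seed`.
#' @export
simulate_person <- function(gt, cfg = sim_config(), seed = 1L,
                            person_id = "SIM", likert = TRUE) {
  stopifnot(inherits(gt, "ema_ground_truth"), inherits(cfg, "sim_config"))
  sched <- schedule_times(cfg)
  n <- length(sched)
  p <- length(gt$symptoms)
  M <- latent_means(gt, sched)

  # rescale signal to hit target population R2 over this schedule
  sig_var <- apply(M, 2L, function(m) mean((m - mean(m))^2))
  pop_r2 <- sig_var / (sig_var + gt$noise_sd^2)
  if (!is.null(gt$target_r2)) {
    for (j in seq_len(p)) {
      tr2 <- gt$target_r2[j]
      if (tr2 == 0) {
        M[, j] <- 0
      } else {
        if (sig_var[j] <= 0)
          stop("symptom ", gt$symptoms[j],
               " has target_r2 > 0 but no temporal signal")
        sc <- sqrt(tr2 * gt$noise_sd[j]^2 / ((1 - tr2) * sig_var[j]))
        M[, j] <- M[, j] * sc
      }
    }
    sig_var <- apply(M, 2L, function(m) mean((m - mean(m))^2))
    pop_r2 <- sig_var / (sig_var + gt$noise_sd^2)
  }

  Sigma <- stats::cov2cor(solve(gt$Omega))
  Sigma <- diag(gt$noise_sd) %*% Sigma %*% diag(gt$noise_sd)
  ch <- chol(Sigma)

  with_seed(seed, {
    E <- matrix(rnorm(n * p), n, p) %*% ch
    latent <- M + E
    if (likert) {
      m_marg <- colMeans(M)
      sd_marg <- sqrt(sig_var + gt$noise_sd^2)
      ratings <- matrix(0, n, p, dimnames = list(NULL, gt$symptoms))
      for (j in seq_len(p)) {
        thr <- qnorm(seq_len(6) / 7) * sd_marg[j] + m_marg[j] +
          gt$floor_shift * sd_marg[j]
        ratings[, j] <- findInterval(latent[, j], thr)
      }
    } else {
      ratings <- latent
    }
    ratings[, !(gt$symptoms %in% gt$endorsed)] <- 0
    miss <- rbinom(n, 1L, gt$missing_rate) == 1L
    ratings[miss, ] <- NA
    delay_min <- runif(n, 0, cfg$response_window_min)
    ts <- sched
    ts[!miss] <- ts[!miss] + delay_min[!miss] * 60
  })

  ds <- if (likert) {
    ema_dataset(person_id, ratings, ts, gt$schema, n_scheduled = n)
  } else {
    structure(list(person_id = as.character(person_id), ratings = ratings,
                   timestamps = ts, schema = gt$schema,
                   n_scheduled = n), class = "ema_dataset")
  }
  attr(ds, "sim_meta") <- list(population_r2 = pop_r2,
                               response_rate = mean(!miss),
                               latent = latent, ground_truth = gt,
                               seed = seed)
  ds
}

#' @rdname simulate_person
#' @param object an `"ema_ground_truth"` (for the `simulate` method).
#' @param nsim number of datasets to generate.
#' @param ... passed to [simulate_person()].
#' @export
simulate.ema_ground_truth <- function(object, nsim = 1, seed = 1L, ...) {
  seeds <- if (nsim > 1L) derive_seeds(seed, nsim) else seed
  out <- lapply(seq_len(nsim), function(i)
    simulate_person(object, seed = seeds[[i]],
                    person_id = sprintf("SIM%02d", i), ...))
  if (nsim == 1L) out[[1L]] else out
}

#' Tridiagonal (chain) precision matrix
#'
#' Precision matrix of a path-graph Gaussian graphical model whose
#' consecutive-node partial correlations all equal `rho`: unit diagonal and
#' `-rho` on the first off-diagonal.
#'
#' @param p number of nodes.
#' @param rho chain partial correlation (|rho| < 0.5 guarantees positive
#'   definiteness for any p).
#' @return p x p precision matrix.
#' @export
chain_precision <- function(p, rho = 0.3) {
  O <- diag(p)
  for (j in seq_len(p - 1L)) {
    O[j, j + 1L] <- O[j + 1L, j] <- -rho
  }
  ev <- eigen(O, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("chain precision not positive definite; reduce |rho|")
  O
}

#' Simulate a heterogeneous cohort
#'
#' @param gts list of [ground_truth()] objects (one per person).
#' @param cfg a [sim_config()]; recycled across persons, with the three
#'   preset schedules rotated.
#' @param seed master seed; per-person seeds are derived from it.
#' @return named list of [ema_dataset()] objects (`P01`, `P02`, ...).
#' @export
simulate_cohort <- function(gts, cfg = sim_config(), seed = 1L) {
  stopifnot(length(gts) >= 1L)
  seeds <- derive_seeds(seed, length(gts))
  scheds <- rep_len(c("early", "mid", "late"), length(gts))
  out <- lapply(seq_along(gts), function(i) {
    ci <- cfg
    ci$schedule <- scheds[i]
    ci$start_hour <- c(early = 8, mid = 9, late = 10)[[scheds[i]]]
    simulate_person(gts[[i]], ci, seed = seeds[i],
                    person_id = sprintf("P%02d", i))
  })
  names(out) <- sprintf("P%02d", seq_along(gts))
  out
}

#' Ground truths for the default 10-person study cohort
#'
#' Builds a heterogeneous cohort in the spirit of the study design: persons
#' differ in which symptoms they endorse, how much variance time explains,
#' and how dense their residual network is. Person 5 is a two-symptom
#' endorser (headache and fatigue only), so its detrended-network
#' centrality is uninterpretable; person 7 carries all symptom covariation
#' through shared trends and cycles (identity residual precision), so its
#' detrended network should be empty.
#'
#' @param seed master seed for the randomly drawn phases and structures.
#' @param missing_rate shared missingness rate (default 0.27, i.e. a 73%
#'   response rate).
#' @return list of 10 `"ema_ground_truth"` objects.
#' @export
default_cohort_truths <- function(seed = 20L, missing_rate = 0.27) {
  schema <- pcss_schema()
  syms <- schema$analysis_items
  p <- length(syms)
  seeds <- derive_seeds(seed, 10L)
  mk <- function(i, endorsed, r2, Omega, trend_sign = -1) {
    with_seed(seeds[i], {
      pe <- length(endorsed)
      idx <- match(endorsed, syms)
      trend <- matrix(0, p, 3L)
      # recovery-shaped polynomial: declining with curvature
      trend[idx, 1L] <- trend_sign * runif(pe, 1, 2)
      trend[idx, 2L] <- runif(pe, -0.5, 0.5)
      trend[idx, 3L] <- runif(pe, -0.3, 0.3)
      amp24 <- amp12 <- rep(0, p)
      amp24[idx] <- runif(pe, 0.3, 1)
      amp12[idx] <- runif(pe, 0, 0.5)
      tr2 <- rep(0, p)
      tr2[idx] <- rep_len(r2, pe)
      Om <- diag(p)
      Om[idx, idx] <- Omega
      ground_truth(symptoms = syms, endorsed = endorsed, trend = trend,
                   amp24 = amp24, phase24 = runif(p, 0, 2 * pi),
                   amp12 = amp12, phase12 = runif(p, 0, 2 * pi),
                   Omega = Om, missing_rate = missing_rate,
                   target_r2 = tr2, schema = schema)
    })
  }
  # densely interconnected residual structure: partial correlations 0.32 to
  # first neighbors and 0.16 to second neighbors (positive definite for all
  # k <= 18); strengths sit where the regularized estimator can resolve
  # them at ~73 complete prompts, mirroring the roughly half-and-half split
  # between sparse and densely connected detrended networks
  dense_band <- function(k, rho = 0.32) {
    O <- diag(k)
    for (d in 1:2) for (j in seq_len(k - d)) {
      O[j, j + d] <- O[j + d, j] <- -rho / d
    }
    O
  }
  cohort <- vector("list", 10L)
  for (i in seq_len(10L)) {
    if (i == 5L) {
      cohort[[i]] <- mk(i, c("Headache", "Fatigue"), c(0.47, 0.28),
                        chain_precision(2L, 0.35))
    } else if (i == 7L) {
      endorsed <- syms[c(1, 4, 5, 6, 9, 14, 15, 16, 17)] # nine symptoms
      cohort[[i]] <- mk(i, endorsed, c(0.4, 0.5, 0.3), diag(9L))
    } else {
      n_end <- c(16L, 12L, 14L, 18L, NA, 15L, NA, 10L, 8L, 16L)[i]
      endorsed <- with_seed(seeds[i] + 1L,
                            sort(sample(seq_len(p), n_end)))
      r2 <- list(c(0.3, 0.5, 0.1), c(0, 0.1, 0.45), c(0.2, 0.4),
                 c(0.2, 0.35, 0), NULL, c(0.25, 0.45), NULL,
                 c(0, 0.15, 0.3), c(0.5, 0.6, 0.15), c(0, 0.1, 0.4))[[i]]
      # persons 2/4/6 dense; person 1 a strong chain; the rest weak chains
      # whose residual structure mostly falls below detectability, i.e.
      # sparse detrended networks
      Om <- if (i %in% c(2L, 4L, 6L)) dense_band(n_end)
            else if (i == 1L) chain_precision(n_end, 0.45)
            else chain_precision(n_end, 0.3)
      cohort[[i]] <- mk(i, syms[endorsed], r2, Om)
    }
  }
  cohort
}
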