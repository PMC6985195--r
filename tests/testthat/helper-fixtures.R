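# Shared fixture builders for the test suite.

# A study-like schedule: `n_days` days x 5 prompts at 3-h intervals from 08:00.
fixture_timestamps <- function(n_days = 20L, jitter_min = 0) {
  ts <- schedule_times(sim_config(n_days = n_days))
  if (jitter_min > 0) ts + runif(length(ts), 0, jitter_min * 60) else ts
}

# Small complete EMA dataset with deterministic ratings.
fixture_dataset <- function(n_days = 4L,
                            symptoms = c("Headache", "Fatigue", "Nausea"),
                            seed = 1L) {
  ts <- fixture_timestamps(n_days)
  n <- length(ts)
  set.seed(seed)
  Y <- matrix(sample(0:6, n * length(symptoms), replace = TRUE), n,
              dimnames = list(NULL, symptoms))
  ema_dataset("T01", Y, ts)
}

# Long-format CSV for a ratings matrix (NA rows become empty rating cells).
write_long_csv <- function(Y, ts, path, person = "T01") {
  df <- data.frame(
    person_id = person,
    timestamp = rep(format(ts, "%Y-%m-%dT%H:%M:%S"), each = ncol(Y)),
    symptom = rep(colnames(Y), times = nrow(Y)),
    rating = as.vector(t(Y)))
  write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  path
}

# Random well-conditioned correlation matrix via a factor construction.
fixture_correlation <- function(p, seed, ridge = 2) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  cov2cor(crossprod(A) + diag(p) * ridge)
}

# Toy network object with a given weight matrix.
fixture_ggm <- function(W, kinds = "symptom") {
  p <- ncol(W)
  nodes <- colnames(W) %||% LETTERS[seq_len(p)]
  dimnames(W) <- list(nodes, nodes)
  ut <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  kinds <- rep_len(kinds, p)
  structure(list(nodes = nodes, kinds = kinds, W = W, Theta = W, S = W,
                 lambda_path = numeric(0), ebic = numeric(0),
                 selected_lambda = NA_real_, selected_index = NA_integer_,
                 gamma = 0.5, n_obs = 0L,
                 edges = data.frame(node_a = nodes[ut[, 1]],
                                    node_b = nodes[ut[, 2]],
                                    weight = W[ut],
                                    kind_a = kinds[ut[, 1]],
                                    kind_b = kinds[ut[, 2]],
                                    stringsAsFactors = FALSE),
                 uninterpretable = p < 3L),
            class = "ggm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
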