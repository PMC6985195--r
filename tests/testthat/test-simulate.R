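test_that("the schedule produces the protocol's prompt grid", {
  cfg <- sim_config()
  ts <- schedule_times(cfg)
  expect_length(ts, 100L)
  lt <- as.POSIXlt(ts)
  expect_setequal(unique(lt$hour), c(8, 11, 14, 17, 20))
  cfg_late <- sim_config(schedule = "late")
  expect_setequal(unique(as.POSIXlt(schedule_times(cfg_late))$hour),
                  c(10, 13, 16, 19, 22))
})

test_that("no missingness yields a full grid of valid Likert ratings", {
  gt <- ground_truth(symptoms = c("Headache", "Fatigue"),
                     target_r2 = c(0.3, 0), missing_rate = 0)
  ds <- simulate_person(gt, seed = 3L)
  expect_identical(nrow(ds$ratings), 100L)
  expect_false(anyNA(ds$ratings))
  expect_true(all(ds$ratings %in% 0:6))
  # response delays stay within the 90-minute window
  delay <- as.numeric(ds$timestamps - schedule_times(sim_config()),
                      units = "mins")
  expect_true(all(delay >= 0 & delay <= 90))
})

test_that("identical seeds give bit-identical datasets", {
  gt <- ground_truth(symptoms = c("Headache", "Fatigue"),
                     target_r2 = c(0.3, 0.2), missing_rate = 0.27)
  a <- simulate_person(gt, seed = 11L)
  b <- simulate_person(gt, seed = 11L)
  expect_identical(a$ratings, b$ratings)
  expect_identical(a$timestamps, b$timestamps)
  c <- simulate_person(gt, seed = 12L)
  expect_false(identical(a$ratings, c$ratings))
})

test_that("missingness hits whole prompts at the configured rate", {
  gt <- ground_truth(symptoms = c("Headache", "Fatigue"),
                     target_r2 = c(0.3, 0), missing_rate = 0.27)
  rates <- vapply(1:200, function(i)
    attr(simulate_person(gt, seed = i), "sim_meta")$response_rate,
    numeric(1))
  expect_equal(mean(rates), 0.73, tolerance = 0.02)
  # missingness is whole-prompt: a row is all-NA or fully observed
  ds <- simulate_person(gt, seed = 1L)
  nmiss <- rowSums(is.na(ds$ratings))
  expect_true(all(nmiss %in% c(0L, ncol(ds$ratings))))
})

test_that("non-endorsed symptoms rate zero throughout", {
  gt <- ground_truth(symptoms = c("Headache", "Fatigue", "Vomiting"),
                     endorsed = c("Headache", "Fatigue"),
                     target_r2 = c(0.3, 0.3, 0), missing_rate = 0)
  ds <- simulate_person(gt, seed = 4L)
  expect_true(all(ds$ratings[, "Vomiting"] == 0))
  rep <- screen_endorsement(ds)
  expect_identical(rep$status[rep$symptom == "Vomiting"],
                   "insufficient_variance")
})

test_that("the population R-squared metadata matches its target", {
  gt <- ground_truth(symptoms = c("A", "B", "C"),
                     target_r2 = c(0, 0.3, 0.6), missing_rate = 0)
  meta <- attr(simulate_person(gt, seed = 5L, likert = FALSE), "sim_meta")
  expect_equal(unname(meta$population_r2), c(0, 0.3, 0.6), tolerance = 1e-10)
})

test_that("latent residual correlations converge to the precision's inverse", {
  Om <- chain_precision(4, 0.35)
  gt <- ground_truth(symptoms = paste0("S", 1:4), Omega = Om,
                     missing_rate = 0)
  ds <- simulate_person(gt, sim_config(n_days = 2000L), seed = 6L,
                        likert = FALSE)
  R_target <- cov2cor(solve(Om))
  expect_lt(max(abs(cor(ds$ratings) - R_target)), 0.05)
})

test_that("invalid ground truths are rejected before sampling", {
  expect_error(ground_truth(symptoms = c("A", "B"),
                            Omega = matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
  expect_error(ground_truth(symptoms = "A", missing_rate = 1.5),
               "missing_rate")
  expect_error(ground_truth(symptoms = c("A", "B"), target_r2 = c(0.5, 1)),
               "target_r2")
  expect_error(ground_truth(symptoms = "A", endorsed = "B"), "subset")
  expect_error(chain_precision(4, 0.9), "positive definite")
})

test_that("cohorts derive independent per-person seeds deterministically", {
  gts <- list(ground_truth(symptoms = c("A", "B"), target_r2 = 0.3,
                           missing_rate = 0.1),
              ground_truth(symptoms = c("A", "B"), target_r2 = 0.3,
                           missing_rate = 0.1))
  c1 <- simulate_cohort(gts, seed = 7L)
  c2 <- simulate_cohort(gts, seed = 7L)
  expect_identical(lapply(c1, `[[`, "ratings"),
                   lapply(c2, `[[`, "ratings"))
  expect_named(c1, c("P01", "P02"))
  # same truths, different derived seeds: persons differ
  expect_false(identical(c1$P01$ratings, c1$P02$ratings))
  # cohort of one is valid
  expect_length(simulate_cohort(gts[1], seed = 7L), 1L)
})

test_that("the default cohort includes the designed special cases", {
  gts <- default_cohort_truths()
  expect_length(gts, 10L)
  expect_identical(sort(gts[[5]]$endorsed), c("Fatigue", "Headache"))
  expect_identical(gts[[7]]$Omega, diag(18L))
  expect_length(gts[[7]]$endorsed, 9L)
  expect_true(all(vapply(gts, function(g) g$missing_rate, numeric(1)) ==
                    0.27))
})
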