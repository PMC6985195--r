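test_that("long CSV pivots to the wide matrix and validates ratings", {
  ts <- fixture_timestamps(1L)[1L]
  f <- tempfile(fileext = ".csv")
  Y <- matrix(c(2, 0, 1), 1L,
              dimnames = list(NULL, c("Headache", "Fatigue", "Nausea")))
  write_long_csv(Y, ts, f)
  ds <- read_ema_csv(f)
  expect_s3_class(ds, "ema_dataset")
  expect_identical(dim(ds$ratings), c(1L, 3L))
  expect_equal(unname(ds$ratings[1L, c("Headache", "Fatigue", "Nausea")]),
               c(2, 0, 1))

  Y_bad <- Y; Y_bad[1L, 1L] <- 7
  write_long_csv(Y_bad, ts, f)
  expect_error(read_ema_csv(f), "rating outside")

  writeLines(c("person_id,timestamp,symptom,rating",
               "T01,not-a-time,Headache,2"), f)
  expect_error(read_ema_csv(f), "timestamp")

  df <- read.csv(write_long_csv(Y, ts, f))
  df <- rbind(df, df[1L, ]) # duplicate (timestamp, symptom)
  write.csv(df, f, row.names = FALSE)
  expect_error(read_ema_csv(f), "duplicate")
})

test_that("missing prompts survive the round trip and set the response rate", {
  ts <- fixture_timestamps(20L)
  set.seed(11)
  Y <- matrix(sample(0:6, 100 * 3, replace = TRUE), 100,
              dimnames = list(NULL, c("Headache", "Fatigue", "Nausea")))
  miss <- sort(sample(100, 27))
  Y[miss, ] <- NA
  f <- tempfile(fileext = ".csv")
  write_long_csv(Y, ts, f)
  ds <- read_ema_csv(f)
  expect_identical(dim(ds$ratings), c(100L, 3L))
  expect_identical(sum(rowSums(is.na(ds$ratings)) == 3L), 27L)
  rep <- screen_endorsement(ds)
  expect_equal(attr(rep, "response_rate"), 0.73)

  # write -> read round trip is exact
  f2 <- tempfile(fileext = ".csv")
  write_ema_csv(ds, f2)
  ds2 <- read_ema_csv(f2)
  expect_equal(ds2$ratings, ds$ratings)
  expect_equal(ds2$timestamps, ds$timestamps)
  expect_identical(ds2$schema, ds$schema)
})

test_that("out-of-schema symptoms are rejected", {
  ts <- fixture_timestamps(1L)[1L]
  f <- tempfile(fileext = ".csv")
  writeLines(c("person_id,timestamp,symptom,rating",
               sprintf("T01,%s,NotASymptom,3",
                       format(ts, "%Y-%m-%dT%H:%M:%S"))), f)
  expect_error(read_ema_csv(f), "NotASymptom")
})

test_that("endorsement screen applies the count and SD rules", {
  ts <- fixture_timestamps(20L)
  Y <- cbind(Headache = rep(0, 100),                   # never endorsed
             Fatigue = c(rep(0, 99), 1),               # one nonzero
             Nausea = rep(c(1, 3), 50))                # alternating
  ds <- ema_dataset("T01", Y, ts)
  rep <- screen_endorsement(ds, min_nonzero = 3L, min_sd = 0.1)
  status <- setNames(rep$status, rep$symptom)
  expect_identical(status[["Headache"]], "insufficient_variance")
  expect_identical(status[["Fatigue"]], "insufficient_variance")
  expect_identical(status[["Nausea"]], "endorsed")
  expect_identical(endorsed_symptoms(rep), "Nausea")
})

test_that("endorsement screen is invariant to row order", {
  ds <- fixture_dataset(n_days = 10L)
  rep1 <- screen_endorsement(ds)
  perm <- sample(nrow(ds$ratings))
  ds2 <- ema_dataset(ds$person_id, ds$ratings[perm, ], ds$timestamps[perm],
                     ds$schema)
  rep2 <- screen_endorsement(ds2)
  expect_equal(rep1, rep2)
})

test_that("complete-case restriction drops missing rows and is idempotent", {
  ts <- fixture_timestamps(20L)
  set.seed(3)
  Y <- matrix(sample(0:6, 300, replace = TRUE), 100,
              dimnames = list(NULL, c("Headache", "Fatigue", "Nausea")))
  Y[sample(100, 27), ] <- NA
  ds <- ema_dataset("T01", Y, ts)
  cc <- complete_cases_ema(ds)
  expect_identical(nrow(cc$ratings), 73L)
  expect_true(all(cc$timestamps %in% ds$timestamps))
  expect_equal(complete_cases_ema(cc), cc)

  # no missingness: identity
  ds_full <- fixture_dataset()
  expect_equal(complete_cases_ema(ds_full)$ratings, ds_full$ratings)

  # one symptom fully missing
  Y2 <- Y; Y2[, "Nausea"] <- NA
  ds2 <- ema_dataset("T01", Y2, ts)
  expect_error(complete_cases_ema(ds2, "Nausea"), "complete rows")
})
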