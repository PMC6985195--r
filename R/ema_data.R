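#' Construct a person-level EMA dataset
#'
#' Holds one person's ecological momentary assessment series as an
#' observations-by-symptoms matrix of Likert ratings (0-6) with `NA` marking
#' unanswered prompts, together with the prompt timestamps and the symptom
#' schema. Rows are sorted by timestamp; duplicate timestamps are rejected.
#'
#' @param person_id identifier for the person.
#' @param ratings numeric matrix (n_obs x n_symptoms) with column names among
#'   the schema items; entries integer 0-6 or `NA`.
#' @param timestamps `POSIXct` vector of length `nrow(ratings)`, strictly
#'   increasing after sorting.
#' @param schema a [symptom_schema()].
#' @param n_scheduled number of scheduled prompts (used for the response
#'   rate); defaults to `nrow(ratings)`.
#' @return An object of class `"ema_dataset"`.
#' @export
ema_dataset <- function(person_id, ratings, timestamps, schema = pcss_schema(),
                        n_scheduled = nrow(ratings)) {
  ratings <- as.matrix(ratings)
  if (is.null(colnames(ratings)))
    stop("ratings must have symptom column names")
  if (!all(colnames(ratings) %in% schema$items))
    stop("unknown symptom label(s): ",
         paste(setdiff(colnames(ratings), schema$items), collapse = ", "))
  if (!inherits(timestamps, "POSIXct"))
    stop("timestamps must be POSIXct")
  if (length(timestamps) != nrow(ratings))
    stop("timestamps length must equal nrow(ratings)")
  ord <- order(timestamps)
  timestamps <- timestamps[ord]
  ratings <- ratings[ord, , drop = FALSE]
  # canonical column order: as the schema lists the items
  ratings <- ratings[, intersect(schema$items, colnames(ratings)),
                     drop = FALSE]
  if (anyDuplicated(timestamps))
    stop("duplicate timestamps for person ", person_id)
  vals <- ratings[!is.na(ratings)]
  if (length(vals) && (any(vals < .rating_min) || any(vals > .rating_max) ||
                       any(vals != round(vals))))
    stop("ratings must be integers in ", .rating_min, "..", .rating_max)
  structure(list(person_id = as.character(person_id), ratings = ratings,
                 timestamps = timestamps, schema = schema,
                 n_scheduled = as.integer(n_scheduled)),
            class = "ema_dataset")
}

#' @export
print.ema_dataset <- function(x, ...) {
  n_ans <- sum(rowSums(!is.na(x$ratings)) > 0)
  cat("EMA dataset for person", x$person_id, "\n")
  cat(" ", nrow(x$ratings), "prompts (", n_ans, "answered ),",
      ncol(x$ratings), "symptoms\n")
  cat("  window:", format(min(x$timestamps)), "to",
      format(max(x$timestamps)), "\n")
  invisible(x)
}

#' Read long-format EMA records from CSV
#'
#' Expects columns `person_id`, `timestamp` (ISO-8601, parsed in UTC),
#' `symptom` and `rating` (integer 0-6, empty for an unanswered prompt).
#' Rows are pivoted to the wide observations-by-symptoms matrix; prompts
#' whose every rating is empty become all-missing rows.
#'
#' @param path CSV file path.
#' @param schema a [symptom_schema()]; out-of-schema symptom labels are an
#'   error.
#' @param tz timezone for timestamp parsing (default `"UTC"`).
#' @return A list of [ema_dataset()] objects, one per person (named by
#'   person id). With a single person the dataset itself is returned.
#' @export
read_ema_csv <- function(path, schema = pcss_schema(), tz = "UTC") {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("person_id", "timestamp", "symptom", "rating")
  if (!all(need %in% names(df)))
    stop("CSV must have columns: ", paste(need, collapse = ", "))
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")
  ts <- tryCatch(as.POSIXct(df$timestamp, tz = tz, tryFormats = fmts),
                 error = function(e) rep(as.POSIXct(NA), nrow(df)))
  if (anyNA(ts)) {
    bad <- vapply(df$timestamp, function(x)
      inherits(tryCatch(as.POSIXct(x, tz = tz, tryFormats = fmts),
                        error = function(e) e), "error"), TRUE)
    stop("unparseable timestamp at row(s): ",
         paste(head(which(bad | is.na(ts)), 5L), collapse = ", "))
  }
  bad_sym <- !(df$symptom %in% schema$items)
  if (any(bad_sym))
    stop("symptom label(s) not in schema: ",
         paste(unique(df$symptom[bad_sym]), collapse = ", "))
  rating <- suppressWarnings(as.numeric(df$rating))
  rated <- nzchar(trimws(df$rating))
  if (any(rated & is.na(rating)))
    stop("non-numeric rating at row(s): ",
         paste(head(which(rated & is.na(rating)), 5L), collapse = ", "))
  if (any(rated & (rating < .rating_min | rating > .rating_max |
                   rating != round(rating))))
    stop("rating outside ", .rating_min, "..", .rating_max,
         " at row(s): ",
         paste(head(which(rated & (rating < .rating_min |
                                   rating > .rating_max |
                                   rating != round(rating))), 5L),
               collapse = ", "))
  rating[!rated] <- NA_real_

  out <- lapply(split(seq_len(nrow(df)), df$person_id), function(ix) {
    sub <- df[ix, , drop = FALSE]
    sub_ts <- ts[ix]
    sub_r <- rating[ix]
    key <- paste(format(sub_ts, "%Y-%m-%d %H:%M:%OS3"), sub$symptom)
    if (anyDuplicated(key))
      stop("duplicate (timestamp, symptom) for person ", sub$person_id[1L])
    u_ts <- sort(unique(sub_ts))
    syms <- intersect(schema$items, unique(sub$symptom))
    m <- matrix(NA_real_, length(u_ts), length(syms),
                dimnames = list(NULL, syms))
    ri <- match(sub_ts, u_ts)
    ci <- match(sub$symptom, syms)
    m[cbind(ri, ci)] <- sub_r
    ema_dataset(sub$person_id[1L], m, u_ts, schema)
  })
  if (length(out) == 1L) out[[1L]] else out
}

#' Write an EMA dataset back to long-format CSV
#'
#' Inverse of [read_ema_csv()]: one row per (prompt, symptom), with an empty
#' rating cell for missing entries so that all-missing prompts survive the
#' round trip.
#'
#' @param ds an [ema_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ema_csv <- function(ds, path) {
  stopifnot(inherits(ds, "ema_dataset"))
  n <- nrow(ds$ratings)
  p <- ncol(ds$ratings)
  df <- data.frame(
    person_id = rep(ds$person_id, n * p),
    timestamp = rep(format(ds$timestamps, "%Y-%m-%dT%H:%M:%S"), each = p),
    symptom = rep(colnames(ds$ratings), times = n),
    rating = as.vector(t(ds$ratings)),
    stringsAsFactors = FALSE
  )
  write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Screen symptoms for endorsement
#'
#' A symptom enters a person's models only if it shows enough variation: at
#' least `min_nonzero` non-zero ratings and a standard deviation of at least
#' `min_sd` rating units. Symptoms failing either part are flagged
#' `insufficient_variance` and excluded downstream.
#'
#' @param ds an [ema_dataset()].
#' @param min_nonzero minimum count of non-zero ratings (default 3).
#' @param min_sd minimum SD in rating units (default 0.1).
#' @return An object of class `"endorsement_report"`: a data frame with one
#'   row per symptom (`symptom`, `n_obs`, `n_nonzero`, `sd`, `status`) plus
#'   attribute `response_rate`.
#' @export
screen_endorsement <- function(ds, min_nonzero = 3L, min_sd = 0.1) {
  stopifnot(inherits(ds, "ema_dataset"))
  Y <- ds$ratings
  answered <- rowSums(!is.na(Y)) > 0
  if (sum(answered) < 2L)
    stop("fewer than 2 answered prompts; cannot screen endorsement")
  stats <- lapply(colnames(Y), function(s) {
    y <- Y[, s]
    y <- y[!is.na(y)]
    data.frame(symptom = s, n_obs = length(y),
               n_nonzero = sum(y != 0),
               sd = if (length(y) >= 2L) sd(y) else NA_real_,
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, stats)
  rep$status <- ifelse(rep$n_nonzero >= min_nonzero &
                         !is.na(rep$sd) & rep$sd >= min_sd,
                       "endorsed", "insufficient_variance")
  attr(rep, "response_rate") <- sum(answered) / ds$n_scheduled
  attr(rep, "min_nonzero") <- min_nonzero
  attr(rep, "min_sd") <- min_sd
  class(rep) <- c("endorsement_report", "data.frame")
  rep
}

#' @export
print.endorsement_report <- function(x, ...) {
  cat("Endorsement screen:", sum(x$status == "endorsed"), "of", nrow(x),
      "symptoms endorsed; response rate",
      sprintf("%.2f", attr(x, "response_rate")), "\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Endorsed symptom labels from an endorsement report
#' @param report an `"endorsement_report"`.
#' @return character vector of endorsed symptom labels.
#' @export
endorsed_symptoms <- function(report) {
  report$symptom[report$status == "endorsed"]
}

#' Restrict an EMA dataset to complete cases
#'
#' Drops every prompt with a missing rating for any of the requested
#' symptoms (listwise deletion), so that detrending and network estimation
#' operate on identical rows.
#'
#' @param ds an [ema_dataset()].
#' @param symptoms symptom labels to require; default all columns.
#' @param min_rows minimum acceptable number of remaining rows (default 10).
#' @return An [ema_dataset()] restricted to the complete rows and the
#'   requested symptom columns.
#' @export
complete_cases_ema <- function(ds, symptoms = colnames(ds$ratings),
                               min_rows = 10L) {
  stopifnot(inherits(ds, "ema_dataset"))
  if (!all(symptoms %in% colnames(ds$ratings)))
    stop("symptom(s) not present: ",
         paste(setdiff(symptoms, colnames(ds$ratings)), collapse = ", "))
  keep <- complete.cases(ds$ratings[, symptoms, drop = FALSE])
  if (sum(keep) < min_rows)
    stop("only ", sum(keep), " complete rows (need >= ", min_rows, ")")
  ema_dataset(ds$person_id, ds$ratings[keep, symptoms, drop = FALSE],
              ds$timestamps[keep], ds$schema, n_scheduled = ds$n_scheduled)
}
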