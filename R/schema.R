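#' Post-concussion symptom schema
#'
#' The symptom item set used for analysis. The default schema contains the 18
#' post-concussion symptoms modeled throughout the package: headache, nausea,
#' vomiting, dizziness, fatigue, drowsiness, light and noise sensitivity,
#' irritability, sadness, nervousness, feeling more emotional, numbness or
#' tingling, feeling slowed down, feeling mentally foggy, difficulty
#' concentrating, memory problems, and visual problems. Ratings are integer
#' Likert scores from 0 ("not at all") to 6 ("extremely").
#'
#' @param items character vector of all item labels.
#' @param analysis_items subset of `items` entering the models; defaults to
#'   `items`.
#' @return An object of class `"symptom_schema"`: a list with elements
#'   `items` and `analysis_items`.
#' @examples
#' sch <- pcss_schema()
#' sch$analysis_items
#' @export
symptom_schema <- function(items, analysis_items = items) {
  items <- as.character(items)
  analysis_items <- as.character(analysis_items)
  if (anyDuplicated(items))
    stop("symptom labels must be unique")
  if (!all(analysis_items %in% items))
    stop("analysis_items must be a subset of items")
  structure(list(items = items, analysis_items = analysis_items),
            class = "symptom_schema")
}

#' @rdname symptom_schema
#' @export
pcss_schema <- function() {
  symptom_schema(c(
    "Headache", "Nausea", "Vomiting", "Dizziness", "Fatigue", "Drowsiness",
    "Light", "Noise", "Irritability", "Sadness", "Nervousness", "Emotional",
    "Numb", "Slow", "Foggy", "Concentration", "Memory", "Vision"
  ))
}

#' @export
print.symptom_schema <- function(x, ...) {
  cat("Symptom schema:", length(x$items), "items,",
      length(x$analysis_items), "analysis items\n")
  cat(" ", paste(x$analysis_items, collapse = ", "), "\n")
  invisible(x)
}

# Rating bounds for the Likert scale
.rating_min <- 0L
.rating_max <- 6L
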