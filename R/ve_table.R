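#' Variance-explained grid across a cohort
#'
#' Assembles the symptoms-by-persons table of per-symptom R-squared values
#' from a set of fitted person-specific models, with the two special cell
#' states kept distinct: a symptom the person did not endorse (insufficient
#' variance) is an empty cell rendered as an en-dash, while an endorsed
#' symptom for which the LASSO retained no temporal predictors is a true
#' 0.00. Row and column averages exclude not-endorsed cells; 0.00 cells
#' count as zero.
#'
#' @param fits named list of `"idionet"` objects (names become column
#'   labels).
#' @return An object of class `"ve_table"`: list with `r2` (numeric matrix,
#'   `NA` = not endorsed), `no_predictors` (logical matrix), `row_means`,
#'   `col_means`, `grand_mean`.
#' @export
variance_explained <- function(fits) {
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, TRUE, "idionet")))
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, `[[`, character(1), "person_id")
  symptoms <- fits[[1L]]$data$schema$analysis_items
  M <- matrix(NA_real_, length(symptoms), length(fits),
              dimnames = list(symptoms, names(fits)))
  NP <- matrix(FALSE, length(symptoms), length(fits),
               dimnames = dimnames(M))
  for (j in seq_along(fits)) {
    r2 <- fits[[j]]$r_squared
    M[names(r2), j] <- r2
    np <- names(r2)[vapply(fits[[j]]$detrend,
                           function(d) length(d$retained) == 0L, TRUE)]
    NP[np, j] <- TRUE
  }
  structure(list(r2 = M, no_predictors = NP,
                 row_means = rowMeans(M, na.rm = TRUE),
                 col_means = colMeans(M, na.rm = TRUE),
                 grand_mean = mean(M, na.rm = TRUE)),
            class = "ve_table")
}

#' Render a variance-explained table as character cells
#'
#' @param x a `"ve_table"`.
#' @param digits decimals for the cells (default 2).
#' @param dash string for not-endorsed cells (an en-dash by default).
#' @param averages append the `Avg.` row and column.
#' @return character matrix.
#' @export
format_ve_table <- function(x, digits = 2L, dash = "–",
                            averages = TRUE) {
  stopifnot(inherits(x, "ve_table"))
  fmt <- function(v) sprintf(paste0("%.", digits, "f"), v)
  G <- matrix(dash, nrow(x$r2), ncol(x$r2), dimnames = dimnames(x$r2))
  G[!is.na(x$r2)] <- fmt(x$r2[!is.na(x$r2)])
  if (averages) {
    G <- cbind(G, Avg. = ifelse(is.nan(x$row_means), dash,
                                fmt(x$row_means)))
    G <- rbind(G, Avg. = c(fmt(x$col_means), fmt(x$grand_mean)))
  }
  G
}

#' @export
print.ve_table <- function(x, ...) {
  cat("Variance explained by temporal structure (rows: symptoms, columns:",
      "persons)\n")
  print(format_ve_table(x), quote = FALSE)
  cat("Note: – = insufficient variance / not endorsed;",
      "0.00 = no predictors retained.\n")
  invisible(x)
}

#' Write a variance-explained table to CSV
#' @param x a `"ve_table"`.
#' @param path output path.
#' @param dash string used for not-endorsed cells; defaults to `"-"` for
#'   CSV friendliness.
#' @return `path`, invisibly.
#' @export
write_ve_table <- function(x, path, dash = "-") {
  G <- format_ve_table(x, dash = dash)
  df <- data.frame(Symptom = rownames(G), G, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
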