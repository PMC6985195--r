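#' Temporal design matrix: trends and diurnal/ultradian cycles
#'
#' Builds the seven temporal predictors used throughout the package: linear,
#' quadratic and cubic trends in elapsed time, and sine/cosine pairs for
#' 24-hour and 12-hour cycles in clock time. Modeling each frequency as a
#' sine plus cosine pair leaves the cycle's amplitude and phase free, so the
#' fit is invariant to how the clock is anchored.
#'
#' Trend columns use hours elapsed since `anchor` (default: the first
#' timestamp); cycle columns use actual time of day in hours, so diurnal
#' processes stay anchored to the day regardless of when observation began.
#'
#' @param timestamps strictly increasing `POSIXct` vector.
#' @param anchor `POSIXct` origin for elapsed time; must not be after the
#'   first timestamp. Default: first timestamp.
#' @return An object of class `"temporal_basis"`: list with `X` (n x 7
#'   unstandardized matrix, columns `trend_linear`, `trend_quadratic`,
#'   `trend_cubic`, `sin24`, `cos24`, `sin12`, `cos12`), `t` (elapsed hours),
#'   `clock` (time of day in hours), `timestamps`, and standardization
#'   metadata (empty until [standardize_basis()]).
#' @examples
#' ts <- as.POSIXct("2024-01-01 08:00", tz = "UTC") + 3600 * seq(0, 72, by = 3)
#' b <- temporal_basis(ts)
#' head(b$X)
#' @export
temporal_basis <- function(timestamps, anchor = timestamps[1L]) {
  if (!inherits(timestamps, "POSIXct"))
    stop("timestamps must be POSIXct")
  if (length(timestamps) < 1L) stop("no timestamps")
  if (any(diff(as.numeric(timestamps)) <= 0))
    stop("timestamps must be strictly increasing")
  if (as.numeric(anchor) > as.numeric(timestamps[1L]))
    stop("anchor must not be after the first timestamp")
  t_h <- as.numeric(timestamps - anchor, units = "hours")
  lt <- as.POSIXlt(timestamps)
  clock <- lt$hour + lt$min / 60 + lt$sec / 3600
  X <- cbind(
    trend_linear = t_h,
    trend_quadratic = t_h^2,
    trend_cubic = t_h^3,
    sin24 = sin(2 * pi * clock / 24),
    cos24 = cos(2 * pi * clock / 24),
    sin12 = sin(2 * pi * clock / 12),
    cos12 = cos(2 * pi * clock / 12)
  )
  structure(list(X = X, t = t_h, clock = clock, timestamps = timestamps,
                 anchor = anchor, standardized = FALSE,
                 center = NULL, scale = NULL, dropped = character(0)),
            class = "temporal_basis")
}

#' Standardize the temporal basis
#'
#' Centers and scales every basis column to mean 0, SD 1, recording the
#' transform so coefficients can be mapped back. Standardization is required
#' before L1-penalized fitting: the cubic trend in raw hours dwarfs the unit
#' sine/cosine columns by many orders of magnitude, which would make a common
#' penalty meaningless. Columns with (numerically) zero variance -- e.g. the
#' 24-h sine when every prompt falls at the same clock time -- are dropped
#' with a warning and recorded in `dropped`.
#'
#' @param basis a [temporal_basis()].
#' @param tol relative SD below which a column counts as constant.
#' @return The basis with `X` standardized, `center`/`scale` filled in and
#'   `standardized = TRUE`. Idempotent.
#' @export
standardize_basis <- function(basis, tol = 1e-10) {
  stopifnot(inherits(basis, "temporal_basis"))
  if (isTRUE(basis$standardized)) return(basis)
  if (nrow(basis$X) < 2L) stop("need at least 2 observations to standardize")
  X <- basis$X
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  ref <- pmax(abs(ctr), 1)
  keep <- scl > tol * ref
  if (!all(keep)) {
    warning("dropping zero-variance basis column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    basis$dropped <- c(basis$dropped, colnames(X)[!keep])
  }
  X <- X[, keep, drop = FALSE]
  ctr <- ctr[keep]; scl <- scl[keep]
  basis$X <- scale(X, center = ctr, scale = scl)
  attr(basis$X, "scaled:center") <- NULL
  attr(basis$X, "scaled:scale") <- NULL
  basis$center <- ctr
  basis$scale <- scl
  basis$standardized <- TRUE
  basis
}

#' @export
print.temporal_basis <- function(x, ...) {
  cat("Temporal basis:", nrow(x$X), "observations x", ncol(x$X), "columns",
      if (x$standardized) "(standardized)" else "(raw)", "\n")
  cat("  span:", sprintf("%.1f", max(x$t)), "hours\n")
  if (length(x$dropped))
    cat("  dropped:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

# Subset a basis to rows `keep` (logical or integer), preserving raw state.
basis_rows <- function(basis, keep) {
  stopifnot(inherits(basis, "temporal_basis"), !basis$standardized)
  temporal_basis(basis$timestamps[keep], anchor = basis$anchor)
}
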