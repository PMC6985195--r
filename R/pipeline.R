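#' Run the full analysis for one person and write a result bundle
#'
#' Fits [idionet()] and writes every artifact to `out_dir`: the endorsement
#' report, per-symptom detrend summaries (JSON), both networks as edge
#' lists, adjacency matrices and JSON bundles, both centrality tables, the
#' raw-versus-detrended comparison, and a `manifest.json` listing every
#' file with its MD5 content hash and the configuration. Output is
#' deterministic: rerunning with the same data, control and seed yields
#' byte-identical files.
#'
#' @param ds an [ema_dataset()] (or CSV path).
#' @param control an [idionet_control()].
#' @param out_dir output directory (created if needed).
#' @return the `"idionet"` fit, invisibly, with attribute `"bundle"` (the
#'   manifest).
#' @export
analyze_person <- function(ds, control = idionet_control(),
                           out_dir = ".") {
  fit <- idionet(ds, control)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    files <<- c(files, name)
    path
  }

  wr("endorsement.csv", function(p) {
    df <- as.data.frame(fit$endorsement)
    df$response_rate <- attr(fit$endorsement, "response_rate")
    write.csv(df, p, row.names = FALSE, quote = FALSE)
  })
  wr("detrend.json", function(p) {
    out <- lapply(fit$detrend, function(d)
      list(symptom = d$symptom, retained = as.list(d$retained),
           beta = as.list(d$beta), r_squared = d$r_squared,
           lambda = d$lambda, n_obs = d$n_obs))
    jsonlite::write_json(out, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })
  ve <- variance_explained(list(fit))
  wr("variance_explained.csv", function(p) write_ve_table(ve, p))

  write_net <- function(net, stem) {
    wr(paste0(stem, "_edges.csv"), function(p)
      write.csv(net$edges, p, row.names = FALSE, quote = FALSE))
    wr(paste0(stem, "_adjacency.csv"), function(p)
      write.csv(data.frame(node = rownames(net$W), net$W,
                           check.names = FALSE), p,
                row.names = FALSE, quote = FALSE))
    wr(paste0(stem, ".json"), function(p)
      jsonlite::write_json(
        list(nodes = net$nodes, kinds = net$kinds,
             W = net$W, selected_lambda = net$selected_lambda,
             gamma = net$gamma, n_obs = net$n_obs,
             n_lambda = length(net$lambda_path),
             uninterpretable = net$uninterpretable),
        p, auto_unbox = TRUE, digits = NA, pretty = TRUE))
  }
  write_net(fit$network_raw, "network_raw")
  write_net(fit$network_detrended, "network_detrended")

  wr("centrality_raw.csv", function(p)
    write.csv(as.data.frame(fit$centrality_raw), p, row.names = FALSE,
              quote = FALSE))
  wr("centrality_detrended.csv", function(p)
    write.csv(as.data.frame(fit$centrality_detrended), p,
              row.names = FALSE, quote = FALSE))
  if (!is.null(fit$comparison)) {
    wr("comparison.csv", function(p)
      write.csv(as.data.frame(fit$comparison), p, row.names = FALSE,
                quote = FALSE))
    wr("comparison.json", function(p)
      jsonlite::write_json(
        list(metric = attr(fit$comparison, "metric"),
             rank_correlation = attr(fit$comparison, "rank_correlation"),
             uninterpretable = attr(fit$comparison, "uninterpretable"),
             table = fit$comparison),
        p, auto_unbox = TRUE, digits = NA, pretty = TRUE))
  }

  manifest <- list(
    person_id = fit$person_id,
    control = unclass(fit$control),
    n_obs = nrow(fit$data$ratings),
    files = lapply(setNames(files, files), function(f)
      unname(tools::md5sum(file.path(out_dir, f))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(fit, "bundle") <- manifest
  invisible(fit)
}

#' Analyze a cohort and assemble the cross-person report
#'
#' Runs [analyze_person()] for every dataset, isolating failures (a person
#' whose analysis errors is recorded and skipped), then writes the cohort
#' variance-explained grid with its `Avg.` row and column.
#'
#' @param datasets named list of [ema_dataset()] objects, or character
#'   vector of CSV paths.
#' @param control an [idionet_control()].
#' @param out_dir output directory; per-person bundles go to subdirectories
#'   named by person id.
#' @return list with `fits` (successful `"idionet"` objects), `errors`
#'   (named character vector of failure messages) and `table` (the
#'   [variance_explained()] grid), invisibly.
#' @export
analyze_cohort <- function(datasets, control = idionet_control(),
                           out_dir = ".") {
  if (is.character(datasets)) {
    paths <- datasets
    datasets <- lapply(paths, function(p)
      tryCatch(read_ema_csv(p), error = function(e) e))
    names(datasets) <- vapply(seq_along(datasets), function(i)
      if (inherits(datasets[[i]], "ema_dataset"))
        datasets[[i]]$person_id else basename(paths[i]), character(1))
  }
  if (is.null(names(datasets)))
    names(datasets) <- vapply(datasets, function(d)
      if (inherits(d, "ema_dataset")) d$person_id else "?", character(1))

  fits <- list()
  errors <- character(0)
  for (id in names(datasets)) {
    d <- datasets[[id]]
    res <- if (inherits(d, "error")) d else
      tryCatch(analyze_person(d, control, file.path(out_dir, id)),
               error = function(e) e)
    if (inherits(res, "error")) {
      errors[id] <- conditionMessage(res)
    } else {
      fits[[id]] <- res
    }
  }
  if (!length(fits)) stop("no person could be analyzed; first error: ",
                          errors[1L])
  tab <- cohort_report(fits, out_dir)
  if (length(errors)) {
    write.csv(data.frame(person = names(errors), error = unname(errors)),
              file.path(out_dir, "errors.csv"), row.names = FALSE)
  }
  invisible(list(fits = fits, errors = errors, table = tab))
}

#' Assemble and write the cohort report
#'
#' @param fits named list of `"idionet"` objects.
#' @param out_dir directory for `variance_explained.csv` and
#'   `cohort_manifest.json`; `NULL` to skip writing.
#' @return the `"ve_table"`, invisibly.
#' @export
cohort_report <- function(fits, out_dir = NULL) {
  tab <- variance_explained(fits)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(out_dir, "variance_explained.csv")
    write_ve_table(tab, path)
    summary_df <- data.frame(
      person = names(fits),
      n_obs = vapply(fits, function(f) nrow(f$data$ratings), integer(1)),
      n_endorsed = vapply(fits, function(f) length(f$detrend), integer(1)),
      mean_r2 = vapply(fits, function(f) mean(f$r_squared), numeric(1)),
      edges_raw = vapply(fits, function(f)
        nrow(f$network_raw$edges), integer(1)),
      edges_detrended = vapply(fits, function(f)
        nrow(f$network_detrended$edges), integer(1)),
      row.names = NULL)
    write.csv(summary_df, file.path(out_dir, "cohort_summary.csv"),
              row.names = FALSE, quote = FALSE)
    manifest <- list(
      persons = names(fits),
      files = lapply(setNames(nm = c("variance_explained.csv",
                                     "cohort_summary.csv")), function(f)
        unname(tools::md5sum(file.path(out_dir, f)))))
    jsonlite::write_json(manifest, file.path(out_dir,
                                             "cohort_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(tab)
}
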