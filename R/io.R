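#' Read feeding trials from a delimited text file
#'
#' Reads a comma-delimited, UTF-8, headered table and validates it into a
#' `feeding_trials` object. External header names are adapted through
#' `mapping`, a named character vector `canonical = "file column"`; any
#' canonical column not mapped is looked up under its own name. Ring count
#' and structure presence are derived from the complexity level when the
#' file does not carry them; the trial duration defaults to 1 day.
#' Validation failures name the offending rows.
#'
#' @param path path to a CSV file.
#' @param mapping optional named character vector, e.g.
#'   `c(n_initial = "density", n_eaten = "killed")`.
#' @return a `feeding_trials` table.
#' @export
read_trials <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop("read_trials: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!is.null(mapping)) {
    stopifnot(is.character(mapping), !is.null(names(mapping)))
    for (canon in names(mapping)) {
      src <- mapping[[canon]]
      if (!src %in% names(df))
        stop("read_trials: mapped column '", src, "' (for ", canon,
             ") not in file")
      names(df)[names(df) == src] <- canon
    }
  }
  if ("structure_present" %in% names(df) && is.character(df$structure_present))
    df$structure_present <- tolower(df$structure_present) %in%
      c("true", "t", "1", "yes")
  feeding_trials(df)
}

#' Write feeding trials as canonical CSV
#'
#' UTF-8, comma-delimited, header row, booleans serialized as
#' `true`/`false`. `read_trials(write_trials(x, f))` is lossless.
#'
#' @param trials a `feeding_trials` table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_trials <- function(trials, path) {
  trials <- feeding_trials(trials)
  out <- as.data.frame(trials)
  out$structure_present <- ifelse(out$structure_present, "true", "false")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Run manifest
#'
#' A small provenance record written next to every CLI output: package
#' version, seed, configuration, and MD5 digests of the input files, so a
#' run can be reproduced exactly.
#'
#' @param seed the seed of the run.
#' @param config the `fit_config` (or any list) in force.
#' @param data_files character vector of input paths to digest.
#' @param extra optional named list merged into the manifest.
#' @return a named list.
#' @export
run_manifest <- function(seed, config = NULL, data_files = character(),
                         extra = list()) {
  digests <- if (length(data_files)) {
    d <- tools::md5sum(data_files)
    stats::setNames(as.list(unname(d)), basename(data_files))
  } else list()
  c(list(package = "habfr",
         version = as.character(utils::packageVersion("habfr")),
         seed = seed,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
         config = unclass(config),
         data_md5 = digests),
    extra)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Serialize a fit or a suite to JSON
#'
#' Structured text serialization of fit results (closures, raw trials and
#' config are dropped; estimates, CIs, likelihood and diagnostics are
#' kept), with an optional manifest for provenance.
#'
#' @param fit an `fr_fit`.
#' @param path output path (`.json`).
#' @param manifest optional [run_manifest()] list.
#' @return the path, invisibly.
#' @export
write_fit_json <- function(fit, path, manifest = NULL) {
  stopifnot(inherits(fit, "fr_fit"))
  write_json_file(c(fit_payload(fit), list(manifest = manifest)), path)
}

fit_payload <- function(fit) {
  list(model = fit$name, family = fit$family, df = fit$df, n = fit$n,
       loglik = fit$loglik, aic = fit$aic, bic = fit$bic,
       converged = fit$converged,
       coef_link = as.list(fit$coef),
       vcov = if (fit$vcov_ok) unname(apply(fit$vcov, 1, as.list)) else NULL,
       estimates = fit$estimates)
}

#' @rdname write_fit_json
#' @param suite an `fr_suite`.
#' @export
write_suite_json <- function(suite, path, manifest = NULL) {
  stopifnot(inherits(suite, "fr_suite"))
  write_json_file(list(
    species = suite$species,
    best = suite$best,
    table = suite$table,
    fits = lapply(suite$fits, fit_payload),
    failures = as.list(suite$failures),
    manifest = manifest), path)
}
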