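#' Write / read species traits as CSV
#'
#' One row per species: `species_id`, `maintenance`, then one `c_<a>`
#' column per resource type (0-based resource indices).
#'
#' @param traits a [cr_traits].
#' @param path file path.
#' @return `write_traits_csv` returns `path` invisibly; `read_traits_csv`
#'   returns a [cr_traits].
#' @export
write_traits_csv <- function(traits, path) {
  M <- ncol(traits$uptake)
  df <- data.frame(species_id = traits$species_ids,
                   maintenance = traits$maintenance)
  up <- as.data.frame(traits$uptake)
  names(up) <- paste0("c_", seq_len(M) - 1L)
  utils::write.csv(cbind(df, up), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traits_csv
#' @export
read_traits_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cc <- grep("^c_", names(df))
  cr_traits(as.matrix(df[, cc, drop = FALSE]), df$maintenance,
            df$species_id)
}

#' Write / read an environment as CSV
#'
#' One row per resource type: `resource` (0-based index), `supply`, then
#' one `D_<b>` column per source resource holding the conversion
#' proportions (row a, column b: share of consumed b leaked as a).
#' Leakage and dissipation are carried in comment-free extra columns
#' `leakage` and `dissipation` (constant down the file).
#'
#' @param env a [cr_env].
#' @param path file path.
#' @return `write_env_csv` returns `path` invisibly; `read_env_csv`
#'   returns a [cr_env].
#' @export
write_env_csv <- function(env, path) {
  M <- length(env$supply)
  D <- as.data.frame(env$conversion)
  names(D) <- paste0("D_", seq_len(M) - 1L)
  df <- cbind(data.frame(resource = seq_len(M) - 1L, supply = env$supply,
                         leakage = env$leakage,
                         dissipation = env$dissipation), D)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_env_csv
#' @export
read_env_csv <- function(path) {
  df <- utils::read.csv(path)
  dc <- grep("^D_", names(df))
  cr_env(df$supply, as.matrix(df[, dc, drop = FALSE]),
         leakage = df$leakage[1], dissipation = df$dissipation[1])
}

#' Write invasion records to CSV
#'
#' Plain UTF-8 CSV with a header row, one row per trial, "." decimal.
#'
#' @param records a records `data.frame` from [run_trial()] or
#'   [run_sweep()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(extinct_resident_ranks = "character"))
}

#' Load a generation config from YAML or JSON
#'
#' The file maps one-to-one onto [generation_config()] arguments; unknown
#' keys raise an error naming the offending key. An optional `assembly`
#' block maps onto [assembly_config()] (with a nested `solver` block for
#' [solver_config()]).
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return A list with `gen` (a [generation_config]) and `assembly` (an
#'   [assembly_config]).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  acfg_raw <- raw$assembly
  raw$assembly <- NULL
  known <- names(formals(generation_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  gen <- do.call(generation_config, raw)
  acfg <- if (is.null(acfg_raw)) assembly_config() else {
    solver_raw <- acfg_raw$solver
    acfg_raw$solver <- NULL
    bad <- setdiff(names(acfg_raw), names(formals(assembly_config)))
    if (length(bad) > 0)
      stop("unknown assembly key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (!is.null(solver_raw))
      acfg_raw$solver <- do.call(solver_config, solver_raw)
    do.call(assembly_config, acfg_raw)
  }
  list(gen = gen, assembly = acfg)
}

#' Write a run manifest
#'
#' Records the config snapshot, root seed, artifact paths, trial counts
#' and package version as JSON. Written last in every command so its
#' presence signals a complete run.
#'
#' @param path output path.
#' @param gen_cfg,acfg the configs used.
#' @param seed root seed.
#' @param artifacts named character vector of output files.
#' @param counts named list of counts (trials run, failed, classified).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, gen_cfg, acfg, seed, artifacts = c(),
                           counts = list()) {
  manifest <- list(
    tool = "crinvade",
    version = as.character(utils::packageVersion("crinvade")),
    seed = seed,
    generation = unclass(gen_cfg),
    assembly = local({
      a <- unclass(acfg)
      a$solver <- unclass(a$solver)
      a
    }),
    artifacts = as.list(artifacts),
    counts = counts)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
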