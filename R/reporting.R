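#' Write all result tables for a model run
#'
#' Writes the comparison table, the per-year ledgers (wide and long format),
#' the uptake schedule, the risk table and a JSON run manifest to `dir`.
#' Rounding happens only here, at the writer: counts to whole persons where
#' labelled as counts, rates to six significant digits; the engine itself is
#' never rounded. Two runs with identical bundles produce byte-identical
#' files (the manifest timestamp is excluded from that guarantee).
#'
#' @param comparison An `scd_comparison` from [compare_worlds()].
#' @param dir Output directory (created if missing).
#' @param seed Seed recorded in the manifest (the projection itself is
#'   deterministic; the seed matters only for simulated response mode).
#' @return Invisibly, the manifest list.
#' @export
write_results <- function(comparison, dir, seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  params <- comparison$params
  fmt <- function(x) signif(x, 6)

  cmp <- comparison$comparison %>% mutate(across(c("without", "with", "impact", "percent"), fmt))
  write_one <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    path
  }
  files <- c(
    write_one(cmp, "comparison.csv"),
    write_one(as_tibble(comparison$without) %>% mutate(across(-year, fmt)),
              "ledger_without.csv"),
    write_one(as_tibble(comparison$with) %>% mutate(across(-year, fmt)),
              "ledger_with.csv"),
    write_one(bind_rows(tidy(comparison$without), tidy(comparison$with)) %>%
                mutate(value = fmt(value)),
              "ledger_long.csv"),
    write_one(build_schedule(params) %>%
                mutate(treated = round(treated), across(c("share", "coverage"), fmt)),
              "uptake_schedule.csv"),
    write_one(risk_table(params) %>% mutate(across(-"outcome", fmt)),
              "risk_table.csv")
  )
  manifest <- run_manifest(params, files, seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Run manifest
#'
#' Provenance record for a run: a stable hash of the resolved parameter
#' bundle, the package version, the seed, a timestamp and the output files.
#' The hash is identical for identical bundles.
#'
#' @param params An [scd_parameters] object.
#' @param files Character vector of output paths.
#' @param seed Seed used for any stochastic component.
#' @return A named list.
#' @export
run_manifest <- function(params, files = character(), seed = NA_integer_) {
  list(
    bundle_hash = rlang::hash(flatten_params(unclass(params))),
    package_version = as.character(utils::packageVersion("scdproj")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = as.list(basename(files))
  )
}
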