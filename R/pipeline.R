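#' Pipeline run configuration
#'
#' @param manifest incidence input: a manifest CSV or a directory of
#'   incidence CSVs (see [read_incidence()]). Alternatively give `sim` to
#'   run on a synthetic survey.
#' @param traits trait CSV path (ignored when `sim` is given).
#' @param sim optional [sim_config()] for a synthetic run.
#' @param out_dir output directory for run artifacts.
#' @param n_null null matrices per watershed.
#' @param n_perm permutations per regression term.
#' @param burn_in,thin curveball chain protocol (trades).
#' @param perm_mode permutation scheme, see [permutation_test()].
#' @param min_lakes,min_species watershed size filter.
#' @param seed master seed; per-watershed chains and the permutation
#'   streams are seeded deterministically from it.
#' @return Validated list of class `"run_config"`.
#' @export
run_config <- function(manifest = NULL, traits = NULL, sim = NULL,
                       out_dir = "cooc_run", n_null = 999L, n_perm = 9999L,
                       burn_in = 1000L, thin = 100L,
                       perm_mode = c("pair_shuffle", "species_identity"),
                       min_lakes = 20L, min_species = 20L, seed = 1L) {
  perm_mode <- match.arg(perm_mode)
  if (is.null(sim)) {
    if (is.null(manifest) || is.null(traits)) {
      stop("give either 'sim' or both 'manifest' and 'traits'")
    }
    if (!file.exists(manifest)) stop(sprintf("input path does not exist: '%s'", manifest))
    if (!file.exists(traits)) stop(sprintf("trait file does not exist: '%s'", traits))
  } else {
    stopifnot(inherits(sim, "sim_config"))
  }
  if (n_null < 2L) stop("'n_null' must be >= 2")
  if (n_perm < 1L) stop("'n_perm' must be >= 1")
  structure(list(manifest = manifest, traits = traits, sim = sim,
                 out_dir = out_dir, n_null = as.integer(n_null),
                 n_perm = as.integer(n_perm), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), perm_mode = perm_mode,
                 min_lakes = as.integer(min_lakes),
                 min_species = as.integer(min_species),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Top-level keys are the arguments of [run_config()]; a `sim` mapping is
#' passed to [sim_config()]. Flags given in `overrides` (e.g. from a CLI)
#' replace file values.
#'
#' @param path `.yaml`/`.yml` or `.json` config file.
#' @param overrides named list of [run_config()] arguments taking
#'   precedence.
#' @return A [run_config()].
#' @export
read_run_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop(sprintf("config file does not exist: '%s'", path))
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  raw[names(overrides)] <- overrides
  if (!is.null(raw$sim)) raw$sim <- do.call(sim_config, as.list(raw$sim))
  rel <- function(p) {
    if (!is.null(p) && !grepl("^(/|[A-Za-z]:)", p)) file.path(dirname(path), p) else p
  }
  if (is.null(overrides$manifest)) raw$manifest <- rel(raw$manifest)
  if (is.null(overrides$traits)) raw$traits <- rel(raw$traits)
  do.call(run_config, raw)
}

#' Deterministic per-watershed seed
#'
#' Fans the master seed out to one seed per watershed via a polynomial
#' string hash, so each watershed's null chain is reproducible in isolation
#' and independent of processing order.
#'
#' @param master_seed integer master seed.
#' @param watershed_id watershed id string.
#' @return Integer seed in `[0, 2^31 - 2]`.
#' @export
watershed_seed <- function(master_seed, watershed_id) {
  h <- 0
  for (code in utf8ToInt(watershed_id)) h <- (h * 31 + code) %% 2147483647
  as.integer((master_seed %% 2147483647 + h) %% 2147483647)
}

#' Run the full co-occurrence-vs-traits pipeline
#'
#' Orchestrates read -> filter -> per-watershed null-model SES -> pooling ->
#' trait distances -> the four hypothesis regressions, writing every stage's
#' table to `config$out_dir`:
#'
#' * `pair_ses.csv` — per-watershed pair SES records;
#' * `pooled_ses.csv` — pooled mean SES per pair;
#' * `design_table.csv` — response + distance predictors;
#' * `regression_reports.csv` / `.json` and `report.txt`;
#' * `run_manifest.json` — config echo, seeds, version, wall time,
#'   per-watershed pair and degenerate-pair counts.
#'
#' Stage outputs are faithful checkpoints: [regress_from_design()] on the
#' written design table reproduces the reports exactly (given the same seed
#' and permutation settings).
#'
#' @param config a [run_config()].
#' @return Invisibly, a list of class `"cooc_run"` with elements `matrices,
#'   traits, pair_ses, pooled, design, reports, manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$sim)) {
    survey <- simulate_survey(config$sim, seed = config$seed)
    matrices <- survey$matrices
    traits <- survey$traits_complete
  } else {
    matrices <- read_incidence(config$manifest)
    traits <- impute_temperature(read_traits(config$traits))
  }
  matrices <- filter_watersheds(matrices, config$min_lakes, config$min_species)
  check_coverage(matrices, traits)

  ws_seeds <- vapply(names(matrices), function(id) watershed_seed(config$seed, id),
                     integer(1L))
  pair_ses <- do.call(rbind, lapply(names(matrices), function(id) {
    set.seed(ws_seeds[[id]])
    watershed_pair_ses(matrices[[id]], n_samples = config$n_null,
                       burn_in = config$burn_in, thin = config$thin)
  }))
  write.csv(pair_ses, file.path(config$out_dir, "pair_ses.csv"), row.names = FALSE)

  pooled <- pool_mean_ses(pair_ses)
  write.csv(pooled, file.path(config$out_dir, "pooled_ses.csv"), row.names = FALSE)

  z <- zscore_traits(traits, species = sort(unique(c(pooled$species_a, pooled$species_b))))
  design <- build_design_table(pooled, z)
  write.csv(design, file.path(config$out_dir, "design_table.csv"), row.names = FALSE)

  reports <- run_hypotheses(design, n_perm = config$n_perm,
                            mode = config$perm_mode, seed = config$seed)
  flat <- report_table(reports)
  write.csv(flat, file.path(config$out_dir, "regression_reports.csv"),
            row.names = FALSE)
  jsonlite::write_json(flat, file.path(config$out_dir, "regression_reports.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  writeLines(report_render(reports), file.path(config$out_dir, "report.txt"))

  per_ws <- data.frame(
    watershed_id = names(matrices),
    seed = unname(ws_seeds),
    n_species = vapply(matrices, nrow, integer(1L)),
    n_lakes = vapply(matrices, ncol, integer(1L)),
    n_pairs = as.integer(vapply(names(matrices), function(id)
      sum(pair_ses$watershed_id == id), numeric(1L))),
    n_degenerate = as.integer(vapply(names(matrices), function(id)
      sum(pair_ses$degenerate[pair_ses$watershed_id == id]), numeric(1L))),
    stringsAsFactors = FALSE
  )
  manifest <- list(
    config = config_echo(config),
    master_seed = config$seed,
    package_version = as.character(packageVersion("cooctraits")),
    r_version = as.character(getRversion()),
    watersheds = per_ws,
    n_pairs_pooled = nrow(pooled),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "run_manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)

  invisible(structure(list(matrices = matrices, traits = traits,
                           pair_ses = pair_ses, pooled = pooled,
                           design = design, reports = reports,
                           manifest = manifest),
                      class = "cooc_run"))
}

config_echo <- function(config) {
  out <- unclass(config)
  if (!is.null(out$sim)) out$sim <- unclass(out$sim)
  out[!vapply(out, is.null, logical(1L))]
}

#' @export
print.cooc_run <- function(x, ...) {
  cat(sprintf("Co-occurrence pipeline run: %d watersheds, %d pooled pairs\n\n",
              length(x$matrices), nrow(x$pooled)))
  print(x$reports)
  invisible(x)
}

#' Re-run the regressions from a written design table
#'
#' Checkpoint re-entry: reads `design_table.csv` (or a compatible CSV) and
#' fits the four hypothesis models, skipping the null-model stage.
#'
#' @param path design-table CSV written by [run_pipeline()].
#' @inheritParams run_hypotheses
#' @return A `cooc_hypotheses` list.
#' @export
regress_from_design <- function(path, n_perm = 9999L,
                                mode = c("pair_shuffle", "species_identity"),
                                seed = NULL) {
  if (!file.exists(path)) stop(sprintf("design table does not exist: '%s'", path))
  design <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("mean_ses", unlist(cooc_models$H1_full))
  missing <- setdiff(needed, names(design))
  if (length(missing) > 0L) {
    stop(sprintf("'%s' lacks design columns: %s", path,
                 paste(missing, collapse = ", ")))
  }
  run_hypotheses(design, n_perm = n_perm, mode = match.arg(mode), seed = seed)
}
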