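#' Configuration for the synthetic metacommunity generator
#'
#' Collects and validates the knobs of the trait-driven assembly simulator.
#' Defaults emulate the study system the package targets: a species pool of
#' 70 lake fish spread over multiple watersheds of at least 20 lakes, with
#' environmental filtering on temperature preference and predation driven by
#' large trophic-level differences switched on, and body-size-mediated
#' competition off.
#'
#' @param n_species species pool size (>= 20 so outputs pass the size filter).
#' @param n_watersheds number of watersheds (incidence matrices).
#' @param lakes_per_watershed lakes per watershed (>= 20).
#' @param base_occupancy baseline presence probability in (0, 1) before any
#'   trait effect.
#' @param beta_env environmental-filtering strength (>= 0): the log-odds of
#'   presence drop by `beta_env * ((temp_pref - lake_temp) / temp_scale)^2`.
#' @param temp_scale scale (degrees C) of the thermal mismatch, i.e. the
#'   mismatch at which filtering reaches full strength `beta_env`.
#' @param beta_pred predation strength (>= 0): each co-occurring species
#'   whose trophic level exceeds a species' own by more than `pred_gap`
#'   contributes an independent removal hazard, giving removal probability
#'   `1 - exp(-beta_pred * n_predators_present)`.
#' @param pred_gap trophic-level difference beyond which predation applies.
#' @param beta_comp competition strength (>= 0): in lakes holding a pair
#'   with body-size z-difference below `comp_width`, one member (at random)
#'   is removed with probability `1 - exp(-beta_comp)`.
#' @param comp_width body-size similarity window (z-score units).
#' @param missing_temp_frac fraction of species whose temperature preference
#'   is withheld (as missing) to exercise congeneric imputation.
#' @param genus_size species per genus; genera are assigned in blocks so
#'   congeners exist for imputation.
#' @param min_lakes,min_species size filter the generated watersheds must
#'   pass; watersheds falling below are regenerated.
#' @param max_retries regeneration attempts per watershed before erroring.
#' @return Validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_species = 70L, n_watersheds = 10L,
                       lakes_per_watershed = 50L, base_occupancy = 0.35,
                       beta_env = 1.5, temp_scale = 5, beta_pred = 0.8,
                       pred_gap = 2, beta_comp = 0, comp_width = 0.25,
                       missing_temp_frac = 0.05, genus_size = 3L,
                       min_lakes = 20L, min_species = 20L, max_retries = 20L) {
  cfg <- list(n_species = as.integer(n_species),
              n_watersheds = as.integer(n_watersheds),
              lakes_per_watershed = as.integer(lakes_per_watershed),
              base_occupancy = base_occupancy, beta_env = beta_env,
              temp_scale = temp_scale, beta_pred = beta_pred,
              pred_gap = pred_gap, beta_comp = beta_comp,
              comp_width = comp_width, missing_temp_frac = missing_temp_frac,
              genus_size = as.integer(genus_size),
              min_lakes = as.integer(min_lakes),
              min_species = as.integer(min_species),
              max_retries = as.integer(max_retries))
  stopifnot(cfg$n_species >= 2L, cfg$n_watersheds >= 1L,
            cfg$lakes_per_watershed >= 20L,
            cfg$base_occupancy > 0, cfg$base_occupancy < 1,
            cfg$beta_env >= 0, cfg$beta_pred >= 0, cfg$beta_comp >= 0,
            cfg$temp_scale > 0, cfg$pred_gap >= 0, cfg$comp_width >= 0,
            cfg$missing_temp_frac >= 0, cfg$missing_temp_frac < 1,
              cfg$genus_size >= 1L, cfg$max_retries >= 1L)
  if (cfg$n_species < cfg$min_species) {
    stop("'n_species' below 'min_species': no watershed could pass the filter")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic species trait table
#'
#' Draws traits on realistic scales for north-temperate lake fish: body size
#' (adult total length, cm) log-normal and right-skewed, from minnows to
#' large predators; temperature preference normal around 18 degrees C,
#' spanning cold- to warm-water guilds; trophic level uniform on 2 to 4.5.
#' Genera are assigned in blocks so that a configurable fraction of species
#' can have their temperature preference withheld (flagged missing) and
#' later recovered by congeneric imputation.
#'
#' @param config a [sim_config()].
#' @return Trait data.frame as from [read_traits()] (missing `temp_pref`
#'   encoded as `NA` with `temp_pref_missing = TRUE`). Uses R's RNG: seed
#'   with [set.seed()].
#' @export
generate_traits <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_species
  genus <- sprintf("genus%02d", ceiling(seq_len(n) / config$genus_size))
  traits <- data.frame(
    species_id = sprintf("sp%03d", seq_len(n)),
    genus = genus,
    body_size = rlnorm(n, meanlog = log(25), sdlog = 0.7),
    temp_pref = rnorm(n, mean = 18, sd = 5.5),
    trophic_level = runif(n, 2, 4.5),
    stringsAsFactors = FALSE
  )
  traits$temp_pref_missing <- FALSE
  n_miss <- floor(config$missing_temp_frac * n)
  if (n_miss > 0L) {
    # only species with >= 1 congener keep an imputation donor
    genus_n <- table(traits$genus)
    eligible <- which(genus_n[traits$genus] >= 2L)
    keep_known <- tapply(eligible, traits$genus[eligible], function(i) i[1L])
    candidates <- setdiff(eligible, unlist(keep_known))
    miss <- sample(candidates, min(n_miss, length(candidates)))
    traits$temp_pref[miss] <- NA_real_
    traits$temp_pref_missing[miss] <- TRUE
  }
  traits
}

#' Generate synthetic watershed incidence matrices
#'
#' Assembles each watershed in three stages, the simplest generative
#' analogues of the three hypothesized trait-based drivers:
#'
#' 1. *Environmental filtering*: each lake draws a temperature; a species'
#'    presence probability is `plogis(qlogis(base_occupancy) - beta_env *
#'    ((temp_pref - lake_temp) / temp_scale)^2)`, then presences are
#'    independent Bernoulli draws. With `beta_env = 0` occupancy is i.i.d.
#'    `Bernoulli(base_occupancy)` (the neutral null).
#' 2. *Predation culling*: within each lake, every co-occurring species
#'    whose trophic level exceeds a species' own by more than `pred_gap` is
#'    an independent removal hazard of rate `beta_pred`, so a species facing
#'    `k` present predators is removed with probability
#'    `1 - exp(-beta_pred * k)`. Tying removal to which predators share the
#'    lake (rather than to whether any does) is what makes predation leave a
#'    pair-specific segregation signal.
#' 3. *Competition culling*: within each lake, for every present pair with
#'    body-size z-difference below `comp_width`, one member at random is
#'    removed with probability `1 - exp(-beta_comp)`.
#'
#' Stages run once, in that order. Species absent from every lake of a
#' watershed are dropped; a watershed falling below the size filter is
#' regenerated (up to `max_retries`, then an error).
#'
#' @param traits complete (post-imputation) trait table.
#' @param config a [sim_config()].
#' @return List of [incidence_matrix()] objects, ids `ws01, ws02, ...`.
#'   Uses R's RNG: seed with [set.seed()].
#' @export
generate_metacommunity <- function(traits, config) {
  stopifnot(inherits(config, "sim_config"))
  validate_traits(traits, allow_missing_temp = FALSE, context = "generator traits")
  stopifnot(nrow(traits) == config$n_species)
  body_z <- as.numeric(scale(traits$body_size))
  out <- vector("list", config$n_watersheds)
  for (w in seq_len(config$n_watersheds)) {
    id <- sprintf("ws%02d", w)
    m <- NULL
    for (try in seq_len(config$max_retries)) {
      cand <- assemble_watershed(traits, body_z, config, id)
      if (nrow(cand) >= config$min_species && ncol(cand) >= config$min_lakes) {
        m <- cand
        break
      }
      warning(sprintf(
        "watershed '%s' attempt %d: only %d species x %d lakes after culling; regenerating",
        id, try, nrow(cand), ncol(cand)))
    }
    if (is.null(m)) {
      stop(sprintf("watershed '%s': could not reach %d species x %d lakes in %d attempts",
                   id, config$min_species, config$min_lakes, config$max_retries))
    }
    out[[w]] <- m
  }
  names(out) <- vapply(out, watershed_id, character(1L))
  out
}

assemble_watershed <- function(traits, body_z, config, id) {
  n_sp <- config$n_species
  n_lk <- config$lakes_per_watershed
  lake_temp <- rnorm(n_lk, mean = rnorm(1L, 18, 3), sd = 2.5)
  mismatch <- outer(traits$temp_pref, lake_temp, "-") / config$temp_scale
  p <- plogis(qlogis(config$base_occupancy) - config$beta_env * mismatch^2)
  occ <- matrix(rbinom(n_sp * n_lk, 1L, p), n_sp, n_lk)
  if (config$beta_pred > 0) {
    # each co-occurring predator (trophic level > own + pred_gap) is an
    # independent removal hazard beta_pred, so removal depends on which
    # predators share the lake, not just whether any does
    tl <- traits$trophic_level
    for (l in seq_len(n_lk)) {
      present <- which(occ[, l] == 1L)
      if (length(present) < 2L) next
      n_pred <- vapply(present, function(i)
        sum(tl[present] > tl[i] + config$pred_gap), integer(1L))
      p_cull <- 1 - exp(-config$beta_pred * n_pred)
      culled <- present[runif(length(present)) < p_cull]
      occ[culled, l] <- 0L
    }
  }
  if (config$beta_comp > 0) {
    p_cull <- 1 - exp(-config$beta_comp)
    for (l in seq_len(n_lk)) {
      present <- which(occ[, l] == 1L)
      if (length(present) < 2L) next
      d <- abs(outer(body_z[present], body_z[present], "-"))
      pairs <- which(upper.tri(d) & d < config$comp_width, arr.ind = TRUE)
      if (nrow(pairs) == 0L) next
      for (k in sample.int(nrow(pairs))) {
        pr <- present[pairs[k, ]]
        pr <- pr[occ[pr, l] == 1L]
        if (length(pr) == 2L && runif(1L) < p_cull) {
          occ[sample(pr, 1L), l] <- 0L
        }
      }
    }
  }
  dimnames(occ) <- list(traits$species_id, sprintf("%s_lake%03d", id, seq_len(n_lk)))
  suppressWarnings(incidence_matrix(occ, id))
}

#' Planted effect directions of a simulation configuration
#'
#' Machine-readable statement, by construction of the generator, of which
#' regression terms should come out positive, negative or null, used by
#' parameter-recovery tests: environmental filtering plants a positive
#' temperature-distance slope, predation a positive trophic quadratic term,
#' and competition a negative body-size slope (segregation of similar-sized
#' species fading with distance).
#'
#' @param config a [sim_config()].
#' @return Named character vector over the five predictor terms with values
#'   `"positive"`, `"negative"` or `"null"`.
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  c(
    d_body = if (config$beta_comp > 0) "negative" else "null",
    d_body_sq = "null",
    d_temp = if (config$beta_env > 0) "positive" else "null",
    d_trophic = "null",
    d_trophic_sq = if (config$beta_pred > 0) "positive" else "null"
  )
}

#' Generate a complete synthetic survey
#'
#' Convenience wrapper: traits (with optional missing temperature values),
#' the imputed trait table actually used for assembly, the watershed
#' incidence matrices, and the planted ground truth. Optionally writes
#' everything to `dir` in the package's CSV interchange formats
#' (`traits.csv`, one incidence CSV per watershed, `manifest.csv`,
#' `ground_truth.json`).
#'
#' @param config a [sim_config()].
#' @param seed integer seed for the whole survey.
#' @param dir optional output directory (created if needed).
#' @return `list(config, traits, traits_complete, matrices, truth)`,
#'   invisibly when `dir` is given.
#' @export
simulate_survey <- function(config = sim_config(), seed = 1L, dir = NULL) {
  set.seed(seed)
  traits <- generate_traits(config)
  traits_complete <- suppressMessages(impute_temperature(traits))
  matrices <- generate_metacommunity(traits_complete, config)
  out <- list(config = config, traits = traits,
              traits_complete = traits_complete, matrices = matrices,
              truth = ground_truth(config))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    tr <- traits[c("species_id", "genus", "body_size", "temp_pref", "trophic_level")]
    write.csv(tr, file.path(dir, "traits.csv"), row.names = FALSE, quote = FALSE)
    files <- character(length(matrices))
    for (i in seq_along(matrices)) {
      files[i] <- paste0(watershed_id(matrices[[i]]), ".csv")
      write_incidence(matrices[[i]], file.path(dir, files[i]))
    }
    write.csv(data.frame(watershed_id = names(matrices), path = files),
              file.path(dir, "manifest.csv"), row.names = FALSE, quote = FALSE)
    jsonlite::write_json(as.list(out$truth), file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(out))
  }
  out
}
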