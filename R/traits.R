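#' Read a species trait table
#'
#' Expects a CSV with columns `species_id, genus, body_size, temp_pref,
#' trophic_level`: body size is adult total length in cm, temperature
#' preference in degrees C (may be empty and later imputed from congeners),
#' trophic level dimensionless (>= 1). Only temperature preference may be
#' missing; a missing body size or trophic level is a hard error.
#'
#' @param path trait CSV path.
#' @return data.frame with one row per species and a logical
#'   `temp_pref_missing` column flagging values awaiting imputation.
#' @export
read_traits <- function(path) {
  if (!file.exists(path)) stop(sprintf("trait file does not exist: '%s'", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("species_id", "genus", "body_size", "temp_pref", "trophic_level")
  absent <- setdiff(needed, names(df))
  if (length(absent) > 0L) {
    stop(sprintf("'%s': missing columns: %s", path, paste(absent, collapse = ", ")))
  }
  df <- df[needed]
  df$species_id <- trimws(as.character(df$species_id))
  df$genus <- trimws(as.character(df$genus))
  for (col in c("body_size", "temp_pref", "trophic_level")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  if (anyDuplicated(df$species_id)) {
    stop(sprintf("duplicate species_id in '%s': %s", path,
                 paste(unique(df$species_id[duplicated(df$species_id)]), collapse = ", ")))
  }
  validate_traits(df, allow_missing_temp = TRUE, context = path)
  df$temp_pref_missing <- is.na(df$temp_pref)
  df
}

validate_traits <- function(df, allow_missing_temp, context = "trait table") {
  bad <- df$species_id[is.na(df$body_size) | df$body_size <= 0]
  if (length(bad) > 0L) {
    stop(sprintf("%s: missing or non-positive body_size for: %s",
                 context, paste(bad, collapse = ", ")))
  }
  bad <- df$species_id[is.na(df$trophic_level) | df$trophic_level < 1]
  if (length(bad) > 0L) {
    stop(sprintf("%s: missing or out-of-range (< 1) trophic_level for: %s",
                 context, paste(bad, collapse = ", ")))
  }
  if (!allow_missing_temp && anyNA(df$temp_pref)) {
    stop(sprintf("%s: missing temp_pref for: %s", context,
                 paste(df$species_id[is.na(df$temp_pref)], collapse = ", ")))
  }
  invisible(df)
}

#' Impute missing temperature preferences from congeners
#'
#' Each missing temperature preference is replaced by the unweighted
#' arithmetic mean of the known temperature preferences of species in the
#' same genus. Non-missing values are never altered. A missing species with
#' no congener of known temperature preference is a hard error naming it.
#'
#' @param traits trait table from [read_traits()].
#' @return The trait table with `temp_pref` complete; imputed species are
#'   reported via `message()` and keep `temp_pref_missing = TRUE` as a record
#'   of imputation.
#' @export
impute_temperature <- function(traits) {
  miss <- which(is.na(traits$temp_pref))
  if (length(miss) == 0L) return(traits)
  genus_mean <- tapply(traits$temp_pref, traits$genus,
                       function(x) mean(x, na.rm = TRUE))
  for (i in miss) {
    g <- traits$genus[i]
    value <- genus_mean[[g]]
    if (is.null(value) || is.nan(value)) {
      stop(sprintf(
        "cannot impute temp_pref for '%s': no congener in genus '%s' has a known value",
        traits$species_id[i], g
      ))
    }
    traits$temp_pref[i] <- value
  }
  message(sprintf("imputed temp_pref from congeners for %d species: %s",
                  length(miss), paste(traits$species_id[miss], collapse = ", ")))
  traits
}

#' Standardize traits to z-scores
#'
#' Converts `body_size`, `temp_pref` and `trophic_level` to z-scores,
#' `(x - mean(x)) / sd(x)` with the sample (n - 1) standard deviation, so the
#' three traits act on a comparable scale in the regression. Standardization
#' is computed over the species actually supplied, so restrict `traits` to
#' the analysed community (e.g. the species entering the pooled pair table)
#' before calling if that is the intended reference set.
#'
#' @param traits complete (post-imputation) trait table.
#' @param species optional character vector: subset to these species before
#'   standardizing.
#' @return data.frame `species_id, body_size, temp_pref, trophic_level` in
#'   z-score units. A zero-variance trait column is a hard error.
#' @export
zscore_traits <- function(traits, species = NULL) {
  if (!is.null(species)) {
    missing <- setdiff(species, traits$species_id)
    if (length(missing) > 0L) {
      stop(sprintf("species not in trait table: %s", paste(missing, collapse = ", ")))
    }
    traits <- traits[match(species, traits$species_id), , drop = FALSE]
  }
  validate_traits(traits, allow_missing_temp = FALSE)
  out <- data.frame(species_id = traits$species_id, stringsAsFactors = FALSE)
  for (col in c("body_size", "temp_pref", "trophic_level")) {
    x <- traits[[col]]
    s <- sd(x)
    if (!is.finite(s) || s == 0) {
      stop(sprintf("trait '%s' has zero variance; z-scores undefined", col))
    }
    out[[col]] <- (x - mean(x)) / s
  }
  out
}
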