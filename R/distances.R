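#' Euclidean distance between two species for one trait
#'
#' Traits are kept separate (one distance per trait, not a combined
#' multi-trait distance); for a single trait the Euclidean distance reduces
#' to the absolute difference of the z-scores.
#'
#' @param z standardized trait table from [zscore_traits()].
#' @param trait one of `"body_size"`, `"temp_pref"`, `"trophic_level"`.
#' @param a,b species ids.
#' @return Non-negative scalar, in z-score units.
#' @export
pair_trait_distance <- function(z, trait, a, b) {
  trait <- match.arg(trait, c("body_size", "temp_pref", "trophic_level"))
  unknown <- setdiff(c(a, b), z$species_id)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown species id: %s", paste(unknown, collapse = ", ")))
  }
  x <- z[[trait]][match(c(a, b), z$species_id)]
  abs(x[1L] - x[2L])
}

#' Build the regression design table
#'
#' Joins the pooled mean SES response to the per-trait distance predictors:
#' one row per pooled species pair with the body-size, temperature-preference
#' and trophic-level distances plus the squared (quadratic) terms for body
#' size and trophic level. Squares are taken of the raw z-scale distances
#' (not re-centered), so the quadratic term reads directly as curvature of
#' the SES-distance relationship.
#'
#' @param pooled pooled pair table from [pool_mean_ses()].
#' @param z standardized trait table from [zscore_traits()]; must cover
#'   every pooled species.
#' @return data.frame with columns `species_a, species_b, mean_ses,
#'   n_watersheds, d_body, d_body_sq, d_temp, d_trophic, d_trophic_sq`.
#' @export
build_design_table <- function(pooled, z) {
  stopifnot(is.data.frame(pooled),
            all(c("species_a", "species_b", "mean_ses") %in% names(pooled)))
  species <- unique(c(pooled$species_a, pooled$species_b))
  missing <- setdiff(species, z$species_id)
  if (length(missing) > 0L) {
    bad <- pooled$species_a %in% missing | pooled$species_b %in% missing
    stop(sprintf("pairs not covered by the trait table: %s",
                 paste(paste(pooled$species_a[bad], pooled$species_b[bad], sep = "/"),
                       collapse = ", ")))
  }
  dist_col <- function(trait) {
    d <- as.matrix(dist(setNames(z[[trait]], z$species_id)))
    d[cbind(pooled$species_a, pooled$species_b)]
  }
  d_body <- dist_col("body_size")
  d_trophic <- dist_col("trophic_level")
  out <- data.frame(
    species_a = pooled$species_a,
    species_b = pooled$species_b,
    mean_ses = pooled$mean_ses,
    n_watersheds = if ("n_watersheds" %in% names(pooled)) pooled$n_watersheds else NA_integer_,
    d_body = d_body,
    d_body_sq = d_body^2,
    d_temp = dist_col("temp_pref"),
    d_trophic = d_trophic,
    d_trophic_sq = d_trophic^2,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
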