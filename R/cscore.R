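#' Pairwise C-score (checkerboard units)
#'
#' For species a and b with occupancies (row totals) `r_a`, `r_b` and `s`
#' shared lakes, the C-score is `(r_a - s) * (r_b - s)`: the number of
#' checkerboard units the pair forms. Larger values mean stronger
#' segregation; identical distributions score 0.
#'
#' @param matrix an [incidence_matrix()].
#' @param a,b species ids (rownames); must be distinct and present.
#' @return Non-negative integer-valued scalar.
#' @examples
#' m <- incidence_matrix(rbind(a = c(1, 1, 1, 0), b = c(0, 0, 1, 1)), "w")
#' pair_c_score(m, "a", "b") # (3-1)*(2-1) = 2
#' @export
pair_c_score <- function(matrix, a, b) {
  if (identical(a, b)) stop("'a' and 'b' must be distinct species")
  unknown <- setdiff(c(a, b), rownames(matrix))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown species id: %s", paste(unknown, collapse = ", ")))
  }
  ra <- sum(matrix[a, ])
  rb <- sum(matrix[b, ])
  s <- sum(matrix[a, ] * matrix[b, ])
  (ra - s) * (rb - s)
}

# All-pairs C-score matrix; [i, j] is the C-score of rows i and j.
pair_cscore_matrix <- function(m) {
  s <- tcrossprod(m)
  r <- matrix(rowSums(m), nrow(m), nrow(m))
  (r - s) * (t(r) - s)
}

# Unordered pair index in the order used throughout (and by the C++ chain):
# column-major upper triangle (1,2),(1,3),(2,3),(1,4),...
pair_index <- function(n) {
  which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
}

#' One curveball trade
#'
#' Applies a single trade of the curveball Markov chain: two distinct rows
#' are picked uniformly at random, the columns held by exactly one of them
#' are pooled, and the pool is re-partitioned uniformly at random with each
#' row keeping its number of exclusive columns. Row and column totals are
#' invariant; the chain's stationary distribution is uniform over all binary
#' matrices with the observed marginals (the fixed-fixed null).
#'
#' @param matrix an [incidence_matrix()] (any binary matrix with >= 2 rows).
#' @return The matrix after one trade, attributes preserved. Uses R's RNG:
#'   seed with [set.seed()].
#' @export
curveball_trade <- function(matrix) {
  if (nrow(matrix) < 2L) stop("curveball trade needs a matrix with >= 2 rows")
  out <- curveball_steps_cpp(unclass(matrix), 1L)
  attributes(out) <- attributes(matrix)
  out
}

#' Sample the fixed-fixed null ensemble
#'
#' Runs the curveball chain from the observed matrix and records
#' `n_samples` states: `burn_in` trades first, then one state every `thin`
#' trades. Every sample has exactly the observed row and column totals.
#'
#' @param matrix an [incidence_matrix()].
#' @param n_samples number of null matrices (>= 2, or the null SD is
#'   undefined).
#' @param burn_in,thin trades before the first sample / between samples.
#' @return Integer array `(species x lakes x n_samples)` with species and
#'   lake dimnames. Deterministic given [set.seed()].
#' @export
sample_null <- function(matrix, n_samples = 999L, burn_in = 1000L, thin = 100L) {
  if (nrow(matrix) < 2L) stop("null sampling needs a matrix with >= 2 rows")
  if (n_samples < 2L) stop("'n_samples' must be >= 2 (null SD undefined otherwise)")
  if (burn_in < 0L || thin < 1L) stop("'burn_in' must be >= 0 and 'thin' >= 1")
  out <- curveball_sample_cpp(unclass(matrix), as.integer(n_samples),
                              as.integer(burn_in), as.integer(thin))
  dimnames(out) <- list(rownames(matrix), colnames(matrix), NULL)
  out
}

#' Standardized effect sizes for all species pairs in one watershed
#'
#' For every unordered species pair: the observed C-score, the mean and
#' sample (n - 1) standard deviation of its C-score over `n_samples`
#' curveball null matrices, and the standardized effect size
#' `SES = (C_obs - C_exp) / SD_exp`. Positive SES means the pair co-occurs
#' less than expected (segregation), negative SES aggregation. Pairs whose
#' null C-score distribution has zero spread are flagged `degenerate` and
#' carry `ses = NA`: an uninformative null supports no effect size.
#'
#' The observed matrix is not included among the null samples; set
#' `include_observed = TRUE` to append it to the ensemble.
#'
#' @inheritParams sample_null
#' @param include_observed count the observed matrix as one more null draw?
#' @return data.frame with one row per pair: `watershed_id, species_a,
#'   species_b` (pair in lexicographic order), `c_obs, null_mean, null_sd,
#'   ses, degenerate`. Deterministic given [set.seed()].
#' @export
watershed_pair_ses <- function(matrix, n_samples = 999L, burn_in = 1000L,
                               thin = 100L, include_observed = FALSE) {
  if (nrow(matrix) < 2L) stop("need >= 2 species for pairwise SES")
  if (n_samples < 2L) stop("'n_samples' must be >= 2 (null SD undefined otherwise)")
  sp <- rownames(matrix)
  idx <- pair_index(nrow(matrix))
  c_obs <- pair_cscore_matrix(unclass(matrix))[idx]
  null_c <- curveball_pair_cscores_cpp(unclass(matrix), as.integer(n_samples),
                                       as.integer(burn_in), as.integer(thin))
  if (include_observed) null_c <- cbind(null_c, c_obs)
  n <- ncol(null_c)
  null_mean <- rowMeans(null_c)
  null_sd <- sqrt(rowSums((null_c - null_mean)^2) / (n - 1))
  degenerate <- null_sd == 0
  ses <- ifelse(degenerate, NA_real_, (c_obs - null_mean) / null_sd)
  a <- sp[idx[, 1L]]
  b <- sp[idx[, 2L]]
  data.frame(
    watershed_id = watershed_id(matrix),
    species_a = pmin(a, b),
    species_b = pmax(a, b),
    c_obs = c_obs,
    null_mean = null_mean,
    null_sd = null_sd,
    ses = ses,
    degenerate = degenerate,
    stringsAsFactors = FALSE
  )
}

#' Pool pairwise SES across watersheds
#'
#' The overall co-occurrence value of a species pair is the arithmetic mean
#' of its defined SES values over the watersheds where both species occur.
#' Degenerate records (zero null spread) contribute to neither the mean nor
#' the watershed count; a pair with only degenerate records is dropped with
#' a warning.
#'
#' @param records row-bound output of [watershed_pair_ses()] over >= 1
#'   watershed.
#' @return data.frame `species_a, species_b, mean_ses, n_watersheds`, one
#'   row per pair with at least one defined SES, pairs sorted
#'   lexicographically.
#' @export
pool_mean_ses <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0L,
            all(c("species_a", "species_b", "ses", "degenerate") %in% names(records)))
  key <- paste(records$species_a, records$species_b, sep = "\r")
  ok <- !records$degenerate & !is.na(records$ses)
  dropped <- setdiff(unique(key[!ok]), unique(key[ok]))
  if (length(dropped) > 0L) {
    warning(sprintf("dropping %d pair(s) with only degenerate SES records: %s",
                    length(dropped),
                    paste(gsub("\r", "/", dropped), collapse = ", ")))
  }
  if (!any(ok)) stop("no pair has a defined SES in any watershed")
  agg <- aggregate(list(mean_ses = records$ses[ok]),
                   by = list(key = key[ok]), FUN = mean)
  cnt <- as.data.frame(table(key = key[ok]), stringsAsFactors = FALSE)
  agg <- merge(agg, cnt, by = "key")
  parts <- strsplit(agg$key, "\r", fixed = TRUE)
  out <- data.frame(
    species_a = vapply(parts, `[[`, character(1L), 1L),
    species_b = vapply(parts, `[[`, character(1L), 2L),
    mean_ses = agg$mean_ses,
    n_watersheds = as.integer(agg$Freq),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$species_a, out$species_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
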