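# Shared fixture builders and independent oracles. Oracles here are brute
# force on purpose: they must not share code with the implementation paths
# they check.

make_im <- function(m, id = "ws_test") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("sp%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("lk%02d", seq_len(ncol(m)))
  incidence_matrix(m, id)
}

# random binary matrix guaranteed no all-zero species row
random_im <- function(n_sp, n_lk, p = 0.5, id = "ws_rand") {
  m <- matrix(rbinom(n_sp * n_lk, 1L, p), n_sp, n_lk)
  m[rowSums(m) == 0L, sample.int(n_lk, 1L)] <- 1L
  make_im(m, id)
}

make_traits <- function(n = 6L, genus_size = 2L, seed = 42L) {
  set.seed(seed)
  data.frame(
    species_id = sprintf("sp%02d", seq_len(n)),
    genus = sprintf("genus%02d", ceiling(seq_len(n) / genus_size)),
    body_size = round(rlnorm(n, log(25), 0.7), 1),
    temp_pref = round(rnorm(n, 18, 5), 1),
    trophic_level = round(runif(n, 2, 4.5), 2),
    temp_pref_missing = FALSE,
    stringsAsFactors = FALSE
  )
}

write_traits_csv <- function(traits, path) {
  write.csv(traits[c("species_id", "genus", "body_size", "temp_pref", "trophic_level")],
            path, row.names = FALSE, quote = FALSE)
  path
}

# brute-force C-score: count shared lakes by explicit loop
bf_c_score <- function(m, a, b) {
  shared <- 0L
  for (l in seq_len(ncol(m))) {
    if (m[a, l] == 1L && m[b, l] == 1L) shared <- shared + 1L
  }
  (sum(m[a, ]) - shared) * (sum(m[b, ]) - shared)
}

# enumerate every binary matrix with the row and column sums of m
enumerate_fixed_marginal <- function(m) {
  rs <- rowSums(m)
  cs <- colSums(m)
  nc <- ncol(m)
  row_options <- lapply(rs, function(k) {
    combs <- combn(nc, k)
    lapply(seq_len(ncol(combs)), function(j) {
      v <- integer(nc)
      v[combs[, j]] <- 1L
      v
    })
  })
  out <- list()
  rec <- function(i, rows, colleft) {
    if (i > length(rs)) {
      if (all(colleft == 0L)) out[[length(out) + 1L]] <<- do.call(rbind, rows)
      return(invisible())
    }
    for (v in row_options[[i]]) {
      nxt <- colleft - v
      if (all(nxt >= 0L)) rec(i + 1L, c(rows, list(v)), nxt)
    }
  }
  rec(1L, list(), cs)
  out
}

# encode a small binary matrix (< 31 cells) as a single number
encode_mat <- function(m) sum(as.vector(m) * 2^(seq_along(m) - 1))

# all permutations of 1:n (n small)
perms_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms_all(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# normal-equations OLS oracle
ne_coefs <- function(X, y) drop(solve(crossprod(X), crossprod(X, y)))

# design table with known structure for regression tests
make_design <- function(n = 50L, seed = 99L) {
  set.seed(seed)
  d_body <- runif(n, 0, 3)
  d_trophic <- runif(n, 0, 3)
  data.frame(
    species_a = sprintf("a%03d", seq_len(n)),
    species_b = sprintf("b%03d", seq_len(n)),
    mean_ses = rnorm(n),
    d_body = d_body, d_body_sq = d_body^2,
    d_temp = runif(n, 0, 3),
    d_trophic = d_trophic, d_trophic_sq = d_trophic^2,
    stringsAsFactors = FALSE
  )
}

# full pipeline on an in-memory synthetic survey, with per-watershed seeding
run_survey_pipeline <- function(cfg, seed, n_null, n_perm, models = NULL) {
  s <- suppressWarnings(simulate_survey(cfg, seed = seed))
  pair_ses <- do.call(rbind, lapply(names(s$matrices), function(id) {
    set.seed(watershed_seed(seed, id))
    watershed_pair_ses(s$matrices[[id]], n_samples = n_null)
  }))
  pooled <- suppressWarnings(pool_mean_ses(pair_ses))
  z <- zscore_traits(s$traits_complete,
                     species = sort(unique(c(pooled$species_a, pooled$species_b))))
  design <- build_design_table(pooled, z)
  if (is.null(models)) {
    reports <- run_hypotheses(design, n_perm = n_perm, seed = seed)
  } else {
    reports <- lapply(models, function(mid)
      cooc_lm(design, model = mid, n_perm = n_perm, seed = seed))
    names(reports) <- models
  }
  list(survey = s, pair_ses = pair_ses, pooled = pooled, design = design,
       reports = reports)
}

term_row <- function(report, term) {
  report$coef_table[report$coef_table$term == term, , drop = FALSE]
}
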