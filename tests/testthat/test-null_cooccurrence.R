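test_that("pair C-score matches its definition and a brute-force counter", {
  m <- make_im(rbind(c(1, 1, 1, 0, 0), c(0, 0, 1, 1, 0)))
  expect_equal(pair_c_score(m, "sp01", "sp02"), 2) # (3-1)*(2-1)
  m2 <- make_im(rbind(c(1, 0, 1), c(1, 0, 1)))
  expect_equal(pair_c_score(m2, "sp01", "sp02"), 0) # identical rows
  m3 <- make_im(rbind(c(1, 1, 0, 0, 0), c(0, 0, 1, 1, 1)))
  expect_equal(pair_c_score(m3, "sp01", "sp02"), 6) # disjoint: r_a * r_b
  expect_error(pair_c_score(m, "sp01", "nope"), "unknown species")
  expect_error(pair_c_score(m, "sp01", "sp01"), "distinct")

  set.seed(301)
  for (rep in 1:200) {
    m <- random_im(sample(3:6, 1), sample(4:8, 1), runif(1, 0.2, 0.8))
    pair <- sample(rownames(m), 2)
    expect_identical(pair_c_score(m, pair[1], pair[2]),
                     bf_c_score(m, pair[1], pair[2]))
  }
})

test_that("curveball trades preserve marginals and fix unique-fill matrices", {
  # 2x2 checkerboard: only two matrices share these marginals
  m <- make_im(diag(2))
  set.seed(5)
  for (i in 1:50) {
    tr <- curveball_trade(m)
    expect_true(identical(unclass(tr), unclass(m)) ||
                  all(tr == 1 - unclass(m)))
    expect_equal(rowSums(tr), rowSums(m))
    expect_equal(colSums(tr), colSums(m))
  }
  # marginal-unique matrix is returned unchanged by any trade
  u <- make_im(rbind(c(1, 1), c(1, 0)))
  set.seed(6)
  for (i in 1:25) expect_identical(unclass(curveball_trade(u)), unclass(u))
  expect_error(curveball_trade(make_im(matrix(1, 1, 3))), ">= 2 rows")

  # conservation over a long chain on a larger random matrix
  set.seed(7)
  big <- random_im(20, 20)
  cur <- big
  for (i in 1:2000) cur <- curveball_trade(cur)
  expect_equal(rowSums(cur), rowSums(big))
  expect_equal(colSums(cur), colSums(big))
})

test_that("null sampling is deterministic, conserving, and fixes unique fills", {
  m <- random_im(10, 12, id = "wsD")
  set.seed(42)
  a1 <- sample_null(m, n_samples = 20, burn_in = 100, thin = 10)
  set.seed(42)
  a2 <- sample_null(m, n_samples = 20, burn_in = 100, thin = 10)
  expect_identical(a1, a2)
  for (k in seq_len(dim(a1)[3])) {
    expect_equal(rowSums(a1[, , k]), rowSums(m))
    expect_equal(colSums(a1[, , k]), colSums(m))
  }
  u <- make_im(rbind(c(1, 1), c(1, 0)))
  su <- sample_null(u, n_samples = 5, burn_in = 10, thin = 3)
  for (k in 1:5) expect_true(all(su[, , k] == unclass(u)))
  expect_error(sample_null(m, n_samples = 1), ">= 2")
})

test_that("curveball sampling is uniform over an enumerable fixed-marginal set", {
  # 3x3, row sums (1,1,2), col sums (1,1,2): enumerate by brute force
  m <- make_im(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 1, 1)))
  states <- enumerate_fixed_marginal(m)
  codes <- sort(vapply(states, encode_mat, numeric(1)))
  expect_gt(length(codes), 1)
  set.seed(8)
  a <- sample_null(m, n_samples = 50000, burn_in = 100, thin = 5)
  seen <- colSums(matrix(a, nrow = 9) * 2^(0:8))
  expect_true(all(seen %in% codes))
  counts <- tabulate(match(seen, codes), nbins = length(codes))
  gof <- chisq.test(counts)
  expect_gt(gof$p.value, 0.01)
})

test_that("pairwise SES agrees with an exhaustive-enumeration null", {
  set.seed(9)
  m <- random_im(4, 4, p = 0.5, id = "wsE")
  states <- enumerate_fixed_marginal(m)
  idx <- which(upper.tri(matrix(0, 4, 4)), arr.ind = TRUE)
  # exact null moments per pair over the uniform fixed-marginal set
  cs <- sapply(states, function(s) {
    apply(idx, 1, function(ij) bf_c_score(make_im(s), rownames(m)[ij[1]],
                                          rownames(m)[ij[2]]))
  })
  set.seed(10)
  n <- 999
  rec <- watershed_pair_ses(m, n_samples = n)
  for (p in seq_len(nrow(idx))) {
    x <- cs[p, ]
    mu <- mean(x); sg <- sd(x) * sqrt((length(x) - 1) / length(x))
    if (sg == 0) {
      expect_true(rec$degenerate[p])
      next
    }
    c_obs <- rec$c_obs[p]
    ses_exact <- (c_obs - mu) / sg
    mu3 <- mean((x - mu)^3); mu4 <- mean((x - mu)^4)
    var_sd <- (mu4 - sg^4) / (4 * sg^2 * n)
    cov_msd <- mu3 / (2 * sg * n)
    var_ses <- (sg^2 / n + ses_exact^2 * var_sd + 2 * ses_exact * cov_msd) / sg^2
    expect_lt(abs(rec$ses[p] - ses_exact), 3 * sqrt(max(var_ses, 1e-12)))
  }
})

test_that("SES definition, sign convention and degeneracy flags hold", {
  set.seed(12)
  m <- random_im(6, 8, id = "wsF")
  rec <- watershed_pair_ses(m, n_samples = 199)
  ok <- !rec$degenerate
  expect_equal(rec$ses[ok], (rec$c_obs[ok] - rec$null_mean[ok]) / rec$null_sd[ok])
  expect_true(all(is.na(rec$ses[!ok])))
  expect_true(all(rec$null_sd[!ok] == 0))
  # canonical pair order
  expect_true(all(rec$species_a < rec$species_b))
  # c_obs bounded by product of row totals
  r <- rowSums(m)
  expect_true(all(rec$c_obs <= r[rec$species_a] * r[rec$species_b]))

  # maximal segregation given marginals cannot have negative SES:
  # two disjoint species on 4 lakes, c_obs is the attainable maximum
  md <- make_im(rbind(c(1, 1, 0, 0), c(0, 0, 1, 1), c(1, 0, 1, 0)), "wsG")
  set.seed(13)
  recd <- watershed_pair_ses(md, n_samples = 199)
  row1 <- recd[recd$species_a == "sp01" & recd$species_b == "sp02", ]
  if (!row1$degenerate) expect_gte(row1$ses, 0)

  # determinism: identical seed, bit-identical records
  set.seed(77); r1 <- watershed_pair_ses(m, n_samples = 99)
  set.seed(77); r2 <- watershed_pair_ses(m, n_samples = 99)
  expect_identical(r1, r2)
})

test_that("pooling averages defined SES and excludes degenerate records", {
  rec <- data.frame(
    watershed_id = c("w1", "w2", "w1", "w1", "w2"),
    species_a = c("a", "a", "a", "b", "b"),
    species_b = c("b", "b", "c", "c", "c"),
    c_obs = 1, null_mean = 0, null_sd = c(1, 1, 1, 0, 1),
    ses = c(1, -1, 2.5, NA, 0.5),
    degenerate = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  pooled <- pool_mean_ses(rec)
  expect_equal(pooled$mean_ses[pooled$species_a == "a" & pooled$species_b == "b"], 0)
  expect_equal(pooled$n_watersheds[pooled$species_a == "a" & pooled$species_b == "b"], 2L)
  expect_equal(pooled$mean_ses[pooled$species_a == "a" & pooled$species_b == "c"], 2.5)
  expect_equal(pooled$mean_ses[pooled$species_a == "b" & pooled$species_b == "c"], 0.5)
  expect_equal(pooled$n_watersheds[pooled$species_a == "b" & pooled$species_b == "c"], 1L)

  # a pair with only degenerate records is dropped with a warning
  rec$degenerate[5] <- TRUE
  rec$ses[5] <- NA
  expect_warning(p2 <- pool_mean_ses(rec), "b/c")
  expect_false(any(p2$species_a == "b" & p2$species_b == "c"))
})

test_that("null pair statistics agree with vegan's curveball implementation", {
  skip_if_not_installed("vegan")
  set.seed(21)
  m <- random_im(8, 10, id = "wsH")
  set.seed(22)
  ours <- watershed_pair_ses(m, n_samples = 1500, burn_in = 500, thin = 20)
  nm <- vegan::nullmodel(unclass(m), "curveball")
  sims <- stats::simulate(nm, nsim = 1500, thin = 20, burnin = 500, seed = 23)
  idx <- which(upper.tri(matrix(0, nrow(m), nrow(m))), arr.ind = TRUE)
  ref <- apply(sims, 3, function(s) {
    sh <- tcrossprod(s)
    r <- matrix(rowSums(s), nrow(s), nrow(s))
    ((r - sh) * (t(r) - sh))[idx]
  })
  ref_mean <- rowMeans(ref)
  ref_sd <- apply(ref, 1, sd)
  # both estimate the same null mean: difference within combined MC error
  tol <- 3 * sqrt(ref_sd^2 / 1500 + ours$null_sd^2 / 1500) + 1e-9
  expect_true(all(abs(ours$null_mean - ref_mean) <= tol))
})
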