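test_that("OLS fit recovers exact linear structure and matches normal equations", {
  d <- make_design(50)
  # exact linear case: response constructed as 2*d_temp + 1
  d$mean_ses <- 2 * d$d_temp + 1
  fit <- suppressWarnings(ols_fit(d, "d_temp")) # perfect fit is the point
  expect_equal(fit$table$estimate[fit$table$term == "d_temp"], 2, tolerance = 1e-10)
  expect_equal(fit$table$estimate[fit$table$term == "(Intercept)"], 1, tolerance = 1e-10)
  expect_lt(max(abs(residuals(fit$fit))), 1e-10)

  # noise orthogonalized against the predictors has exactly zero slopes
  d2 <- make_design(60, seed = 101)
  terms <- c("d_body", "d_body_sq", "d_temp", "d_trophic", "d_trophic_sq")
  X <- cbind(1, as.matrix(d2[terms]))
  eps <- rnorm(60)
  d2$mean_ses <- eps - X %*% solve(crossprod(X), crossprod(X, eps))
  fit2 <- ols_fit(d2, terms)
  expect_lt(max(abs(fit2$table$estimate)), 1e-10)

  # normal-equations oracle on a random design
  d3 <- make_design(50, seed = 55)
  fit3 <- ols_fit(d3, terms)
  expect_equal(unname(coef(fit3$fit)), unname(ne_coefs(X = cbind(1, as.matrix(d3[terms])),
                                                       y = d3$mean_ses)),
               tolerance = 1e-10)

  # rank deficiency is an error naming the collinear term
  d4 <- make_design(40)
  d4$d_body_sq <- 2 * d4$d_body
  expect_error(ols_fit(d4, c("d_body", "d_body_sq")), "d_body_sq")
  expect_error(ols_fit(make_design(4), terms), "pairs")
})

test_that("sampled permutation p matches the exhaustive permutation oracle", {
  set.seed(61)
  n <- 4L
  d <- make_design(n, seed = 61)
  d$mean_ses <- rnorm(n)
  terms <- c("d_temp")
  X <- cbind(1, as.matrix(d[terms]))
  b_obs <- ne_coefs(X, d$mean_ses)[-1]
  P <- perms_all(n) # all 24 pair shuffles
  b_perm <- apply(P, 1, function(p) ne_coefs(X, d$mean_ses[p])[-1])
  p_exact <- mean(abs(b_perm) >= abs(b_obs))
  n_perm <- 10000L
  p_sampled <- permutation_test(d, terms, n_perm = n_perm, seed = 62)
  se <- sqrt(p_exact * (1 - p_exact) / n_perm)
  expect_lt(abs(p_sampled[["d_temp"]] - p_exact), 3 * se + 2 / (n_perm + 1))
})

test_that("permutation p handles degenerate and scaled responses, deterministically", {
  d <- make_design(30, seed = 71)
  terms <- c("d_body", "d_temp")
  # constant response: every permuted slope equals the observed zero slope
  dc <- d
  dc$mean_ses <- rep(1.5, 30)
  expect_equal(unname(suppressWarnings(
    permutation_test(dc, terms, n_perm = 199, seed = 1))), c(1, 1))
  # p bounded on its attainable grid
  p <- permutation_test(d, terms, n_perm = 99, seed = 2)
  expect_true(all(p >= 1 / 100 & p <= 1))
  # determinism
  expect_identical(permutation_test(d, terms, n_perm = 499, seed = 3),
                   permutation_test(d, terms, n_perm = 499, seed = 3))
  # invariant to positive rescaling of the response
  d2 <- d
  d2$mean_ses <- 3 * d$mean_ses
  expect_identical(permutation_test(d, terms, n_perm = 499, seed = 4),
                   permutation_test(d2, terms, n_perm = 499, seed = 4))
})

test_that("species-identity mode permutes labels and leaves estimates unchanged", {
  # complete pair set over 6 species: exact Mantel-style relabelling
  sp <- sprintf("s%d", 1:6)
  pairs <- t(combn(sp, 2))
  set.seed(81)
  d <- data.frame(species_a = pairs[, 1], species_b = pairs[, 2],
                  mean_ses = rnorm(15), d_temp = runif(15),
                  d_body = runif(15), d_trophic = runif(15),
                  stringsAsFactors = FALSE)
  d$d_body_sq <- d$d_body^2
  d$d_trophic_sq <- d$d_trophic^2
  f1 <- cooc_lm(d, "H3_temp", n_perm = 199, mode = "pair_shuffle", seed = 5)
  f2 <- cooc_lm(d, "H3_temp", n_perm = 199, mode = "species_identity", seed = 5)
  expect_equal(coef(f1), coef(f2)) # mode affects only p_perm
  expect_true(all(f2$coef_table$p_perm[-1] >= 1 / 200 &
                    f2$coef_table$p_perm[-1] <= 1))
  # under relabelling of a label-symmetric design, a planted strong signal
  # stays significant
  d$mean_ses <- 5 * d$d_temp + rnorm(15, sd = 0.1)
  f3 <- cooc_lm(d, "H3_temp", n_perm = 999, mode = "species_identity", seed = 6)
  expect_lt(term_row(f3, "d_temp")$p_perm, 0.05)
})

test_that("the four hypothesis models carry their defining terms", {
  d <- make_design(80, seed = 91)
  reps <- run_hypotheses(d, n_perm = 99, seed = 7)
  expect_named(reps, c("H1_full", "H2_body", "H3_temp", "H4_trophic"))
  expect_setequal(reps$H1_full$terms,
                  c("d_body", "d_body_sq", "d_temp", "d_trophic", "d_trophic_sq"))
  expect_setequal(reps$H2_body$terms, c("d_body", "d_body_sq"))
  expect_equal(reps$H3_temp$terms, "d_temp")
  expect_setequal(reps$H4_trophic$terms, c("d_trophic", "d_trophic_sq"))
  # H2 report: exactly two non-intercept rows
  expect_equal(sum(reps$H2_body$coef_table$term != "(Intercept)"), 2L)
  # rendered report has one block per model and the table-style columns
  lines <- report_render(reps)
  expect_equal(sum(grepl("^== H", lines)), 4L)
  expect_true(any(grepl("p-value randomization", lines)))
  expect_warning(empty <- report_render(list()), "no regression reports")
  expect_length(empty, 0L)
})

test_that("cooc_lm methods behave like a standard model object", {
  d <- make_design(60, seed = 111)
  d$mean_ses <- 0.5 * d$d_temp - 0.2 * d$d_trophic + rnorm(60, sd = 0.3)
  fit <- cooc_lm(d, "H1_full", n_perm = 99, seed = 8)
  expect_s3_class(fit, "cooc_lm")
  expect_length(coef(fit), 6L)
  expect_equal(length(residuals(fit)), 60L)
  expect_equal(unname(predict(fit)[1]),
               unname(sum(coef(fit) * c(1, unlist(d[1, fit$terms])))),
               tolerance = 1e-10)
  # predict fills quadratic columns from the linear ones
  nd <- data.frame(d_body = 1, d_temp = 0.5, d_trophic = 2)
  expect_equal(unname(predict(fit, nd)),
               unname(sum(coef(fit) * c(1, 1, 1, 0.5, 2, 4))), tolerance = 1e-10)
  sim <- simulate(fit, nsim = 2, seed = 9)
  expect_equal(dim(sim), c(60L, 2L))
  out <- utils::capture.output(print(summary(fit)))
  expect_true(any(grepl("R\\^2", out)))
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit, trait = "d_temp"))
})
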