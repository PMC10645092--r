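#' @rdname cooc_lm
#' @format NULL
#' @export
cooc_models <- list(
  H1_full = c("d_body", "d_body_sq", "d_temp", "d_trophic", "d_trophic_sq"),
  H2_body = c("d_body", "d_body_sq"),
  H3_temp = "d_temp",
  H4_trophic = c("d_trophic", "d_trophic_sq")
)

cooc_term_labels <- c(
  `(Intercept)` = "(intercept)",
  d_body = "body size",
  d_body_sq = "body size (QT)",
  d_temp = "temperature preference",
  d_trophic = "trophic level",
  d_trophic_sq = "trophic level (QT)"
)

#' Ordinary least-squares fit of mean SES on trait distances
#'
#' Fits `mean_ses ~ 1 + terms` by OLS and returns the per-term slope,
#' standard error, t statistic and two-sided parametric p-value. The
#' parametric p-values assume independent pairs, which pairwise distances
#' are not; they are reported for completeness, and the permutation test
#' ([permutation_test()]) is the headline inference.
#'
#' @param design design table from [build_design_table()].
#' @param terms character vector of predictor column names.
#' @return `list(fit = <lm>, table = <data.frame term/estimate/se/t/p_param>)`
#'   (intercept row included). A rank-deficient design is an error naming
#'   the collinear terms.
#' @export
ols_fit <- function(design, terms) {
  stopifnot(is.data.frame(design), "mean_ses" %in% names(design))
  missing <- setdiff(terms, names(design))
  if (length(missing) > 0L) {
    stop(sprintf("design table lacks predictor column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(design) <= length(terms) + 1L) {
    stop(sprintf("need more than %d pairs to fit %d terms plus intercept",
                 length(terms) + 1L, length(terms)))
  }
  fit <- lm(stats::reformulate(terms, response = "mean_ses"), data = design)
  cf <- coef(fit)
  if (anyNA(cf)) {
    stop(sprintf("rank-deficient design; collinear term(s): %s",
                 paste(names(cf)[is.na(cf)], collapse = ", ")))
  }
  sm <- summary(fit)$coefficients
  table <- data.frame(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    t = sm[, "t value"],
    p_param = sm[, "Pr(>|t|)"],
    stringsAsFactors = FALSE
  )
  rownames(table) <- NULL
  list(fit = fit, table = table)
}

#' Mantel-style permutation test for the trait-distance slopes
#'
#' Holds the per-pair combination of trait distances fixed and re-fits the
#' OLS model under permutations of the SES response, recording each term's
#' slope. The two-sided permutation p-value per term is
#' `(1 + #\{|slope_perm| >= |slope_obs|\}) / (n_perm + 1)`.
#'
#' Two permutation schemes are provided. `"pair_shuffle"` permutes the
#' pooled mean SES values freely over species pairs. `"species_identity"`
#' permutes the species labels and carries each pair's SES along, as in the
#' Mantel test, preserving the dependence among pairs sharing a species;
#' when the pair set is incomplete, pairs mapped onto unobserved pairs are
#' dropped from that replicate's refit.
#'
#' @inheritParams ols_fit
#' @param n_perm number of permutations (>= 1).
#' @param mode `"pair_shuffle"` (free shuffle) or `"species_identity"`
#'   (Mantel-style relabelling).
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the permutation stream is reproducible.
#' @return Named numeric vector of permutation p-values, one per requested
#'   term (the intercept is not tested).
#' @export
permutation_test <- function(design, terms, n_perm = 9999L,
                             mode = c("pair_shuffle", "species_identity"),
                             seed = NULL) {
  mode <- match.arg(mode)
  if (n_perm < 1L) stop("'n_perm' must be >= 1")
  obs <- ols_fit(design, terms)
  if (!is.null(seed)) set.seed(seed)
  X <- model.matrix(obs$fit)
  QR <- obs$fit$qr
  y <- design$mean_ses
  n <- length(y)
  b_obs <- coef(obs$fit)[terms]
  exceed <- setNames(numeric(length(terms)), terms)

  if (mode == "pair_shuffle") {
    block <- 500L
    done <- 0L
    while (done < n_perm) {
      k <- min(block, n_perm - done)
      idx <- vapply(seq_len(k), function(i) sample.int(n), integer(n))
      B <- qr.coef(QR, matrix(y[idx], n, k))[terms, , drop = FALSE]
      exceed <- exceed + rowSums(abs(B) >= abs(b_obs))
      done <- done + k
    }
  } else {
    species <- sort(unique(c(design$species_a, design$species_b)))
    nsp <- length(species)
    smat <- matrix(NA_real_, nsp, nsp, dimnames = list(species, species))
    ia <- match(design$species_a, species)
    ib <- match(design$species_b, species)
    smat[cbind(ia, ib)] <- y
    smat[cbind(ib, ia)] <- y
    complete <- !anyNA(smat[upper.tri(smat)])
    for (p in seq_len(n_perm)) {
      sig <- sample.int(nsp)
      yp <- smat[cbind(sig[ia], sig[ib])]
      ok <- !is.na(yp)
      if (complete || all(ok)) {
        B <- qr.coef(QR, yp)[terms]
      } else if (sum(ok) > length(terms) + 1L) {
        fit_p <- stats::lm.fit(X[ok, , drop = FALSE], yp[ok])
        B <- fit_p$coefficients[terms]
      } else {
        B <- rep(NA_real_, length(terms))
      }
      exceed <- exceed + (is.na(B) | abs(B) >= abs(b_obs))
    }
  }
  (1 + exceed) / (n_perm + 1)
}

#' Fit a co-occurrence-on-trait-distance model
#'
#' The central model of the package: OLS regression of pooled pairwise
#' co-occurrence SES on per-trait distances, with Mantel-style permutation
#' inference on every slope. Four named hypothesis models are built in,
#' mirroring the trait hypotheses (`cooc_models` holds the term sets):
#'
#' * `H1_full` — all traits: body size and trophic level with quadratic
#'   terms, plus temperature preference.
#' * `H2_body` — body size, linear + quadratic (competition vs predation).
#' * `H3_temp` — temperature preference, linear (environmental filtering).
#' * `H4_trophic` — trophic level, linear + quadratic (competition vs
#'   predation).
#'
#' @inheritParams permutation_test
#' @param model one of `names(cooc_models)`, ignored when `terms` is given.
#' @param terms optional custom set of predictor columns.
#' @return An object of class `"cooc_lm"`: the inner `lm` fit plus a
#'   coefficient table with columns `term, label, estimate, se, t, p_param,
#'   p_perm`. Methods: `print`, `summary`, `coef`, `predict`, `residuals`,
#'   `simulate`, `plot`.
#' @examples
#' set.seed(1)
#' d <- data.frame(
#'   species_a = "a", species_b = "b",
#'   mean_ses = rnorm(60), d_temp = runif(60),
#'   d_body = runif(60), d_trophic = runif(60)
#' )
#' d$d_body_sq <- d$d_body^2
#' d$d_trophic_sq <- d$d_trophic^2
#' fit <- cooc_lm(d, "H3_temp", n_perm = 99, seed = 1)
#' coef(fit)
#' @export
cooc_lm <- function(design, model = names(cooc_models), terms = NULL,
                    n_perm = 9999L, mode = c("pair_shuffle", "species_identity"),
                    seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(terms)) {
    model <- match.arg(model)
    terms <- cooc_models[[model]]
  } else {
    model <- "custom"
  }
  obs <- ols_fit(design, terms)
  p_perm <- permutation_test(design, terms, n_perm = n_perm, mode = mode,
                             seed = seed)
  table <- obs$table
  table$p_perm <- c(NA_real_, p_perm[table$term[-1L]])
  labels <- cooc_term_labels[table$term]
  table$label <- ifelse(is.na(labels), table$term, labels)
  table <- table[c("term", "label", "estimate", "se", "t", "p_param", "p_perm")]
  structure(
    list(model_id = model, terms = terms, fit = obs$fit, coef_table = table,
         n_perm = as.integer(n_perm), n_pairs = nrow(design), mode = mode,
         seed = seed, call = match.call()),
    class = "cooc_lm"
  )
}

#' @export
print.cooc_lm <- function(x, digits = 3L, ...) {
  cat(sprintf("Co-occurrence ~ trait-distance model '%s' (%d pairs)\n",
              x$model_id, x$n_pairs))
  cat(sprintf("Permutation test: %d permutations, mode '%s'\n\n",
              x$n_perm, x$mode))
  tab <- x$coef_table[x$coef_table$term != "(Intercept)", , drop = FALSE]
  print(format_report_table(tab, digits = digits), row.names = FALSE)
  invisible(x)
}

format_report_table <- function(tab, digits = 3L) {
  data.frame(
    term = tab$label,
    `estimate slope` = signif(tab$estimate, digits),
    `standard error` = signif(tab$se, digits),
    `t-value` = signif(tab$t, digits),
    `p-value regression` = signif(tab$p_param, digits),
    `p-value randomization` = signif(tab$p_perm, digits),
    check.names = FALSE
  )
}

#' @export
summary.cooc_lm <- function(object, ...) {
  structure(
    list(model_id = object$model_id, coef_table = object$coef_table,
         n_pairs = object$n_pairs, n_perm = object$n_perm, mode = object$mode,
         r_squared = summary(object$fit)$r.squared,
         adj_r_squared = summary(object$fit)$adj.r.squared,
         sigma = summary(object$fit)$sigma),
    class = "summary.cooc_lm"
  )
}

#' @export
print.summary.cooc_lm <- function(x, digits = 3L, ...) {
  cat(sprintf("Model '%s': %d species pairs, R^2 = %.3f (adj. %.3f), residual SD %.3f\n\n",
              x$model_id, x$n_pairs, x$r_squared, x$adj_r_squared, x$sigma))
  print(format_report_table(x$coef_table, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
coef.cooc_lm <- function(object, ...) coef(object$fit)

#' @export
predict.cooc_lm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::predict(object$fit, ...))
  needed <- setdiff(object$terms, names(newdata))
  if ("d_body_sq" %in% needed && "d_body" %in% names(newdata)) {
    newdata$d_body_sq <- newdata$d_body^2
  }
  if ("d_trophic_sq" %in% needed && "d_trophic" %in% names(newdata)) {
    newdata$d_trophic_sq <- newdata$d_trophic^2
  }
  stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.cooc_lm <- function(object, ...) stats::residuals(object$fit, ...)

#' @export
simulate.cooc_lm <- function(object, nsim = 1L, seed = NULL, ...) {
  stats::simulate(object$fit, nsim = nsim, seed = seed, ...)
}

#' Plot SES against one trait distance with the fitted trend
#'
#' Scatter of pooled mean SES against one of the model's distance terms,
#' with the model-implied trend (other predictors held at their means)
#' overlaid, in the style of single-trait regression trend plots.
#'
#' @param x a `cooc_lm`.
#' @param trait distance column to put on the x axis; defaults to the
#'   model's first term.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.cooc_lm <- function(x, trait = NULL, ...) {
  design <- x$fit$model
  if (is.null(trait)) trait <- x$terms[1L]
  stopifnot(trait %in% x$terms)
  xs <- design[[trait]]
  plot(xs, design$mean_ses,
       xlab = sprintf("%s distance (z-score units)",
                      cooc_term_labels[[trait]]),
       ylab = "mean SES", pch = 16, cex = 0.5,
       col = "grey40", ...)
  grid_x <- seq(min(xs), max(xs), length.out = 100L)
  nd <- as.data.frame(lapply(design[x$terms], function(col) rep(mean(col), 100L)))
  nd[[trait]] <- grid_x
  sq <- paste0(trait, "_sq")
  if (sq %in% x$terms) nd[[sq]] <- grid_x^2
  graphics::lines(grid_x, stats::predict(x$fit, newdata = nd), lwd = 2)
  invisible(x)
}

#' Fit the four trait hypothesis models
#'
#' Runs [cooc_lm()] for `H1_full`, `H2_body`, `H3_temp` and `H4_trophic` on
#' one design table, with per-model permutation seeds derived from `seed`.
#'
#' @inheritParams cooc_lm
#' @return Named list of `cooc_lm` objects, class `"cooc_hypotheses"`, with
#'   a print method rendering the combined report.
#' @export
run_hypotheses <- function(design, n_perm = 9999L,
                           mode = c("pair_shuffle", "species_identity"),
                           seed = NULL) {
  mode <- match.arg(mode)
  ids <- names(cooc_models)
  out <- lapply(seq_along(ids), function(i) {
    cooc_lm(design, model = ids[i], n_perm = n_perm, mode = mode,
            seed = if (is.null(seed)) NULL else seed + i)
  })
  names(out) <- ids
  class(out) <- "cooc_hypotheses"
  out
}

#' @export
print.cooc_hypotheses <- function(x, ...) {
  cat(report_render(x), sep = "\n")
  invisible(x)
}

#' Render regression reports as a fixed-width table
#'
#' One block per model with columns `term, estimate slope, standard error,
#' t-value, p-value regression, p-value randomization` (intercept omitted).
#'
#' @param reports a `cooc_hypotheses` list, a list of `cooc_lm` objects, or
#'   a single `cooc_lm`.
#' @return Character vector of report lines.
#' @export
report_render <- function(reports) {
  if (inherits(reports, "cooc_lm")) reports <- list(reports)
  if (length(reports) == 0L) {
    warning("no regression reports to render")
    return(character(0L))
  }
  unlist(lapply(reports, function(r) {
    tab <- r$coef_table[r$coef_table$term != "(Intercept)", , drop = FALSE]
    c(sprintf("== %s (%d pairs, %d permutations, %s) ==",
              r$model_id, r$n_pairs, r$n_perm, r$mode),
      utils::capture.output(print(format_report_table(tab), row.names = FALSE)),
      "")
  }), use.names = FALSE)
}

# Flat data.frame of all reported terms, for CSV/JSON export.
report_table <- function(reports) {
  if (inherits(reports, "cooc_lm")) reports <- list(reports)
  do.call(rbind, lapply(reports, function(r) {
    tab <- r$coef_table[r$coef_table$term != "(Intercept)", , drop = FALSE]
    cbind(data.frame(model_id = r$model_id, stringsAsFactors = FALSE),
          tab, n_perm = r$n_perm, n_pairs = r$n_pairs)
  }))
}
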