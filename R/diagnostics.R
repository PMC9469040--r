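#' Per-triad accuracy table for the nonadditivity regression
#'
#' Aggregates responses per unique triad and computes the fraction of correct
#' judgments (a response is correct when the test with the larger perceived
#' difference from the standard was chosen). Triads without a well-posed
#' judgment are excluded: those whose two perceived differences are equal
#' (no correct answer) and those containing a zero difference (one test
#' coincides perceptually with the standard, making the judgment trivial).
#'
#' @inheritParams response_prob
#' @return data frame with one row per retained triad: `standard`, `test1`,
#'   `test2`, `abs_delta` (`|d1 - d2|`), `dbar` (`(d1 + d2)/2`), `n`, `acc`.
#' @export
accuracy_table <- function(responses, psi = NULL) {
  agg <- aggregate_triads(responses, psi)
  tol <- 1e-9 * max(1, agg$d1, agg$d2)
  keep <- abs(agg$d1 - agg$d2) > tol & agg$d1 > tol & agg$d2 > tol
  agg <- agg[keep, , drop = FALSE]
  if (nrow(agg) == 0L) {
    stop("no triad has distinct nonzero perceived differences; ",
         "accuracy is undefined")
  }
  correct <- ifelse(agg$d1 > agg$d2, agg$successes, agg$n - agg$successes)
  out <- data.frame(
    standard = agg$standard, test1 = agg$test1, test2 = agg$test2,
    abs_delta = abs(agg$d1 - agg$d2), dbar = (agg$d1 + agg$d2) / 2,
    n = agg$n, acc = correct / agg$n
  )
  rownames(out) <- NULL
  out
}

#' Regression test for nonadditivity of perceived differences
#'
#' If differences are additive, triad accuracy should depend only on the
#' difference of differences `|delta d|`, not on the average difference
#' `dbar`. This fits the ordinary least-squares regression
#' `acc ~ beta0 + beta1 |delta d| + beta2 dbar` and applies a two-sided
#' t-test to `beta2`. A significantly negative `beta2` indicates diminishing
#' returns (a concave scaling function), a significantly positive one
#' increasing returns (convex); otherwise additivity is not rejected.
#'
#' @param rows an accuracy table from [accuracy_table()].
#' @param alpha significance level for the t-test (default 0.05).
#' @return an object of class `nonadditivity_test` with `$coefficients`
#'   (estimate, std. error, t, p per term), `$beta2`, `$p_value`, `$alpha`
#'   and `$verdict` in `"diminishing"`, `"increasing"`,
#'   `"additivity-not-rejected"`.
#' @export
nonadditivity_test <- function(rows, alpha = 0.05) {
  if (nrow(rows) < 4L) stop("at least 4 accuracy rows are required")
  for (v in c("abs_delta", "dbar")) {
    if (length(unique(rows[[v]])) < 2L) {
      stop(sprintf("predictor '%s' is constant; regression is rank-deficient", v))
    }
  }
  X <- cbind(1, rows$abs_delta, rows$dbar)
  if (qr(X)$rank < 3L) {
    stop("predictors |delta d| and dbar are collinear; regression is rank-deficient")
  }
  fit <- stats::lm(acc ~ abs_delta + dbar, data = rows)
  co <- stats::coef(summary(fit))
  rownames(co) <- c("beta0", "beta1", "beta2")
  beta2 <- co["beta2", "Estimate"]
  p <- co["beta2", "Pr(>|t|)"]
  verdict <- if (p < alpha && beta2 < 0) {
    "diminishing"
  } else if (p < alpha && beta2 > 0) {
    "increasing"
  } else {
    "additivity-not-rejected"
  }
  structure(list(coefficients = co, beta2 = beta2,
                 t_value = co["beta2", "t value"], p_value = p,
                 alpha = alpha, verdict = verdict, model = fit),
            class = "nonadditivity_test")
}

#' @export
print.nonadditivity_test <- function(x, ...) {
  cat("Nonadditivity regression: acc ~ |delta d| + dbar\n")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("Verdict at alpha = %g: %s (beta2 = %.4g, p = %.4g)\n",
              x$alpha, x$verdict, x$beta2, x$p_value))
  invisible(x)
}

# normalize a function (or scaling_function) onto the unit square
unit_square <- function(f, grid) {
  fe <- if (inherits(f, "scaling_function")) as.function(f) else f
  dom <- attr(fe, "domain")
  if (is.null(dom)) dom <- attr(f, "domain")
  if (is.null(dom)) dom <- c(0, 1)
  y <- fe(dom[1L] + grid * (dom[2L] - dom[1L]))
  rng <- range(y)
  if (diff(rng) <= 0) stop("cannot normalize a constant function")
  (y - rng[1L]) / diff(rng)
}

#' RMSE between a fitted and a true scaling function
#'
#' Both functions are rescaled so that domain and range map onto `[0, 1]`,
#' evaluated at 1000 equidistant points, and the root mean squared difference
#' is returned. The normalization makes the measure invariant to affine
#' rescaling of either function's input or output units, so it compares
#' shapes only.
#'
#' @param f_true,f_hat functions or [scaling_function()] objects; plain
#'   functions may carry a `"domain"` attribute (default `[0, 1]`).
#' @return nonnegative RMSE.
#' @examples
#' rmse_to_truth(function(x) x, function(x) x^2) # ~ sqrt(1/30)
#' @export
rmse_to_truth <- function(f_true, f_hat) {
  grid <- seq(0, 1, length.out = 1000L)
  a <- unit_square(f_true, grid)
  b <- unit_square(f_hat, grid)
  sqrt(mean((a - b)^2))
}

#' Accuracy of a fitted model in predicting responses
#'
#' Fraction of responses for which the model's predicted choice
#' (`p > 0.5` predicts `R = 1`, `p < 0.5` predicts `R = 0`) matches the
#' observed response; triads with `p` exactly 0.5 receive half credit, which
#' keeps the chance baseline at exactly 0.5.
#'
#' @inheritParams response_prob
#' @return accuracy in `[0, 1]`.
#' @export
prediction_accuracy <- function(responses, psi, f, sigma) {
  agg <- aggregate_triads(responses, psi)
  fe <- if (inherits(f, "scaling_function")) as.function(f) else f
  p <- stats::pnorm((fe(agg$d1) - fe(agg$d2)) / sigma)
  tie <- abs(p - 0.5) <= 1e-12
  credit <- ifelse(tie, agg$n / 2,
                   ifelse(p > 0.5, agg$successes, agg$n - agg$successes))
  sum(credit) / sum(agg$n)
}

#' Akaike information criterion from a negative log-likelihood
#'
#' `AIC = 2 k + 2 NLL` (equivalently `2k - 2 ln L`).
#'
#' @param nll negative log-likelihood of the fitted model.
#' @param k_params number of free parameters (>= 0).
#' @return the AIC value.
#' @export
aic <- function(nll, k_params) {
  if (k_params < 0) stop("k_params must be nonnegative")
  2 * k_params + 2 * nll
}

#' k-fold cross-validated prediction accuracy
#'
#' Splits the response records into `k_folds` folds stratified by triad
#' (each triad's responses are spread across folds, so every triad appears
#' in every training set), refits the difference-scaling model on each
#' training set and evaluates [prediction_accuracy()] on the held-out fold.
#'
#' @inheritParams fit_difference_scaling
#' @param k_folds number of folds (>= 2).
#' @param seed seed controlling both the fold assignment and the fit
#'   restarts.
#' @return an object of class `cv_report`: `$accuracy` per fold, `$mean`,
#'   `$half_width` (t-based 95% half-width), `$k_folds`.
#' @export
kfold_cv <- function(responses, psi = NULL, k_folds = 4,
                     kind = "spline", k = 4, fix = c(sigma = 1.46),
                     restarts = 10, seed = 1L) {
  if (k_folds < 2L) stop("k_folds must be at least 2")
  n <- nrow(responses)
  if (n < k_folds) stop("fewer records than folds")
  key <- paste(responses$standard, responses$test1, responses$test2)
  old <- if (exists(".Random.seed", envir = .GlobalEnv)) {
    get(".Random.seed", envir = .GlobalEnv)
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(derive_seed(seed, 2L))
  fold <- integer(n)
  for (g in split(seq_len(n), key)) {
    fold[g] <- sample(rep_len(seq_len(k_folds), length(g)))
  }
  if (any(tabulate(fold, k_folds) == 0L)) {
    stop("a fold received zero records; reduce k_folds")
  }
  accs <- numeric(k_folds)
  for (i in seq_len(k_folds)) {
    train <- responses[fold != i, , drop = FALSE]
    test <- responses[fold == i, , drop = FALSE]
    fit <- fit_difference_scaling(train, psi = psi, kind = kind, k = k,
                                  fix = fix, restarts = restarts,
                                  seed = derive_seed(seed, 10L + i))
    accs[i] <- prediction_accuracy(test, psi, fit$f, fit$sigma)
  }
  hw <- if (k_folds > 1L) {
    stats::qt(0.975, df = k_folds - 1L) * stats::sd(accs) / sqrt(k_folds)
  } else {
    NA_real_
  }
  structure(list(accuracy = accs, mean = mean(accs), half_width = hw,
                 k_folds = k_folds),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validated accuracy: %.4f +/- %.4f (95%% CI)\n",
              x$k_folds, x$mean, x$half_width))
  cat("Per-fold:", paste(sprintf("%.4f", x$accuracy), collapse = " "), "\n")
  invisible(x)
}

#' Residual-versus-average-difference diagnostic
#'
#' For each triad, the absolute residual between the observed choice
#' frequency and the model probability is regressed on the triad's average
#' perceived difference `dbar`. A fitted model that is adequate across all
#' difference sizes should show no trend; a model that ignores diminishing
#' returns typically shows residuals growing with `dbar`.
#'
#' @inheritParams response_prob
#' @return an object of class `residual_diag`: per-triad `$table`
#'   (`dbar`, `observed`, `predicted`, `residual`), correlation `$r`,
#'   `$t_value`, `$p_value` and `$slope`.
#' @export
residual_vs_dbar <- function(responses, psi, f, sigma) {
  agg <- aggregate_triads(responses, psi)
  if (any(agg$n == 0L)) {
    warning("triads with zero responses excluded")
    agg <- agg[agg$n > 0L, , drop = FALSE]
  }
  if (nrow(agg) < 3L) stop("at least 3 triads are required")
  fe <- if (inherits(f, "scaling_function")) as.function(f) else f
  p <- stats::pnorm((fe(agg$d1) - fe(agg$d2)) / sigma)
  tab <- data.frame(
    dbar = (agg$d1 + agg$d2) / 2,
    observed = agg$successes / agg$n,
    predicted = p
  )
  tab$residual <- abs(tab$observed - tab$predicted)
  fit <- stats::lm(residual ~ dbar, data = tab)
  co <- stats::coef(summary(fit))
  structure(list(
    table = tab,
    r = stats::cor(tab$residual, tab$dbar),
    slope = co["dbar", "Estimate"],
    t_value = co["dbar", "t value"],
    p_value = co["dbar", "Pr(>|t|)"]
  ), class = "residual_diag")
}

#' @export
print.residual_diag <- function(x, ...) {
  cat(sprintf(
    "Residual vs dbar: R = %.3f, t = %.3f, p = %.4g (slope %.4g)\n",
    x$r, x$t_value, x$p_value, x$slope
  ))
  invisible(x)
}
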