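#' Construct a perceptual scale
#'
#' A perceptual scale maps a discrete set of stimulus levels to perceived
#' strengths `psi`, anchored at `psi[1] = 0` and nondecreasing.
#'
#' @param levels ascending stimulus levels.
#' @param psi perceived strengths, same length, `psi[1] = 0`, nondecreasing.
#' @return an object of class `perceptual_scale`.
#' @export
perceptual_scale <- function(levels, psi) {
  levels <- as.numeric(levels)
  psi <- as.numeric(psi)
  if (length(levels) != length(psi)) stop("levels and psi lengths differ")
  if (any(diff(levels) <= 0)) stop("levels must be strictly ascending")
  if (abs(psi[1L]) > 1e-12) stop("psi must be anchored at 0")
  psi[1L] <- 0
  if (any(diff(psi) < 0)) stop("psi must be nondecreasing")
  structure(list(levels = levels, psi = psi), class = "perceptual_scale")
}

#' @export
print.perceptual_scale <- function(x, ...) {
  cat(sprintf("Perceptual scale over %d levels (psi in [0, %g])\n",
              length(x$levels), max(x$psi)))
  print(data.frame(level = x$levels, psi = x$psi))
  invisible(x)
}

# look up perceived strengths for stimulus values (error if absent)
psi_lookup <- function(psi, values) {
  if (is.null(psi)) return(values)
  if (is.function(psi)) return(psi(values))
  stopifnot(inherits(psi, "perceptual_scale"))
  idx <- match_tol(values, psi$levels)
  if (anyNA(idx)) {
    stop("stimulus level absent from the perceptual scale: ",
         paste(unique(values[is.na(idx)]), collapse = ", "))
  }
  psi$psi[idx]
}

# Aggregate a long response table to per-triad binomial counts with
# perceived differences. The likelihood only depends on these.
aggregate_triads <- function(responses, psi = NULL) {
  if (nrow(responses) == 0L) stop("response set is empty")
  key <- paste(responses$standard, responses$test1, responses$test2)
  counts <- rowsum(cbind(successes = as.numeric(responses$response),
                         n = rep(1, nrow(responses))), group = key)
  first <- !duplicated(key)
  tri <- responses[first, c("standard", "test1", "test2"), drop = FALSE]
  m <- match(rownames(counts), key[first])
  out <- data.frame(
    standard = tri$standard[m], test1 = tri$test1[m], test2 = tri$test2[m],
    successes = counts[, "successes"], n = counts[, "n"]
  )
  ps <- psi_lookup(psi, out$standard)
  p1 <- psi_lookup(psi, out$test1)
  p2 <- psi_lookup(psi, out$test2)
  out$d1 <- abs(ps - p1)
  out$d2 <- abs(p2 - ps)
  out[order(out$standard, out$d1, out$d2), , drop = FALSE]
}

PROB_EPS <- 1e-9

#' Model probability of choosing test1, under a fitted model
#'
#' `pnorm((f(d1) - f(d2)) / sigma)` with `d1`, `d2` the perceived differences
#' of the two tests from the standard under the perceptual scale `psi`,
#' clamped to `[1e-9, 1 - 1e-9]` before any use in a log-likelihood.
#'
#' @param responses a response or design data frame with `standard`, `test1`,
#'   `test2` columns.
#' @param psi a [perceptual_scale()], a function, or `NULL` for the identity
#'   map (stimulus strengths used as perceived strengths).
#' @param f a [scaling_function()] (or plain function).
#' @param sigma positive noise standard deviation on the perceived
#'   difference-of-differences.
#' @return probability of `R = 1` per row of `responses`.
#' @export
response_prob <- function(responses, psi, f, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  ps <- psi_lookup(psi, responses$standard)
  p1 <- psi_lookup(psi, responses$test1)
  p2 <- psi_lookup(psi, responses$test2)
  fe <- if (inherits(f, "scaling_function")) as.function(f) else f
  p <- stats::pnorm((fe(abs(ps - p1)) - fe(abs(p2 - ps))) / sigma)
  pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)
}

#' Negative log-likelihood of triad responses
#'
#' `-sum log P(R | triad, f, psi, sigma)` over all response records, with the
#' Bernoulli probability from [response_prob()]. Also reports the average NLL
#' (divided by the record count), the quantity to use when comparing models
#' fitted to different numbers of trials or participants.
#'
#' @inheritParams response_prob
#' @param responses a nonempty long response table (one row per response,
#'   column `response` in \{0, 1\}).
#' @return list with `nll`, `avg_nll` and `n_records`.
#' @export
nll_responses <- function(responses, psi, f, sigma) {
  if (nrow(responses) == 0L) stop("response set is empty")
  agg <- aggregate_triads(responses, psi)
  fe <- if (inherits(f, "scaling_function")) as.function(f) else f
  nll <- nll_from_counts(agg$d1, agg$d2, agg$successes, agg$n, fe, sigma)
  list(nll = nll, avg_nll = nll / sum(agg$n), n_records = sum(agg$n))
}

# Bernoulli NLL from per-triad counts. Evaluated through the Gaussian
# log-CDF so the objective keeps a usable gradient deep in the tails
# (a clamped probability would make the surface flat there); equals the
# clamped -sum(k log p + (n-k) log(1-p)) to double precision away from
# the boundary.
nll_from_counts <- function(d1, d2, successes, n, fe, sigma) {
  z <- (fe(d1) - fe(d2)) / sigma
  lp <- stats::pnorm(z, log.p = TRUE)
  lq <- stats::pnorm(-z, log.p = TRUE)
  -sum(successes * lp + (n - successes) * lq)
}

restart_inits <- function(n_par, restarts, seed) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv)) {
    get(".Random.seed", envir = .GlobalEnv)
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(derive_seed(seed, 1L))
  matrix(stats::runif(n_par * restarts), nrow = restarts)
}

# One restart = a Nelder-Mead search followed by a quasi-Newton (BFGS)
# polish. The simplex stage takes local steps only, which keeps it off the
# flat zero-function plateau of the likelihood (where the softplus transform
# saturates and gradients vanish); the polish then sharpens the optimum.
run_restarts <- function(objective, inits) {
  fits <- vector("list", nrow(inits))
  for (r in seq_len(nrow(inits))) {
    fits[[r]] <- tryCatch({
      # rerun the simplex from its own solution until it stops improving
      # (the standard guard against Nelder-Mead false convergence)
      nm <- stats::optim(inits[r, ], objective, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-8))
      for (round in 1:4) {
        nm2 <- stats::optim(nm$par, objective, method = "Nelder-Mead",
                            control = list(maxit = 2000, reltol = 1e-8))
        improved <- nm$value - nm2$value > 1e-6 * (abs(nm$value) + 1e-6)
        nm <- nm2
        if (!improved) break
      }
      qn <- tryCatch(
        stats::optim(nm$par, objective, method = "BFGS",
                     control = list(maxit = 200)),
        error = function(e) nm
      )
      if (qn$value <= nm$value) qn else nm
    }, error = function(e) list(par = inits[r, ], value = Inf,
                                convergence = 99L))
  }
  values <- vapply(fits, `[[`, numeric(1), "value")
  conv <- vapply(fits, `[[`, numeric(1), "convergence")
  ok <- conv == 0 & is.finite(values)
  if (!any(ok)) {
    warning("no optimization restart converged; returning the best attempt ",
            "(flagged non-converged)")
    best <- which.min(values)
  } else {
    best <- which(ok)[which.min(values[ok])]
  }
  list(
    par = fits[[best]]$par, value = values[best],
    converged = conv[best] == 0,
    pars = do.call(rbind, lapply(fits, `[[`, "par")),
    restarts = data.frame(restart = seq_along(values), nll = values,
                          convergence = conv)
  )
}

#' Fit a difference-scaling function by maximum likelihood
#'
#' Minimizes the negative log-likelihood of the responses over the knot
#' values of a monotone scaling function (and, when the scale maximum is the
#' fixed quantity, over the free noise standard deviation). The likelihood
#' depends only on `f / sigma`, so exactly one of the two must be fixed:
#' `fix = c(sigma = ...)` (the recommended regime; the scale maximum is then
#' estimated) or `fix = c(max = ...)` (the MLDS-style convention; `sigma` is
#' then estimated). Monotonicity is enforced by optimizing unconstrained
#' reals mapped through a softplus transform to positive knot increments.
#' Multiple restarts with U(0, 1) initial values guard against local optima;
#' the best converged restart is returned.
#'
#' @inheritParams response_prob
#' @param kind `"spline"` with `k` free knot values equally spaced on the
#'   difference range (plus the anchor at 0), or `"discrete"` with one free
#'   value per distinct nonzero perceived difference in the data (`k` is then
#'   ignored).
#' @param k number of free spline parameters (knots above the anchor).
#' @param fix named length-1 numeric: `c(sigma = value)` or `c(max = value)`.
#' @param restarts number of random restarts (default 10).
#' @param seed integer seed for the restart initial values.
#' @return an object of class `diff_scaling_fit`: the fitted
#'   [scaling_function()] (`$f`), `$sigma`, `$max`, `$nll`, `$avg_nll`,
#'   per-restart diagnostics (`$restarts`), convergence and boundary flags.
#' @export
fit_difference_scaling <- function(responses, psi = NULL,
                                   kind = c("spline", "discrete"), k = 4,
                                   fix = c(sigma = 1.46), restarts = 10,
                                   seed = 1L) {
  kind <- match.arg(kind)
  if (length(fix) != 1L || !names(fix) %in% c("sigma", "max")) {
    stop("fix must be a named length-1 value: c(sigma = ...) or c(max = ...)")
  }
  if (fix <= 0) stop("the fixed value must be positive")
  if (restarts < 1L) stop("restarts must be at least 1")
  agg <- aggregate_triads(responses, psi)
  d_max <- max(agg$d1, agg$d2)
  if (d_max <= 0) stop("all perceived differences are zero; model unidentifiable")
  if (kind == "spline") {
    if (k < 2L) stop("spline fits need k >= 2 free parameters")
    knot_x <- seq(0, d_max, length.out = k + 1L)
  } else {
    dif <- sort(unique(round(c(agg$d1, agg$d2), 9)))
    dif <- dif[dif > 0]
    knot_x <- c(0, dif)
    k <- length(dif)
  }
  fix_max <- if (names(fix) == "max") unname(fix) else NULL
  fix_sigma <- if (names(fix) == "sigma") unname(fix) else NULL
  n_par <- k + if (is.null(fix_sigma)) 1L else 0L

  build <- function(par) {
    f <- params_to_function(par[seq_len(k)], knot_x, kind = kind,
                            fixed_max = fix_max)
    sigma <- if (is.null(fix_sigma)) softplus(par[k + 1L]) else fix_sigma
    list(f = f, sigma = sigma)
  }
  fe_cache <- function(f) as.function(f)
  objective <- function(par) {
    mdl <- build(par)
    nll_from_counts(agg$d1, agg$d2, agg$successes, agg$n,
                    fe_cache(mdl$f), mdl$sigma)
  }
  best <- run_restarts(objective, restart_inits(n_par, restarts, seed))
  mdl <- build(best$par)
  p_hat <- stats::pnorm((as.function(mdl$f)(agg$d1) - as.function(mdl$f)(agg$d2)) /
                          mdl$sigma)
  boundary <- any(p_hat <= PROB_EPS | p_hat >= 1 - PROB_EPS)
  if (boundary) {
    warning("fitted probabilities pinned at the clamp boundary; ",
            "the data may be degenerate (e.g. all responses identical)")
  }
  structure(list(
    f = mdl$f, sigma = mdl$sigma, max = max(mdl$f$knot_y),
    fixed = fix, kind = kind, k = k,
    nll = best$value, avg_nll = best$value / sum(agg$n),
    n_records = sum(agg$n), n_triads = nrow(agg),
    par = best$par, converged = best$converged, boundary = boundary,
    restarts = best$restarts, restart_pars = best$pars,
    knot_x = knot_x, fix_max = fix_max, seed = seed
  ), class = "diff_scaling_fit")
}

#' @export
print.diff_scaling_fit <- function(x, ...) {
  cat(sprintf(
    "Difference-scaling fit (%s, k = %d; fixed %s = %g)\n",
    x$kind, x$k, names(x$fixed), x$fixed
  ))
  cat(sprintf("  sigma = %.4g, scale max = %.4g\n", x$sigma, x$max))
  cat(sprintf("  NLL = %.4f (avg %.6f over %d responses, %d triads)\n",
              x$nll, x$avg_nll, x$n_records, x$n_triads))
  cat(sprintf("  converged: %s; restarts converged: %d/%d\n",
              x$converged, sum(x$restarts$convergence == 0),
              nrow(x$restarts)))
  invisible(x)
}

#' Fit a perceptual scale (additive difference model)
#'
#' Maximum-likelihood estimate of the perceived strength of each stimulus
#' level under the additive Thurstonian model
#' `P(R = 1) = pnorm(((psi_s - psi_t1) - (psi_t2 - psi_s)) / sigma)`,
#' the classical MLDS analysis. Identifiability is resolved by anchoring
#' `psi[1] = 0` and fixing `sigma` (default 1); the scale is monotone by
#' construction (softplus increments).
#'
#' @param responses a long response table covering at least 3 distinct
#'   stimulus levels.
#' @param sigma fixed noise standard deviation (sets the psi units).
#' @param restarts,seed multi-restart protocol as in
#'   [fit_difference_scaling()].
#' @return a [perceptual_scale()] with attributes `nll`, `avg_nll`,
#'   `converged` and `restarts`.
#' @export
fit_perceptual_scale <- function(responses, sigma = 1, restarts = 10,
                                 seed = 1L) {
  if (nrow(responses) == 0L) stop("response set is empty")
  levels <- sort(unique(c(responses$standard, responses$test1,
                          responses$test2)))
  if (length(levels) < 3L) stop("at least 3 distinct stimulus levels required")
  agg <- aggregate_triads(responses, NULL)
  is_ <- match_tol(agg$standard, levels)
  i1 <- match_tol(agg$test1, levels)
  i2 <- match_tol(agg$test2, levels)
  if (all(i1 == is_ & i2 == is_)) {
    stop("all tests coincide with the standard; scale unidentifiable")
  }
  n_par <- length(levels) - 1L
  objective <- function(par) {
    psi <- c(0, cumsum(softplus(par)))
    z <- ((psi[is_] - psi[i1]) - (psi[i2] - psi[is_])) / sigma
    -sum(agg$successes * stats::pnorm(z, log.p = TRUE) +
           (agg$n - agg$successes) * stats::pnorm(-z, log.p = TRUE))
  }
  best <- run_restarts(objective, restart_inits(n_par, restarts, seed))
  out <- perceptual_scale(levels, c(0, cumsum(softplus(best$par))))
  attr(out, "nll") <- best$value
  attr(out, "avg_nll") <- best$value / sum(agg$n)
  attr(out, "converged") <- best$converged
  attr(out, "restarts") <- best$restarts
  out
}

#' Per-restart fitted scaling functions
#'
#' Rebuilds the scaling function found by each optimization restart of a
#' [fit_difference_scaling()] result. The multi-restart protocol analyzes
#' the output across all random initializations (not only the best), so
#' stability comparisons between model-selection regimes score every
#' restart's model.
#'
#' @param fit a `diff_scaling_fit`.
#' @return list of [scaling_function()] objects, one per restart.
#' @export
restart_scalings <- function(fit) {
  stopifnot(inherits(fit, "diff_scaling_fit"))
  lapply(seq_len(nrow(fit$restart_pars)), function(r) {
    params_to_function(fit$restart_pars[r, seq_len(fit$k)], fit$knot_x,
                       kind = fit$kind, fixed_max = fit$fix_max)
  })
}
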