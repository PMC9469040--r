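#' Build a factorial method-of-triads design
#'
#' Enumerates every triad `(standard, test1, test2)` with
#' `d1 = standard - test1` and `d2 = test2 - standard` drawn from
#' `differences`, such that `d1 - d2` lies in `deltas`, for every standard.
#' Triads whose stimuli fall outside the gamut are dropped (the number dropped
#' is reported via a message). The result is deduplicated and ordered by
#' `(standard, d1, d2)`.
#'
#' The default arguments reproduce a balanced 320-triad design: standards at
#' 30, 40, 50, 60, 70; differences 0 to 30 in steps of 2.5; differences of
#' differences of +/-2.5, +/-5 and +/-10; stimulus gamut `[0, 100]`.
#'
#' @param standards numeric vector of standard stimulus strengths.
#' @param differences numeric vector of nonnegative candidate differences
#'   (sorted ascending; may include 0).
#' @param deltas numeric vector of nonzero signed differences of differences
#'   `d1 - d2` to include.
#' @param gamut length-2 numeric interval of allowed stimulus strengths.
#' @return a `data.frame` of class `triad_design` with columns `standard`,
#'   `test1`, `test2`, `d1`, `d2`, `delta_d`, `dbar`.
#' @examples
#' nrow(triad_design()) # 320
#' @export
triad_design <- function(standards = c(30, 40, 50, 60, 70),
                         differences = seq(0, 30, by = 2.5),
                         deltas = c(-10, -5, -2.5, 2.5, 5, 10),
                         gamut = c(0, 100)) {
  if (length(standards) == 0L) stop("standards must be nonempty")
  if (length(deltas) == 0L) stop("deltas must be nonempty")
  if (any(deltas == 0)) stop("deltas must be nonzero")
  if (any(differences < 0)) stop("differences must be nonnegative")
  differences <- sort(unique(differences))
  pairs <- expand.grid(d1 = differences, d2 = differences)
  keep <- !is.na(match_tol(pairs$d1 - pairs$d2, sort(unique(deltas))))
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0L) {
    warning("no (d1, d2) pair satisfies the requested differences of differences")
    out <- data.frame(standard = numeric(0), test1 = numeric(0),
                      test2 = numeric(0), d1 = numeric(0), d2 = numeric(0),
                      delta_d = numeric(0), dbar = numeric(0))
    class(out) <- c("triad_design", "data.frame")
    return(out)
  }
  out <- do.call(rbind, lapply(sort(unique(standards)), function(s) {
    data.frame(
      standard = s,
      test1 = s - pairs$d1,
      test2 = s + pairs$d2,
      d1 = pairs$d1,
      d2 = pairs$d2
    )
  }))
  tol <- 1e-9 * max(1, abs(gamut))
  in_gamut <- out$test1 >= gamut[1L] - tol & out$test2 <= gamut[2L] + tol &
    out$standard >= gamut[1L] - tol & out$standard <= gamut[2L] + tol
  n_dropped <- sum(!in_gamut)
  if (n_dropped > 0L) {
    message(sprintf("%d triads outside the gamut [%g, %g] were excluded",
                    n_dropped, gamut[1L], gamut[2L]))
  }
  out <- out[in_gamut, , drop = FALSE]
  out <- unique(out)
  out <- out[order(out$standard, out$d1, out$d2), , drop = FALSE]
  if (nrow(out) == 0L) warning("the design contains no triads")
  out$delta_d <- out$d1 - out$d2
  out$dbar <- (out$d1 + out$d2) / 2
  rownames(out) <- NULL
  class(out) <- c("triad_design", "data.frame")
  out
}

#' All triads from a set of stimulus levels
#'
#' Enumerates every 3-subset of `levels` as a triad `(test1, standard,
#' test2)` with `test1 < standard < test2`, the design used by
#' all-combinations method-of-triads experiments.
#'
#' @param levels numeric vector of distinct stimulus levels.
#' @return a `triad_design` data frame (one row per 3-subset).
#' @examples
#' nrow(all_triads(1:8)) # choose(8, 3) = 56
#' @export
all_triads <- function(levels) {
  levels <- sort(unique(levels))
  if (length(levels) < 3L) stop("at least 3 distinct levels are required")
  combos <- utils::combn(levels, 3L)
  out <- data.frame(
    standard = combos[2L, ],
    test1 = combos[1L, ],
    test2 = combos[3L, ]
  )
  out$d1 <- out$standard - out$test1
  out$d2 <- out$test2 - out$standard
  out$delta_d <- out$d1 - out$d2
  out$dbar <- (out$d1 + out$d2) / 2
  out <- out[order(out$standard, out$d1, out$d2), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("triad_design", "data.frame")
  out
}

#' Balance an all-combinations design by restricting standards and test range
#'
#' All-combinations designs are unbalanced in the differences they probe
#' (many more small than large differences). This filter keeps only triads
#' whose standard is among `standards` and whose tests lie at most
#' `max_steps` level positions away from the standard, the usual remedy.
#'
#' @param design a `triad_design` built from discrete levels.
#' @param levels the full ordered level set the design was built from.
#' @param standards levels allowed as the standard.
#' @param max_steps maximum number of level steps between the standard and
#'   either test.
#' @return the filtered `triad_design`.
#' @examples
#' d <- all_triads(1:10)
#' nrow(filter_triads(d, 1:10, standards = 4:7, max_steps = 3)) # 36
#' @export
filter_triads <- function(design, levels, standards, max_steps) {
  levels <- sort(unique(levels))
  idx <- function(v) {
    i <- match_tol(v, levels)
    if (anyNA(i)) stop("design contains stimuli not in `levels`")
    i
  }
  is_ <- idx(design$standard)
  i1 <- idx(design$test1)
  i2 <- idx(design$test2)
  keep <- !is.na(match_tol(design$standard, sort(unique(standards)))) &
    abs(is_ - i1) <= max_steps & abs(i2 - is_) <= max_steps
  out <- design[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Translate a just-noticeable difference into a discriminal dispersion
#'
#' The JND is the difference identified correctly with probability
#' `criterion` (0.75 by default). Under the Gaussian difference-of-differences
#' model, `d_jnd / (2 * sigma) = z_criterion`, so
#' `sigma = d_jnd / (2 * qnorm(criterion))`.
#'
#' @param d_jnd positive JND in stimulus (or perceptual) units.
#' @param criterion probability in (0.5, 1) defining the JND.
#' @return the standard deviation `sigma` of the difference-of-differences
#'   Gaussian, in the same units as `d_jnd`.
#' @examples
#' jnd_to_sigma(1.25) # ~0.9267
#' @export
jnd_to_sigma <- function(d_jnd, criterion = 0.75) {
  if (any(d_jnd <= 0)) stop("d_jnd must be positive")
  if (criterion <= 0.5 || criterion >= 1) {
    stop("criterion must lie strictly between 0.5 and 1")
  }
  d_jnd / (2 * stats::qnorm(criterion))
}

#' Discriminal-dispersion levels used by the simulation studies
#'
#' The four task-difficulty levels paired with nominal JNDs of 1.25, 2.75,
#' 4.25 and 5.75 stimulus units. These are fixed configuration constants of
#' the validation studies; note they deliberately differ from
#' [jnd_to_sigma()] applied to those JNDs (see the methods vignette).
#'
#' @return named numeric vector of standard deviations.
#' @export
sigma_dd_levels <- function() {
  c(jnd1.25 = 3.63, jnd2.75 = 8.03, jnd4.25 = 12.41, jnd5.75 = 16.79)
}

#' Ground-truth scaling-function families
#'
#' Returns one of five named monotone functions on `[0, x_max]`, scaled to
#' pass through `(0, 0)` and `(x_max, y_max)`:
#' `circle` (quarter circle, concave), `root` (square root, concave),
#' `sine` (quarter sine wave, concave), `convex` (square) and `linear`.
#'
#' @param name one of `"circle"`, `"root"`, `"sine"`, `"convex"`, `"linear"`.
#' @param x_max,y_max scale anchors; defaults give the simulation-study
#'   convention that a difference of 30 is perceived as 12 perceptual units.
#' @return a vectorized function with a `"domain"` attribute.
#' @export
true_scaling <- function(name = c("circle", "root", "sine", "convex", "linear"),
                         x_max = 30, y_max = 12) {
  name <- match.arg(name)
  base <- switch(name,
    circle = function(u) sqrt(pmax(0, 1 - (u - 1)^2)),
    root = function(u) sqrt(u),
    sine = function(u) sin(pi * u / 2),
    convex = function(u) u^2,
    linear = function(u) u
  )
  f <- function(x) y_max * base(x / x_max)
  attr(f, "domain") <- c(0, x_max)
  attr(f, "name") <- name
  f
}

#' Perceptual maps from stimulus strength to perceived strength
#'
#' @param name `"identity"`, `"root"` (concave) or `"square"` (convex).
#' @return a vectorized function of stimulus strength.
#' @export
perceptual_map <- function(name = c("identity", "root", "square")) {
  name <- match.arg(name)
  g <- switch(name,
    identity = function(s) s,
    root = function(s) sqrt(s),
    square = function(s) s^2
  )
  attr(g, "name") <- name
  g
}

# Per-triad perceived differences under a perceptual map.
psi_differences <- function(design, psi_map = NULL) {
  if (is.null(psi_map)) psi_map <- function(s) s
  list(
    d1 = abs(psi_map(design$standard) - psi_map(design$test1)),
    d2 = abs(psi_map(design$test2) - psi_map(design$standard))
  )
}

#' Analytic probability of choosing test1 as the more different test
#'
#' Under the Thurstonian difference-of-differences model the probability of
#' selecting test1 is
#' `pnorm((f(|psi_s - psi_t1|) - f(|psi_t2 - psi_s|)) / sigma)`, where `psi`
#' is the perceptual map, `f` the scaling function and `sigma` the
#' discriminal dispersion (sd of the difference-of-differences Gaussian).
#'
#' @param design a `triad_design` (or any data frame with `standard`,
#'   `test1`, `test2`).
#' @param f scaling function: a [scaling_function()] or a plain monotone
#'   function with `f(0) = 0`.
#' @param sigma positive discriminal dispersion.
#' @param psi_map perceptual map (function); identity if `NULL`.
#' @return numeric vector of probabilities in (0, 1), one per triad.
#' @examples
#' d <- data.frame(standard = 50, test1 = 40, test2 = 55)
#' choice_prob(d, true_scaling("linear"), sigma = 3.63) # pnorm(2/3.63)
#' @export
choice_prob <- function(design, f, sigma, psi_map = NULL) {
  if (sigma <= 0) stop("sigma must be positive")
  fe <- if (inherits(f, "scaling_function")) as.function(f) else f
  dd <- psi_differences(design, psi_map)
  stats::pnorm((fe(dd$d1) - fe(dd$d2)) / sigma)
}

# deterministic sub-seed derivation (keeps everything below 2^31 - 1)
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483647 + 48271 * (as.double(i) %% 40000)) %%
               2147483647)
}

#' Simulate Bernoulli method-of-triads responses
#'
#' For each triad the response `R` is Bernoulli with the analytic
#' [choice_prob()] success probability; `R = 1` means test1 was judged the
#' more different test. Draws are made in a canonical triad order (sorted by
#' standard, d1, d2), so reordering the design rows does not change the
#' simulated responses for a given seed.
#'
#' @inheritParams choice_prob
#' @param n_per_triad number of responses (replicates) per triad.
#' @param seed integer random seed; the run is fully reproducible given it.
#' @return a `data.frame` of class `mot_responses` with columns `standard`,
#'   `test1`, `test2`, `response`, `participant`.
#' @export
simulate_mot <- function(design, f, sigma, n_per_triad, psi_map = NULL,
                         seed = 1L) {
  if (n_per_triad < 1L) stop("n_per_triad must be at least 1")
  if (nrow(design) == 0L) stop("design is empty")
  p <- choice_prob(design, f, sigma, psi_map)
  ord <- order(design$standard, design$standard - design$test1,
               design$test2 - design$standard)
  old <- if (exists(".Random.seed", envir = .GlobalEnv)) {
    get(".Random.seed", envir = .GlobalEnv)
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(derive_seed(seed, 0L))
  draws <- matrix(NA_integer_, nrow = n_per_triad, ncol = nrow(design))
  for (j in seq_along(ord)) {
    t <- ord[j]
    draws[, t] <- stats::rbinom(n_per_triad, 1L, p[t])
  }
  out <- data.frame(
    standard = rep(design$standard, each = n_per_triad),
    test1 = rep(design$test1, each = n_per_triad),
    test2 = rep(design$test2, each = n_per_triad),
    response = as.integer(draws[cbind(
      rep(seq_len(n_per_triad), times = nrow(design)),
      rep(seq_len(nrow(design)), each = n_per_triad)
    )]),
    participant = rep(seq_len(n_per_triad), times = nrow(design))
  )
  class(out) <- c("mot_responses", "data.frame")
  out
}
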