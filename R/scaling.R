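#' Smooth positive transform used for monotone parameterizations
#'
#' Maps unconstrained reals to strictly positive increments (softplus,
#' `log(1 + exp(x))`), numerically stable for large `|x|`. The inverse maps
#' positive increments back to the unconstrained scale.
#'
#' @param x numeric vector of unconstrained reals.
#' @return numeric vector of positive values.
#' @keywords internal
softplus <- function(x) {
  out <- x
  small <- x < 30
  out[small] <- log1p(exp(x[small]))
  out
}

#' @rdname softplus
#' @param y numeric vector of positive values.
#' @keywords internal
inv_softplus <- function(y) {
  stopifnot(all(y > 0))
  out <- y
  small <- y < 30
  out[small] <- log(expm1(y[small]))
  out
}

#' Monotone tangents for a cubic Hermite interpolant (Fritsch-Carlson)
#'
#' Computes one tangent per knot such that the cubic Hermite interpolant
#' through `(knot_x, knot_y)` is monotone nondecreasing on every segment,
#' using the Fritsch-Carlson method: tangents are initialized from secant
#' averages (one-sided at the ends), set to zero wherever a secant is flat,
#' and rescaled onto the circle of radius 3 whenever the normalized pair
#' `(alpha, beta) = (m_i, m_{i+1}) / S_i` satisfies `alpha^2 + beta^2 > 9`.
#'
#' @param knot_x strictly ascending numeric vector (at least 2 knots).
#' @param knot_y nondecreasing numeric vector, same length as `knot_x`.
#' @return numeric vector of tangents, one per knot.
#' @examples
#' fritsch_carlson_tangents(c(0, 1, 2), c(0, 1, 2)) # c(1, 1, 1)
#' @export
fritsch_carlson_tangents <- function(knot_x, knot_y) {
  n <- length(knot_x)
  if (n < 2L) stop("at least 2 knots are required")
  if (length(knot_y) != n) stop("knot_x and knot_y must have the same length")
  if (any(diff(knot_x) <= 0)) stop("knot_x must be strictly ascending")
  if (any(diff(knot_y) < 0)) stop("knot_y must be nondecreasing")
  S <- diff(knot_y) / diff(knot_x)
  if (n == 2L) {
    m <- c(S, S)
  } else {
    m <- c(S[1L], (S[-1L] + S[-(n - 1L)]) / 2, S[n - 1L])
  }
  for (i in seq_len(n - 1L)) {
    if (S[i] == 0) {
      m[i] <- 0
      m[i + 1L] <- 0
    } else {
      alpha <- m[i] / S[i]
      beta <- m[i + 1L] / S[i]
      r2 <- alpha^2 + beta^2
      if (r2 > 9) {
        tau <- 3 / sqrt(r2)
        m[i] <- tau * alpha * S[i]
        m[i + 1L] <- tau * beta * S[i]
      }
    }
  }
  m
}

# Cubic Hermite evaluation on the segment containing each xout.
hermite_eval <- function(knot_x, knot_y, tangents, xout) {
  n <- length(knot_x)
  i <- findInterval(xout, knot_x, rightmost.closed = TRUE)
  i[i < 1L] <- 1L
  i[i >= n] <- n - 1L
  h <- knot_x[i + 1L] - knot_x[i]
  t <- (xout - knot_x[i]) / h
  h00 <- (1 + 2 * t) * (1 - t)^2
  h10 <- t * (1 - t)^2
  h01 <- t^2 * (3 - 2 * t)
  h11 <- t^2 * (t - 1)
  h00 * knot_y[i] + h10 * h * tangents[i] +
    h01 * knot_y[i + 1L] + h11 * h * tangents[i + 1L]
}

#' Construct a difference-scaling function
#'
#' A scaling function maps a (perceived-strength) difference to the perceived
#' magnitude of that difference. Two kinds are supported: a monotone cubic
#' Hermite spline through the knots (Fritsch-Carlson tangents), and a discrete
#' monotone mapping defined only at the knots (one perceived value per design
#' difference). In both cases the perceived difference of identical stimuli is
#' anchored at zero: `knot_y[1] == 0`.
#'
#' @param knot_x strictly ascending difference values, starting at 0.
#' @param knot_y nondecreasing perceived-difference values; `knot_y[1]` must
#'   be 0.
#' @param kind `"spline"` (continuous, differentiable, monotone) or
#'   `"discrete"` (exact lookup at the knots only).
#' @return an object of class `scaling_function`.
#' @seealso [eval_scaling()], [params_to_function()]
#' @export
scaling_function <- function(knot_x, knot_y, kind = c("spline", "discrete")) {
  kind <- match.arg(kind)
  knot_x <- as.numeric(knot_x)
  knot_y <- as.numeric(knot_y)
  if (length(knot_x) < 2L) stop("at least 2 knots are required")
  if (length(knot_x) != length(knot_y)) {
    stop("knot_x and knot_y must have the same length")
  }
  if (any(diff(knot_x) <= 0)) stop("knot_x must be strictly ascending")
  if (abs(knot_y[1L]) > 1e-12) stop("knot_y must be anchored at 0 (f(0) = 0)")
  knot_y[1L] <- 0
  if (any(diff(knot_y) < 0)) stop("knot_y must be nondecreasing")
  f <- list(kind = kind, knot_x = knot_x, knot_y = knot_y)
  if (kind == "spline") {
    f$tangents <- fritsch_carlson_tangents(knot_x, knot_y)
  }
  class(f) <- "scaling_function"
  f
}

#' @export
print.scaling_function <- function(x, ...) {
  cat(sprintf(
    "Difference-scaling function (%s), %d knots on [%g, %g], max %g\n",
    x$kind, length(x$knot_x), min(x$knot_x), max(x$knot_x),
    max(x$knot_y)
  ))
  print(data.frame(knot_x = x$knot_x, knot_y = x$knot_y))
  invisible(x)
}

#' Evaluate a scaling function
#'
#' Spline kind: cubic Hermite value on the containing segment; no
#' extrapolation is performed (values outside the knot span by more than a
#' 1e-9 tolerance are an error; values within the tolerance are clamped).
#' Discrete kind: exact lookup; `x` must be one of the knots.
#'
#' @param f a [scaling_function()].
#' @param x numeric vector of difference values.
#' @return perceived differences, same length as `x`.
#' @export
eval_scaling <- function(f, x) {
  stopifnot(inherits(f, "scaling_function"))
  lo <- f$knot_x[1L]
  hi <- f$knot_x[length(f$knot_x)]
  tol <- 1e-9 * max(1, abs(hi))
  if (any(x < lo - tol | x > hi + tol)) {
    stop(sprintf(
      "difference value outside the scaling function domain [%g, %g]", lo, hi
    ))
  }
  x <- pmin(pmax(x, lo), hi)
  if (f$kind == "spline") {
    hermite_eval(f$knot_x, f$knot_y, f$tangents, x)
  } else {
    idx <- match_tol(x, f$knot_x)
    if (anyNA(idx)) {
      stop("discrete scaling functions can only be evaluated at their knots")
    }
    f$knot_y[idx]
  }
}

# match with a small absolute/relative tolerance (for float design grids)
match_tol <- function(x, table, tol = 1e-8) {
  i <- findInterval(x, table + tol * pmax(1, abs(table)))
  cand <- pmin(i + 1L, length(table))
  ok1 <- abs(x - table[cand]) <= tol * pmax(1, abs(x))
  cand2 <- pmax(i, 1L)
  ok2 <- abs(x - table[cand2]) <= tol * pmax(1, abs(x))
  out <- ifelse(ok1, cand, ifelse(ok2, cand2, NA_integer_))
  as.integer(out)
}

#' Convert a scaling function to an ordinary R function
#'
#' Splines evaluate through the monotone Hermite interpolant. Discrete
#' mappings are linearly interpolated between knots, which makes them
#' evaluable on a dense grid for goodness-of-fit summaries such as
#' [rmse_to_truth()]; the likelihood itself always uses exact lookup.
#'
#' @param x a [scaling_function()].
#' @param ... unused.
#' @return a vectorized function of one argument with a `"domain"` attribute.
#' @export
as.function.scaling_function <- function(x, ...) {
  f <- x
  out <- if (f$kind == "spline") {
    function(v) eval_scaling(f, v)
  } else {
    stats::approxfun(f$knot_x, f$knot_y, rule = 2)
  }
  attr(out, "domain") <- range(f$knot_x)
  out
}

#' Map unconstrained parameters to a monotone scaling function
#'
#' The optimizer works on `k` unconstrained reals. Each is passed through a
#' softplus transform to a strictly positive increment; the cumulative sum of
#' the increments gives the knot values, anchored at `f(0) = 0`. When
#' `fixed_max` is supplied the increments are renormalized so the value at the
#' last knot equals `fixed_max` exactly (the MLDS-style convention of fixing
#' the scale maximum); otherwise the maximum is free and the noise standard
#' deviation is typically the fixed quantity.
#'
#' @param raw numeric vector of `k` unconstrained reals.
#' @param knot_x ascending knot locations starting at 0, length `k + 1`.
#' @param kind `"spline"` or `"discrete"`.
#' @param fixed_max optional positive value for the last knot.
#' @return a [scaling_function()].
#' @seealso [function_to_params()]
#' @export
params_to_function <- function(raw, knot_x, kind = "spline", fixed_max = NULL) {
  k <- length(raw)
  if (length(knot_x) != k + 1L) {
    stop("knot_x must have length(raw) + 1 entries (anchor at 0 included)")
  }
  inc <- softplus(raw)
  y <- cumsum(inc)
  if (!is.null(fixed_max)) {
    y <- y * (fixed_max / y[k])
  }
  scaling_function(knot_x, c(0, y), kind = kind)
}

#' Recover unconstrained parameters from a scaling function
#'
#' Inverse of [params_to_function()] (without `fixed_max` renormalization):
#' returns the softplus-inverse of the knot increments. Requires strictly
#' increasing knot values.
#'
#' @param f a [scaling_function()].
#' @return numeric vector of unconstrained reals.
#' @export
function_to_params <- function(f) {
  stopifnot(inherits(f, "scaling_function"))
  inc <- diff(f$knot_y)
  if (any(inc <= 0)) {
    stop("knot values must be strictly increasing to invert the transform")
  }
  inv_softplus(inc)
}

#' Serialize a scaling function to flat key-value text
#'
#' @param f a [scaling_function()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scaling <- function(f, path) {
  stopifnot(inherits(f, "scaling_function"))
  lines <- c(
    paste0("kind: ", f$kind),
    paste0("knot_x: ", paste(format(f$knot_x, digits = 17), collapse = ", ")),
    paste0("knot_y: ", paste(format(f$knot_y, digits = 17), collapse = ", "))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_scaling
#' @export
read_scaling <- function(path) {
  lines <- readLines(path)
  get_field <- function(key) {
    ln <- grep(paste0("^", key, ":"), lines, value = TRUE)
    if (length(ln) != 1L) stop(sprintf("field '%s' missing from %s", key, path))
    sub(paste0("^", key, ":\\s*"), "", ln)
  }
  parse_nums <- function(s) as.numeric(strsplit(s, ",\\s*")[[1L]])
  scaling_function(
    knot_x = parse_nums(get_field("knot_x")),
    knot_y = parse_nums(get_field("knot_y")),
    kind = get_field("kind")
  )
}
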