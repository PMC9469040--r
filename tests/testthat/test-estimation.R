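test_that("response probabilities respect chance, complement and known values", {
  tri <- data.frame(standard = 50, test1 = 40, test2 = 55)
  idf <- function(x) x
  expect_equal(response_prob(tri, NULL, idf, 3.63), pnorm(5 / 3.63),
               tolerance = 1e-9)
  sym <- data.frame(standard = 50, test1 = 44, test2 = 56)
  expect_equal(response_prob(sym, NULL, true_scaling("circle"), 2), 0.5)
  swapped <- data.frame(standard = 50, test1 = 45, test2 = 60)
  mirror <- data.frame(standard = 50, test1 = 40, test2 = 55)
  f <- true_scaling("sine")
  expect_equal(response_prob(swapped, NULL, f, 1.3) +
                 response_prob(mirror, NULL, f, 1.3), 1, tolerance = 1e-9)
  ps <- perceptual_scale(c(0, 1, 2), c(0, 1, 2))
  bad <- data.frame(standard = 5, test1 = 0, test2 = 1)
  expect_error(response_prob(bad, ps, idf, 1), "absent")
})

test_that("NLL equals brute-force summation on toy sets", {
  set.seed(5)
  f_id <- function(x) x
  for (i in 1:5) {
    n_tri <- sample(2:5, 1)
    tri <- data.frame(standard = 50, test1 = 50 - sample(1:10, n_tri),
                      test2 = 50 + sample(1:10, n_tri))
    resp <- tri[rep(seq_len(n_tri), each = 4), ]
    resp$response <- rbinom(nrow(resp), 1, 0.5)
    resp$participant <- rep(1:4, n_tri)
    for (mdl in list(list(psi = NULL, f = f_id, sigma = 3.63),
                     list(psi = sqrt, f = true_scaling("root", 10, 4),
                          sigma = 0.7))) {
      got <- nll_responses(resp, mdl$psi, mdl$f, mdl$sigma)
      psi_fun <- if (is.null(mdl$psi)) function(x) x else mdl$psi
      want <- brute_force_nll(resp, psi_fun, mdl$f, mdl$sigma)
      expect_equal(got$nll, want, tolerance = 1e-10)
      expect_equal(got$avg_nll, want / nrow(resp), tolerance = 1e-10)
    }
  }
})

test_that("symmetric triads contribute exactly log(2) per response", {
  tri <- data.frame(standard = 50, test1 = 45, test2 = 55)
  resp <- tri[rep(1, 10), ]
  resp$response <- rep(c(0L, 1L), 5)
  resp$participant <- 1:10
  got <- nll_responses(resp, NULL, function(x) x, 2)
  expect_equal(got$nll, 10 * log(2), tolerance = 1e-12)
  expect_error(nll_responses(resp[0, ], NULL, function(x) x, 2), "empty")
})

test_that("joint rescaling of f and sigma leaves the likelihood invariant", {
  d <- small_design()
  r <- simulate_mot(d, true_scaling("root"), 3.63, 20, seed = 12)
  f <- scaling_function(c(0, 10, 20), c(0, 4, 6))
  base <- nll_responses(r, NULL, f, 1.7)$nll
  for (c_scale in c(0.01, 0.5, 3, 250)) {
    fc <- scaling_function(f$knot_x, f$knot_y * c_scale)
    expect_equal(nll_responses(r, NULL, fc, 1.7 * c_scale)$nll, base,
                 tolerance = 1e-9)
  }
})

test_that("fitting recovers a linear generating function", {
  d <- triad_design()
  f_true <- true_scaling("linear")
  r <- simulate_mot(d, f_true, 3.63, 300, seed = 55)
  fit <- fit_difference_scaling(r, k = 4, fix = c(sigma = 1.46),
                                restarts = 10, seed = 5)
  expect_lte(rmse_to_truth(f_true, fit$f), 0.05)
  expect_true(fit$converged)
  expect_equal(fit$nll, min(fit$restarts$nll))
  expect_gte(fit$nll, 0)
})

test_that("fits are bitwise reproducible given a seed", {
  d <- small_design()
  r <- simulate_mot(d, true_scaling("root"), 3.63, 30, seed = 8)
  f1 <- fit_difference_scaling(r, k = 3, fix = c(sigma = 1), restarts = 3,
                               seed = 4)
  f2 <- fit_difference_scaling(r, k = 3, fix = c(sigma = 1), restarts = 3,
                               seed = 4)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$nll, f2$nll)
})

test_that("degenerate unanimous responses raise the boundary flag", {
  # one-sided design (d1 > d2 everywhere): unanimity is then attainable and
  # the likelihood pushes every probability onto the boundary
  d <- suppressMessages(triad_design(50, seq(0, 20, 5), deltas = c(5, 10)))
  r <- simulate_mot(d, function(x) x, 1e-9, 10, seed = 2)
  r$response <- 1L
  expect_warning(
    fit <- fit_difference_scaling(r, k = 3, fix = c(sigma = 0.5),
                                  restarts = 2, seed = 1),
    "boundary|degenerate"
  )
  expect_true(fit$boundary)
})

test_that("fix argument is validated and scale invariance shows in fits", {
  d <- small_design()
  r <- simulate_mot(d, true_scaling("root"), 3.63, 100, seed = 6)
  expect_error(fit_difference_scaling(r, fix = c(foo = 1)), "fix")
  expect_error(fit_difference_scaling(r, fix = c(sigma = -1)), "positive")
  # fixing sigma at c*s scales the fitted function by about c
  f1 <- fit_difference_scaling(r, k = 4, fix = c(sigma = 1), restarts = 5,
                               seed = 3)
  f2 <- fit_difference_scaling(r, k = 4, fix = c(sigma = 3), restarts = 5,
                               seed = 3)
  expect_equal(f2$max / f1$max, 3, tolerance = 0.05)
  # fixed max pins the top knot and estimates sigma instead
  f3 <- fit_difference_scaling(r, k = 4, fix = c(max = 12), restarts = 5,
                               seed = 3)
  expect_equal(f3$max, 12)
  expect_gt(f3$sigma, 0)
})

test_that("the perceptual-scale fit recovers a concave map", {
  d <- triad_design(standards = c(40, 50, 60), differences = seq(0, 20, 5),
                    deltas = c(-10, -5, 5, 10))
  r <- simulate_mot(d, function(x) x, 0.3, 300, psi_map = sqrt, seed = 9)
  ps <- fit_perceptual_scale(r, restarts = 10, seed = 2)
  resc <- function(v) (v - min(v)) / (max(v) - min(v))
  expect_lt(max(abs(resc(ps$psi) - resc(sqrt(ps$levels)))), 0.05)
  expect_true(all(diff(ps$psi) >= 0))
  expect_identical(ps$psi[1], 0)
})

test_that("the perceptual-scale fit is record-order invariant and validates input", {
  d <- small_design()
  r <- simulate_mot(d, function(x) x, 2, 20, seed = 3)
  p1 <- fit_perceptual_scale(r, restarts = 2, seed = 1)
  p2 <- fit_perceptual_scale(r[sample(nrow(r)), ], restarts = 2, seed = 1)
  expect_equal(p1$psi, p2$psi, tolerance = 1e-12)
  two <- data.frame(standard = 1, test1 = 0, test2 = 1,
                    response = c(0L, 1L), participant = 1:2)
  expect_error(fit_perceptual_scale(two), "3 distinct")
  degen <- data.frame(standard = c(1, 2, 3), test1 = c(1, 2, 3),
                      test2 = c(1, 2, 3), response = 0L, participant = 1L)
  expect_error(fit_perceptual_scale(degen), "unidentifiable")
})
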