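test_that("accuracy is counted per triad with correct sign handling", {
  tri <- data.frame(standard = 50, test1 = 40, test2 = 55) # d1 = 10 > d2 = 5
  resp <- tri[rep(1, 4), ]
  resp$response <- c(1L, 1L, 0L, 1L)
  resp$participant <- 1:4
  expect_equal(accuracy_table(resp)$acc, 0.75)
  tri2 <- data.frame(standard = 50, test1 = 45, test2 = 60) # d1 = 5 < d2 = 10
  resp2 <- tri2[rep(1, 4), ]
  resp2$response <- rep(0L, 4)
  resp2$participant <- 1:4
  expect_equal(accuracy_table(resp2)$acc, 1.0)
})

test_that("triads without a well-posed judgment are excluded", {
  d <- triad_design()
  r <- simulate_mot(d, true_scaling("linear"), 3.63, 2, seed = 1)
  tab <- accuracy_table(r)
  # 30 triads contain a zero difference and drop out of the 320
  expect_equal(nrow(tab), 290)
  expect_true(all(tab$abs_delta > 0))
  # all-symmetric data has no judgeable triad
  sym <- data.frame(standard = 50, test1 = 45, test2 = 55,
                    response = 1L, participant = 1L)
  expect_error(accuracy_table(sym), "undefined|no triad")
})

test_that("a constructed additive null gives beta2 = 0 and no rejection", {
  grid <- expand.grid(abs_delta = c(2.5, 5, 10), dbar = seq(5, 25, 2.5))
  rows <- data.frame(grid, n = 100, acc = 0.5 + 0.01 * grid$abs_delta)
  rows$standard <- 50; rows$test1 <- 0; rows$test2 <- 0
  # the noiseless fixture triggers base R's perfect-fit note; irrelevant here
  ht <- suppressWarnings(nonadditivity_test(rows))
  expect_equal(ht$beta2, 0, tolerance = 1e-12)
  expect_identical(ht$verdict, "additivity-not-rejected")
  expect_equal(ht$coefficients["beta1", "Estimate"], 0.01, tolerance = 1e-10)
})

test_that("the regression rejects degenerate predictor sets", {
  rows <- data.frame(abs_delta = 5, dbar = c(5, 10, 15, 20), acc = 0.7, n = 10)
  expect_error(nonadditivity_test(rows), "constant|rank")
  rows2 <- data.frame(abs_delta = c(2, 4, 6, 8), dbar = c(1, 2, 3, 4),
                      acc = 0.7, n = 10)
  expect_error(nonadditivity_test(rows2), "collinear")
  expect_error(nonadditivity_test(rows2[1:3, ]), "4")
})

test_that("simulated concavity drives beta2 sign and significance", {
  d <- triad_design()
  r_con <- simulate_mot(d, true_scaling("root"), 3.63, 300, seed = 77)
  ht <- nonadditivity_test(accuracy_table(r_con))
  expect_lt(ht$beta2, 0)
  expect_lt(ht$p_value, 0.05)
  expect_identical(ht$verdict, "diminishing")
  r_cvx <- simulate_mot(d, true_scaling("convex"), 3.63, 300, seed = 77)
  ht2 <- nonadditivity_test(accuracy_table(r_cvx))
  expect_identical(ht2$verdict, "increasing")
})

test_that("RMSE-to-truth normalizes to the unit square", {
  f <- true_scaling("sine")
  expect_equal(rmse_to_truth(f, f), 0)
  got <- rmse_to_truth(function(x) x, function(x) x^2)
  expect_lt(abs(got - sqrt(1 / 30)), 1e-4)
  # invariant to affine rescaling of either input's units
  f_scaled <- function(x) 7 * (x / 3)^2
  attr(f_scaled, "domain") <- c(0, 3)
  expect_equal(rmse_to_truth(function(x) x, f_scaled), got, tolerance = 1e-12)
  expect_error(rmse_to_truth(function(x) x, function(x) rep(1, length(x))),
               "constant")
})

test_that("representation floors: few equispaced knots limit concave-shape recovery", {
  # even a perfectly placed 4-knot spline cannot track a square root closely,
  # while a 12-point mapping (linearly interpolated) can
  f <- true_scaling("root")
  kx4 <- seq(0, 30, length.out = 5)
  sp <- scaling_function(kx4, f(kx4))
  expect_gt(rmse_to_truth(f, sp), 0.03)
  expect_lt(rmse_to_truth(f, sp), 0.05)
  kx12 <- seq(0, 30, by = 2.5)
  dl <- scaling_function(kx12, f(kx12), kind = "discrete")
  expect_lt(rmse_to_truth(f, dl), 0.02)
})

test_that("prediction accuracy follows the tie and counting conventions", {
  tri <- data.frame(standard = 50, test1 = 40, test2 = 55)
  resp <- tri[rep(1, 4), ]
  resp$response <- c(1L, 1L, 0L, 1L)
  resp$participant <- 1:4
  idf <- function(x) x
  expect_equal(prediction_accuracy(resp, NULL, idf, 3.63), 0.75)
  # model at exactly chance gets half credit everywhere
  flat <- scaling_function(c(0, 30), c(0, 0) + c(0, 1e-30))
  sym <- data.frame(standard = 50, test1 = 45, test2 = 55,
                    response = c(1L, 0L, 1L, 0L), participant = 1:4)
  expect_equal(prediction_accuracy(sym, NULL, idf, 1), 0.5)
  # near-deterministic generator with the true model is predicted perfectly
  d <- small_design()
  r <- simulate_mot(d, idf, 1e-6, 10, seed = 4)
  keep <- abs((r$standard - r$test1) - (r$test2 - r$standard)) > 0
  expect_equal(prediction_accuracy(r[keep, ], NULL, idf, 1e-6), 1.0)
  # brute-force tally oracle on a random toy set
  set.seed(13)
  toy <- small_design()[sample(1:42, 5), ]
  toy <- toy[rep(seq_len(5), each = 6), ]
  toy$response <- rbinom(30, 1, 0.5)
  toy$participant <- rep(1:6, 5)
  f <- true_scaling("root")
  p <- response_prob(toy, NULL, f, 3.63)
  manual <- mean(ifelse(abs(p - 0.5) < 1e-12, 0.5,
                        (p > 0.5) == toy$response))
  expect_equal(prediction_accuracy(toy, NULL, f, 3.63), manual,
               tolerance = 1e-12)
})

test_that("aic is the linear transform of the NLL", {
  expect_equal(aic(100, 4), 208)
  expect_equal(aic(0, 0), 0)
  expect_error(aic(10, -1), "nonnegative")
  expect_gt(aic(11, 4), aic(10, 4))
})

test_that("cross-validation is stratified, seeded, and beats chance on curved data", {
  d <- triad_design()
  r <- simulate_mot(d, true_scaling("root"), 3.63, 12, seed = 31)
  cv1 <- kfold_cv(r, k_folds = 4, k = 4, fix = c(sigma = 1.46), restarts = 3,
                  seed = 7)
  cv2 <- kfold_cv(r, k_folds = 4, k = 4, fix = c(sigma = 1.46), restarts = 3,
                  seed = 7)
  expect_identical(cv1$accuracy, cv2$accuracy)
  expect_length(cv1$accuracy, 4)
  expect_true(all(cv1$accuracy >= 0 & cv1$accuracy <= 1))
  # diminishing-returns data are predicted clearly above chance
  expect_gt(cv1$mean, 0.55)
  expect_error(kfold_cv(r, k_folds = 1), "at least 2")
})

test_that("leave-one-out runs on a tiny set with three-valued accuracies", {
  tri <- data.frame(standard = c(50, 50), test1 = c(40, 35), test2 = c(55, 60))
  toy <- tri[rep(1:2, each = 4), ]
  toy$response <- c(1L, 1L, 0L, 1L, 1L, 0L, 1L, 1L)
  toy$participant <- rep(1:4, 2)
  cv <- kfold_cv(toy, k_folds = 4, k = 2, fix = c(sigma = 1.46), restarts = 2,
                 seed = 3)
  expect_true(all(cv$accuracy %in% c(0, 0.5, 1)))
})

test_that("residual diagnostic is null for the generating model and flags misfit", {
  d <- triad_design()
  # under an additive generator the choice probability does not depend on
  # dbar at all, so residuals against the true model are pure binomial noise
  f_lin <- true_scaling("linear")
  r_lin <- simulate_mot(d, f_lin, 3.63, 300, seed = 41)
  null_diag <- residual_vs_dbar(r_lin, NULL, f_lin, 3.63)
  expect_gt(null_diag$p_value, 0.05)
  # an additive straight-line model fit to curved data leaves residuals
  # that vary systematically with the average difference
  f_cvx <- true_scaling("convex")
  r_cvx <- simulate_mot(d, f_cvx, 3.63, 300, seed = 41)
  lin_fit <- fit_difference_scaling(r_cvx, k = 2, fix = c(sigma = 1.46),
                                    restarts = 3, seed = 2)
  lin_f <- scaling_function(c(0, 30), c(0, lin_fit$max))
  mis_diag <- residual_vs_dbar(r_cvx, NULL, lin_f, lin_fit$sigma)
  expect_gt(abs(mis_diag$r), 0.1)
  expect_lt(mis_diag$p_value, 0.05)
  expect_error(residual_vs_dbar(r_lin[1:2, ], NULL, f_lin, 3.63), "3 triads")
})
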