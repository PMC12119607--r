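test_that("noiseless linear data is recovered to machine precision", {
  doses <- c(0, 100, 200, 400)
  df <- do.call(rbind, lapply(doses, function(d) {
    A <- 2 * d + 1
    data.frame(donor = 1L, exposure = 1L, dose = d, draw = 1:3,
               A = A + c(-1, 0, 1) * 1e-9, B = 3 * A - 1)
  }))
  rs <- make_resamples(df, nodes = c("A", "B"))
  fit <- fit_gbn(rs, chain_graph(), exposure = 1)
  expect_equal(unname(fit$fits$A$beta), c(1, 2), tolerance = 1e-6)
  expect_equal(unname(fit$fits$B$beta), c(-1, 3), tolerance = 1e-6)
  expect_lt(fit$fits$B$sigma2, 1e-12)
})

test_that("GBN coefficients equal stats::lm and recover truth within 3 SE", {
  rs <- chain_draws(c(0, 100, 300, 600), M = 2500,
                    a0 = 0.5, a1 = 0.004, s2a = 0.09,
                    b0 = -0.2, b1 = 1.5, s2b = 0.04, seed = 31)
  fit <- fit_gbn(rs, chain_graph(), exposure = 1)

  # dual route: our standardized-QR fit vs a direct lm() call
  lmA <- lm(A ~ dose, data = rs)
  lmB <- lm(B ~ A, data = rs)
  expect_equal(unname(fit$fits$A$beta), unname(coef(lmA)), tolerance = 1e-8)
  expect_equal(unname(fit$fits$B$beta), unname(coef(lmB)), tolerance = 1e-8)

  # recovery within 3 standard errors
  seA <- sqrt(diag(vcov(lmA)))
  expect_true(all(abs(fit$fits$A$beta - c(0.5, 0.004)) < 3 * seA))
  seB <- sqrt(diag(vcov(lmB)))
  expect_true(all(abs(fit$fits$B$beta - c(-0.2, 1.5)) < 3 * seB))
  expect_equal(fit$fits$B$sigma2, 0.04, tolerance = 0.1)
})

test_that("the fit is invariant to draw order", {
  rs <- chain_draws(c(0, 200), M = 500, a0 = 0, a1 = 0.01, s2a = 0.1,
                    b0 = 1, b1 = 0.5, s2b = 0.05, seed = 2)
  set.seed(9)
  shuffled <- make_resamples(rs[sample(nrow(rs)), ], nodes = c("A", "B"))
  f1 <- fit_gbn(rs, chain_graph(), exposure = 1)
  f2 <- fit_gbn(shuffled, chain_graph(), exposure = 1)
  expect_equal(f1$fits$A$beta, f2$fits$A$beta, tolerance = 1e-10)
  expect_equal(f1$fits$B$sigma2, f2$fits$B$sigma2, tolerance = 1e-10)
})

test_that("exactly collinear parents fail fast, naming the culprits", {
  g <- aop_graph(c("dose", "P", "Q", "AO"),
                 rbind(c("dose", "P"), c("dose", "Q"),
                       c("P", "AO"), c("Q", "AO")),
                 roles = c(dose = "dose", P = "KE", Q = "KE", AO = "AO"))
  set.seed(4)
  d <- rep(c(0, 100, 200), each = 50)
  P <- 0.01 * d + rnorm(150, 0, 0.1)
  df <- data.frame(donor = 1L, exposure = 1L, dose = d, draw = 1:150,
                   P = P, Q = 2 * P, AO = P + rnorm(150, 0, 0.1))
  rs <- make_resamples(df, nodes = c("P", "Q", "AO"))
  expect_error(fit_gbn(rs, g, exposure = 1), "collinear.*AO|AO.*collinear")
})

test_that("forward sampling with zero variance propagates deterministically", {
  rs <- chain_draws(c(0, 100, 200), M = 200, a0 = 1, a1 = 0.02, s2a = 0.04,
                    b0 = 0.5, b1 = 2, s2b = 0.02, seed = 5)
  fit <- fit_gbn(rs, chain_graph(), exposure = 1)
  fit$fits$A$sigma2 <- 0
  fit$fits$B$sigma2 <- 0
  x <- forward_sample(fit, dose = 150, M = 10L, seed = 1L)
  aA <- fit$fits$A$beta
  aB <- fit$fits$B$beta
  expect_true(all(x[, "A"] == aA[1] + aA[2] * 150))
  expect_true(all(x[, "B"] == aB[1] + aB[2] * x[1, "A"]))
  # determinism with noise
  fit2 <- fit_gbn(rs, chain_graph(), exposure = 1)
  expect_identical(forward_sample(fit2, 100, 500L, seed = 3L),
                   forward_sample(fit2, 100, 500L, seed = 3L))
})

test_that("forward samples match the closed-form Gaussian chain marginal", {
  pars <- list(a0 = 0.3, a1 = 0.003, s2a = 0.09, b0 = -0.1, b1 = 1.2,
               s2b = 0.05)
  rs <- do.call(chain_draws, c(list(doses = c(0, 250, 500, 1000), M = 5000,
                                    seed = 13), pars))
  fit <- fit_gbn(rs, chain_graph(), exposure = 1)
  x <- forward_sample(fit, dose = 400, M = 100000L, seed = 21L)
  truth <- do.call(chain_b_marginal, c(list(d = 400), pars))
  # the fitted coefficients differ from truth by O(1/sqrt(n)); compare the
  # MC marginal against the closed form under the *fitted* parameters
  fitted_mean <- fit$fits$B$beta[1] +
    fit$fits$B$beta[2] * (fit$fits$A$beta[1] + fit$fits$A$beta[2] * 400)
  fitted_var <- fit$fits$B$beta[2]^2 * fit$fits$A$sigma2 + fit$fits$B$sigma2
  expect_equal(mean(x[, "B"]), unname(fitted_mean),
               tolerance = 4 * sqrt(fitted_var / 1e5) / abs(fitted_mean))
  expect_equal(var(x[, "B"]), unname(fitted_var), tolerance = 0.05)
  # and the fitted chain is close to the generating one
  expect_equal(unname(fitted_mean), truth$mean, tolerance = 0.05)
})

test_that("event probabilities agree with the Gaussian CDF oracle", {
  pars <- list(a0 = 0.3, a1 = 0.003, s2a = 0.09, b0 = -0.1, b1 = 1.2,
               s2b = 0.05)
  rs <- do.call(chain_draws, c(list(doses = c(0, 250, 500, 1000), M = 5000,
                                    seed = 17), pars))
  fit <- fit_gbn(rs, chain_graph(), exposure = 1)
  M <- 100000L
  cases <- list(c(delta = 0.5, dose = 100), c(delta = 1.0, dose = 400),
                c(delta = 1.5, dose = 700), c(delta = 0.8, dose = 250),
                c(delta = 2.0, dose = 900))
  for (cs in cases) {
    ep <- event_probability(fit, "B", cs["delta"], cs["dose"], M = M,
                            seed = 7L)
    m <- fit$fits$B$beta[1] + fit$fits$B$beta[2] *
      (fit$fits$A$beta[1] + fit$fits$A$beta[2] * cs["dose"])
    v <- fit$fits$B$beta[2]^2 * fit$fits$A$sigma2 + fit$fits$B$sigma2
    p_true <- unname(1 - pnorm((cs["delta"] - m) / sqrt(v)))
    se <- sqrt(p_true * (1 - p_true) / M)
    expect_lt(abs(ep$p - p_true), 3 * se + 1e-9)
  }
})

test_that("degenerate thresholds give probability 0 and 1", {
  rs <- chain_draws(c(0, 100), M = 200, a0 = 0, a1 = 0.01, s2a = 0.05,
                    b0 = 0, b1 = 1, s2b = 0.05, seed = 3)
  fit <- fit_gbn(rs, chain_graph(), exposure = 1)
  expect_equal(event_probability(fit, "B", -Inf, 50, M = 100, seed = 1)$p, 1)
  expect_equal(event_probability(fit, "B", Inf, 50, M = 100, seed = 1)$p, 0)
  expect_error(event_probability(fit, "B", 0, 50, M = 0), "M must be")
})

test_that("threshold conversions are explicit and exact", {
  expect_equal(threshold_to_log(2, "FC"), log(2), tolerance = 1e-12)
  expect_equal(threshold_to_log(2, "FC") / log(10), 0.301, tolerance = 5e-4)
  expect_equal(threshold_to_log(1, "FC"), 0)
  expect_equal(threshold_to_log(2, "log2FC"), 2 * log(2), tolerance = 1e-12)
  expect_equal(threshold_to_log(0.301, "log10FC"), 0.301 * log(10),
               tolerance = 1e-12)
  expect_error(threshold_to_log(-1, "FC"), "FC threshold")
  expect_error(threshold_to_log(2, "foo"))
})

test_that("goodness of fit matches the analytic variance decomposition", {
  # noiseless linear child: R2 = 1
  doses <- c(0, 100, 200, 300)
  df <- do.call(rbind, lapply(doses, function(d) {
    data.frame(donor = 1L, exposure = 1L, dose = d, draw = 1:50,
               A = 0.01 * d + rnorm(50, 0, 0.2))
  }))
  df$B <- 2 * df$A + 1
  rs <- make_resamples(df, nodes = c("A", "B"))
  fit <- fit_gbn(rs, chain_graph(), exposure = 1)
  r2 <- goodness_of_fit(fit, rs)
  expect_equal(unname(r2["B"]), 1, tolerance = 1e-9)

  # known signal-to-noise: R2 ~= var(signal) / var(total)
  set.seed(8)
  sig <- 1.5 * df$A
  noise <- rnorm(nrow(df), 0, 0.3)
  df2 <- df; df2$B <- sig + noise
  rs2 <- make_resamples(df2, nodes = c("A", "B"))
  fit2 <- fit_gbn(rs2, chain_graph(), exposure = 1)
  r22 <- goodness_of_fit(fit2, rs2)
  expect_equal(unname(r22["B"]), var(sig) / (var(sig) + var(noise)),
               tolerance = 0.05)

  # pure-noise child: R2 ~= 0
  df3 <- df; df3$B <- rnorm(nrow(df))
  rs3 <- make_resamples(df3, nodes = c("A", "B"))
  fit3 <- fit_gbn(rs3, chain_graph(), exposure = 1)
  expect_lt(goodness_of_fit(fit3, rs3)["B"], 0.05)
})

test_that("probability curves behave on degenerate and monotone inputs", {
  rs <- chain_draws(c(0, 300, 600, 1000), M = 2000, a0 = 0, a1 = 0.002,
                    s2a = 0.04, b0 = 0, b1 = 1.5, s2b = 0.04, seed = 19)
  fit <- fit_gbn(rs, chain_graph(), exposure = 1)
  flat <- probability_curve(fit, "B", -Inf, c(0, 500, 1000), M = 500, seed = 1)
  expect_true(all(flat$probability == 1))

  one <- probability_curve(fit, "B", 0.5, 500, M = 500, seed = 1)
  expect_equal(nrow(one), 1L)

  curve <- probability_curve(fit, "B", 1.0, seq(0, 1000, by = 100),
                             M = 20000, seed = 2)
  expect_true(all(diff(curve$probability) > -0.02)) # nondecreasing up to MC noise
  expect_error(probability_curve(fit, "B", 1, numeric(0)), "empty")
})

test_that("exceedance probability is nonincreasing in the threshold", {
  rs <- chain_draws(c(0, 500, 1000), M = 2000, a0 = 0.2, a1 = 0.002,
                    s2a = 0.04, b0 = 0, b1 = 1, s2b = 0.04, seed = 23)
  fit <- fit_gbn(rs, chain_graph(), exposure = 1)
  deltas <- threshold_to_log(c(1.5, 2, 3), "FC")
  ps <- sapply(deltas, function(dl) {
    event_probability(fit, "B", dl, 800, M = 20000, seed = 11)$p
  })
  expect_true(all(diff(ps) <= 0))
})

test_that("the dose window epsilon averages over nearby doses", {
  rs <- chain_draws(c(0, 500, 1000), M = 2000, a0 = 0, a1 = 0.003,
                    s2a = 0.01, b0 = 0, b1 = 1, s2b = 0.01, seed = 29)
  fit <- fit_gbn(rs, chain_graph(), exposure = 1)
  p_mid <- event_probability(fit, "B", 1.2, 400, M = 50000, seed = 3)$p
  p_win <- event_probability(fit, "B", 1.2, 400, epsilon = 100, M = 50000,
                             seed = 3)$p
  p_lo <- event_probability(fit, "B", 1.2, 300, M = 50000, seed = 3)$p
  p_hi <- event_probability(fit, "B", 1.2, 500, M = 50000, seed = 3)$p
  expect_gte(p_win, p_lo - 0.01)
  expect_lte(p_win, p_hi + 0.01)
  expect_equal(p_win, p_mid, tolerance = 0.15)
})

test_that("extrapolation beyond the fitted dose range warns but proceeds", {
  rs <- chain_draws(c(0, 100), M = 100, a0 = 0, a1 = 0.01, s2a = 0.01,
                    b0 = 0, b1 = 1, s2b = 0.01, seed = 1)
  fit <- fit_gbn(rs, chain_graph(), exposure = 1)
  expect_warning(forward_sample(fit, 500, M = 10, seed = 1), "extrapolating")
})
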