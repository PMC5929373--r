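test_that("noiseless exponentials are recovered to machine-level accuracy", {
  cond <- reaction_conditions(1, 500)
  t <- seq(0, 0.1, length.out = 120)
  tr <- kin_trace(t, 0.2 + 1 * exp(-100 * t), cond)
  f <- fit_exponential(tr, 1)
  expect_equal(f$k_obs, 100, tolerance = 1e-6)
  expect_equal(f$amplitudes, 1, tolerance = 1e-6)
  expect_equal(f$endpoint, 0.2, tolerance = 1e-6)
  # biphasic, rates sorted descending
  y2 <- 0.1 + 0.6 * exp(-300 * t) + 0.3 * exp(-25 * t)
  f2 <- fit_exponential(kin_trace(t, y2, cond), 2)
  expect_equal(f2$k_obs, c(300, 25), tolerance = 1e-5)
  expect_equal(f2$amplitudes, c(0.6, 0.3), tolerance = 1e-5)
  expect_gt(f2$k_obs[1], f2$k_obs[2])
})

test_that("exp_fit methods are mutually consistent", {
  cond <- reaction_conditions(1, 500)
  t <- seq(0, 0.1, length.out = 150)
  set.seed(2)
  tr <- kin_trace(t, 0.2 + exp(-80 * t) + rnorm(150, 0, 0.01), cond)
  f <- fit_exponential(tr, 1)
  expect_equal(predict(f), fitted(f), tolerance = 1e-12)
  expect_equal(residuals(f), tr$signal - fitted(f), tolerance = 1e-12)
  cf <- coef(f)
  expect_named(cf, c("endpoint", "A1", "k_obs1"))
  expect_equal(sum(residuals(f)^2), f$sse, tolerance = 1e-12)
})

test_that("flat traces are flagged, short traces rejected", {
  cond <- reaction_conditions(1, 500)
  t <- seq(0, 1, length.out = 60)
  f <- fit_exponential(kin_trace(t, rep(0.5, 60), cond), 1)
  expect_true("amplitude_near_zero" %in% f$flags)
  # dead-time trimming can leave too few usable points for the model
  tr_short <- kin_trace(seq(0, 1, length.out = 25),
                        rep(0.5, 25), cond, dead_time = 0.5)
  expect_error(fit_exponential(tr_short, 2), "usable points")
})

test_that("dead-time points are excluded from the fit", {
  cond <- reaction_conditions(1, 500)
  t <- seq(0, 0.1, length.out = 200)
  y <- 0.2 + exp(-100 * t)
  y[t < 0.002] <- 5  # corrupted mixing artefact
  f <- fit_exponential(kin_trace(t, y, cond, dead_time = 0.002), 1)
  expect_equal(f$k_obs, 100, tolerance = 1e-6)
})

test_that("a branched-scheme trace needs two phases and matches the eigenvalue oracle", {
  rs <- wt_ssa_fixture_rates()
  cond <- reaction_conditions(4, 1500)
  tr <- gen_trace(rs, cond, noise_model(sigma = 0, n_replicates = 1))
  f1 <- fit_exponential(tr, 1)
  f2 <- fit_exponential(tr, 2)
  sel <- select_order(f1, f2)
  expect_identical(sel$order, 2L)
  # order-1 residuals are systematically structured
  expect_lt(runs_test(residuals(f1))$p_value, 0.01)
  nz <- sort(relaxation_rates(rs, 1500))
  nz <- nz[nz > 0]
  for (k in f2$k_obs) {
    nearest <- nz[which.min(abs(nz - k))]
    expect_lt(abs(k - nearest) / nearest, 0.05)
  }
})

test_that("the extra-sum-of-squares F-test follows its defining formula", {
  fake <- function(order, sse, n) {
    structure(list(order = order, sse = sse, n = n,
                   df = n - (2L * order + 1L)),
              class = "exp_fit")
  }
  f1 <- fake(1L, 2.0, 100)
  f2 <- fake(2L, 1.5, 100)
  sel <- select_order(f1, f2, alpha = 0.05)
  F_expect <- ((2.0 - 1.5) / 2) / (1.5 / 95)
  expect_equal(sel$F, F_expect)
  expect_equal(sel$p_value, pf(F_expect, 2, 95, lower.tail = FALSE))
  expect_identical(sel$order, 2L)
  # identical SSE: no support for the extra phase
  sel0 <- select_order(f1, fake(2L, 2.0, 100))
  expect_identical(sel0$order, 1L)
  expect_equal(sel0$F, 0)
  # pathological: higher order fits worse
  expect_warning(selp <- select_order(f1, fake(2L, 2.5, 100)), "larger SSE")
  expect_identical(selp$order, 1L)
  expect_error(select_order(f2, f1), "higher order")
  expect_error(select_order(f1, f2, alpha = 1.5), "alpha")
})

test_that("hyperbolic k_obs regression recovers noiseless parameters exactly", {
  S <- c(30, 100, 250, 470, 800, 1500)
  ks <- kobs_series(S, eq4_kobs(S, 370, 470, 280))
  fit <- fit_kobs_hyperbolic(ks)
  expect_equal(fit$k2, 370, tolerance = 1e-5)
  expect_equal(fit$K_S, 470, tolerance = 1e-5)
  expect_equal(fit$intercept, 280, tolerance = 1e-5)
  expect_equal(predict(fit, S), ks$kobs, tolerance = 1e-5)
})

test_that("degenerate k_obs series are flagged or redirected", {
  S <- c(50, 150, 400, 800, 1500)
  # flat: k2 ~ 0, K_S undetermined
  flat <- fit_kobs_hyperbolic(kobs_series(S, rep(48, 5)))
  expect_equal(flat$k2, 0)
  expect_true("K_S_undetermined" %in% flat$flags)
  # decreasing data sent to the hyperbolic model
  y_dec <- 10 + 38 / (1 + S / 500)
  expect_error(fit_kobs_hyperbolic(kobs_series(S, y_dec)), "decreas")
  # increasing data sent to the decreasing model
  expect_error(fit_kobs_decreasing(kobs_series(S, eq4_kobs(S, 370, 470, 280))),
               "increases")
  expect_error(fit_kobs_hyperbolic(kobs_series(S[1:3], y_dec[1:3])),
               "4 distinct")
})

test_that("sub-K_S sampling inflates the k2 and K_S standard errors", {
  # full design vs a window far below K_S: k2/K_S stays identifiable,
  # k2 and K_S separately do not
  set.seed(7)
  S_full <- c(30, 100, 250, 470, 800, 1500)
  S_low <- c(5, 10, 20, 30, 40, 50)
  noise <- function(S) eq4_kobs(S, 370, 470, 280) * (1 + rnorm(length(S), 0, 0.01))
  f_full <- fit_kobs_hyperbolic(kobs_series(S_full, noise(S_full)))
  f_low <- fit_kobs_hyperbolic(kobs_series(S_low, noise(S_low)))
  expect_gt((f_low$se$k2 / f_low$k2) / (f_full$se$k2 / f_full$k2), 10)
  expect_true(any(c("extrapolated_K_S", "weakly_identified") %in% f_low$flags))
})

test_that("decreasing k_obs regression returns the S = 0 rate sum", {
  S <- c(50, 150, 400, 800, 1500)
  fit <- fit_kobs_decreasing(kobs_series(S, 10 + 38 / (1 + S / 500),
                                         phase = "slow"))
  expect_equal(fit$intercept, 48, tolerance = 1e-5)
  expect_equal(fit$k_lim, 10, tolerance = 1e-4)
  expect_equal(fit$K_app, 500, tolerance = 1e-3)
  # no substrate dependence at all: intercept is the flat level
  flat <- fit_kobs_decreasing(kobs_series(S, rep(12, 5), phase = "slow"))
  expect_equal(flat$intercept, 12)
  expect_equal(flat$k_rev, 0)
})

test_that("decreasing-model intercept is recovered across noise seeds", {
  S <- c(50, 150, 400, 800, 1500)
  truth <- 10 + 38 / (1 + S / 500)
  ints <- vapply(1:100, function(s) {
    set.seed(s)
    y <- truth * (1 + rnorm(length(S), 0, 0.05))
    fit_kobs_decreasing(kobs_series(S, y, phase = "slow"))$intercept
  }, 0)
  expect_lt(abs(stats::median(ints) - 48) / 48, 0.10)
})

test_that("micro-rate extraction matches the published decompositions", {
  mr <- extract_micro_rates(k2 = 370, K_S = 470, sum_km2_k3 = 280,
                            kcat = 63, se_k2 = 20, se_sum = 30,
                            se_kcat = 3)
  expect_equal(mr$k3, 63 * 650 / 370, tolerance = 1e-12)
  expect_lt(abs(mr$k3 - 110), 10)    # printed 110 +/- 10
  expect_lt(abs(mr$k_m2 - 170), 20)  # printed 170 +/- 20
  expect_true(is.finite(mr$se$k3) && mr$se$k3 > 0)
  mr2 <- extract_micro_rates(k2 = 1400, K_S = 2700, sum_km2_k3 = 42,
                             kcat = 31)
  expect_equal(mr2$k3, 31.9, tolerance = 0.01)
  expect_equal(mr2$k_m2, 10.1, tolerance = 0.01)
})

test_that("extraction is an exact left inverse of the steady-state expression", {
  set.seed(21)
  for (i in 1:20) {
    k2 <- runif(1, 10, 3000); k_m2 <- runif(1, 0, 300)
    k3 <- runif(1, 1, 200); K_S <- runif(1, 10, 5000)
    ss <- steady_state_params(k2, k_m2, k3, K_S)
    mr <- extract_micro_rates(k2, K_S, k_m2 + k3, ss$kcat)
    expect_equal(mr$k3, k3, tolerance = 1e-9)
    expect_equal(mr$k_m2, k_m2, tolerance = 1e-6)
    expect_equal(steady_state_params(k2, mr$k_m2, mr$k3, K_S)$kcat,
                 ss$kcat, tolerance = 1e-12)
  }
  # k_m2 = 0 boundary
  ss0 <- steady_state_params(200, 0, 50, 100)
  mr0 <- extract_micro_rates(200, 100, 50, ss0$kcat)
  expect_equal(mr0$k_m2, 0, tolerance = 1e-9)
})

test_that("an implied negative k-2 is reported and flagged, not clipped", {
  mr <- extract_micro_rates(k2 = 100, K_S = 100, sum_km2_k3 = 50,
                            kcat = 40)
  expect_lt(mr$k_m2, 0)
  expect_true("implied_negative_k_m2" %in% mr$flags)
})

test_that("single-turnover recovery reports the saturated relaxation rate", {
  rs <- as_rate_set(table1_fixture("wild_type", "(S,S)-1b"))
  cond <- reaction_conditions(60, 50, mode = "single_turnover")
  tr <- gen_trace(rs, cond, noise_model(sigma = 0, n_replicates = 1),
                  horizon = 3)
  res <- single_turnover_k3(tr, K_S = 5.5)
  oracle <- saturated_slow_eigen(23, 4.5, 3.9)
  expect_lt(abs(res$k3 - oracle) / oracle, 0.05)
  # multiple-turnover traces are rejected
  tr_mt <- gen_trace(rs, reaction_conditions(1, 50), noise_model(sigma = 0,
                                                                 n_replicates = 1))
  expect_error(single_turnover_k3(tr_mt), "single-turnover")
  # saturation below 2x K_S warns
  low <- reaction_conditions(8, 7, mode = "single_turnover")
  tr_low <- gen_trace(rs, low, noise_model(sigma = 0, n_replicates = 1),
                      horizon = 3)
  expect_warning(single_turnover_k3(tr_low, K_S = 5.5), "saturation")
})

test_that("recovered single-turnover rate rises monotonically with saturation", {
  rs <- as_rate_set(table1_fixture("wild_type", "(S,S)-1b"))
  ks <- vapply(c(1, 2, 5, 10, 20), function(m) {
    cond <- reaction_conditions(m * 5.5 * 1.2, m * 5.5,
                                mode = "single_turnover")
    tr <- gen_trace(rs, cond, noise_model(sigma = 0, n_replicates = 1),
                    horizon = 5)
    suppressWarnings(single_turnover_k3(tr))$k3
  }, 0)
  expect_true(all(diff(ks) > 0))
  expect_lt(ks[5], 3.9)  # bounded above by k3 itself
})

test_that("a hydrolysis-dead single-turnover trace is flagged flat", {
  rs <- rate_set(k2 = 23, k_m2 = 4.5, k3 = 0, K_S = 5.5)
  cond <- reaction_conditions(60, 50, mode = "single_turnover")
  tr <- gen_trace(rs, cond, noise_model(sigma = 0, n_replicates = 1),
                  horizon = 3)
  res <- single_turnover_k3(tr)
  expect_true(any(grepl("flat|amplitude", res$flags)))
})
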