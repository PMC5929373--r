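test_that("rate_set validates fields and names the offender", {
  expect_error(rate_set(k2 = NA, k_m2 = 0, k3 = 1, K_S = 1), "k2")
  expect_error(rate_set(k2 = 1, k_m2 = -1, k3 = 1, K_S = 1), "k_m2")
  expect_error(rate_set(k2 = 1, k_m2 = 0, k3 = 1, K_S = 0), "K_S")
  expect_error(rate_set(k2 = 1, k_m2 = 0, k3 = 1, K_S = 1, kon = Inf),
               "kon")
  rs <- wt_ssa_rates()
  expect_true(is_linear_scheme(rs))
  expect_false(is_linear_scheme(rate_set(k2 = 1, k_m2 = 0, k3 = 1,
                                         K_S = 1, k5 = 2, k_m5 = 2)))
})

test_that("a frozen scheme stays put and has no relaxations", {
  rs <- rate_set(k2 = 0, k_m2 = 0, k3 = 0, K_S = 1, kon = 1e-30)
  cond <- reaction_conditions(1, 100)
  traj <- simulate_scheme(rs, cond, seq(0, 10, length.out = 50))
  expect_lt(max(abs(traj$E - 1)), 1e-9)
  expect_lt(max(abs(traj$S - 100)), 1e-7)
  expect_lt(max(traj$P1, traj$P2, traj$ES, traj$EA), 1e-9)
  expect_lt(max(relaxation_rates(rs, 100)), 1e-12)
})

test_that("single-branch scheme exhausts all substrate into P1", {
  rs <- wt_ssa_rates()
  cond <- reaction_conditions(1, 1500)
  traj <- simulate_scheme(rs, cond, c(0, 10^seq(-5, 2, length.out = 200)))
  n <- nrow(traj)
  expect_equal(traj$P1[n], 1500, tolerance = 1e-6)
  expect_equal(traj$P2[n], 0, tolerance = 1e-9)
})

test_that("a fully symmetric branched scheme splits product equally", {
  rs <- rate_set(k2 = 100, k_m2 = 10, k3 = 50, K_S = 100,
                 k2_prime = 100, k_m2_prime = 10, k3_prime = 50,
                 k5 = 5, k_m5 = 5, k0 = 5, k_m0 = 5)
  cond <- reaction_conditions(1, 20)
  traj <- simulate_scheme(rs, cond, c(0, 10^seq(-5, 2, length.out = 200)),
                          start_equilibrated = TRUE)
  n <- nrow(traj)
  expect_equal(traj$P1[n], traj$P2[n], tolerance = 1e-6)
  expect_gt(traj$P1[n] + traj$P2[n], 19.99)
})

test_that("mass balances hold on every trajectory", {
  set.seed(11)
  for (i in 1:5) {
    rs <- rate_set(k2 = runif(1, 1, 500), k_m2 = runif(1, 0, 200),
                   k3 = runif(1, 1, 200), K_S = runif(1, 10, 2000),
                   k2_prime = runif(1, 0, 300), k_m2_prime = runif(1, 0, 100),
                   k3_prime = runif(1, 0, 100), k5 = runif(1, 0, 50),
                   k_m5 = runif(1, 0, 50))
    cond <- reaction_conditions(runif(1, 0.5, 5), runif(1, 100, 1500))
    traj <- simulate_scheme(rs, cond, c(0, 10^seq(-5, 1, length.out = 100)))
    expect_lt(max(attr(traj, "conservation")), 1e-6)
  }
})

test_that("zeroing one branch reproduces the linear scheme trajectory", {
  # with no path into the primed branch its rate constants are inert
  rs_branched <- rate_set(k2 = 370, k_m2 = 170, k3 = 110, K_S = 470,
                          k2_prime = 250, k_m2_prime = 80, k3_prime = 40)
  rs_linear <- wt_ssa_rates()
  cond <- reaction_conditions(2, 500)
  tg <- c(0, 10^seq(-5, 0, length.out = 120))
  t1 <- simulate_scheme(rs_branched, cond, tg)
  t2 <- simulate_scheme(rs_linear, cond, tg)
  for (sp in c("E", "ES", "EA", "S", "P1", "P2"))
    expect_equal(t1[[sp]], t2[[sp]], tolerance = 1e-8)
})

test_that("simulate_scheme rejects malformed time grids", {
  rs <- wt_ssa_rates()
  cond <- reaction_conditions(1, 500)
  expect_error(simulate_scheme(rs, cond, c(0.1, 0.2)), "start at 0")
  expect_error(simulate_scheme(rs, cond, c(0, 0.2, 0.1)), "increasing")
})

test_that("steady-state parameters match the published turnover numbers", {
  # printed kcat values with their standard errors
  cases <- list(list(c(370, 170, 110, 470), 63, 3),
                list(c(2100, 240, 75, 1600), 65, 2),
                list(c(1400, 10, 32, 2700), 31, 1),
                list(c(2600, 74, 84, 6500), 79, 5))
  for (cs in cases) {
    p <- cs[[1]]
    ss <- steady_state_params(p[1], p[2], p[3], p[4])
    expect_lt(abs(ss$kcat - cs[[2]]), cs[[3]])
    expect_lt(ss$kcat, min(p[1], p[3]))
    expect_lt(ss$Km, p[4])
    expect_equal(ss$kcat_over_Km, ss$kcat / ss$Km * 1000)
  }
  expect_error(steady_state_params(0, 1, 1, 1), "k2")
  expect_error(steady_state_params(1, 1, -1, 1), "k3")
})

test_that("steady-state kcat is the k_m2 = 0, large-k2 limit of the scheme", {
  ss <- steady_state_params(1e9, 0, 110, 470)
  expect_equal(ss$kcat, 110, tolerance = 1e-6)
  expect_lt(ss$Km, 1e-4)
})

test_that("Eyring barriers reproduce the published experimental values", {
  expect_equal(round(eyring_barrier(370, 303.15), 1), 14.2)
  expect_equal(round(eyring_barrier(4.7, 303.15), 1), 16.8)
  expect_equal(eyring_barrier(.kB_T_over_h(303.15), 303.15), 0,
               tolerance = 1e-12)
  expect_error(eyring_barrier(0), "k")
})

test_that("Eyring conversion is an exact involution", {
  expect_equal(eyring_rate(0, 310), .kB_T_over_h(310), tolerance = 1e-12)
  # published k2 back from its rounded barrier, within print rounding
  expect_equal(eyring_rate(14.2, 303.15), 370, tolerance = 0.02)
  set.seed(4)
  dG <- runif(1000, 0.5, 30)
  Tv <- runif(1000, 274, 372)
  back <- vapply(seq_along(dG),
                 function(i) eyring_barrier(eyring_rate(dG[i], Tv[i]), Tv[i]),
                 0)
  expect_lt(max(abs(back - dG) / dG), 1e-10)
})

test_that("slowest relaxation matches the hyperbolic transient-rate law", {
  rs <- wt_ssa_rates()  # binding >= 100-fold faster than chemistry
  for (S in c(100, 470, 1500)) {
    rel <- relaxation_rates(rs, S)
    nz <- rel[rel > 0]
    expect_lt(abs(min(nz) - eq4_kobs(S, 370, 470, 280)) /
                eq4_kobs(S, 370, 470, 280), 0.01)
  }
})

test_that("decoupled identical branches give degenerate relaxation pairs", {
  rs <- rate_set(k2 = 100, k_m2 = 20, k3 = 40, K_S = 200,
                 k2_prime = 100, k_m2_prime = 20, k3_prime = 40)
  rel <- relaxation_rates(rs, 300)
  pairs <- matrix(rel, ncol = 2, byrow = TRUE)
  expect_equal(pairs[, 1], pairs[, 2], tolerance = 1e-8)
})

test_that("simulated steady-state velocity matches the analytic kcat and Km", {
  rs <- wt_ssa_rates()
  cond <- reaction_conditions(1, 1500)
  ss <- steady_state_params(370, 170, 110, 470)
  # sample right after the pre-steady-state burst, before depletion
  kobs <- eq4_kobs(1500, 370, 470, 280)
  t1 <- 8 / kobs
  tg <- seq(0, t1 + 0.02, length.out = 400)
  traj <- simulate_scheme(rs, cond, tg)
  sel <- traj$time >= t1
  slope <- stats::coef(stats::lm(traj$P1[sel] ~ traj$time[sel]))[2]
  v_pred <- ss$kcat * 1500 / (ss$Km + 1500) * cond$E_total
  expect_lt(abs(slope - v_pred) / v_pred, 0.02)
})

test_that("rate sets and conditions survive a YAML roundtrip losslessly", {
  rs <- rate_set(k2 = 370.123456789012, k_m2 = 170, k3 = 110,
                 K_S = 470.000000000123, k5 = 16, k_m5 = 16)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_rate_set(rs, f)
  rs2 <- read_rate_set(f)
  expect_equal(unclass(rs2), unclass(rs), tolerance = 1e-12)
  cond <- reaction_conditions(1.25, 512.5, 310.15)
  f2 <- withr::local_tempfile(fileext = ".yaml")
  write_conditions(cond, f2)
  expect_equal(unclass(read_conditions(f2)), unclass(cond),
               tolerance = 1e-12)
})
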