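make_two_block <- function(N = 10, Dv = 10, cc = 0, C = 1, seed = 1) {
  update_params(dispersal_instability_params(N = N, C = C, c = cc), D_v = Dv)
}

test_that("rhs vanishes at extinction and at the logistic fixed point", {
  p <- community_params(N = 2, N_u = 1, C = 0, c = 0, D_u = 0, D_v = 0)
  A <- suppressWarnings(sample_interaction_matrix(p, seed = 1))
  cfg <- sim_config(p, a = 1, L = 10, n_x = 16, t_end = 1, seed = 1)
  zero <- matrix(0, 1, 16)
  r <- rhs_fields(zero, zero, A, cfg)
  expect_true(all(r$du == 0) && all(r$dv == 0))
  # single prey with no interactions: u' = u(a - u), fixed point u* = a
  r2 <- rhs_fields(matrix(1, 1, 16), zero, A, cfg)
  expect_lt(max(abs(r2$du)), 1e-14)
  r3 <- rhs_fields(matrix(0.5, 1, 16), zero, A, cfg)
  expect_equal(r3$du[1, 1], 0.5 * (1 - 0.5))
})

test_that("diffusion term is exactly zero for spatially uniform fields", {
  p <- make_two_block()
  A <- sample_interaction_matrix(p, seed = 2)
  cfg <- sim_config(p, a = 1, L = 20, n_x = 32, t_end = 1, seed = 1)
  u <- matrix(rep(runif(p$N_u, 0.2, 1), 32), p$N_u, 32)
  v <- matrix(rep(runif(p$N_v, 0.2, 1), 32), p$N_v, 32)
  with_d <- rhs_fields(u, v, A, cfg, diffusion = TRUE)
  without <- rhs_fields(u, v, A, cfg, diffusion = FALSE)
  expect_equal(with_d$du, without$du, tolerance = 1e-12)
  expect_equal(with_d$dv, without$dv, tolerance = 1e-12)
})

test_that("zero-variance full-connectance equilibrium matches the reduced
           two-variable fixed point", {
  p <- make_two_block(N = 10, cc = 0, C = 1)
  A <- sample_interaction_matrix(p, seed = 3)
  cfg <- sim_config(p, a = 1, L = 20, n_x = 32, t_end = 1, seed = 5)
  eq <- find_feasible_equilibrium(A, cfg)
  expect_true(eq$converged)
  red <- ls_reduced(p, a = 1)
  expect_equal(unname(eq$u_star), rep(red$fp[1], p$N_u), tolerance = 1e-6)
  expect_equal(unname(eq$v_star), rep(red$fp[2], p$N_v), tolerance = 1e-6)
})

test_that("all-zero equilibrium when growth is absent and means nonpositive", {
  p <- community_params(N = 10, N_u = 5, C = 1, c = 0, m_uu = -1, m_uv = -2,
                        m_vu = 0, m_vv = -1)
  A <- sample_interaction_matrix(p, seed = 1)
  cfg <- sim_config(p, a = 1e-12, L = 10, n_x = 16, t_end = 1, seed = 1)
  # extinction without growth is algebraic (x' ~ -x^2), so the horizon leaves
  # a small residual rather than exact zero
  eq <- find_feasible_equilibrium(A, cfg)
  expect_true(all(c(eq$u_star, eq$v_star) < 2e-3))
})

test_that("analytic equilibrium Jacobian matches finite differences and is
           linearly stable at the feasible equilibrium", {
  p <- dispersal_instability_params(N = 40, C = 0.5, c = 0.3)
  A <- sample_interaction_matrix(p, seed = 6)
  cfg <- sim_config(p, a = 1, L = 20, n_x = 32, t_end = 1, seed = 2)
  eq <- suppressMessages(find_feasible_equilibrium(A, cfg))
  jac <- equilibrium_jacobian(A, eq, cfg)
  x <- c(eq$u_star, eq$v_star)
  Jnum <- numerical_jacobian(A, cfg, x)[eq$survivors, eq$survivors]
  expect_equal(jac$J, Jnum, tolerance = 1e-6)
  ev <- eigen(jac$J, only.values = TRUE)$values
  expect_lt(max(Re(ev)), 1e-6)
})

test_that("unperturbed uniform equilibrium is preserved by the integrator", {
  p <- make_two_block(N = 10, Dv = 2)
  A <- sample_interaction_matrix(p, seed = 3)
  cfg <- sim_config(p, a = 1, L = 20, n_x = 32, t_end = 5, seed = 7,
                    init_noise = 0)
  eq <- find_feasible_equilibrium(A, cfg)
  traj <- run_simulation(A, cfg, eq)
  # drift is bounded by the equilibrium residual (max rate < 1e-9) times the
  # horizon, not by integrator error
  drift <- abs(traj$diagnostics$total_u - traj$diagnostics$total_u[1])
  expect_lt(max(drift), 1e-7)
  expect_lt(max(traj$diagnostics$spatial_var_u), 1e-18)
  expect_equal(traj$clamped, 0L)
})

test_that("recorded abundances are nonnegative throughout", {
  p <- make_two_block(N = 10, Dv = 10)
  A <- sample_interaction_matrix(p, seed = 3)
  cfg <- sim_config(p, a = 1, L = 20, n_x = 64, t_end = 20, seed = 7,
                    init_noise = 0.01)
  traj <- run_simulation(A, cfg)
  expect_true(all(traj$profiles$prey >= 0))
  expect_true(all(traj$profiles$predator >= 0))
  for (s in traj$snapshots) expect_true(min(s$u, s$v) >= 0)
})

test_that("RK4 converges at fourth order on the reaction-only system", {
  p <- community_params(N = 6, N_u = 3, C = 1, c = 0, m_uu = 2, m_uv = -3,
                        m_vu = 3, D_u = 0, D_v = 0)
  A <- sample_interaction_matrix(p, seed = 4)
  run_dt <- function(dt) {
    cfg <- sim_config(p, a = 1, L = 10, n_x = 16, dt = dt, t_end = 2,
                      seed = 9, init_noise = 0.05, record_every = 2)
    eq <- list(u_star = rep(0.5, 3), v_star = rep(0.4, 3),
               survivors = rep(TRUE, 6), converged = TRUE)
    traj <- run_simulation(A, cfg, eq)
    traj$profiles[traj$profiles$t == max(traj$profiles$t), c("prey", "predator")]
  }
  ref <- run_dt(0.2 / 16)
  errs <- vapply(c(0.2, 0.1, 0.05), function(dt) {
    out <- run_dt(dt)
    max(abs(out$prey - ref$prey), abs(out$predator - ref$predator))
  }, numeric(1))
  order_fit <- stats::coef(stats::lm(log(errs) ~ log(c(0.2, 0.1, 0.05))))[2]
  expect_gte(order_fit, 3.5)
})

test_that("early-time growth of the dominant mode matches the realized-community
           linear prediction", {
  p <- make_two_block(N = 10, Dv = 10)
  A <- sample_interaction_matrix(p, seed = 3)
  cfg <- sim_config(p, a = 1, L = 30, n_x = 96, t_end = 30, seed = 11,
                    init_noise = 1e-6, record_every = 1, cfl_safety = 0.4)
  eq <- find_feasible_equilibrium(A, cfg)
  qg <- seq(0.2, 6, 0.1)
  ed <- equilibrium_dispersion(A, eq, cfg, qg)
  q_star <- qg[which.max(ed$re_max)]
  growth_pred <- max(ed$re_max)
  expect_gt(growth_pred, 0)
  traj <- run_simulation(A, cfg, eq)
  # amplitude of the q* Fourier mode of the summed prey profile over time
  prof <- traj$profiles
  times <- sort(unique(prof$t))
  k_star <- round(q_star * cfg$L / (2 * pi))
  amp <- vapply(times, function(tt) {
    y <- prof$prey[prof$t == tt]
    Mod(stats::fft(y - mean(y)))[k_star + 1L]
  }, numeric(1))
  # fit the exponential window while amplitudes are still linear-regime small
  win <- times >= 5 & amp < 1e-1 & amp > 1e-8
  fit <- stats::coef(stats::lm(log(amp[win]) ~ times[win]))[2]
  expect_equal(unname(fit), growth_pred, tolerance = 0.1)
})

test_that("diagnostics: uniform trajectories have zero heterogeneity and
           volatility", {
  p <- make_two_block(N = 10, Dv = 2)
  A <- sample_interaction_matrix(p, seed = 3)
  cfg <- sim_config(p, a = 1, L = 20, n_x = 32, t_end = 2, seed = 7,
                    init_noise = 0)
  traj <- run_simulation(A, cfg)
  d <- sim_diagnostics(traj)
  expect_true(all(d$heterogeneity < 1e-18))
  expect_true(all(d$volatility == 0))
  expect_true(all(is.na(d$dominant_wavelength)))
})

test_that("configuration guards reject unstable settings", {
  p <- make_two_block(N = 10, Dv = 10)
  expect_error(sim_config(p, n_x = 8), "n_x")
  expect_error(sim_config(p, a = -1), "positive")
  expect_error(sim_config(p, L = 20, n_x = 32, dt = 1), "stability bound")
  expect_error(sim_config(p, cfl_safety = 0.9), "cfl_safety")
})
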