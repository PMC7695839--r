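# Closed-form oracles, coded independently of the generic solvers.

# Uncorrelated-ensemble bulk boundary locus (Gamma = 0):
# gamma_u / |omega + h_u|^2 + gamma_v / |omega + h_v|^2 = 1 / c.
# Returns the locus residual at the supplied curve points.
closed_form_locus_residual <- function(params, q, omega_x, omega_y) {
  hu <- params$d_u + q^2 * params$D_u
  hv <- params$d_v + q^2 * params$D_v
  params$gamma_u / ((omega_x + hu)^2 + omega_y^2) +
    params$gamma_v / ((omega_x + hv)^2 + omega_y^2) - 1 / params$c
}

# 2x2 block-mean matrix whose eigenvalues the outliers approach as c -> 0
mean_matrix_2x2 <- function(params, q) {
  hu <- params$d_u + q^2 * params$D_u
  hv <- params$d_v + q^2 * params$D_v
  matrix(c(-hu + params$gamma_u * params$m_uu, params$gamma_v * params$m_uv,
           params$gamma_u * params$m_vu, -hv + params$gamma_v * params$m_vv),
         2, 2, byrow = TRUE)
}

# Uncorrelated outlier equation is exactly quadratic in omega (chi_a is then
# 1/(omega + h_a) for every c): roots of
# (omega + h_u - g_u m_uu)(omega + h_v - g_v m_vv) = g_u g_v m_uv m_vu
quadratic_outlier_oracle <- function(params, q) {
  M <- mean_matrix_2x2(params, q)
  eigen(M, only.values = TRUE)$values
}

# Reduced two-variable system of a c = 0, C = 1 community (all species within
# a block identical): block-level interaction matrix, fixed point and
# wavenumber-dependent Jacobian for the nonlinear Levin-Segel model.
ls_reduced <- function(params, a) {
  stopifnot(params$c == 0, params$C == 1)
  mu <- ecostab::mu_matrix(params)
  B <- matrix(c(-1 + (params$N_u - 1) * mu["u", "u"], params$N_v * mu["u", "v"],
                params$N_u * mu["v", "u"], -1 + (params$N_v - 1) * mu["v", "v"]),
              2, 2, byrow = TRUE)
  fp <- solve(-B, c(a, 0))
  J <- diag(fp) %*% B
  list(B = B, fp = fp, J = J)
}

# rightmost eigenvalue of the reduced Jacobian at wavenumber q
ls_reduced_re_max <- function(red, params, q) {
  Jq <- red$J - diag(q^2 * c(params$D_u, params$D_v))
  max(Re(eigen(Jq, only.values = TRUE)$values))
}

# classical two-species Turing threshold on D_v (D_u fixed) by bisection on
# the reduced system: smallest D_v with growth at some q > 0
ls_reduced_turing_threshold <- function(params, a, q_grid, lo = 0.1, hi = 100) {
  red <- ls_reduced(params, a)
  unstable_at <- function(Dv) {
    p2 <- ecostab::update_params(params, D_v = Dv)
    any(vapply(q_grid[q_grid > 0], function(q) ls_reduced_re_max(red, p2, q),
               numeric(1)) > 0)
  }
  stopifnot(!unstable_at(lo), unstable_at(hi))
  for (k in 1:40) {
    mid <- sqrt(lo * hi)
    if (unstable_at(mid)) hi <- mid else lo <- mid
  }
  sqrt(lo * hi)
}

# finite-difference Jacobian of the non-spatial reaction system
numerical_jacobian <- function(A, config, x, h = 1e-6) {
  p <- config$params
  growth0 <- c(rep(config$a, p$N_u), rep(0, p$N_v))
  f <- function(x) x * (growth0 - x + as.vector(A$values %*% x))
  J <- matrix(0, length(x), length(x))
  for (j in seq_along(x)) {
    e <- rep(0, length(x)); e[j] <- h
    J[, j] <- (f(x + e) - f(x - e)) / (2 * h)
  }
  J
}
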