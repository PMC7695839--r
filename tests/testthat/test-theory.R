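# parameter sets with Gamma = 0 where closed forms exist (unequal d, D, q > 0)
gamma0_sets <- list(
  list(p = may_params(c = 0.5), q = 0),
  list(p = community_params(N = 1000, C = 0.2, c = 0.8, d_u = 1, d_v = 2), q = 0),
  list(p = community_params(N = 1000, N_u = 300, C = 0.2, c = 1.5,
                            d_u = 0.5, d_v = 1.5), q = 0),
  list(p = community_params(N = 1000, C = 0.2, c = 0.6, d_u = 1, d_v = 1,
                            D_u = 0.01, D_v = 1), q = 2),
  list(p = community_params(N = 1000, N_u = 700, C = 0.2, c = 1,
                            d_u = 2, d_v = 0.8, D_u = 0.05, D_v = 0.5), q = 1.5))

test_that("resolvent solver reduces to the closed form when correlations vanish", {
  for (s in gamma0_sets) {
    om <- complex(real = c(0.5, -0.2, 1), imaginary = c(1.5, 2.5, -2))
    r <- resolve_chi(s$p, s$q, om)
    hu <- s$p$d_u + s$q^2 * s$p$D_u
    hv <- s$p$d_v + s$q^2 * s$p$D_v
    expect_lt(max(Mod(r$chi_u - 1 / (om + hu))), 1e-10)
    expect_lt(max(Mod(r$chi_v - 1 / (om + hv))), 1e-10)
    expect_true(all(r$converged))
  }
})

test_that("correlation terms vanish at c = 0 regardless of Gamma", {
  p <- community_params(N = 500, C = 0.2, c = 0, Gamma_u = 0.9,
                        Gamma_v = -0.9, Gamma_uv = 0.7, d_u = 1, d_v = 3)
  om <- complex(real = 0.3, imaginary = 1.2)
  r <- resolve_chi(p, 0, om)
  expect_lt(Mod(r$chi_u - 1 / (om + 1)), 1e-12)
  expect_lt(Mod(r$chi_v - 1 / (om + 3)), 1e-12)
})

test_that("physical branch has chi ~ 1/omega asymptotics and tiny residual", {
  p <- community_params(N = 1000, C = 0.2, c = 1, m_uv = -4, m_vu = 4,
                        Gamma_u = 0.5, Gamma_v = -0.3, Gamma_uv = -0.5)
  om_far <- complex(real = 1e6, imaginary = 1e6)
  r <- resolve_chi(p, 0, om_far)
  expect_lt(Mod(r$chi_u * om_far - 1), 1e-4)
  expect_lt(Mod(r$chi_v * om_far - 1), 1e-4)
  # residual of the self-consistency relations at generic points
  om <- complex(real = c(0.5, -3, 0), imaginary = c(2, 1, 3))
  r2 <- resolve_chi(p, 1, om)
  expect_true(all(r2$residual <= 1e-10))
})

test_that("generic boundary solver matches the uncorrelated closed-form locus", {
  for (s in gamma0_sets) {
    b <- bulk_boundary(s$p, s$q, n_points = 60)
    res <- closed_form_locus_residual(s$p, s$q, b$curve$omega_x,
                                      b$curve$omega_y)
    expect_lt(max(abs(res)), 1e-8)
    expect_true(all(b$curve$omega_y >= 0))
  }
})

test_that("May-limit boundary is the circle of radius sqrt(c) and c* = 1", {
  b <- bulk_boundary(may_params(c = 0.5), 0)
  expect_equal(b$components, 1L)
  expect_equal(b$rightmost_x, sqrt(0.5) - 1, tolerance = 1e-9)
  radii <- sqrt((b$curve$omega_x + 1)^2 + b$curve$omega_y^2)
  expect_lt(max(abs(radii - sqrt(0.5))), 1e-8)
  thr <- may_threshold(tol = 1e-8)
  expect_equal(thr$c_star, 1, tolerance = 1e-7)
})

test_that("bulk degenerates at c = 0 and is empty of curve points", {
  b <- bulk_boundary(community_params(N = 100, C = 0.2, c = 0), 0)
  expect_equal(nrow(b$curve), 0)
  expect_equal(b$components, 0L)
})

test_that("uncorrelated outlier solver reproduces the quadratic closed form", {
  # worked example: h = 1, gamma = 1/2, m_uv = -4, m_vu = 4 -> omega = -1 +/- 2i
  p <- community_params(N = 1000, C = 0.2, c = 0.5, m_uv = -4, m_vu = 4)
  o <- outlier_eigenvalues(p, 0)
  adm <- o$values$omega[o$values$admissible]
  expect_equal(length(adm), 2L)
  expect_lt(min(Mod(adm - complex(real = -1, imaginary = 2))), 1e-10)
  expect_lt(min(Mod(adm - complex(real = -1, imaginary = -2))), 1e-10)
  # generic Gamma = 0 sets against the quadratic oracle
  for (s in gamma0_sets[2:5]) {
    p2 <- update_params(s$p, m_uu = 2, m_uv = -3, m_vu = 5, m_vv = -1)
    o2 <- outlier_eigenvalues(p2, s$q)
    oracle <- quadratic_outlier_oracle(p2, s$q)
    for (w in o2$values$omega) expect_lt(min(Mod(w - oracle)), 1e-10)
  }
})

test_that("no mean structure means no outliers", {
  o <- outlier_eigenvalues(may_params(c = 0.5), 0)
  expect_equal(nrow(o$values), 0)
  o2 <- outlier_eigenvalues(
    community_params(N = 500, C = 0.2, c = 0.5, Gamma_uv = -0.5), 2)
  expect_equal(nrow(o2$values), 0)
})

test_that("outliers converge to the block-mean eigenvalues as c -> 0", {
  p <- community_params(N = 1000, C = 0.2, c = 1e-8, m_uu = 3, m_uv = -4,
                        m_vu = 4, Gamma_u = 0.5, Gamma_uv = -0.5,
                        D_u = 0.01, D_v = 1)
  for (q in c(0, 3)) {
    o <- outlier_eigenvalues(p, q)
    oracle <- eigen(mean_matrix_2x2(p, q), only.values = TRUE)$values
    adm <- o$values$omega[o$values$admissible]
    expect_equal(length(adm), 2L)
    for (w in oracle) expect_lt(min(Mod(adm - w)), 1e-6)
  }
})

test_that("outlier sets are closed under conjugation", {
  p <- dispersal_instability_params(N = 1000)
  o <- outlier_eigenvalues(p, 0)
  for (w in o$values$omega[abs(Im(o$values$omega)) > 1e-10]) {
    expect_lt(min(Mod(o$values$omega - Conj(w))), 1e-8)
  }
})

test_that("bulk rightmost point is nondecreasing in complexity", {
  cs <- c(0.2, 0.5, 1, 1.5, 2.5)
  for (Gammas in list(c(0, 0, 0), c(0.5, 0, -0.5))) {
    rx <- vapply(cs, function(cc) {
      p <- community_params(N = 1000, C = 0.2, c = cc, Gamma_u = Gammas[1],
                            Gamma_v = Gammas[2], Gamma_uv = Gammas[3])
      bulk_boundary(p, 0, n_points = 40)$rightmost_x
    }, numeric(1))
    expect_true(all(diff(rx) > 0))
  }
})

test_that("theory dispersion: constant without diffusion, exact quadratic law
           for the structureless ensemble, (-,+,-) for the reference set", {
  qg <- c(0, 0.5, 1, 2, 4)
  p_noD <- community_params(N = 500, C = 0.2, c = 0.5, m_uv = -2, m_vu = 2)
  d0 <- dispersion_relation_theory(p_noD, qg)
  expect_lt(max(abs(d0$re_max - d0$re_max[1])), 1e-9)

  p_May <- may_params(c = 0.5, D = 0.05)
  d1 <- dispersion_relation_theory(p_May, qg)
  expect_equal(d1$re_max, d1$re_max[1] - 0.05 * qg^2, tolerance = 1e-9)

  p0 <- dispersal_instability_params()
  d2 <- dispersion_relation_theory(p0, default_q_grid(p0, n = 20))
  bands <- unstable_bands(d2)
  expect_equal(nrow(bands), 1L)
  expect_gt(bands$q_lo, 0)
  expect_lt(d2$re_max[1], 0)
  expect_lt(d2$re_max[nrow(d2)], 0)
})

test_that("tidy methods expose boundary and outliers as tables", {
  p <- dispersal_instability_params(N = 500)
  b <- tidy(bulk_boundary(p, 0, n_points = 30))
  expect_true(all(c("q", "omega_x", "omega_y", "component") %in% names(b)))
  o <- tidy(outlier_eigenvalues(p, 0))
  expect_true(all(c("q", "re", "im", "admissible") %in% names(o)))
})
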