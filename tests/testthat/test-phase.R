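test_that("May-limit classification recovers the complexity bound", {
  sc1 <- stability_class(may_params(c = 0.5), q_grid = c(0, 1))
  expect_equal(sc1$value, "stable")
  expect_equal(sc1$route, "none")
  sc2 <- stability_class(may_params(c = 1.5), q_grid = c(0, 1))
  expect_equal(sc2$value, "nonspatial_unstable")
  expect_equal(sc2$route, "bulk_q0")
  expect_error(stability_class(may_params(c = 0.5), q_grid = c(1, 2)),
               "include q = 0")
})

test_that("reference parameter set is dispersal-induced unstable with an
           interior critical wavenumber", {
  p0 <- dispersal_instability_params()
  sc <- stability_class(p0, default_q_grid(p0, n = 20))
  expect_equal(sc$value, "dispersal_induced_unstable")
  expect_equal(sc$route, "outlier_q_nonzero")
  expect_gt(sc$critical_q, 0)
  # the polished critical q maximizes re_max: compare against neighbours
  f <- function(q) {
    o <- outlier_eigenvalues(p0, q)
    max(Re(o$values$omega[o$values$admissible]))
  }
  expect_gte(f(sc$critical_q) + 1e-6, f(sc$critical_q * 0.9))
  expect_gte(f(sc$critical_q) + 1e-6, f(sc$critical_q * 1.1))
})

test_that("phase diagram: spatial stability is contained in non-spatial
           stability and regions nest correctly", {
  p0 <- dispersal_instability_params()
  pd <- scan_phase_diagram(p0, phase_axis("p", 0.5, 8, 10),
                           phase_axis("c", 0.05, 3, 12),
                           q_grid = default_q_grid(p0, n = 15),
                           refine = FALSE)
  cells <- pd$cells
  expect_true(all(!is.na(cells$class)))
  # every spatially stable cell is also non-spatially stable (re_q0 < 0)
  expect_true(all(cells$re_q0[cells$class == "stable"] < 0))
  # dispersal-induced cells are exactly those stable at q = 0, unstable beyond
  di <- cells$class == "dispersal_induced_unstable"
  expect_true(all(cells$re_q0[di] < 0 & cells$re_spatial[di] > 0))
  expect_gt(sum(di), 0)
  # upper bound on c: the top complexity row is never stable
  top <- cells[cells$axis2 == max(cells$axis2), ]
  expect_true(all(top$class != "stable"))
  # lower bound on p: small predation destabilizes even at small c
  low_p <- cells[cells$axis1 == min(cells$axis1) & cells$axis2 == min(cells$axis2), ]
  expect_true(all(low_p$class == "nonspatial_unstable"))
  # along each p column classes are ordered in c: stable below unstable
  for (col in split(cells, cells$axis1)) {
    col <- col[order(col$axis2), ]
    st <- col$class == "stable"
    if (any(st)) expect_true(all(which(st) <= max(which(st))))
    first_unstable <- which(col$class != "stable")
    if (length(first_unstable) && any(st)) {
      expect_true(min(which(st)) < min(first_unstable) ||
                    all(col$class[1] != "stable"))
    }
  }
})

test_that("equal diffusion coefficients forbid dispersal-induced instability", {
  p1 <- update_params(dispersal_instability_params(), D_v = 0.01)
  pd <- scan_phase_diagram(p1, phase_axis("p", 0.5, 8, 8),
                           phase_axis("c", 0.05, 3, 8),
                           q_grid = default_q_grid(p1, n = 12),
                           refine = FALSE)
  expect_equal(sum(pd$cells$class == "dispersal_induced_unstable"), 0)
})

test_that("threshold refinement brackets classification changes to 1e-3", {
  p0 <- dispersal_instability_params()
  pd <- scan_phase_diagram(p0, phase_axis("p", 3, 5, 3),
                           phase_axis("c", 0.1, 2.5, 8),
                           q_grid = default_q_grid(p0, n = 12),
                           refine = TRUE, tol = 1e-3)
  expect_gt(nrow(pd$thresholds), 0)
  # each threshold sits between differently classified neighbouring cells
  for (i in seq_len(nrow(pd$thresholds))) {
    thr <- pd$thresholds[i, ]
    col <- pd$cells[pd$cells$axis1 == thr$axis1, ]
    below <- col$class[max(which(col$axis2 <= thr$axis2))]
    above <- col$class[min(which(col$axis2 > thr$axis2))]
    expect_false(identical(below, above))
  }
})

test_that("critical diffusion ratio is nonincreasing in complexity and matches
           the two-species oracle at vanishing complexity", {
  p <- update_params(dispersal_instability_params(N = 100, C = 1), D_v = 0.01)
  cdr <- critical_diffusion_ratio(p, c_grid = c(1e-9, 0.3, 0.6),
                                  ratio_range = c(1, 1e4), tol = 1e-3)
  expect_true(all(cdr$status == "threshold"))
  expect_true(all(diff(cdr$ratio_star) <= 0))
  # c -> 0 limit against the independent 2x2 linear-stability oracle, scanned
  # over the same wavenumber grid so that both sides resolve the instability
  # band identically and only the methods differ
  qg <- default_q_grid(p, n = 25L)
  oracle_unstable <- function(ratio) {
    p2 <- update_params(p, c = 0, D_v = ratio * p$D_u)
    any(vapply(qg[qg > 0], function(q)
      max(Re(eigen(mean_matrix_2x2(p2, q), only.values = TRUE)$values)),
      numeric(1)) > 0)
  }
  lo <- 1; hi <- 1e4
  for (k in 1:40) {
    mid <- sqrt(lo * hi)
    if (oracle_unstable(mid)) hi <- mid else lo <- mid
  }
  expect_equal(cdr$ratio_star[1], sqrt(lo * hi), tolerance = 5e-3)
})
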