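#' Stability classification of one parameter set
#'
#' Classifies an equilibrium from the theory-side dispersion relation into
#' `stable` (rightmost predicted eigenvalue below zero for every scanned
#' wavenumber including `q = 0`), `dispersal_induced_unstable` (stable at
#' `q = 0`, unstable on a band of nonzero wavenumbers — a Turing-type
#' instability), or `nonspatial_unstable` (already unstable at `q = 0`). The
#' route records which spectral feature crosses first: the bulk at `q = 0`,
#' an outlier at `q = 0`, or an outlier at nonzero `q`. Bulk-driven
#' instability occurring at nonzero `q` only is never expected; it is
#' surfaced as a warning if encountered.
#'
#' @param params A [community_params()] object.
#' @param q_grid Wavenumber grid, which must include 0.
#' @param polish If `TRUE` (default), refine `critical_q` by golden-section
#'   search around the coarse grid argmax.
#' @return An object of class `stability_class`: list with `value`, `route`
#'   (`"bulk_q0"`, `"outlier_q0"`, `"outlier_q_nonzero"` or `"none"`),
#'   `critical_q` (argmax of `re_max` over `q`, `NA` unless the route is
#'   `outlier_q_nonzero`), and the underlying `dispersion` tibble.
#' @examples
#' stability_class(may_params(c = 0.5), q_grid = 0)
#' @export
stability_class <- function(params, q_grid = default_q_grid(params),
                            polish = TRUE) {
  stopifnot(inherits(params, "community_params"))
  if (!any(q_grid == 0)) stop("stability_class: q_grid must include q = 0")
  disp <- dispersion_relation_theory(params, q_grid)
  at0 <- disp[disp$q == 0, ]
  pos <- disp[disp$q > 0, ]
  critical_q <- NA_real_
  if (at0$re_max > 0) {
    value <- "nonspatial_unstable"
    route <- if (at0$re_bulk > 0) "bulk_q0" else "outlier_q0"
  } else if (nrow(pos) && any(pos$re_max > 0)) {
    value <- "dispersal_induced_unstable"
    route <- "outlier_q_nonzero"
    if (any(pos$re_bulk > 0 & pos$re_outlier <= 0)) {
      warning("bulk-driven instability at nonzero q without q = 0 instability; ",
              "this is not expected for this ensemble")
    }
    i <- which.max(pos$re_max)
    critical_q <- pos$q[i]
    if (polish) {
      lo <- if (i > 1) pos$q[i - 1] else 0
      hi <- if (i < nrow(pos)) pos$q[i + 1] else pos$q[i] * 1.5
      critical_q <- golden_max(function(q) theory_re_max(params, q), lo, hi)
    }
  } else {
    value <- "stable"
    route <- "none"
  }
  structure(list(value = value, route = route, critical_q = critical_q,
                 dispersion = disp, params = params),
            class = "stability_class")
}

#' @export
print.stability_class <- function(x, ...) {
  cat(sprintf("<stability_class> %s (route: %s", x$value, x$route))
  if (!is.na(x$critical_q)) cat(sprintf(", critical q = %.4g", x$critical_q))
  cat(")\n")
  invisible(x)
}

theory_re_max <- function(params, q) {
  o <- outlier_eigenvalues(params, q)
  ro <- if (any(o$values$admissible))
    max(Re(o$values$omega[o$values$admissible])) else -Inf
  max(bulk_rightmost(params, q), ro)
}

golden_max <- function(f, lo, hi, tol = 1e-4, max_iter = 40L) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  for (k in seq_len(max_iter)) {
    if (b - a < tol) break
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- f(x1)
    }
  }
  (a + b) / 2
}

#' Axis specification for phase-diagram scans
#'
#' @param param Parameter to vary: any numeric field of [community_params()],
#'   or `"p"` (predation: sets `m_vu = p`, `m_uv = -loss_gain_ratio * p`) or
#'   `"D_ratio"` (sets `D_v = D_ratio * D_u`).
#' @param from,to Range endpoints.
#' @param n Number of grid points.
#' @param log If `TRUE`, space the grid geometrically.
#' @return A `phase_axis` list used by [scan_phase_diagram()].
#' @export
phase_axis <- function(param, from, to, n = 40L, log = FALSE) {
  stopifnot(is.character(param), length(param) == 1L, from < to, n >= 2)
  values <- if (log) exp(seq(base::log(from), base::log(to), length.out = n))
            else seq(from, to, length.out = n)
  structure(list(param = param, values = values, log = log),
            class = "phase_axis")
}

apply_axis <- function(params, name, value, loss_gain_ratio = 1) {
  if (name == "p") {
    update_params(params, m_vu = value, m_uv = -loss_gain_ratio * value)
  } else if (name == "D_ratio") {
    update_params(params, D_v = value * params$D_u)
  } else {
    args <- stats::setNames(list(value), name)
    do.call(update_params, c(list(params), args))
  }
}

# ---- vectorized classification engine ---------------------------------------
# Classifies a list of parameter sets over one q grid. Bulk rightmost points
# are computed once per unique bulk-relevant parameter combination; outlier
# roots are solved for all cells simultaneously by the vectorized Newton
# iteration (seeded from the exact Gamma = 0 quadratic roots at each q).
classify_cells <- function(cells, q_grid) {
  n <- length(cells)
  grab <- function(f) vapply(cells, `[[`, numeric(1), f)
  cvec <- grab("c")
  bulk_key <- paste(cvec, grab("Gamma_u"), grab("Gamma_v"), grab("Gamma_uv"),
                    grab("gamma_u"), grab("d_u"), grab("d_v"))
  uk <- !duplicated(bulk_key)
  re_bulk0 <- vapply(cells[uk], function(p) bulk_rightmost(p, 0, tol = 1e-10),
                     numeric(1))[match(bulk_key, bulk_key[uk])]

  outlier_re <- function(q, active) {
    idx <- which(active)
    seeds <- unlist(lapply(cells[idx], outlier_quadratic_roots, q = q))
    rep2 <- rep(idx, each = 2L)
    cf <- list(
      hu = grab("d_u")[rep2] + q^2 * grab("D_u")[rep2],
      hv = grab("d_v")[rep2] + q^2 * grab("D_v")[rep2],
      au = (cvec * grab("Gamma_u") * grab("gamma_u"))[rep2],
      bu = (cvec * grab("Gamma_uv") * grab("gamma_v"))[rep2],
      av = (cvec * grab("Gamma_v") * grab("gamma_v"))[rep2],
      bv = (cvec * grab("Gamma_uv") * grab("gamma_u"))[rep2],
      gamma_u = grab("gamma_u")[rep2], gamma_v = grab("gamma_v")[rep2],
      c = cvec[rep2])
    pv <- list(gamma_u = cf$gamma_u, gamma_v = cf$gamma_v,
               m_uu = grab("m_uu")[rep2], m_vv = grab("m_vv")[rep2],
               m_uv = grab("m_uv")[rep2], m_vu = grab("m_vu")[rep2])
    r <- outlier_newton_multi(seeds, cf, pv, iters = 40L)
    good <- r$fval <= 1e-8 & r$indicator < 0
    re <- ifelse(good, Re(r$omega), -Inf)
    # no convergent admissible root means no outlier: a valid outcome
    out <- rep(-Inf, n)
    agg <- tapply(re, rep2, max)
    out[as.integer(names(agg))] <- agg
    out
  }

  re_out0 <- outlier_re(0, rep(TRUE, n))
  re0 <- pmax(re_bulk0, re_out0)
  nonspatial <- re0 > 0

  re_spatial <- rep(-Inf, n)
  best_q <- rep(NA_real_, n)
  active <- !nonspatial & !is.na(re0)
  for (q in q_grid[q_grid > 0]) {
    if (!any(active)) break
    rq <- outlier_re(q, active)
    better <- active & !is.na(rq) & rq > re_spatial
    re_spatial[better] <- rq[better]
    best_q[better] <- q
  }

  cls <- ifelse(is.na(re0), NA_character_,
         ifelse(nonspatial, "nonspatial_unstable",
         ifelse(re_spatial > 0, "dispersal_induced_unstable", "stable")))
  route <- ifelse(is.na(cls), NA_character_,
           ifelse(cls == "nonspatial_unstable",
                  ifelse(re_bulk0 > 0, "bulk_q0", "outlier_q0"),
           ifelse(cls == "dispersal_induced_unstable", "outlier_q_nonzero",
                  "none")))
  tibble::tibble(class = cls, route = route,
                 re_q0 = re0, re_spatial = re_spatial,
                 critical_q = ifelse(!is.na(cls) &
                                       cls == "dispersal_induced_unstable",
                                     best_q, NA_real_))
}

# outlier_newton generalised to per-element mean parameters
outlier_newton_multi <- function(omega, cf, pv, iters = 40L) {
  su <- pv$gamma_u * pv$m_uu
  sv <- pv$gamma_v * pv$m_vv
  K <- pv$gamma_u * pv$gamma_v * pv$m_uv * pv$m_vu
  s <- chi_path(omega, cf)
  chi_u <- s$chi_u; chi_v <- s$chi_v
  for (k in seq_len(iters)) {
    Fo <- (su - 1 / chi_u) * (sv - 1 / chi_v) - K
    J11 <- -(omega + cf$hu) + 2 * cf$au * chi_u + cf$bu * chi_v
    J12 <- cf$bu * chi_u
    J21 <- cf$bv * chi_v
    J22 <- -(omega + cf$hv) + cf$bv * chi_u + 2 * cf$av * chi_v
    det <- J11 * J22 - J12 * J21
    dchi_u <- (chi_u * J22 - chi_v * J12) / det
    dchi_v <- (J11 * chi_v - J21 * chi_u) / det
    dF <- (dchi_u / chi_u^2) * (sv - 1 / chi_v) +
      (su - 1 / chi_u) * (dchi_v / chi_v^2)
    step <- Fo / dF
    step[!is.finite(step)] <- 0
    big <- Mod(step) > 0.5
    step[big] <- 0.5 * step[big] / Mod(step[big])
    if (max(Mod(step)) < 1e-13) break
    omega <- omega - step
    s <- chi_newton(omega, cf, chi_u, chi_v, iters = 5L)
    chi_u <- s$chi_u; chi_v <- s$chi_v
  }
  Fo <- (su - 1 / chi_u) * (sv - 1 / chi_v) - K
  indicator <- cf$gamma_u * Mod(chi_u)^2 + cf$gamma_v * Mod(chi_v)^2 - 1 / cf$c
  list(omega = omega, fval = Mod(Fo) + s$residual, indicator = indicator)
}

#' Scan a two-parameter stability phase diagram
#'
#' Classifies every cell of a two-axis parameter grid (see [phase_axis()])
#' into stable / dispersal-induced unstable / non-spatially unstable, and
#' refines the classification-change thresholds along the second axis by
#' bisection. This reproduces the structure of the predation-complexity and
#' complexity-diffusion-ratio stability diagrams.
#'
#' @param params Base [community_params()]; axis parameters override fields.
#' @param axis1,axis2 [phase_axis()] specifications.
#' @param q_grid Wavenumber grid used for each cell (0 is prepended if
#'   absent).
#' @param loss_gain_ratio Coupling used by the `"p"` axis: `m_uv = -r * m_vu`.
#' @param refine If `TRUE` (default), bisection-refine threshold curves along
#'   `axis2` to `tol`.
#' @param tol Bisection tolerance in the `axis2` parameter (default `1e-3`).
#' @return An object of class `phase_diagram`: list with `cells` (tibble:
#'   `axis1`, `axis2`, `class`, `route`, `critical_q`), `thresholds` (tibble:
#'   `axis1`, `axis2`, `transition`), axis metadata, `params`.
#' @export
scan_phase_diagram <- function(params, axis1, axis2,
                               q_grid = default_q_grid(params, n = 25L),
                               loss_gain_ratio = 1,
                               refine = TRUE, tol = 1e-3) {
  stopifnot(inherits(params, "community_params"),
            inherits(axis1, "phase_axis"), inherits(axis2, "phase_axis"))
  if (!any(q_grid == 0)) q_grid <- c(0, q_grid)
  grid <- tidyr::expand_grid(a1 = axis1$values, a2 = axis2$values)
  cells <- purrr::map2(grid$a1, grid$a2, function(v1, v2) {
    p <- apply_axis(params, axis1$param, v1, loss_gain_ratio)
    apply_axis(p, axis2$param, v2, loss_gain_ratio)
  })
  res <- classify_cells(cells, q_grid)
  cells_tbl <- dplyr::bind_cols(
    tibble::tibble(axis1 = grid$a1, axis2 = grid$a2), res)

  thresholds <- tibble::tibble(axis1 = numeric(), axis2 = numeric(),
                               transition = character())
  if (refine) {
    thresholds <- refine_thresholds(params, axis1, axis2, cells_tbl,
                                    q_grid, loss_gain_ratio, tol)
  }
  structure(list(cells = cells_tbl, thresholds = thresholds,
                 axis1 = axis1, axis2 = axis2, q_grid = q_grid,
                 params = params),
            class = "phase_diagram")
}

# bisection refinement of class changes along axis2, vectorized across the
# axis1 columns (all brackets advance together; 30-iteration cap)
refine_thresholds <- function(params, axis1, axis2, cells_tbl, q_grid,
                              loss_gain_ratio, tol) {
  cols <- split(cells_tbl, cells_tbl$axis1)
  brackets <- purrr::list_rbind(purrr::map(cols, function(col) {
    col <- col[order(col$axis2), ]
    ch <- which(col$class[-1] != col$class[-nrow(col)] &
                  !is.na(col$class[-1]) & !is.na(col$class[-nrow(col)]))
    if (!length(ch)) return(NULL)
    tibble::tibble(axis1 = col$axis1[1],
                   lo = col$axis2[ch], hi = col$axis2[ch + 1L],
                   class_lo = col$class[ch], class_hi = col$class[ch + 1L])
  }))
  if (is.null(brackets) || !nrow(brackets)) {
    return(tibble::tibble(axis1 = numeric(), axis2 = numeric(),
                          transition = character()))
  }
  for (it in 1:30) {
    if (max(brackets$hi - brackets$lo) < tol) break
    mid <- (brackets$lo + brackets$hi) / 2
    cells <- purrr::map2(brackets$axis1, mid, function(v1, v2) {
      p <- apply_axis(params, axis1$param, v1, loss_gain_ratio)
      apply_axis(p, axis2$param, v2, loss_gain_ratio)
    })
    cls <- classify_cells(cells, q_grid)$class
    same_lo <- !is.na(cls) & cls == brackets$class_lo
    brackets$lo <- ifelse(same_lo, mid, brackets$lo)
    brackets$hi <- ifelse(same_lo, brackets$hi, mid)
  }
  tibble::tibble(axis1 = brackets$axis1,
                 axis2 = (brackets$lo + brackets$hi) / 2,
                 transition = paste(brackets$class_lo, "->",
                                    brackets$class_hi))
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("<phase_diagram> %s x %s, %d x %d cells\n",
              x$axis1$param, x$axis2$param,
              length(x$axis1$values), length(x$axis2$values)))
  print(dplyr::count(x$cells, .data$class))
  invisible(x)
}

#' @export
tidy.phase_diagram <- function(x, ...) x$cells

#' @export
glance.phase_diagram <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$cells),
    n_stable = sum(x$cells$class == "stable", na.rm = TRUE),
    n_dispersal_induced = sum(x$cells$class == "dispersal_induced_unstable",
                              na.rm = TRUE),
    n_nonspatial = sum(x$cells$class == "nonspatial_unstable", na.rm = TRUE),
    n_indeterminate = sum(is.na(x$cells$class)))
}

#' Critical diffusion ratio for Turing instability as a function of complexity
#'
#' For each complexity value, bisects on `D_v / D_u` (log scale) for the onset
#' of dispersal-induced instability: the smallest diffusion ratio at which the
#' community, stable as a non-spatial system, becomes unstable against some
#' nonzero wavenumber. Cells whose `q = 0` equilibrium is already unstable get
#' `NA` (the ratio is then irrelevant: the equilibrium is unstable regardless
#' of dispersal).
#'
#' @param params Base [community_params()] (its `D_u` is held fixed).
#' @param c_grid Complexity values to scan.
#' @param ratio_range Search interval for `D_v / D_u` (default `c(1, 1e4)`).
#' @param q_grid Wavenumber grid (0 prepended if absent).
#' @param tol Relative bisection tolerance on the ratio (default `1e-3`).
#' @return Tibble with columns `c`, `ratio_star`, `status`
#'   (`"threshold"`, `"nonspatial_unstable"`, `"no_instability_in_range"`,
#'   or `"unstable_at_lower_bound"`).
#' @export
critical_diffusion_ratio <- function(params, c_grid,
                                     ratio_range = c(1, 1e4),
                                     q_grid = default_q_grid(params, n = 25L),
                                     tol = 1e-3) {
  stopifnot(inherits(params, "community_params"))
  if (!any(q_grid == 0)) q_grid <- c(0, q_grid)
  make_cell <- function(cc, ratio)
    update_params(params, c = cc, D_v = ratio * params$D_u)

  cls_at <- function(cc_vec, ratio_vec) {
    cells <- purrr::map2(cc_vec, ratio_vec, make_cell)
    classify_cells(cells, q_grid)$class
  }
  n <- length(c_grid)
  lo_cls <- cls_at(c_grid, rep(ratio_range[1], n))
  hi_cls <- cls_at(c_grid, rep(ratio_range[2], n))
  status <- rep("threshold", n)
  status[lo_cls == "nonspatial_unstable"] <- "nonspatial_unstable"
  status[lo_cls == "dispersal_induced_unstable"] <- "unstable_at_lower_bound"
  status[lo_cls == "stable" & hi_cls == "stable"] <- "no_instability_in_range"

  lo <- base::log(rep(ratio_range[1], n))
  hi <- base::log(rep(ratio_range[2], n))
  act <- status == "threshold"
  for (it in 1:40) {
    if (!any(act) || max(hi[act] - lo[act]) < tol) break
    mid <- (lo + hi) / 2
    cls <- rep(NA_character_, n)
    cls[act] <- cls_at(c_grid[act], exp(mid[act]))
    turing <- !is.na(cls) & cls == "dispersal_induced_unstable"
    hi <- ifelse(act & turing, mid, hi)
    lo <- ifelse(act & !turing, mid, lo)
  }
  tibble::tibble(c = c_grid,
                 ratio_star = ifelse(status == "threshold", exp((lo + hi) / 2),
                              ifelse(status == "unstable_at_lower_bound",
                                     ratio_range[1], NA_real_)),
                 status = status)
}

#' Critical complexity of the structureless (May) ensemble
#'
#' Bisects on the complexity `c` for the point at which the rightmost point of
#' the theoretical bulk boundary crosses zero at `q = 0`, in the structureless
#' single-block limit (zero means, zero correlations, uniform self-regulation
#' `d`). The classical bound gives `c* = d^2`; with `d = 1`, `c* = 1`.
#'
#' @param d Common self-regulation coefficient (default 1).
#' @param c_range Bisection bracket (default `c(0.05, 4)`).
#' @param tol Absolute tolerance on `c*` (default `1e-8`).
#' @return List with `c_star` and `iterations`.
#' @export
may_threshold <- function(d = 1, c_range = c(0.05, 4), tol = 1e-8) {
  f <- function(cc) bulk_rightmost(may_params(c = cc, d = d), 0)
  lo <- c_range[1]; hi <- c_range[2]
  if (f(lo) >= 0 || f(hi) <= 0)
    stop("may_threshold: bracket does not straddle the stability boundary")
  it <- 0L
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    it <- it + 1L
  }
  list(c_star = (lo + hi) / 2, iterations = it)
}
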