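# Coefficients of the resolvent self-consistency system at wavenumber q.
# hu/hv are the diagonal dampings d_alpha + q^2 D_alpha; au, bu, av, bv the
# quadratic coupling coefficients c*Gamma*gamma entering the chi equations.
theory_coefs <- function(params, q) {
  list(hu = params$d_u + q^2 * params$D_u,
       hv = params$d_v + q^2 * params$D_v,
       au = params$c * params$Gamma_u * params$gamma_u,
       bu = params$c * params$Gamma_uv * params$gamma_v,
       av = params$c * params$Gamma_v * params$gamma_v,
       bv = params$c * params$Gamma_uv * params$gamma_u,
       gamma_u = params$gamma_u, gamma_v = params$gamma_v, c = params$c)
}

# Damped Newton iterations on the coupled chi system
#   0 = 1 - (omega + h_a) chi_a + a_a chi_a^2 + b_a chi_a chi_b
# All arguments vectorized and recycled; returns chi pair and residual.
chi_newton <- function(omega, cf, chi_u, chi_v, iters = 6L) {
  for (k in seq_len(iters)) {
    Fu <- 1 - (omega + cf$hu) * chi_u + cf$au * chi_u^2 + cf$bu * chi_u * chi_v
    Fv <- 1 - (omega + cf$hv) * chi_v + cf$bv * chi_u * chi_v + cf$av * chi_v^2
    J11 <- -(omega + cf$hu) + 2 * cf$au * chi_u + cf$bu * chi_v
    J12 <- cf$bu * chi_u
    J21 <- cf$bv * chi_v
    J22 <- -(omega + cf$hv) + cf$bv * chi_u + 2 * cf$av * chi_v
    det <- J11 * J22 - J12 * J21
    du <- (Fu * J22 - Fv * J12) / det
    dv <- (J11 * Fv - J21 * Fu) / det
    ok <- is.finite(du) & is.finite(dv)
    chi_u <- ifelse(ok, chi_u - du, chi_u)
    chi_v <- ifelse(ok, chi_v - dv, chi_v)
  }
  Fu <- 1 - (omega + cf$hu) * chi_u + cf$au * chi_u^2 + cf$bu * chi_u * chi_v
  Fv <- 1 - (omega + cf$hv) * chi_v + cf$bv * chi_u * chi_v + cf$av * chi_v^2
  list(chi_u = chi_u, chi_v = chi_v, residual = pmax(Mod(Fu), Mod(Fv)))
}

# Physical-branch chi(omega): seeded from the exact Gamma = 0 closed form
# chi_a = 1/(omega + h_a) far above the real axis, carried to full coupling by
# homotopy in the quadratic coefficients, then continued down to the target
# omega. The physical branch is pinned by chi ~ 1/omega as |omega| -> Inf.
chi_path <- function(omega, cf, n_gamma = 6L, n_path = 18L) {
  scale <- sqrt(abs(cf$au) + abs(cf$bu) + abs(cf$av) + abs(cf$bv) + 1)
  S0 <- 3 + 3 * max(scale)
  om <- omega + 1i * S0
  chi_u <- 1 / (om + cf$hu)
  chi_v <- 1 / (om + cf$hv)
  for (t in seq(0, 1, length.out = n_gamma)[-1L]) {
    cft <- cf
    cft$au <- t * cf$au; cft$bu <- t * cf$bu
    cft$av <- t * cf$av; cft$bv <- t * cf$bv
    s <- chi_newton(om, cft, chi_u, chi_v, iters = 5L)
    chi_u <- s$chi_u; chi_v <- s$chi_v
  }
  for (f in seq(1, 0, length.out = n_path + 1L)[-1L]) {
    s <- chi_newton(omega + 1i * S0 * f, cf, chi_u, chi_v, iters = 4L)
    chi_u <- s$chi_u; chi_v <- s$chi_v
  }
  chi_newton(omega, cf, chi_u, chi_v, iters = 8L)
}

#' Physical-branch resolvent quantities \eqn{\chi_u(\omega)}, \eqn{\chi_v(\omega)}
#'
#' Solves the coupled self-consistency system
#' \deqn{-1 = -(\omega + d_\alpha + q^2 D_\alpha)\chi_\alpha
#'       + c\Gamma_\alpha\gamma_\alpha\chi_\alpha^2
#'       + c\Gamma_{uv}\gamma_\beta\chi_\beta\chi_\alpha}
#' for the block-resolved resolvent traces, selecting the physical branch
#' (\eqn{\chi_\alpha \to 1/(\omega + d_\alpha + q^2 D_\alpha)} as
#' \eqn{|\omega|\to\infty}) by homotopy from the uncorrelated closed form.
#'
#' @param params A [community_params()] object.
#' @param q Nonnegative wavenumber.
#' @param omega Complex vector of spectral points.
#' @return A tibble with columns `omega`, `chi_u`, `chi_v`, `residual`,
#'   `converged`. A residual above `1e-10` marks a branch-tracking failure and
#'   is reported (`converged = FALSE`), never silently returned as a root.
#' @export
resolve_chi <- function(params, q, omega) {
  stopifnot(inherits(params, "community_params"), q >= 0)
  cf <- theory_coefs(params, q)
  s <- chi_path(as.complex(omega), cf)
  tibble::tibble(omega = as.complex(omega),
                 chi_u = s$chi_u, chi_v = s$chi_v,
                 residual = s$residual, converged = s$residual <= 1e-10)
}

#' Bulk support indicator
#'
#' Evaluates \eqn{\sum_\alpha \gamma_\alpha |\chi_\alpha(\omega)|^2 - 1/c} on
#' the physical resolvent branch. The bulk eigenvalue support is the region
#' where the indicator is nonnegative; its zero level set is the bulk
#' boundary, and an outlier eigenvalue is admissible only where the indicator
#' is strictly negative.
#'
#' @inheritParams resolve_chi
#' @return Numeric vector of indicator values (`-Inf` for `c = 0`, where the
#'   bulk degenerates to points).
#' @export
support_indicator <- function(params, q, omega) {
  if (params$c == 0) return(rep(-Inf, length(omega)))
  cf <- theory_coefs(params, q)
  s <- chi_path(as.complex(omega), cf)
  cf$gamma_u * Mod(s$chi_u)^2 + cf$gamma_v * Mod(s$chi_v)^2 - 1 / cf$c
}

# Indicator from coefficient list, reusing a chi solution when supplied.
indicator_cf <- function(omega, cf) {
  s <- chi_path(omega, cf)
  cf$gamma_u * Mod(s$chi_u)^2 + cf$gamma_v * Mod(s$chi_v)^2 - 1 / cf$c
}

# Vectorized "support present at real part x" test: max of the indicator over
# a ladder of heights above the real axis. x may be a vector.
support_at_x <- function(x, cf, y_grid) {
  om <- outer(x, y_grid, function(a, b) complex(real = a, imaginary = b))
  I <- indicator_cf(as.vector(om), cf)
  apply(matrix(I, nrow = length(x)), 1L, max)
}

# Rightmost real part of the bulk support at wavenumber q (scalar params).
# Scans the real axis (plus a ladder of imaginary offsets to catch lobes that
# peak off-axis), then refines the rightmost crossing by bisection.
bulk_rightmost <- function(params, q, n_scan = 101L, tol = 1e-12) {
  if (params$c == 0) return(-min(params$d_u + q^2 * params$D_u,
                                 params$d_v + q^2 * params$D_v))
  cf <- theory_coefs(params, q)
  r <- sqrt(cf$c) * (1 + max(abs(params$Gamma_u), abs(params$Gamma_v),
                             abs(params$Gamma_uv)))
  y_grid <- c(0, 0.25, 0.6, 1, 1.5) * max(sqrt(cf$c), 0.5)
  # the support lies in lobes near the block centres -h_u, -h_v; scan windows
  # around each rather than the (possibly vast) full range between them
  xs <- sort(unique(c(
    seq(-cf$hu - 3 * r - 1, -cf$hu + 3 * r + 1, length.out = n_scan),
    seq(-cf$hv - 3 * r - 1, -cf$hv + 3 * r + 1, length.out = n_scan))))
  g <- support_at_x(xs, cf, y_grid)
  inside <- which(g > 0)
  if (!length(inside)) {
    stop("bulk_rightmost: no bulk support found on the scan range; ",
         "the continuation along the support indicator failed")
  }
  lo <- xs[max(inside)]
  hi <- if (max(inside) < length(xs)) xs[max(inside) + 1L] else lo + r
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (support_at_x(mid, cf, y_grid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Boundary of the bulk eigenvalue spectrum
#'
#' Computes the closed curve(s) in the complex plane bounding the bulk of the
#' eigenvalues of the stability matrix at wavenumber `q`, as the zero level
#' set of the support indicator: points where
#' \eqn{\sum_\alpha \gamma_\alpha|\chi_\alpha|^2 = 1/c} holds simultaneously
#' with the resolvent self-consistency relations. For each real part in a
#' scan across the support, the boundary height is found by bisection from
#' above (outside the support); the curve is closed by conjugate reflection.
#'
#' @inheritParams resolve_chi
#' @param n_points Number of real-part scan points per disjoint component.
#' @return An object of class `bulk_boundary`: list with `curve` (tibble of
#'   `omega_x`, `omega_y >= 0`, `component`), `rightmost_x`, `components`,
#'   `q`, `params`. At `c = 0` the bulk degenerates to points and the curve
#'   is empty.
#' @examples
#' b <- bulk_boundary(may_params(c = 0.5), q = 0)
#' b$rightmost_x  # sqrt(0.5) - 1
#' @export
bulk_boundary <- function(params, q, n_points = 120L) {
  stopifnot(inherits(params, "community_params"), q >= 0)
  empty <- tibble::tibble(omega_x = numeric(), omega_y = numeric(),
                          component = integer())
  if (params$c == 0) {
    return(structure(list(curve = empty, rightmost_x = NA_real_,
                          components = 0L, q = q, params = params),
                     class = "bulk_boundary"))
  }
  cf <- theory_coefs(params, q)
  r <- sqrt(cf$c) * (1 + max(abs(params$Gamma_u), abs(params$Gamma_v),
                             abs(params$Gamma_uv)))
  y_grid <- c(0, 0.25, 0.6, 1, 1.5) * max(sqrt(cf$c), 0.5)
  y_max <- 2.5 * r + 0.5

  xs <- sort(unique(c(
    seq(-cf$hu - 3 * r - 1, -cf$hu + 3 * r + 1, length.out = 161L),
    seq(-cf$hv - 3 * r - 1, -cf$hv + 3 * r + 1, length.out = 161L))))
  g <- support_at_x(xs, cf, y_grid)
  runs <- split(which(g > 0), cumsum(c(1, diff(which(g > 0)) != 1)))
  if (!length(runs)) {
    stop("bulk_boundary: no support found; indicator continuation failed")
  }
  refine_edge <- function(x_in, x_out) {
    for (k in 1:45) {
      mid <- (x_in + x_out) / 2
      if (support_at_x(mid, cf, y_grid) > 0) x_in <- mid else x_out <- mid
    }
    (x_in + x_out) / 2
  }
  curves <- purrr::imap(runs, function(idx, comp) {
    left <- if (min(idx) > 1) refine_edge(xs[min(idx)], xs[min(idx) - 1L]) else xs[min(idx)]
    right <- if (max(idx) < length(xs)) refine_edge(xs[max(idx)], xs[max(idx) + 1L]) else xs[max(idx)]
    gx <- seq(left, right, length.out = n_points)
    # vectorized bisection in omega_y from outside the support
    lo <- rep(0, n_points)
    hi <- rep(y_max, n_points)
    for (k in 1:45) {
      mid <- (lo + hi) / 2
      I <- indicator_cf(complex(real = gx, imaginary = mid), cf)
      inside <- I > 0
      lo <- ifelse(inside, mid, lo)
      hi <- ifelse(inside, hi, mid)
    }
    tibble::tibble(omega_x = gx, omega_y = (lo + hi) / 2,
                   component = as.integer(comp))
  })
  curve <- dplyr::bind_rows(curves)
  structure(list(curve = curve,
                 rightmost_x = max(curve$omega_x),
                 components = length(runs), q = q, params = params),
            class = "bulk_boundary")
}

#' @export
print.bulk_boundary <- function(x, ...) {
  cat(sprintf("<bulk_boundary> q = %g, %d component(s), rightmost Re = %.6g\n",
              x$q, x$components, x$rightmost_x))
  invisible(x)
}

# Closed-form outlier equation at Gamma = 0: quadratic in omega,
# (omega + hu - gamma_u m_uu)(omega + hv - gamma_v m_vv) = gamma_u gamma_v m_uv m_vu.
# Used to seed the generic solver (and exact at c = 0 or Gamma = 0).
outlier_quadratic_roots <- function(params, q) {
  hu <- params$d_u + q^2 * params$D_u
  hv <- params$d_v + q^2 * params$D_v
  su <- hu - params$gamma_u * params$m_uu
  sv <- hv - params$gamma_v * params$m_vv
  K <- params$gamma_u * params$gamma_v * params$m_uv * params$m_vu
  disc <- sqrt(as.complex((su - sv)^2 + 4 * K))
  c((-(su + sv) + disc) / 2, (-(su + sv) - disc) / 2)
}

#' Outlier eigenvalues predicted by the block-mean structure
#'
#' Solves the outlier condition
#' \deqn{\left[\gamma_u m_{uu} - 1/\chi_u(\omega)\right]
#'       \left[\gamma_v m_{vv} - 1/\chi_v(\omega)\right]
#'       = \gamma_u\gamma_v m_{uv} m_{vu}}
#' simultaneously with the resolvent relations, by Newton iteration from a
#' deterministic multistart grid seeded at the exact uncorrelated
#' (`Gamma = 0`) quadratic roots. Each root is checked against the support
#' condition \eqn{\sum_\alpha\gamma_\alpha|\chi_\alpha|^2 < 1/c}: roots
#' violating it sit inside the bulk and are flagged inadmissible. Finding no
#' solutions is a valid outcome (no mean structure, no outliers).
#'
#' @inheritParams resolve_chi
#' @return An object of class `outlier_set`: list with `values` (tibble of
#'   `omega`, `admissible`, `near_edge`), `q`, `params`. `near_edge` flags
#'   roots whose support indicator is within `1e-3` of the boundary, where
#'   finite-size outlier-bulk merging makes admissibility delicate.
#' @examples
#' p <- community_params(N = 1000, C = 0.2, c = 1e-9, m_uv = -4, m_vu = 4)
#' outlier_eigenvalues(p, q = 0)  # -1 + 2i and -1 - 2i
#' @export
outlier_eigenvalues <- function(params, q) {
  stopifnot(inherits(params, "community_params"), q >= 0)
  no_mean <- params$m_uu == 0 && params$m_vv == 0 &&
    (params$m_uv == 0 || params$m_vu == 0)
  out_tbl <- tibble::tibble(omega = complex(), admissible = logical(),
                            near_edge = logical())
  if (no_mean) {
    return(structure(list(values = out_tbl, q = q, params = params),
                     class = "outlier_set"))
  }
  if (params$c == 0) {
    om <- outlier_quadratic_roots(params, q)
    out_tbl <- tibble::tibble(omega = om,
                              admissible = TRUE, near_edge = FALSE)
    return(structure(list(values = dedupe_conjugate(out_tbl), q = q,
                          params = params), class = "outlier_set"))
  }
  cf <- theory_coefs(params, q)
  seeds0 <- outlier_quadratic_roots(params, q)
  shifts <- c(0, 0.4, -0.4, 0.4i, -0.4i, 0.8 + 0.8i, 0.8 - 0.8i)
  seeds <- as.vector(outer(seeds0, shifts, `+`))
  roots <- outlier_newton(seeds, cf, params)
  ok <- roots$fval <= 1e-10 & is.finite(roots$omega)
  om <- roots$omega[ok]
  ind <- roots$indicator[ok]
  if (length(om)) {
    keep <- !duplicated(round(Re(om), 8) + 1i * round(Im(om), 8))
    # merge at tolerance 1e-8
    om_k <- om[keep][1]
    ind_k <- ind[keep][1]
    for (i in seq_along(om[keep])[-1]) {
      w <- om[keep][i]
      if (all(Mod(w - om_k) > 1e-8)) {
        om_k <- c(om_k, w)
        ind_k <- c(ind_k, ind[keep][i])
      }
    }
    out_tbl <- tibble::tibble(omega = om_k,
                              admissible = ind_k < 0,
                              near_edge = abs(ind_k) < 1e-3)
  }
  structure(list(values = dedupe_conjugate(out_tbl), q = q, params = params),
            class = "outlier_set")
}

# enforce closure under conjugation and a deterministic ordering
dedupe_conjugate <- function(tbl) {
  if (!nrow(tbl)) return(tbl)
  extra <- dplyr::filter(tbl, abs(Im(.data$omega)) > 1e-12)
  extra$omega <- Conj(extra$omega)
  out <- dplyr::bind_rows(tbl, extra)
  out <- out[!duplicated(round(Re(out$omega), 9) + 1i * round(abs(Im(out$omega)), 9) *
                           sign(Im(out$omega))), , drop = FALSE]
  dplyr::arrange(out, dplyr::desc(Re(.data$omega)), Im(.data$omega))
}

# Vectorized Newton on the outlier condition F(omega) = 0 with chi carried as
# a warm start between omega updates; derivative dF/domega obtained exactly by
# implicit differentiation of the chi system.
outlier_newton <- function(omega, cf, params, iters = 60L) {
  su <- params$gamma_u * params$m_uu
  sv <- params$gamma_v * params$m_vv
  K <- params$gamma_u * params$gamma_v * params$m_uv * params$m_vu
  s <- chi_path(omega, cf)
  chi_u <- s$chi_u; chi_v <- s$chi_v
  for (k in seq_len(iters)) {
    Fo <- (su - 1 / chi_u) * (sv - 1 / chi_v) - K
    # implicit derivative of chi wrt omega: J dchi = (chi_u, chi_v)
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
    omega <- omega - step
    s <- chi_newton(omega, cf, chi_u, chi_v, iters = 6L)
    redo <- s$residual > 1e-9
    if (any(redo)) {
      sp <- chi_path(omega[redo], lapply(cf, function(z)
        if (length(z) > 1) z[redo] else z))
      s$chi_u[redo] <- sp$chi_u
      s$chi_v[redo] <- sp$chi_v
      s$residual[redo] <- sp$residual
    }
    chi_u <- s$chi_u; chi_v <- s$chi_v
  }
  Fo <- (su - 1 / chi_u) * (sv - 1 / chi_v) - K
  indicator <- cf$gamma_u * Mod(chi_u)^2 + cf$gamma_v * Mod(chi_v)^2 - 1 / cf$c
  list(omega = omega, fval = Mod(Fo) + s$residual, indicator = indicator)
}

#' @export
print.outlier_set <- function(x, ...) {
  cat(sprintf("<outlier_set> q = %g, %d root(s), %d admissible\n",
              x$q, nrow(x$values), sum(x$values$admissible)))
  if (nrow(x$values)) print(x$values)
  invisible(x)
}

#' Default wavenumber grid
#'
#' Zero plus a geometric ladder up to `q_max`, with `q_max` chosen so that the
#' diffusive damping at the top of the grid dominates the spectral scales:
#' `q_max^2 * min(D > 0) >= 4 * (c + max |m|)`.
#'
#' @param params A [community_params()] object.
#' @param n Number of grid points (default 60).
#' @param q_max Optional override of the upper end.
#' @return Increasing numeric vector starting at 0.
#' @export
default_q_grid <- function(params, n = 60L, q_max = NULL) {
  if (is.null(q_max)) {
    Dmin <- min(c(params$D_u, params$D_v)[c(params$D_u, params$D_v) > 0],
                Inf)
    scale <- 4 * (params$c + max(abs(params$m_uu), abs(params$m_uv),
                                 abs(params$m_vu), abs(params$m_vv), 1))
    q_max <- if (is.finite(Dmin)) sqrt(scale / Dmin) else 1
  }
  c(0, q_max * 100^(seq(-1, 0, length.out = n - 1L)))
}

#' Theory-side dispersion relation
#'
#' The real part of the rightmost predicted eigenvalue as a function of the
#' wavenumber: the maximum of the rightmost point of the bulk boundary and
#' the real parts of all admissible outliers, evaluated on a grid of `q`.
#'
#' @inheritParams resolve_chi
#' @param q_grid Increasing nonnegative wavenumber grid (see
#'   [default_q_grid()]).
#' @return An object of class `dispersion_relation`: a tibble with columns
#'   `q`, `re_max`, `re_bulk`, `re_outlier`, `unstable`, `source = "theory"`.
#'   Use [unstable_bands()] to extract the contiguous unstable `q` intervals.
#' @export
dispersion_relation_theory <- function(params, q_grid = default_q_grid(params)) {
  stopifnot(inherits(params, "community_params"))
  if (!length(q_grid)) stop("q_grid must be nonempty")
  rows <- purrr::map(q_grid, function(q) {
    rb <- bulk_rightmost(params, q)
    o <- outlier_eigenvalues(params, q)
    ro <- if (any(o$values$admissible))
      max(Re(o$values$omega[o$values$admissible])) else -Inf
    tibble::tibble(q = q, re_bulk = rb, re_outlier = ro,
                   re_max = max(rb, ro))
  })
  out <- dplyr::bind_rows(rows)
  out$unstable <- out$re_max > 0
  out$source <- "theory"
  class(out) <- c("dispersion_relation", class(out))
  out
}

#' Unstable wavenumber bands of a dispersion relation
#'
#' @param disp A `dispersion_relation` (from [dispersion_relation_theory()] or
#'   [dispersion_relation_empirical()]).
#' @return Tibble with one row per contiguous unstable band: `q_lo`, `q_hi`
#'   (grid-resolution band edges) and `lambda_lo`, `lambda_hi` (wavelengths
#'   `2 * pi / q`, `Inf` at `q = 0`).
#' @export
unstable_bands <- function(disp) {
  stopifnot(inherits(disp, "dispersion_relation"))
  idx <- which(disp$unstable)
  if (!length(idx)) {
    return(tibble::tibble(q_lo = numeric(), q_hi = numeric(),
                          lambda_lo = numeric(), lambda_hi = numeric()))
  }
  runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
  dplyr::bind_rows(purrr::map(runs, function(r) {
    q_lo <- disp$q[min(r)]
    q_hi <- disp$q[max(r)]
    tibble::tibble(q_lo = q_lo, q_hi = q_hi,
                   lambda_lo = 2 * pi / q_hi,
                   lambda_hi = if (q_lo > 0) 2 * pi / q_lo else Inf)
  }))
}

#' @export
tidy.bulk_boundary <- function(x, ...) {
  dplyr::mutate(x$curve, q = x$q, .before = 1)
}

#' @export
tidy.outlier_set <- function(x, ...) {
  tibble::tibble(q = x$q, re = Re(x$values$omega), im = Im(x$values$omega),
                 admissible = x$values$admissible,
                 near_edge = x$values$near_edge)
}
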