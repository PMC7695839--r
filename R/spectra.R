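#' Full eigenvalue spectrum of a stability matrix
#'
#' Computes all `N` eigenvalues (with multiplicity) of a realized stability
#' matrix by full non-Hermitian eigendecomposition. Full decomposition is
#' deliberate: iterative leading-eigenvalue methods are unreliable for
#' strongly non-normal matrices of this kind.
#'
#' @param M A [stability_matrix][build_stability_matrix()].
#' @return An object of class `spectrum_result`: list with `eigenvalues`
#'   (complex vector), `rightmost` (eigenvalue of maximal real part), `q`,
#'   `labels` (set by [classify_against_theory()], `NA` until then), `params`.
#' @export
compute_spectrum <- function(M) {
  stopifnot(inherits(M, "stability_matrix"))
  if (!all(is.finite(M$values))) stop("compute_spectrum: matrix has non-finite entries")
  ev <- tryCatch(eigen(M$values, only.values = TRUE)$values,
                 error = function(e) stop("eigensolver failed to converge: ",
                                          conditionMessage(e), call. = FALSE))
  structure(list(eigenvalues = ev,
                 rightmost = ev[which.max(Re(ev))],
                 q = M$q,
                 labels = rep(NA_character_, length(ev)),
                 containment = NA_real_,
                 params = M$params),
            class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf("<spectrum_result> N = %d eigenvalues at q = %g, rightmost Re = %.6g\n",
              length(x$eigenvalues), x$q, Re(x$rightmost)))
  if (!is.na(x$containment))
    cat(sprintf("  bulk containment fraction = %.4f\n", x$containment))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.spectrum_result <- function(x, ...) {
  tibble::tibble(q = x$q,
                 re = Re(x$eigenvalues), im = Im(x$eigenvalues),
                 label = x$labels)
}

#' @export
glance.spectrum_result <- function(x, ...) {
  tibble::tibble(n_eigenvalues = length(x$eigenvalues),
                 q = x$q,
                 re_max = Re(x$rightmost),
                 n_outliers = sum(x$labels == "outlier", na.rm = TRUE),
                 containment = x$containment)
}

#' Empirical dispersion relation from one matrix draw
#'
#' Re-uses a single interaction draw across a whole wavenumber grid (only the
#' diagonal of the stability matrix changes with `q`) and records the real
#' part of the rightmost eigenvalue at each grid point.
#'
#' @param A An [interaction_matrix][sample_interaction_matrix()].
#' @param q_grid Increasing nonnegative wavenumber grid.
#' @param params Parameter set; defaults to the one stored in `A`.
#' @return A `dispersion_relation` tibble (`q`, `re_max`, `unstable`,
#'   `source = "empirical"`); see [unstable_bands()].
#' @export
dispersion_relation_empirical <- function(A, q_grid, params = A$params) {
  stopifnot(inherits(A, "interaction_matrix"))
  if (!length(q_grid)) stop("q_grid must be nonempty")
  re_max <- purrr::map_dbl(q_grid, function(q) {
    M <- build_stability_matrix(A, q, params)
    max(Re(eigen(M$values, only.values = TRUE)$values))
  })
  out <- tibble::tibble(q = q_grid, re_max = re_max,
                        unstable = re_max > 0, source = "empirical")
  class(out) <- c("dispersion_relation", class(out))
  out
}

#' Label sampled eigenvalues as bulk or outlier against the theory
#'
#' Labels each eigenvalue of a sampled spectrum `bulk` if it lies inside the
#' predicted bulk support (support indicator nonnegative) or within a
#' tolerance band of the boundary curve, and `outlier` otherwise. The band
#' absorbs the \eqn{O(N^{-1/2})} fluctuation of the bulk edge at finite `N`.
#'
#' @param spec A [spectrum_result][compute_spectrum()].
#' @param boundary A [bulk_boundary()] computed for the same parameters and `q`.
#' @param outliers An [outlier_eigenvalues()] result for the same parameters
#'   and `q`; predicted outliers are excluded from the containment fraction.
#' @param tol Tolerance band width; default
#'   `max(1e-3, 3 * sqrt(c) / sqrt(N))`.
#' @return The `spectrum_result` with `labels` filled and `containment` set to
#'   the fraction of non-outlier eigenvalues inside the band.
#' @export
classify_against_theory <- function(spec, boundary, outliers,
                                    tol = NULL) {
  stopifnot(inherits(spec, "spectrum_result"),
            inherits(boundary, "bulk_boundary"),
            inherits(outliers, "outlier_set"))
  if (!isTRUE(all.equal(spec$q, boundary$q)) ||
      !isTRUE(all.equal(spec$q, outliers$q)))
    stop("spectrum, boundary and outliers must share the same q")
  if (boundary$params$c > 0 && nrow(boundary$curve) == 0)
    stop("boundary curve is empty / not closed")
  p <- boundary$params
  if (is.null(tol)) tol <- max(1e-3, 3 * sqrt(p$c) / sqrt(p$N))
  ev <- spec$eigenvalues

  pred <- outliers$values$omega[outliers$values$admissible]
  near_pred <- if (length(pred)) {
    apply(outer(ev, pred, function(a, b) Mod(a - b)), 1L, min) < 0.15
  } else rep(FALSE, length(ev))

  if (p$c == 0) {
    inside <- rep(FALSE, length(ev))
  } else {
    I <- support_indicator(p, spec$q, ev)
    dist_curve <- if (nrow(boundary$curve)) {
      bc <- complex(real = boundary$curve$omega_x,
                    imaginary = boundary$curve$omega_y)
      bc <- c(bc, Conj(bc))
      apply(outer(ev, bc, function(a, b) Mod(a - b)), 1L, min)
    } else rep(Inf, length(ev))
    inside <- I >= 0 | dist_curve <= tol
  }
  labels <- ifelse(inside & !near_pred, "bulk", "outlier")
  spec$labels <- labels
  spec$containment <- mean(inside[!near_pred])
  spec
}
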