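#' Parameters of a block-structured random community
#'
#' Bundles every parameter of the two-block (prey/predator) random community
#' ensemble: community size and composition, connectance, complexity, scaled
#' block means, pair correlations, self-regulation and diffusion coefficients.
#'
#' The ensemble is parametrised by the size-independent combinations that the
#' analytic theory depends on: the complexity \eqn{c = \sigma^2 N C} and the
#' scaled block means \eqn{m_{\alpha\beta} = N C \mu_{\alpha\beta}}. The raw
#' entry variance \eqn{\sigma^2 = c/(NC)} and entry means
#' \eqn{\mu_{\alpha\beta} = m_{\alpha\beta}/(NC)} are derived quantities (see
#' [sigma_squared()] and [mu_matrix()]), so spectra are stable as `N` grows.
#'
#' @param N Total number of species.
#' @param C Connectance: probability that a given unordered pair of species
#'   interact. In `[0, 1]`.
#' @param c Complexity \eqn{c = \sigma^2 N C}; nonnegative.
#' @param N_u Number of prey-like species (defaults to `N / 2`, rounded).
#'   `N_v = N - N_u`. Block fractions `gamma_u = N_u/N`, `gamma_v = N_v/N`.
#' @param m_uu,m_uv,m_vu,m_vv Scaled block means \eqn{m_{\alpha\beta} =
#'   NC\mu_{\alpha\beta}}. `m_uu > 0` means prey species cooperate on average,
#'   `m_uv < 0` / `m_vu > 0` that prey suffer and predators gain from
#'   predator-prey interactions.
#' @param Gamma_u,Gamma_v,Gamma_uv Pair correlations between diagonally
#'   opposite entries, within the prey block, within the predator block and
#'   across blocks respectively; each in `[-1, 1]`.
#' @param d_u,d_v Positive self-regulation coefficients.
#' @param D_u,D_v Nonnegative diffusion (dispersal) coefficients.
#' @param entry_dist Distribution family of matrix entries: `"gaussian"`
#'   (default), `"uniform"` or `"binary"`. The alternatives are moment-matched
#'   to the Gaussian family (same means, variance and pair correlation) and
#'   exist to exercise universality of the spectra.
#' @param enforce_signs If `TRUE`, require the predator-prey sign convention
#'   `m_uv <= 0`, `m_vu >= 0` at construction.
#'
#' @return An object of class `community_params`: a list with the supplied
#'   fields plus derived `N_v`, `gamma_u`, `gamma_v`.
#'
#' @examples
#' p <- community_params(N = 500, C = 0.2, c = 0.5, m_uv = -4, m_vu = 4,
#'                       Gamma_uv = -0.5, D_u = 0.01, D_v = 1)
#' p
#' sigma_squared(p)
#' predation(p)
#' @export
community_params <- function(N, C, c,
                             N_u = round(N / 2),
                             m_uu = 0, m_uv = 0, m_vu = 0, m_vv = 0,
                             Gamma_u = 0, Gamma_v = 0, Gamma_uv = 0,
                             d_u = 1, d_v = 1,
                             D_u = 0, D_v = 0,
                             entry_dist = c("gaussian", "uniform", "binary"),
                             enforce_signs = FALSE) {
  entry_dist <- match.arg(entry_dist)
  stop_field <- function(field, constraint) {
    stop(sprintf("community_params: field `%s` violates constraint %s",
                 field, constraint), call. = FALSE)
  }
  if (!is.numeric(N) || length(N) != 1L || N < 2 || N != round(N))
    stop_field("N", "N is an integer >= 2")
  if (!is.numeric(N_u) || N_u != round(N_u) || N_u < 1 || N - N_u < 1)
    stop_field("N_u", "N_u >= 1 and N_v = N - N_u >= 1")
  if (!is.numeric(C) || C < 0 || C > 1) stop_field("C", "0 <= C <= 1")
  if (!is.numeric(c) || c < 0) stop_field("c", "c >= 0")
  for (g in c("Gamma_u", "Gamma_v", "Gamma_uv")) {
    val <- get(g)
    if (!is.numeric(val) || abs(val) > 1) stop_field(g, "|Gamma| <= 1")
  }
  if (d_u <= 0) stop_field("d_u", "d_u > 0")
  if (d_v <= 0) stop_field("d_v", "d_v > 0")
  if (D_u < 0) stop_field("D_u", "D_u >= 0")
  if (D_v < 0) stop_field("D_v", "D_v >= 0")
  if (enforce_signs) {
    if (m_uv > 0) stop_field("m_uv", "m_uv <= 0 (prey suffer from predation)")
    if (m_vu < 0) stop_field("m_vu", "m_vu >= 0 (predators gain from predation)")
  }
  structure(
    list(N = as.integer(N), N_u = as.integer(N_u), N_v = as.integer(N - N_u),
         gamma_u = N_u / N, gamma_v = (N - N_u) / N,
         C = C, c = c,
         m_uu = m_uu, m_uv = m_uv, m_vu = m_vu, m_vv = m_vv,
         Gamma_u = Gamma_u, Gamma_v = Gamma_v, Gamma_uv = Gamma_uv,
         d_u = d_u, d_v = d_v, D_u = D_u, D_v = D_v,
         entry_dist = entry_dist),
    class = "community_params")
}

#' @export
print.community_params <- function(x, ...) {
  cat("<community_params>\n")
  cat(sprintf("  N = %d (N_u = %d prey, N_v = %d predators), C = %g, c = %g\n",
              x$N, x$N_u, x$N_v, x$C, x$c))
  cat(sprintf("  scaled means m = [uu %g, uv %g; vu %g, vv %g]\n",
              x$m_uu, x$m_uv, x$m_vu, x$m_vv))
  cat(sprintf("  correlations Gamma_u = %g, Gamma_v = %g, Gamma_uv = %g\n",
              x$Gamma_u, x$Gamma_v, x$Gamma_uv))
  cat(sprintf("  self-regulation d = (%g, %g), diffusion D = (%g, %g)\n",
              x$d_u, x$d_v, x$D_u, x$D_v))
  cat(sprintf("  entry distribution: %s; sigma^2 = %g\n",
              x$entry_dist, sigma_squared(x)))
  invisible(x)
}

#' Derived entry variance \eqn{\sigma^2 = c / (N C)}
#'
#' @param params A [community_params()] object.
#' @return The variance of an individual realized interaction coefficient.
#' @export
sigma_squared <- function(params) {
  if (params$c == 0) return(0)
  params$c / (params$N * params$C)
}

#' Derived block-mean matrix \eqn{\mu_{\alpha\beta} = m_{\alpha\beta}/(NC)}
#'
#' @param params A [community_params()] object.
#' @return A 2x2 matrix of per-entry means with rows/cols named `u`, `v`.
#' @export
mu_matrix <- function(params) {
  m <- matrix(c(params$m_uu, params$m_uv, params$m_vu, params$m_vv),
              2, 2, byrow = TRUE, dimnames = list(c("u", "v"), c("u", "v")))
  m / (params$N * params$C)
}

#' Average degree of predation \eqn{p = C N \mu_{vu}}
#'
#' The mean scaled gain of predators from prey; the horizontal axis of the
#' non-spatial stability diagram. Identical to the scaled mean `m_vu`.
#'
#' @param params A [community_params()] object.
#' @return A single number.
#' @export
predation <- function(params) params$m_vu

#' Update parameters, revalidating invariants
#'
#' @param object A [community_params()] object.
#' @param ... Named fields to replace (any argument of [community_params()],
#'   or `p` to set the predation level `m_vu = p`, `m_uv = -p`, or `D_ratio`
#'   to set `D_v = D_ratio * D_u`).
#' @return A new `community_params` object.
#' @export
update_params <- function(object, ...) {
  params <- object
  upd <- list(...)
  if (!is.null(upd$p)) {
    upd$m_vu <- upd$p
    if (is.null(upd$m_uv)) upd$m_uv <- -upd$p
    upd$p <- NULL
  }
  if (!is.null(upd$D_ratio)) {
    upd$D_v <- upd$D_ratio * params$D_u
    upd$D_ratio <- NULL
  }
  fields <- list(N = params$N, C = params$C, c = params$c, N_u = params$N_u,
                 m_uu = params$m_uu, m_uv = params$m_uv, m_vu = params$m_vu,
                 m_vv = params$m_vv, Gamma_u = params$Gamma_u,
                 Gamma_v = params$Gamma_v, Gamma_uv = params$Gamma_uv,
                 d_u = params$d_u, d_v = params$d_v,
                 D_u = params$D_u, D_v = params$D_v,
                 entry_dist = params$entry_dist)
  fields[names(upd)] <- upd
  do.call(community_params, fields)
}

#' Structureless (May) ensemble parameters
#'
#' A single statistical block: zero means, zero correlations, a common
#' self-regulation `d` and common diffusion `D`. In this limit the bulk
#' spectrum at `q = 0` is the circular law of radius \eqn{\sqrt{c}} centred at
#' `-d`, and the classical stability bound \eqn{\sigma^2 N C < 1} is recovered
#' as `c < d^2` with `d = 1`.
#'
#' @param c Complexity.
#' @param N Community size (default 1000).
#' @param C Connectance (default 0.2).
#' @param d Common self-regulation (default 1).
#' @param D Common diffusion coefficient (default 0).
#' @return A [community_params()] object.
#' @export
may_params <- function(c, N = 1000, C = 0.2, d = 1, D = 0) {
  community_params(N = N, C = C, c = c, d_u = d, d_v = d, D_u = D, D_v = D)
}

#' Reference parameter set exhibiting dispersal-induced instability
#'
#' A documented two-block community that is stable as a non-spatial system
#' (`q = 0`) but unstable against a finite band of nonzero wavenumbers when
#' predators diffuse much faster than prey. Prey cooperate on average
#' (`m_uu = 3`, so the prey block is the "activator") with positively
#' correlated reciprocal coefficients (`Gamma_u = 0.5`, the symmetry expected
#' of mutualistic interactions), predators self-limit (`m_vv = 0`),
#' predator-prey coupling is `m_vu = 4 = -m_uv` with anticorrelated pair
#' coefficients (`Gamma_uv = -0.5`), and the diffusion contrast is
#' `D_v / D_u = 100`. In this regime complexity also lowers the diffusion
#' ratio required for the Turing instability.
#'
#' @param N Community size (default 2000, matching the spectra demonstrations).
#' @param C Connectance (default 0.2).
#' @param c Complexity (default 0.5, below the bulk instability threshold).
#' @param D_u Prey diffusion coefficient (default 0.01).
#' @param D_v Predator diffusion coefficient (default 1).
#' @return A [community_params()] object.
#' @export
dispersal_instability_params <- function(N = 2000, C = 0.2, c = 0.5,
                                         D_u = 0.01, D_v = 1) {
  community_params(N = N, C = C, c = c,
                   m_uu = 3, m_vv = 0, m_uv = -4, m_vu = 4,
                   Gamma_u = 0.5, Gamma_v = 0, Gamma_uv = -0.5,
                   d_u = 1, d_v = 1, D_u = D_u, D_v = D_v)
}
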