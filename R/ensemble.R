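#' Sample a block-structured correlated random interaction matrix
#'
#' Draws the `N x N` interaction matrix `A`. For each unordered pair of
#' species, with probability `C` the pair interacts; both directions live or
#' die together, so the interaction mask is symmetric. For an interacting pair
#' `(i, j)` with `i` in block `a` and `j` in block `b`, the two coefficients
#' `(A[i,j], A[j,i])` are drawn jointly with means `(mu_ab, mu_ba)`, common
#' variance `sigma^2 = c/(NC)` and pair correlation `Gamma_u` (both prey),
#' `Gamma_v` (both predators) or `Gamma_uv` (mixed). All other correlations
#' are zero, the diagonal is identically zero (self-regulation lives in `d`),
#' and non-interacting pairs are exactly zero.
#'
#' Degenerate correlations `|Gamma| = 1` are realized exactly, by constructing
#' the second deviate linearly from the first. Non-Gaussian entry families
#' (`uniform`, `binary`) are moment-matched: identical means, variance and
#' pair correlation (uniform pairs are correlated by a comonotone mixture,
#' binary pairs by the joint sign distribution), which leaves the large-`N`
#' spectrum unchanged (universality).
#'
#' @param params A [community_params()] object.
#' @param seed Integer seed; every draw is explicitly seeded and the seed is
#'   stored in the returned object.
#' @param entry_dist Optional override of `params$entry_dist`.
#'
#' @return An object of class `interaction_matrix` with fields `values`
#'   (`N x N` matrix), `mask` (logical matrix of realized interactions),
#'   `block_sizes` (`c(N_u, N_v)`), `seed`, and `params`.
#'
#' @examples
#' p <- dispersal_instability_params(N = 200)
#' A <- sample_interaction_matrix(p, seed = 1)
#' empirical_moments(A)
#' @export
sample_interaction_matrix <- function(params, seed,
                                      entry_dist = params$entry_dist) {
  stopifnot(inherits(params, "community_params"))
  if (missing(seed) || !is.numeric(seed))
    stop("sample_interaction_matrix: an explicit integer `seed` is required")
  N <- params$N
  N_u <- params$N_u
  set.seed(as.integer(seed))

  values <- matrix(0, N, N)
  mask <- matrix(FALSE, N, N)
  n_pairs <- N * (N - 1) / 2
  if (params$C * n_pairs == 0) {
    warning("no interactions can be realized (C * N(N-1)/2 = 0); returning zero matrix")
  } else {
    ut <- which(upper.tri(values), arr.ind = TRUE)
    live <- stats::runif(nrow(ut)) < params$C
    i <- ut[live, 1L]
    j <- ut[live, 2L]
    if (length(i)) {
      bi <- ifelse(i <= N_u, 1L, 2L)
      bj <- ifelse(j <= N_u, 1L, 2L)
      G <- ifelse(bi == 1L & bj == 1L, params$Gamma_u,
           ifelse(bi == 2L & bj == 2L, params$Gamma_v, params$Gamma_uv))
      z <- draw_entry_pairs(length(i), G, entry_dist)
      sigma <- sqrt(sigma_squared(params))
      mu <- mu_matrix(params)
      values[cbind(i, j)] <- mu[cbind(bi, bj)] + sigma * z$z1
      values[cbind(j, i)] <- mu[cbind(bj, bi)] + sigma * z$z2
      mask[cbind(i, j)] <- TRUE
      mask[cbind(j, i)] <- TRUE
    }
  }
  structure(list(values = values, mask = mask,
                 block_sizes = c(N_u = params$N_u, N_v = params$N_v),
                 seed = as.integer(seed), params = params),
            class = "interaction_matrix")
}

# Pairs (z1, z2) with zero mean, unit variance and correlation G, drawn from
# the requested family. |G| = 1 handled by exact linear construction.
draw_entry_pairs <- function(n, G, entry_dist) {
  if (entry_dist == "gaussian") {
    z1 <- stats::rnorm(n)
    z2 <- ifelse(abs(G) == 1, sign(G) * z1,
                 G * z1 + sqrt(pmax(0, 1 - G^2)) * stats::rnorm(n))
  } else if (entry_dist == "uniform") {
    # comonotone mixture: with prob |G| the pair is sign(G)-comonotone,
    # otherwise independent; marginals exactly uniform, correlation exactly G
    half <- sqrt(3)
    z1 <- stats::runif(n, -half, half)
    indep <- stats::runif(n, -half, half)
    couple <- stats::runif(n) < abs(G)
    z2 <- ifelse(couple, sign(G) * z1, indep)
  } else if (entry_dist == "binary") {
    z1 <- sample(c(-1, 1), n, replace = TRUE)
    same <- stats::runif(n) < (1 + G) / 2
    z2 <- ifelse(same, z1, -z1)
  } else {
    stop("unknown entry distribution: ", entry_dist)
  }
  list(z1 = z1, z2 = z2)
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("<interaction_matrix> N = %d (%d prey + %d predators), seed = %d\n",
              nrow(x$values), x$block_sizes[["N_u"]], x$block_sizes[["N_v"]],
              x$seed))
  cat(sprintf("  realized connectance = %.4f (target C = %g)\n",
              mean(x$mask[upper.tri(x$mask)]), x$params$C))
  invisible(x)
}

#' Assemble the wavenumber-dependent stability matrix
#'
#' Builds \eqn{M_q = A - \mathrm{diag}(d_\alpha + q^2 D_\alpha)}: the
#' interaction matrix with a block-constant diagonal shift combining
#' self-regulation and diffusive damping of a perturbation with wavenumber
#' `q`. The input `A` is not modified, so a single draw can be reused across
#' a whole wavenumber grid. At `q = 0` the result is identical to the matrix
#' with all diffusion switched off.
#'
#' @param A An [interaction_matrix][sample_interaction_matrix()].
#' @param q Nonnegative wavenumber (the spectrum depends on `q^2` only; the
#'   canonical `q >= 0` parametrization is enforced).
#' @param params Parameter set; defaults to the one stored in `A`.
#'
#' @return An object of class `stability_matrix` with fields `values`, `q`,
#'   `params`.
#' @export
build_stability_matrix <- function(A, q, params = A$params) {
  stopifnot(inherits(A, "interaction_matrix"))
  if (!is.numeric(q) || length(q) != 1L || q < 0)
    stop("build_stability_matrix: `q` must be a single nonnegative number")
  shift <- diagonal_damping(params, q)
  M <- A$values
  diag(M) <- diag(M) - shift
  structure(list(values = M, q = q, params = params),
            class = "stability_matrix")
}

# block-wise diagonal damping d_alpha + q^2 D_alpha as a length-N vector
diagonal_damping <- function(params, q) {
  c(rep(params$d_u + q^2 * params$D_u, params$N_u),
    rep(params$d_v + q^2 * params$D_v, params$N_v))
}

#' @export
print.stability_matrix <- function(x, ...) {
  cat(sprintf("<stability_matrix> N = %d, q = %g\n", nrow(x$values), x$q))
  invisible(x)
}

#' Empirical moments of a realized interaction matrix
#'
#' Summarises the realized draw per block: mean and variance over realized
#' (masked-in) entries, correlation of diagonally opposite pairs, realized
#' connectance, and Monte-Carlo standard errors. Blocks with no realized
#' entries are reported as `NA`, not zero.
#'
#' @param A An [interaction_matrix][sample_interaction_matrix()].
#' @return A tibble with one row per directed block (`uu`, `uv`, `vu`, `vv`)
#'   and columns `block`, `n`, `mean`, `mean_se`, `var`, `pair_cor`,
#'   `pair_cor_se`, `target_mean`, `target_var`, `target_cor`, plus the
#'   realized connectance in the `connectance` column (identical across rows).
#' @export
empirical_moments <- function(A) {
  stopifnot(inherits(A, "interaction_matrix"))
  p <- A$params
  N_u <- p$N_u
  N <- p$N
  mu <- mu_matrix(p)
  sig2 <- sigma_squared(p)
  idx <- list(u = seq_len(N_u), v = seq.int(N_u + 1L, N))
  gam <- c(uu = p$Gamma_u, uv = p$Gamma_uv, vu = p$Gamma_uv, vv = p$Gamma_v)
  conn <- mean(A$mask[upper.tri(A$mask)])

  one_block <- function(a, b) {
    sub_mask <- A$mask[idx[[a]], idx[[b]], drop = FALSE]
    vals <- A$values[idx[[a]], idx[[b]], drop = FALSE][sub_mask]
    # paired entries (A_ij, A_ji) for the pair correlation
    tr_mask <- t(A$mask[idx[[b]], idx[[a]], drop = FALSE])
    both <- sub_mask & tr_mask
    if (a == b) both <- both & upper.tri(both)
    v1 <- A$values[idx[[a]], idx[[b]], drop = FALSE][both]
    v2 <- t(A$values[idx[[b]], idx[[a]], drop = FALSE])[both]
    n <- length(vals)
    pc <- if (length(v1) > 2 && stats::var(v1) > 0 && stats::var(v2) > 0)
      stats::cor(v1, v2) else NA_real_
    tibble::tibble(
      block = paste0(a, b),
      n = n,
      mean = if (n) mean(vals) else NA_real_,
      mean_se = if (n > 1) stats::sd(vals) / sqrt(n) else NA_real_,
      var = if (n > 1) stats::var(vals) else NA_real_,
      pair_cor = pc,
      pair_cor_se = if (!is.na(pc)) (1 - pc^2) / sqrt(max(length(v1) - 3, 1)) else NA_real_,
      target_mean = mu[a, b],
      target_var = sig2,
      target_cor = gam[[paste0(a, b)]],
      connectance = conn)
  }
  dplyr::bind_rows(one_block("u", "u"), one_block("u", "v"),
                   one_block("v", "u"), one_block("v", "v"))
}

#' Export / import an interaction matrix as CSV plus a JSON sidecar
#'
#' The dense matrix is written as headerless CSV; the parameters, seed and
#' block sizes go to `<path>.json`. [read_interaction_matrix()] reverses the
#' operation bit-for-bit (the mask is reconstructed from nonzero entries
#' together with the stored mask coordinates for realized-but-zero entries).
#'
#' @param A An [interaction_matrix][sample_interaction_matrix()].
#' @param path CSV file path (sidecar path derived by appending `.json`).
#' @return `path`, invisibly.
#' @export
write_interaction_matrix <- function(A, path) {
  stopifnot(inherits(A, "interaction_matrix"))
  utils::write.table(A$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  side <- list(params = unclass(A$params), seed = A$seed,
               block_sizes = as.list(A$block_sizes),
               mask_true_zero = which(A$mask & A$values == 0))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_interaction_matrix
#' @export
read_interaction_matrix <- function(path) {
  values <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(values) <- NULL
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pl <- side$params
  params <- community_params(
    N = pl$N, C = pl$C, c = pl$c, N_u = pl$N_u,
    m_uu = pl$m_uu, m_uv = pl$m_uv, m_vu = pl$m_vu, m_vv = pl$m_vv,
    Gamma_u = pl$Gamma_u, Gamma_v = pl$Gamma_v, Gamma_uv = pl$Gamma_uv,
    d_u = pl$d_u, d_v = pl$d_v, D_u = pl$D_u, D_v = pl$D_v,
    entry_dist = pl$entry_dist)
  mask <- values != 0
  if (length(side$mask_true_zero)) mask[side$mask_true_zero] <- TRUE
  structure(list(values = values, mask = mask,
                 block_sizes = c(N_u = params$N_u, N_v = params$N_v),
                 seed = as.integer(side$seed), params = params),
            class = "interaction_matrix")
}
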