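#' @title Characteristic-function machinery for the causal mixture
#' @description The likelihood of a z-score under the four-component causal
#' mixture is an LD-convolved mixture with no closed form.  Its
#' characteristic function, however, is a product over LD neighbors of
#' simple Gaussian factors, with the neighbors entering only through their
#' r-squared values.  The package therefore bins neighbor r-squared values
#' (the `r2_counts` / `r2_mean` slots of an [ld_info]), accumulates the log
#' characteristic function over bins, and inverts it to a density by
#' discrete Fourier inversion on a fixed z grid.
#' @name mixture_cf
NULL

mix_grid <- function(n = 128, zmax = 15) {
  stopifnot(n %% 4 == 0)
  dz <- 2 * zmax / n
  k <- seq_len(n) - 1 - n / 2
  list(n = n, dz = dz, z = k * dz, dt = 2 * pi / (n * dz),
       t = k * 2 * pi / (n * dz))
}

cf_invert_1d <- function(phi, dz) {
  n <- length(phi)
  s <- (-1)^(seq_len(n) - 1)
  Re(s * stats::fft(s * phi)) / (n * dz)
}

cf_invert_2d <- function(phi, dz) {
  n <- nrow(phi)
  s <- (-1)^(seq_len(n) - 1)
  sgn <- outer(s, s)
  Re(sgn * stats::fft(sgn * phi)) / (n * dz)^2
}

# per-SNP LD profile: neighbor r2 values/counts plus the self term (r2 = 1)
hist_profile <- function(counts, means, include_self = TRUE) {
  keep <- counts > 0 & is.finite(means)
  v <- means[keep]; k <- counts[keep]
  if (include_self) { v <- c(1, v); k <- c(1, k) }
  list(r2 = v, count = k)
}

univ_cf <- function(t, pi_u, sigma_u_sq, sigma0_sq, N, profile) {
  lc <- -0.5 * sigma0_sq * t^2
  for (b in seq_along(profile$r2)) {
    g <- exp(-0.5 * N * sigma_u_sq * profile$r2[b] * t^2)
    lc <- lc + profile$count[b] * log((1 - pi_u) + pi_u * g)
  }
  exp(lc)
}

univ_density <- function(grid, pi_u, sigma_u_sq, sigma0_sq, N, profile) {
  pmax(cf_invert_1d(univ_cf(grid$t, pi_u, sigma_u_sq, sigma0_sq, N, profile),
                    grid$dz), 0)
}

#' Bivariate mixture density of a z-score pair
#'
#' Computes the model density of `(z_1j, z_2j)` for one SNP's LD profile by
#' characteristic-function products over binned neighbor r-squared values,
#' inverted on a symmetric grid by 2-D discrete Fourier inversion.  Negative
#' ripple from the inversion is clipped at zero and the clipped mass is
#' reported.  An error is raised when the estimated aliasing mass at the
#' grid edge exceeds `1e-3` (the grid is too narrow for the parameters).
#'
#' @param params A [mixture_params()] object.
#' @param rho0 Cross-trait noise (sample overlap) correlation.
#' @param sigma0_sq Length-2 per-trait noise variances (LDSC-intercept
#'   scale, `>= 1` in well-formed data).
#' @param N Length-2 per-trait sample sizes.
#' @param profile LD profile of the SNP: list with `r2` (bin values,
#'   including the self term `r2 = 1`) and `count`; see [ld_info].
#' @param n_grid,zmax Grid resolution and half-width (defaults 128, 15).
#' @return List with `z` (axis), `density` (`n_grid x n_grid`, integrates
#'   to ~1), `dz`, `clip_mass`.
#' @export
mixture_density <- function(params, rho0 = 0, sigma0_sq = c(1, 1), N,
                            profile, n_grid = 128, zmax = 15) {
  grid <- mix_grid(n_grid, zmax)
  phi <- biv_cf(grid, params$pi0, params$pi1, params$pi2, params$pi12,
                params$sigma1_sq, params$sigma2_sq, params$rho12,
                sigma0_sq[1], sigma0_sq[2], rho0, N[1], N[2], profile)
  dens <- cf_invert_2d(phi, grid$dz)
  clip <- -sum(dens[dens < 0]) * grid$dz^2
  dens <- pmax(dens, 0)
  n <- grid$n
  edge <- sum(dens[c(1, 2, n - 1, n), ]) + sum(dens[-c(1, 2, n - 1, n),
                                                    c(1, 2, n - 1, n)])
  if (edge * grid$dz^2 > 1e-3)
    stop("aliasing mass ", signif(edge * grid$dz^2, 3),
         " at the grid edge: enlarge zmax or n_grid")
  list(z = grid$z, density = dens, dz = grid$dz, clip_mass = clip)
}

biv_cf <- function(grid, pi0, pi1, pi2, pi12, s1sq, s2sq, rho12,
                   s01sq, s02sq, rho0, N1, N2, profile) {
  t1 <- matrix(grid$t, grid$n, grid$n)
  t2 <- t(t1)
  lc <- -0.5 * (s01sq * t1^2 + 2 * rho0 * sqrt(s01sq * s02sq) * t1 * t2 +
                  s02sq * t2^2)
  s1 <- sqrt(s1sq); s2 <- sqrt(s2sq)
  for (b in seq_along(profile$r2)) {
    r2 <- profile$r2[b]
    a1 <- N1 * s1sq * r2 * t1^2
    a2 <- N2 * s2sq * r2 * t2^2
    ax <- sqrt(N1 * N2) * rho12 * s1 * s2 * r2 * t1 * t2
    comp <- pi0 + pi1 * exp(-0.5 * a1) + pi2 * exp(-0.5 * a2) +
      pi12 * exp(-0.5 * (a1 + 2 * ax + a2))
    lc <- lc + profile$count[b] * log(comp)
  }
  exp(lc)
}
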