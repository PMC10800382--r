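#' @rdname mixture_cf
#' @details [fit_univariate()] and [fit_bivariate()] maximise the
#' characteristic-function likelihood.  Fitting is sequential: the
#' univariate margins `(pi_u, sigma_u^2, sigma0^2)` of each trait are
#' estimated first and then held fixed while the bivariate stage estimates
#' only the overlap parameters `(pi12, rho12, rho0)`, with
#' `pi12 <= min(pi_u1, pi_u2)` enforced by construction.
NULL

hist_groups <- function(ld, idx) {
  key <- paste(
    apply(ld$r2_counts[idx, , drop = FALSE], 1, paste, collapse = ","),
    apply(round(ld$r2_mean[idx, , drop = FALSE], 8), 1, paste,
          collapse = ","))
  split(seq_along(idx), key)
}

group_profiles <- function(ld, idx, groups) {
  lapply(groups, function(g)
    hist_profile(ld$r2_counts[idx[g[1]], ], ld$r2_mean[idx[g[1]], ]))
}

interp_density_1d <- function(grid, dens, z) {
  zc <- pmin(pmax(z, grid$z[1]), grid$z[grid$n] - 1e-9)
  pmax(stats::approx(grid$z, dens, zc)$y, 1e-300)
}

interp_density_2d <- function(grid, dens, z1, z2) {
  clamp <- function(z) pmin(pmax(z, grid$z[1]), grid$z[grid$n] - 1e-9)
  x <- (clamp(z1) - grid$z[1]) / grid$dz
  y <- (clamp(z2) - grid$z[1]) / grid$dz
  i <- pmin(floor(x) + 1, grid$n - 1); j <- pmin(floor(y) + 1, grid$n - 1)
  fx <- x - (i - 1); fy <- y - (j - 1)
  v <- dens[cbind(i, j)] * (1 - fx) * (1 - fy) +
    dens[cbind(i + 1, j)] * fx * (1 - fy) +
    dens[cbind(i, j + 1)] * (1 - fx) * fy +
    dens[cbind(i + 1, j + 1)] * fx * fy
  pmax(v, 1e-300)
}

#' Fit the univariate causal mixture to one trait
#'
#' Maximises the characteristic-function likelihood of the observed
#' z-scores over `(pi_u, sigma_u^2, sigma0^2)` — the fraction of causal
#' SNPs, the per-causal-variant effect variance, and the noise/inflation
#' variance — by Nelder-Mead on transformed coordinates from a three-point
#' multistart over `pi_u` in `{1e-4, 1e-3, 1e-2}` (effect variance started
#' at a method-of-moments heritability guess divided by `pi_u M`).
#' Deterministic under `seed` (which controls only the SNP subsample).
#'
#' @param stats A `sumstats`.
#' @param ld An [ld_info] (the per-SNP r-squared histograms drive the
#'   likelihood).
#' @param M Reference SNP count (default: LD universe size).
#' @param subsample Maximum number of SNPs entering the likelihood
#'   (default 20000).
#' @param seed RNG seed for the subsample.
#' @param n_grid,zmax Inversion grid (defaults 256 and
#'   `max(15, 1.05 max|z|)`).
#' @param maxit Nelder-Mead iteration cap per start.
#' @return A `mixer_univariate` object: `pi_u, sigma_u_sq, sigma0_sq,
#'   loglik, h2_implied = pi_u M sigma_u_sq, n_used, convergence`.
#' @export
fit_univariate <- function(stats, ld, M = NULL, subsample = 20000, seed = 1,
                           n_grid = 256, zmax = NULL, maxit = 800) {
  al <- align_to_ld(stats, ld)
  if (is.null(M)) M <- length(ld$snp_ids)
  z <- stats$data$z[al$stats_idx]
  N <- stats::median(stats$data$n[al$stats_idx])
  idx <- al$ld_idx
  if (length(idx) > subsample) {
    old <- local_seed(seed)
    keep <- sort(sample.int(length(idx), subsample))
    restore_seed(old)
    idx <- idx[keep]; z <- z[keep]
  }
  if (is.null(zmax)) zmax <- max(15, 1.05 * max(abs(z)))
  grid <- mix_grid(n_grid, zmax)
  groups <- hist_groups(ld, idx)
  profiles <- group_profiles(ld, idx, groups)

  negll <- function(th) {
    pi_u <- 0.5 * stats::plogis(th[1])
    s_u <- exp(th[2]); s0 <- 1 + exp(th[3])
    ll <- 0
    for (g in seq_along(groups)) {
      dens <- univ_density(grid, pi_u, s_u, s0, N, profiles[[g]])
      ll <- ll + sum(log(interp_density_1d(grid, dens, z[groups[[g]]])))
    }
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  mean_ell <- mean(ld$ld_scores[idx])
  h2_mom <- min(max((mean(z^2) - 1) * M / (N * mean_ell), 0.005), 1)
  best <- NULL
  for (pi0 in c(1e-4, 1e-3, 1e-2)) {
    th0 <- c(stats::qlogis(pi0 / 0.5), log(h2_mom / (pi0 * M)), log(0.01))
    fit <- stats::optim(th0, negll, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-8))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (best$convergence != 0) {
    best2 <- stats::optim(best$par, negll, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = 1e-8))
    if (best2$value <= best$value) best <- best2
  }
  th <- best$par
  pi_u <- 0.5 * stats::plogis(th[1])
  out <- structure(list(pi_u = pi_u, sigma_u_sq = exp(th[2]),
                        sigma0_sq = 1 + exp(th[3]), loglik = -best$value,
                        h2_implied = pi_u * M * exp(th[2]),
                        n_used = length(z), M = M, N = N,
                        convergence = best$convergence),
                   class = "mixer_univariate")
  if (!is.finite(out$loglik)) stop("univariate mixture fit diverged")
  out
}

#' @export
print.mixer_univariate <- function(x, ...) {
  cat(sprintf(
    "univariate causal mixture: pi_u=%.3g sigma_u^2=%.3g sigma0^2=%.4f\n",
    x$pi_u, x$sigma_u_sq, x$sigma0_sq))
  cat(sprintf("  implied h2 = %.4f; loglik %.2f over %d SNPs\n",
              x$h2_implied, x$loglik, x$n_used))
  invisible(x)
}

biv_ll_machine <- function(z1, z2, N1, N2, groups, profiles, grid) {
  function(pi0, pi1, pi2, pi12, s1sq, s2sq, rho12, s01sq, s02sq, rho0) {
    ll <- 0
    for (g in seq_along(groups)) {
      phi <- biv_cf(grid, pi0, pi1, pi2, pi12, s1sq, s2sq, rho12,
                    s01sq, s02sq, rho0, N1, N2, profiles[[g]])
      dens <- pmax(cf_invert_2d(phi, grid$dz), 0)
      i <- groups[[g]]
      ll <- ll + sum(log(interp_density_2d(grid, dens, z1[i], z2[i])))
    }
    ll
  }
}

#' Log-likelihood of a bivariate mixture at fixed parameters
#'
#' Evaluates the characteristic-function likelihood of a trait pair at a
#' given parameter point, without fitting.  Useful for profile checks and
#' for verifying the trait-exchange symmetry of the model.
#'
#' @inheritParams fit_bivariate
#' @param params A [mixture_params()].
#' @param rho0 Cross-trait noise correlation.
#' @param sigma0_sq Length-2 noise variances.
#' @return Scalar log-likelihood over the (subsampled) SNPs.
#' @export
bivariate_loglik <- function(stats1, stats2, ld, params, rho0 = 0,
                             sigma0_sq = c(1, 1), subsample = 20000,
                             seed = 1, n_grid = 128, zmax = NULL) {
  pr <- biv_prepare(stats1, stats2, ld, subsample, seed, n_grid, zmax)
  mach <- biv_ll_machine(pr$z1, pr$z2, pr$N1, pr$N2, pr$groups,
                         pr$profiles, pr$grid)
  mach(params$pi0, params$pi1, params$pi2, params$pi12, params$sigma1_sq,
       params$sigma2_sq, params$rho12, sigma0_sq[1], sigma0_sq[2], rho0)
}

biv_prepare <- function(stats1, stats2, ld, subsample, seed, n_grid, zmax) {
  common <- intersect(intersect(ld$snp_ids, stats1$data$snp),
                      stats2$data$snp)
  common <- common[order(match(common, ld$snp_ids))]
  idx <- match(common, ld$snp_ids)
  z1 <- stats1$data$z[match(common, stats1$data$snp)]
  z2 <- stats2$data$z[match(common, stats2$data$snp)]
  N1 <- stats::median(stats1$data$n)
  N2 <- stats::median(stats2$data$n)
  if (length(idx) > subsample) {
    old <- local_seed(seed)
    keep <- sort(sample.int(length(idx), subsample))
    restore_seed(old)
    idx <- idx[keep]; z1 <- z1[keep]; z2 <- z2[keep]
  }
  if (is.null(zmax)) zmax <- max(15, 1.02 * max(abs(c(z1, z2))))
  grid <- mix_grid(n_grid, zmax)
  groups <- hist_groups(ld, idx)
  profiles <- group_profiles(ld, idx, groups)
  list(z1 = z1, z2 = z2, N1 = N1, N2 = N2, idx = idx, grid = grid,
       groups = groups, profiles = profiles)
}

#' Fit the bivariate causal mixture (polygenic overlap)
#'
#' With both univariate margins held fixed (`pi1 + pi12 = pi_u1`,
#' `pi2 + pi12 = pi_u2`, effect and noise variances from the univariate
#' fits), maximises the bivariate likelihood over the overlap fraction
#' `pi12` in `[0, min(pi_u1, pi_u2)]`, the shared-effect correlation
#' `rho12`, and the cross-trait noise correlation `rho0`.  A profile check
#' at `pi12 = 0` is run after optimisation; when the boundary attains the
#' optimum the fit is reported with `boundary = TRUE` (not an error).
#' Parameter uncertainty comes from a parametric bootstrap: `n_boot`
#' resamples drawn from the fitted density and refitted.
#'
#' @param stats1,stats2 `sumstats` objects on a harmonized universe.
#' @param ld An [ld_info].
#' @param fit1,fit2 `mixer_univariate` fits of the two traits.
#' @param subsample,seed,n_grid,zmax As in [fit_univariate()] (grid default
#'   128).
#' @param n_boot Parametric-bootstrap refits for standard errors
#'   (default 20; 0 disables).
#' @param maxit Nelder-Mead iteration cap.
#' @return A `mixer_bivariate` object: `params` ([mixture_params()]),
#'   `rho0`, `loglik`, `se` (named, bootstrap), `boundary`, `boot` (matrix
#'   of bootstrap parameter draws), `pi_u`, `M`.
#' @export
fit_bivariate <- function(stats1, stats2, ld, fit1, fit2,
                          subsample = 20000, seed = 1, n_grid = 128,
                          zmax = NULL, n_boot = 20, maxit = 400) {
  pr <- biv_prepare(stats1, stats2, ld, subsample, seed, n_grid, zmax)
  pu1 <- fit1$pi_u; pu2 <- fit2$pi_u
  if (pu1 + pu2 >= 1)
    stop("univariate causal fractions sum to >= 1; bivariate mixture invalid")
  pmin_u <- min(pu1, pu2)
  s1sq <- fit1$sigma_u_sq; s2sq <- fit2$sigma_u_sq
  s01 <- fit1$sigma0_sq; s02 <- fit2$sigma0_sq
  mach <- biv_ll_machine(pr$z1, pr$z2, pr$N1, pr$N2, pr$groups,
                         pr$profiles, pr$grid)
  ll_at <- function(pi12, rho12, rho0) {
    mach(1 - (pu1 - pi12) - (pu2 - pi12) - pi12, pu1 - pi12, pu2 - pi12,
         pi12, s1sq, s2sq, rho12, s01, s02, rho0)
  }
  negll <- function(th) {
    v <- -ll_at(pmin_u * stats::plogis(th[1]), tanh(th[2]), tanh(th[3]))
    if (!is.finite(v)) 1e12 else v
  }
  r_emp <- stats::cor(pr$z1, pr$z2)
  starts <- list(c(stats::qlogis(0.5), atanh(0.5 * sign(r_emp + 1e-12)), 0),
                 c(stats::qlogis(0.05), 0, atanh(min(max(r_emp, -0.9), 0.9))))
  best <- NULL
  for (th0 in starts) {
    fit <- stats::optim(th0, negll, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-8))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # profile the pi12 = 0 boundary (rho12 is then unidentified)
  opt0 <- stats::optimize(function(th3) -ll_at(0, 0, tanh(th3)),
                          c(-3, 3))
  boundary <- opt0$objective <= best$value + 1e-4
  if (boundary) {
    pi12 <- 0; rho12 <- 0; rho0 <- tanh(opt0$minimum)
    loglik <- -opt0$objective
  } else {
    pi12 <- pmin_u * stats::plogis(best$par[1])
    rho12 <- tanh(best$par[2]); rho0 <- tanh(best$par[3])
    loglik <- -best$value
  }
  params <- mixture_params(1 - (pu1 - pi12) - (pu2 - pi12) - pi12,
                           pu1 - pi12, pu2 - pi12, pi12, s1sq, s2sq, rho12)

  boot <- NULL; se <- c(pi12 = NA_real_, rho12 = NA_real_, rho0 = NA_real_)
  if (n_boot > 0) {
    boot <- matrix(NA_real_, n_boot, 3,
                   dimnames = list(NULL, c("pi12", "rho12", "rho0")))
    old <- local_seed(seed + 77L)
    dens_g <- lapply(seq_along(pr$groups), function(g) {
      phi <- biv_cf(pr$grid, params$pi0, params$pi1, params$pi2,
                    params$pi12, s1sq, s2sq, rho12, s01, s02, rho0,
                    pr$N1, pr$N2, pr$profiles[[g]])
      d <- pmax(cf_invert_2d(phi, pr$grid$dz), 0)
      d / sum(d)
    })
    n <- pr$grid$n
    for (b in seq_len(n_boot)) {
      zb1 <- numeric(0); zb2 <- numeric(0); gidx <- list()
      pos <- 0L
      for (g in seq_along(pr$groups)) {
        ng <- length(pr$groups[[g]])
        cells <- sample.int(n * n, ng, replace = TRUE, prob = dens_g[[g]])
        ci <- (cells - 1) %% n + 1; cj <- (cells - 1) %/% n + 1
        zb1 <- c(zb1, pr$grid$z[ci] + stats::runif(ng, 0, pr$grid$dz))
        zb2 <- c(zb2, pr$grid$z[cj] + stats::runif(ng, 0, pr$grid$dz))
        gidx[[g]] <- pos + seq_len(ng); pos <- pos + ng
      }
      machb <- biv_ll_machine(zb1, zb2, pr$N1, pr$N2, gidx, pr$profiles,
                              pr$grid)
      negb <- function(th) {
        p12 <- pmin_u * stats::plogis(th[1])
        v <- -machb(1 - (pu1 - p12) - (pu2 - p12) - p12, pu1 - p12,
                    pu2 - p12, p12, s1sq, s2sq, tanh(th[2]), s01, s02,
                    tanh(th[3]))
        if (!is.finite(v)) 1e12 else v
      }
      thb <- if (boundary) c(stats::qlogis(0.1), 0, atanh(rho0))
             else best$par
      fb <- stats::optim(thb, negb, method = "Nelder-Mead",
                         control = list(maxit = 200, reltol = 1e-6))
      boot[b, ] <- c(pmin_u * stats::plogis(fb$par[1]), tanh(fb$par[2]),
                     tanh(fb$par[3]))
    }
    restore_seed(old)
    se <- apply(boot, 2, stats::sd)
  }
  structure(list(params = params, rho0 = rho0, loglik = loglik, se = se,
                 boundary = boundary, boot = boot,
                 pi_u = c(pu1, pu2), M = fit1$M,
                 n_used = length(pr$z1)),
            class = "mixer_bivariate")
}

#' @export
print.mixer_bivariate <- function(x, ...) {
  cat("bivariate causal mixture fit",
      if (x$boundary) "(boundary: pi12 = 0)", "\n")
  cat(sprintf("  pi12 = %.3g (se %.3g), rho12 = %.3f (se %.3g), rho0 = %.3f\n",
              x$params$pi12, x$se["pi12"], x$params$rho12, x$se["rho12"],
              x$rho0))
  cat(sprintf("  implied rg = %.3f; loglik %.2f over %d SNPs\n",
              expected_rg(x$params), x$loglik, x$n_used))
  invisible(x)
}

#' Effective number of causal variants explaining 90% of heritability
#'
#' Under Gaussian causal effects the squared effects are scaled chi-square
#' with 1 df; the largest-effect variants dominate.  `n90` is
#' `pi_c M q*`, where `q*` is the upper-tail probability of the smallest
#' effect-size threshold whose exceedances carry 90% of `E[beta^2]` (found
#' by root-finding on the tail-mass ratio).  The result does not depend on
#' `sigma_sq` (scale cancels).  A documented point-mass alternative
#' (`model = "point"`, all causal effects equal) gives `0.9 pi_c M`.
#'
#' @param pi_c Causal fraction.
#' @param sigma_sq Per-causal-variant effect variance (irrelevant for the
#'   Gaussian model; kept for interface symmetry).
#' @param M Number of SNPs.
#' @param model `"gaussian"` (default) or `"point"`.
#' @param coverage Heritability fraction to explain (default 0.9).
#' @return Effective variant count (not in thousands).
#' @export
polygenicity_n90 <- function(pi_c, sigma_sq = 1, M, model = c("gaussian",
                                                              "point"),
                             coverage = 0.9) {
  model <- match.arg(model)
  if (pi_c <= 0) return(0)
  if (model == "point") return(coverage * pi_c * M)
  # E[X 1(X > t)] / E[X] = P(chisq_3 > t) for X ~ chisq_1
  s <- stats::uniroot(function(s)
    stats::pchisq(s, 3, lower.tail = FALSE) - coverage,
    c(1e-10, 100), tol = 1e-12)$root
  qstar <- stats::pchisq(s, 1, lower.tail = FALSE)
  pi_c * M * qstar
}

#' Polygenic-overlap (Venn) summary of a bivariate mixture fit
#'
#' Applies the 90%-of-heritability effective-variant convention to each
#' trait's causal margin and to the shared component.  The raw shared count
#' `pi12 M` is also reported; the 90% convention is the headline.  Shared
#' and unique standard errors come from the bootstrap draws of `pi12`
#' (the margins are held fixed by the sequential fit and carry no bootstrap
#' spread).
#'
#' @param fit A `mixer_bivariate`.
#' @param M Reference SNP count (default from the fit).
#' @return An `overlap_summary` object (counts in variants; printed in
#'   thousands, "0.21K" style).
#' @export
overlap_summary <- function(fit, M = fit$M) {
  q <- function(p) polygenicity_n90(p, 1, M)
  n1 <- q(fit$pi_u[1]); n2 <- q(fit$pi_u[2]); nsh <- q(fit$params$pi12)
  se_sh <- if (!is.null(fit$boot))
    stats::sd(vapply(fit$boot[, "pi12"], q, 0)) else NA_real_
  structure(list(n_causal_1 = n1, n_causal_2 = n2, n_shared = nsh,
                 unique_1 = n1 - nsh, unique_2 = n2 - nsh,
                 se_shared = se_sh, se_unique_1 = se_sh,
                 se_unique_2 = se_sh,
                 n_shared_raw = fit$params$pi12 * M,
                 rg_mixer = expected_rg(fit$params), M = M),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("polygenic overlap (variants explaining 90% of h2):\n")
  cat(sprintf("  unique trait 1: %s   shared: %s (se %s)   unique trait 2: %s\n",
              format_kcount(x$unique_1), format_kcount(x$n_shared),
              ifelse(is.na(x$se_shared), "NA", format_kcount(x$se_shared)),
              format_kcount(x$unique_2)))
  cat(sprintf("  mixture-implied rg = %.3f\n", x$rg_mixer))
  invisible(x)
}

#' Conditional Q-Q curves of cross-trait enrichment
#'
#' Stratifies the primary trait's p-values by significance in a
#' conditioning trait and compares each stratum's quantiles with the
#' uniform expectation.  Leftward separation of successively stricter
#' strata is the classic signature of polygenic overlap.  A scalar shift
#' statistic — the difference in median `-log10 p` between the strictest
#' nonempty stratum and the all-SNPs stratum — is attached.
#'
#' @param primary,conditioning `sumstats` objects on a shared universe.
#' @param thresholds Conditioning p-value thresholds
#'   (default `c(1, 0.1, 0.01, 0.001)`).
#' @return A `conditional_qq` object with per-stratum curves
#'   (`expected`, `observed`, both `-log10` scale) and `shift`.
#' @export
conditional_qq <- function(primary, conditioning,
                           thresholds = c(1, 0.1, 0.01, 0.001)) {
  common <- intersect(primary$data$snp, conditioning$data$snp)
  pp <- primary$data$p[match(common, primary$data$snp)]
  pc <- conditioning$data$p[match(common, conditioning$data$snp)]
  thresholds <- sort(thresholds, decreasing = TRUE)
  strata <- list()
  medians <- c()
  for (tau in thresholds) {
    sel <- pc <= tau
    if (!any(sel)) {
      warning("empty stratum at conditioning threshold ", tau, "; omitted")
      next
    }
    p <- sort(pp[sel])
    n <- length(p)
    strata[[as.character(tau)]] <-
      data.frame(expected = -log10((seq_len(n) - 0.5) / n),
                 observed = -log10(pmax(p, 1e-300)))
    medians[as.character(tau)] <- stats::median(-log10(pmax(p, 1e-300)))
  }
  shift <- if (length(medians) >= 2)
    unname(medians[length(medians)] - medians[1]) else 0
  structure(list(strata = strata, thresholds = thresholds, shift = shift,
                 primary = primary$trait_id,
                 conditioning = conditioning$trait_id),
            class = "conditional_qq")
}

#' @export
print.conditional_qq <- function(x, ...) {
  cat(sprintf("conditional Q-Q: %s | %s; shift statistic %.3f\n",
              x$primary, x$conditioning, x$shift))
  for (nm in names(x$strata))
    cat(sprintf("  p_cond <= %-7s : %d SNPs\n", nm, nrow(x$strata[[nm]])))
  invisible(x)
}

#' @export
plot.conditional_qq <- function(x, ...) {
  xmax <- max(vapply(x$strata, function(s) max(s$expected), 0))
  ymax <- max(vapply(x$strata, function(s) max(s$observed), 0))
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, ymax),
                 xlab = expression(-log[10] ~ "expected p"),
                 ylab = expression(-log[10] ~ "observed p"),
                 main = sprintf("%s conditioned on %s", x$primary,
                                x$conditioning), ...)
  graphics::abline(0, 1, col = "grey")
  cols <- grDevices::hcl.colors(length(x$strata), "Blues 3", rev = TRUE)
  for (i in seq_along(x$strata))
    graphics::lines(x$strata[[i]]$expected, x$strata[[i]]$observed,
                    col = cols[i], lwd = 2)
  graphics::legend("topleft", bty = "n", lwd = 2, col = cols,
                   legend = paste0("p <= ", names(x$strata)))
  invisible(x)
}
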