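#' Four-component bivariate causal mixture parameters
#'
#' The generative architecture for a pair of traits: each SNP is null for
#' both traits (probability `pi0`), causal only for trait 1 (`pi1`), only
#' for trait 2 (`pi2`), or causal for both (`pi12`).  Nonzero effects are
#' Gaussian on the standardized-genotype scale with per-causal-variant
#' variances `sigma1_sq`, `sigma2_sq`; in the shared component the two
#' effects are correlated with correlation `rho12`.
#'
#' @param pi0,pi1,pi2,pi12 Component probabilities (must sum to 1).
#' @param sigma1_sq,sigma2_sq Per-causal-variant effect variances.
#' @param rho12 Effect correlation in the shared component, in `[-1, 1]`.
#' @return A `mixture_params` object.
#' @export
mixture_params <- function(pi0, pi1, pi2, pi12, sigma1_sq, sigma2_sq,
                           rho12 = 0) {
  p <- c(pi0, pi1, pi2, pi12)
  if (any(p < 0)) stop("mixture probabilities must be nonnegative")
  if (abs(sum(p) - 1) > 1e-8) stop("mixture probabilities must sum to 1")
  stopifnot(sigma1_sq > 0, sigma2_sq > 0, rho12 >= -1, rho12 <= 1)
  structure(list(pi0 = pi0, pi1 = pi1, pi2 = pi2, pi12 = pi12,
                 sigma1_sq = sigma1_sq, sigma2_sq = sigma2_sq,
                 rho12 = rho12),
            class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, ...) {
  cat(sprintf(
    "causal mixture: pi0=%.4g pi1=%.4g pi2=%.4g pi12=%.4g  s1^2=%.3g s2^2=%.3g rho12=%.2f\n",
    x$pi0, x$pi1, x$pi2, x$pi12, x$sigma1_sq, x$sigma2_sq, x$rho12))
  invisible(x)
}

#' Draw per-SNP causal components and effect sizes
#'
#' @param params A [mixture_params()] object.
#' @param M Number of SNPs.
#' @param seed RNG seed (draws are reproducible and leave the caller's RNG
#'   state untouched).
#' @return A `sim_truth` object: list with `component` (factor with levels
#'   `null, unique1, unique2, shared`), `beta` (2 x M effect matrix) and
#'   `h2` (length-2 realized heritabilities, `rowSums(beta^2)`).
#' @export
draw_effects <- function(params, M, seed = 1) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  probs <- c(params$pi0, params$pi1, params$pi2, params$pi12)
  comp <- sample.int(4L, M, replace = TRUE, prob = probs)
  beta <- matrix(0, 2, M)
  s1 <- sqrt(params$sigma1_sq); s2 <- sqrt(params$sigma2_sq)
  i1 <- comp == 2L; i2 <- comp == 3L; i12 <- comp == 4L
  beta[1, i1] <- stats::rnorm(sum(i1), 0, s1)
  beta[2, i2] <- stats::rnorm(sum(i2), 0, s2)
  if (any(i12)) {
    n12 <- sum(i12)
    x <- stats::rnorm(n12); y <- stats::rnorm(n12)
    beta[1, i12] <- s1 * x
    beta[2, i12] <- s2 * (params$rho12 * x + sqrt(1 - params$rho12^2) * y)
  }
  structure(list(
    component = factor(c("null", "unique1", "unique2", "shared")[comp],
                       levels = c("null", "unique1", "unique2", "shared")),
    beta = beta, h2 = rowSums(beta^2)),
    class = "sim_truth")
}

#' Simulate GWAS z-scores from causal effects and an LD structure
#'
#' The standard summary-statistics generative model on standardized
#' genotypes: for trait t, `z_t = sqrt(N_t) R beta_t + eta_t` with noise
#' `eta_t ~ N(0, (1 + N_t a_t) R)`; at each SNP the noise of different
#' traits is correlated with correlation `r0` (sample overlap).  `a_t` is a
#' per-trait confounding inflation, giving an LD score regression intercept
#' of `1 + N_t a_t`.
#'
#' @param beta Traits x SNPs effect matrix (or a `sim_truth`, whose 2-row
#'   `beta` is used).
#' @param ld An [ld_info] (block-analytic or dense).
#' @param n Per-trait sample sizes (recycled).
#' @param inflation Per-trait confounding `a_t >= 0` (recycled; default 0).
#' @param r0 Cross-trait noise correlation in `(-1, 1)` (default 0).
#' @param seed RNG seed.
#' @param trait_ids Optional trait labels.
#' @return List of `sumstats` objects (one per trait) with p-values computed
#'   from z; the effect matrix and realized heritabilities are attached as
#'   attribute `"truth"`.
#' @export
simulate_zscores <- function(beta, ld, n, inflation = 0, r0 = 0, seed = 1,
                             trait_ids = NULL) {
  if (inherits(beta, "sim_truth")) beta <- beta$beta
  beta <- rbind(beta)
  T_ <- nrow(beta); M <- ncol(beta)
  if (M != length(ld$snp_ids)) stop("effect matrix does not match LD universe")
  n <- rep_len(n, T_); inflation <- rep_len(inflation, T_)
  stopifnot(all(n > 0), all(inflation >= 0), abs(r0) < 1)
  if (is.null(trait_ids)) trait_ids <- paste0("trait", seq_len(T_))

  old <- local_seed(seed)
  on.exit(restore_seed(old))

  # trait-correlated standard normals: rows are traits
  Lt <- chol_trait(T_, r0)
  mean_part <- sqrt(n) * smear_ld(beta, ld)          # sqrt(N_t) * R beta_t
  E <- Lt %*% matrix(stats::rnorm(T_ * M), T_, M)    # iid over SNPs
  if (is.null(ld$r)) {
    G <- Lt %*% matrix(stats::rnorm(T_ * max(ld$block_of)), T_,
                       max(ld$block_of))
    rho <- ld$rho_of
    eta <- sweep(E, 2, sqrt(1 - rho), "*") +
      sweep(G[, ld$block_of, drop = FALSE], 2, sqrt(rho), "*")
  } else {
    Lr <- chol(psd_floor(ld$r, rescale = FALSE))
    eta <- E %*% Lr
  }
  z <- mean_part + sqrt(1 + n * inflation) * eta
  out <- vector("list", T_)
  for (t in seq_len(T_)) {
    out[[t]] <- sumstats(trait_ids[t], snp = ld$snp_ids, chr = ld$meta$chr,
                         bp = ld$meta$bp, a1 = "A", a2 = "G",
                         z = z[t, ], n = n[t])
  }
  names(out) <- trait_ids
  attr(out, "truth") <- list(beta = beta, h2 = rowSums(beta^2),
                             n = n, inflation = inflation, r0 = r0,
                             seed = seed)
  out
}

chol_trait <- function(T_, r0) {
  if (T_ == 1L) return(matrix(1, 1, 1))
  V <- matrix(r0, T_, T_); diag(V) <- 1
  t(chol(V))
}

# R %*% beta_t for each trait row, exploiting block structure when available
smear_ld <- function(beta, ld) {
  if (is.null(ld$r)) {
    bs <- t(rowsum(t(beta), ld$block_of))          # T x n_blocks block sums
    sweep(beta, 2, 1 - ld$rho_of, "*") +
      sweep(bs[, ld$block_of, drop = FALSE], 2, ld$rho_of, "*")
  } else {
    beta %*% ld$r
  }
}

#' Genetic correlation implied by mixture parameters
#'
#' `rg = pi12 rho12 s1 s2 / sqrt((pi1 + pi12) s1^2 (pi2 + pi12) s2^2)`:
#' the correlation of per-SNP effects across the genome, which shrinks the
#' shared-component correlation by the fraction of each trait's causal
#' variants that are shared.
#'
#' @param params A [mixture_params()] object.
#' @return Scalar genetic correlation; 0 when `pi12 = 0`.
#' @export
expected_rg <- function(params) {
  c1 <- params$pi1 + params$pi12
  c2 <- params$pi2 + params$pi12
  if (c1 <= 0 && c2 <= 0) stop("both traits have no causal variants")
  if (params$pi12 == 0) return(0)
  s1 <- sqrt(params$sigma1_sq); s2 <- sqrt(params$sigma2_sq)
  params$pi12 * params$rho12 * s1 * s2 /
    sqrt(c1 * params$sigma1_sq * c2 * params$sigma2_sq)
}

#' Simulate a trait with annotation-structured heritability
#'
#' Univariate effects `beta_j ~ N(0, sum_c tau_c a_jc)`, then z-scores via
#' [simulate_zscores()].
#'
#' @param annot SNP x category 0/1 matrix.
#' @param tau Per-category per-SNP effect variances.
#' @param ld An [ld_info] over the same SNPs.
#' @param n Sample size.
#' @param inflation Confounding inflation (default 0).
#' @param seed RNG seed.
#' @param trait_id Trait label.
#' @return List with `stats` (a `sumstats`) and `truth`
#'   (`beta`, `h2`, per-category realized `h2_c`).
#' @export
simulate_annotated <- function(annot, tau, ld, n, inflation = 0, seed = 1,
                               trait_id = "annotated") {
  annot <- as.matrix(annot)
  var_j <- drop(annot %*% tau)
  if (any(var_j < 0)) stop("negative per-SNP effect variance")
  old <- local_seed(seed)
  beta <- stats::rnorm(length(var_j), 0, sqrt(var_j))
  restore_seed(old)
  stats <- simulate_zscores(matrix(beta, 1), ld, n, inflation = inflation,
                            seed = seed + 1L, trait_ids = trait_id)[[1]]
  h2_c <- drop(crossprod(annot, beta^2))
  list(stats = stats,
       truth = list(beta = beta, h2 = sum(beta^2), h2_c = h2_c))
}
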