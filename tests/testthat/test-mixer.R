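test_that("null mixture density is the closed-form bivariate normal", {
  p0 <- mixture_params(1, 0, 0, 0, 1e-3, 1e-3, 0)
  prof <- list(r2 = c(1, 0.36), count = c(1, 9))
  md <- mixture_density(p0, rho0 = 0.3, sigma0_sq = c(1, 1),
                        N = c(1e4, 1e4), profile = prof)
  S <- matrix(c(1, 0.3, 0.3, 1), 2)
  Sinv <- solve(S); dt <- det(S)
  tgt <- outer(md$z, md$z, function(a, b)
    exp(-0.5 * (Sinv[1, 1] * a^2 + 2 * Sinv[1, 2] * a * b +
                  Sinv[2, 2] * b^2)) / (2 * pi * sqrt(dt)))
  expect_lt(max(abs(md$density - tgt)), 1e-6)
  expect_lt(md$clip_mass, 1e-9)
})

test_that("single-SNP LD with pi12 = 1 matches the N-scaled closed form", {
  p1 <- mixture_params(0, 0, 0, 1, 2e-3, 1e-3, 0.6)
  md <- mixture_density(p1, 0, c(1, 1), N = c(2e4, 3e4),
                        profile = list(r2 = 1, count = 1),
                        n_grid = 256, zmax = 40)
  S <- diag(2) + matrix(c(2e4 * 2e-3,
                          sqrt(2e4 * 3e4) * 0.6 * sqrt(2e-3 * 1e-3),
                          sqrt(2e4 * 3e4) * 0.6 * sqrt(2e-3 * 1e-3),
                          3e4 * 1e-3), 2)
  Sinv <- solve(S); dt <- det(S)
  tgt <- outer(md$z, md$z, function(a, b)
    exp(-0.5 * (Sinv[1, 1] * a^2 + 2 * Sinv[1, 2] * a * b +
                  Sinv[2, 2] * b^2)) / (2 * pi * sqrt(dt)))
  expect_lt(max(abs(md$density - tgt)), 1e-6)
})

test_that("mixture densities integrate to 1 across parameter points", {
  prof <- list(r2 = c(1, 0.25, 0.04), count = c(1, 6, 12))
  pts <- list(mixture_params(0.99, 0.004, 0.005, 0.001, 2e-3, 1e-3, 0.5),
              mixture_params(0.9, 0.05, 0.04, 0.01, 5e-4, 5e-4, -0.7),
              mixture_params(0.997, 0, 0, 0.003, 1e-3, 2e-3, 0.9))
  for (p in pts) {
    md <- mixture_density(p, 0.1, c(1.02, 1.05), N = c(2e4, 2e4),
                          profile = prof, n_grid = 256, zmax = 25)
    expect_lt(abs(sum(md$density) * md$dz^2 - 1), 1e-3)
  }
})

test_that("too-narrow grids are rejected with an aliasing error", {
  p1 <- mixture_params(0, 0, 0, 1, 2e-3, 1e-3, 0.6)
  expect_error(mixture_density(p1, 0, c(1, 1), N = c(2e4, 3e4),
                               profile = list(r2 = 1, count = 1),
                               n_grid = 64, zmax = 8), "aliasing")
})

test_that("univariate fit recovers a sparse polygenic architecture", {
  M <- 30000; N <- 50000; piu <- 5e-3; h2 <- 0.3
  ld <- ld_block_structure(M, 10, rho = 0.6)
  p <- mixture_params(1 - piu, piu, 0, 0, h2 / (piu * M),
                      h2 / (piu * M), 0)
  tr <- draw_effects(p, M, seed = 1)
  ss <- simulate_zscores(rbind(tr$beta[1, ]), ld, n = N, seed = 2)
  fit <- fit_univariate(ss[[1]], ld, subsample = 15000, seed = 3)
  expect_lt(abs(log2(fit$pi_u / piu)), 1)            # within a factor of 2
  expect_lt(abs(fit$h2_implied / tr$h2[1] - 1), 0.2) # implied h2 within 20%
  expect_gte(fit$sigma0_sq, 1)
})

test_that("an all-null trait yields essentially zero implied heritability", {
  M <- 20000
  ld <- ld_block_structure(M, 10, rho = 0.6)
  ss <- simulate_zscores(matrix(0, 1, M), ld, n = 30000, seed = 5)
  fit <- fit_univariate(ss[[1]], ld, subsample = 10000, seed = 6)
  expect_lt(fit$h2_implied, 0.02)
})

test_that("doubling the subsample barely moves the per-SNP loglik", {
  M <- 20000; N <- 30000; piu <- 3e-3
  ld <- ld_block_structure(M, 10, rho = 0.6)
  p <- mixture_params(1 - piu, piu, 0, 0, 0.3 / (piu * M),
                      0.3 / (piu * M), 0)
  ss <- simulate_zscores(rbind(draw_effects(p, M, seed = 7)$beta[1, ]),
                         ld, n = N, seed = 8)
  f1 <- fit_univariate(ss[[1]], ld, subsample = 5000, seed = 9)
  f2 <- fit_univariate(ss[[1]], ld, subsample = 10000, seed = 9)
  expect_lt(abs(f1$loglik / f1$n_used - f2$loglik / f2$n_used) /
              abs(f2$loglik / f2$n_used), 0.01)
})

test_that("the bivariate likelihood is symmetric under trait exchange", {
  M <- 5000
  ld <- ld_block_structure(M, 10, rho = 0.6)
  p <- mixture_params(0.992, 0.003, 0.004, 0.001, 2e-3, 1e-3, 0.6)
  ss <- simulate_zscores(draw_effects(p, M, seed = 10), ld,
                         n = c(2e4, 3e4), seed = 11)
  p_swap <- mixture_params(0.992, 0.004, 0.003, 0.001, 1e-3, 2e-3, 0.6)
  ll <- bivariate_loglik(ss[[1]], ss[[2]], ld, p, rho0 = 0.2,
                         sigma0_sq = c(1, 1.1))
  ll_swap <- bivariate_loglik(ss[[2]], ss[[1]], ld, p_swap, rho0 = 0.2,
                              sigma0_sq = c(1.1, 1))
  expect_equal(ll, ll_swap, tolerance = 1e-10)
})

test_that("the truth outscores perturbed parameters on a large simulation", {
  M <- 20000; N <- 40000; piu <- 3e-3
  s2 <- 0.3 / (piu * M)
  ld <- ld_block_structure(M, 10, rho = 0.6)
  p <- mixture_params(1 - 1.5 * piu, piu / 2, piu / 2, piu / 2, s2, s2,
                      0.7)
  ss <- simulate_zscores(draw_effects(p, M, seed = 12), ld, n = N,
                         seed = 13)
  ll_truth <- bivariate_loglik(ss[[1]], ss[[2]], ld, p,
                               subsample = 8000)
  for (pp in list(mixture_params(1 - 2.25 * piu, 0.75 * piu, 0.75 * piu,
                                 0.75 * piu, s2, s2, 0.7),
                  mixture_params(1 - 1.5 * piu, piu / 2, piu / 2, piu / 2,
                                 1.5 * s2, 1.5 * s2, 0.7),
                  mixture_params(1 - 1.5 * piu, piu / 2, piu / 2, piu / 2,
                                 s2, s2, 0.35))) {
    expect_gt(ll_truth, bivariate_loglik(ss[[1]], ss[[2]], ld, pp,
                                         subsample = 8000))
  }
})

test_that("n90 has the point-mass limit, scale invariance and sane value", {
  expect_equal(polygenicity_n90(0.01, 1, 1e5, model = "point"),
               0.9 * 0.01 * 1e5)
  a <- polygenicity_n90(0.01, 1, 1e5)
  b <- polygenicity_n90(0.01, 42, 1e5)
  expect_lt(abs(a - b), 1e-10)
  expect_equal(polygenicity_n90(0, 1, 1e5), 0)
  # Gaussian effects concentrate: far fewer than 90% of causals needed
  expect_lt(a, 0.5 * 0.01 * 1e5)
  expect_gt(a, 0.3 * 0.01 * 1e5)
})

test_that("overlap summaries satisfy the Venn identities", {
  fake_fit <- structure(list(
    params = mixture_params(0.994, 0.002, 0.003, 0.001, 1e-3, 1e-3, 0.8),
    pi_u = c(0.003, 0.004), boot = NULL, M = 1e5), class = "mixer_bivariate")
  s <- overlap_summary(fake_fit)
  expect_equal(s$unique_1 + s$n_shared, s$n_causal_1, tolerance = 1e-12)
  expect_equal(s$unique_2 + s$n_shared, s$n_causal_2, tolerance = 1e-12)
  expect_lte(s$n_shared, min(s$n_causal_1, s$n_causal_2))
  expect_equal(s$rg_mixer, expected_rg(fake_fit$params))
  expect_equal(s$n_shared_raw, 0.001 * 1e5)

  fake0 <- fake_fit
  fake0$params <- mixture_params(0.995, 0.002, 0.003, 0, 1e-3, 1e-3, 0)
  expect_equal(overlap_summary(fake0)$n_shared, 0)

  # complete overlap: shared equals both margins
  fakec <- fake_fit
  fakec$params <- mixture_params(0.997, 0, 0, 0.003, 1e-3, 1e-3, 0.9)
  fakec$pi_u <- c(0.003, 0.003)
  sc <- overlap_summary(fakec)
  expect_equal(sc$n_shared, sc$n_causal_1, tolerance = 1e-12)
})

test_that("conditional Q-Q is flat for independent null traits", {
  set.seed(30)
  M <- 20000
  shifts <- replicate(50, {
    mk <- function(id) sumstats(id, sprintf("s%05d", 1:M), "1", 1:M,
                                "A", "G", z = rnorm(M), n = 100)
    conditional_qq(mk("a"), mk("b"), thresholds = c(1, 0.1, 0.01))$shift
  })
  expect_lt(abs(mean(shifts)), 0.1)
})

test_that("polygenic overlap produces increasing leftward Q-Q separation", {
  M <- 20000; piu <- 5e-3; s2 <- 0.4 / (piu * M)
  ld <- ld_block_structure(M, 10, rho = 0.5)
  p <- mixture_params(1 - piu, 0, 0, piu, s2, s2, 0.9)
  pos <- 0
  for (r in 1:10) {
    ss <- simulate_zscores(draw_effects(p, M, seed = 40 + r), ld,
                           n = 5e4, seed = 60 + r)
    cq <- conditional_qq(ss[[1]], ss[[2]])
    if (cq$shift > 0) pos <- pos + 1
  }
  expect_gte(pos, 9)
  # self-conditioning dominates cross-conditioning on the same data
  ss <- simulate_zscores(draw_effects(p, M, seed = 99), ld, n = 5e4,
                         seed = 98)
  self_shift <- conditional_qq(ss[[1]], ss[[1]])$shift
  cross_shift <- conditional_qq(ss[[1]], ss[[2]])$shift
  expect_gt(self_shift, cross_shift)
})

test_that("empty conditioning strata are omitted with a warning", {
  ssa <- sumstats("a", paste0("s", 1:100), "1", 1:100, "A", "G",
                  z = rnorm(100), n = 10)
  ssb <- sumstats("b", paste0("s", 1:100), "1", 1:100, "A", "G",
                  z = rep(0.1, 100), n = 10)
  expect_warning(conditional_qq(ssa, ssb, thresholds = c(1, 1e-8)),
                 "empty stratum")
})
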