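#' Delete-one block jackknife
#'
#' Generic leave-one-block-out jackknife over per-block inputs.  The
#' estimator is a reduction over a list of blocks and may return a scalar or
#' a vector; standard errors use the pseudo-value formula
#' `se^2 = (B - 1) / B * sum_b (theta_(-b) - mean(theta_(-b)))^2`.
#'
#' @param blocks List of per-block inputs (sufficient statistics, index
#'   vectors, ...).
#' @param estimator Function taking a list of blocks and returning the
#'   estimate computed from those blocks only.
#' @return List with `estimate` (on all blocks), `se`, and `loo` (matrix of
#'   leave-one-out estimates, blocks in rows).
#' @export
jackknife <- function(blocks, estimator) {
  B <- length(blocks)
  if (B < 2) stop("jackknife needs at least 2 blocks")
  est <- estimator(blocks)
  loo <- matrix(NA_real_, B, length(est))
  for (b in seq_len(B)) {
    loo[b, ] <- tryCatch(estimator(blocks[-b]),
                         error = function(e)
                           stop("estimator failed leaving out block ", b,
                                ": ", conditionMessage(e)))
  }
  ctr <- sweep(loo, 2, colMeans(loo))
  se <- sqrt((B - 1) / B * colSums(ctr^2))
  list(estimate = est, se = se, loo = loo)
}

# weighted least squares from block-accumulated cross-products
wls_block_stats <- function(X, y, w, block_id) {
  nb <- max(block_id)
  blocks <- vector("list", nb)
  for (b in seq_len(nb)) {
    i <- which(block_id == b)
    Xi <- X[i, , drop = FALSE]; wi <- w[i]
    blocks[[b]] <- list(xtx = crossprod(Xi, Xi * wi),
                        xty = crossprod(Xi, y[i] * wi))
  }
  blocks
}

wls_solve <- function(blocks, ridge = 0) {
  A <- Reduce(`+`, lapply(blocks, `[[`, "xtx"))
  b <- Reduce(`+`, lapply(blocks, `[[`, "xty"))
  if (ridge > 0) A <- A + diag(ridge, nrow(A))
  drop(solve(A, b))
}

align_to_ld <- function(stats, ld) {
  idx <- match(ld$snp_ids, stats$data$snp)
  keep <- !is.na(idx)
  list(ld_idx = which(keep), stats_idx = idx[keep])
}

block_ids <- function(n, n_blocks) {
  as.integer(cut(seq_len(n), breaks = n_blocks, labels = FALSE))
}

#' Univariate LD score regression
#'
#' Fits `E[z_j^2] = intercept + N_j (h2 / M) l_j` by weighted least squares
#' of the chi-square statistics on LD scores.  Weights start at
#' `1 / max(l_j, 1)` and are updated once using the fitted mean (two-step
#' scheme; `weight_iters` fits in total).  Standard errors come from a
#' delete-one block jackknife over `n_blocks` contiguous SNP blocks.
#' An intercept above 1 measures confounding inflation; the slope estimates
#' SNP heritability on the observed scale.
#'
#' @param stats A `sumstats` object.
#' @param ld An [ld_info]; SNPs are matched by id.
#' @param n_blocks Jackknife blocks (default 200).
#' @param M Number of SNPs the heritability refers to (default: size of the
#'   LD universe).
#' @param max_chisq Optional cap; SNPs with `z^2` above it are dropped
#'   (default `Inf`, no cap).
#' @param weight_iters Number of weighted fits (default 2).
#' @return An `ldsc_h2` object: `h2, h2_se, intercept, intercept_se,
#'   mean_chi2, n_snps_used, M, n_blocks`.
#' @export
fit_h2 <- function(stats, ld, n_blocks = 200, M = NULL, max_chisq = Inf,
                   weight_iters = 2) {
  al <- align_to_ld(stats, ld)
  if (is.null(M)) M <- length(ld$snp_ids)
  z <- stats$data$z[al$stats_idx]
  N <- stats$data$n[al$stats_idx]
  ell <- ld$ld_scores[al$ld_idx]
  y <- z^2
  ok <- is.finite(y) & y <= max_chisq
  n_dropped <- sum(!ok)
  y <- y[ok]; N <- N[ok]; ell <- ell[ok]
  n_used <- length(y)
  if (n_used <= n_blocks)
    stop("fewer usable SNPs (", n_used, ") than jackknife blocks")
  X <- cbind(intercept = 1, h2 = N * ell / M)
  w <- 1 / pmax(ell, 1)
  beta <- NULL
  for (it in seq_len(weight_iters)) {
    beta <- wls_solve(wls_block_stats(X, y, w, rep(1L, n_used)))
    fitted <- pmax(drop(X %*% beta), 0.1)
    w <- 1 / (pmax(ell, 1) * fitted^2)
  }
  bid <- block_ids(n_used, n_blocks)
  blocks <- wls_block_stats(X, y, w, bid)
  jk <- jackknife(blocks, wls_solve)
  structure(list(h2 = unname(jk$estimate[2]), h2_se = unname(jk$se[2]),
                 intercept = unname(jk$estimate[1]),
                 intercept_se = unname(jk$se[1]),
                 mean_chi2 = mean(y), n_snps_used = n_used,
                 n_dropped = n_dropped, M = M, n_blocks = n_blocks),
            class = "ldsc_h2")
}

#' @export
print.ldsc_h2 <- function(x, ...) {
  cat(sprintf("LD score regression (observed scale), %d SNPs, %d blocks\n",
              x$n_snps_used, x$n_blocks))
  cat(sprintf("  h2        = %.4f (se %.4f)\n", x$h2, x$h2_se))
  cat(sprintf("  intercept = %.4f (se %.4f)\n", x$intercept, x$intercept_se))
  cat(sprintf("  mean chi2 = %.4f\n", x$mean_chi2))
  invisible(x)
}

#' Bivariate LD score regression (genetic correlation)
#'
#' Fits `E[z_1j z_2j] = cross_intercept + sqrt(N_1j N_2j) (gcov / M) l_j`
#' and forms `rg = gcov / sqrt(h2_1 h2_2)` with the univariate fits from
#' [fit_h2()].  The jackknife re-estimates the numerator and both
#' denominators on every leave-one-block-out subset, so the standard error
#' is for the full ratio.  The free cross-trait intercept absorbs sample
#' overlap.  The p-value is two-sided normal on `rg / rg_se`.
#'
#' @param stats1,stats2 `sumstats` objects on a harmonized SNP universe.
#' @param ld An [ld_info].
#' @param n_blocks Jackknife blocks (default 200).
#' @param M Reference SNP count (default: LD universe size).
#' @return An `ldsc_rg` object.
#' @export
fit_rg <- function(stats1, stats2, ld, n_blocks = 200, M = NULL) {
  if (is.null(M)) M <- length(ld$snp_ids)
  common <- intersect(intersect(ld$snp_ids, stats1$data$snp),
                      stats2$data$snp)
  ord <- match(common, ld$snp_ids)
  common <- common[order(ord)]
  i1 <- match(common, stats1$data$snp)
  i2 <- match(common, stats2$data$snp)
  z1 <- stats1$data$z[i1]; n1 <- stats1$data$n[i1]
  z2 <- stats2$data$z[i2]; n2 <- stats2$data$n[i2]
  ell <- ld$ld_scores[match(common, ld$snp_ids)]
  ok <- is.finite(z1) & is.finite(z2)
  z1 <- z1[ok]; z2 <- z2[ok]; n1 <- n1[ok]; n2 <- n2[ok]; ell <- ell[ok]
  n_used <- length(z1)
  if (n_used <= n_blocks)
    stop("fewer usable SNPs (", n_used, ") than jackknife blocks")

  X1 <- cbind(1, n1 * ell / M)
  X2 <- cbind(1, n2 * ell / M)
  Xx <- cbind(1, sqrt(n1 * n2) * ell / M)
  yx <- z1 * z2
  w0 <- 1 / pmax(ell, 1)
  b1 <- wls_solve(wls_block_stats(X1, z1^2, w0, rep(1L, n_used)))
  b2 <- wls_solve(wls_block_stats(X2, z2^2, w0, rep(1L, n_used)))
  bx <- wls_solve(wls_block_stats(Xx, yx, w0, rep(1L, n_used)))
  f1 <- pmax(drop(X1 %*% b1), 0.1)
  f2 <- pmax(drop(X2 %*% b2), 0.1)
  fx <- drop(Xx %*% bx)
  w <- 1 / (pmax(ell, 1) * (f1 * f2 + fx^2))

  bid <- block_ids(n_used, n_blocks)
  bl <- list(b1 = wls_block_stats(X1, z1^2, w, bid),
             b2 = wls_block_stats(X2, z2^2, w, bid),
             bx = wls_block_stats(Xx, yx, w, bid))
  nb <- n_blocks
  est_rg <- function(keep) {
    c1 <- wls_solve(bl$b1[keep]); c2 <- wls_solve(bl$b2[keep])
    cx <- wls_solve(bl$bx[keep])
    h1 <- c1[2]; h2 <- c2[2]; gc <- cx[2]
    if (h1 <= 0 || h2 <= 0) return(rep(NA_real_, 3))
    unname(c(gc / sqrt(h1 * h2), gc, cx[1]))
  }
  full <- est_rg(seq_len(nb))
  if (any(is.na(full)))
    stop(errorCondition(
      "genetic correlation undefined: a heritability estimate is <= 0",
      class = "pleioscan_rg_undefined"))
  jk <- jackknife(as.list(seq_len(nb)),
                  function(keep) est_rg(unlist(keep)))
  rg <- full[1]; rg_se <- jk$se[1]
  p <- 2 * stats::pnorm(-abs(rg / rg_se))
  structure(list(rg = rg, rg_se = rg_se, p = p,
                 gcov = full[2], gcov_se = jk$se[2],
                 gcov_intercept = full[3],
                 n_snps_used = n_used, n_blocks = n_blocks, M = M),
            class = "ldsc_rg")
}

#' @export
print.ldsc_rg <- function(x, ...) {
  cat(sprintf("bivariate LD score regression, %d SNPs\n", x$n_snps_used))
  cat(sprintf("  rg = %.4f (se %.4f), p = %.3g\n", x$rg, x$rg_se, x$p))
  cat(sprintf("  genetic covariance = %.4g, cross-intercept = %.4f\n",
              x$gcov, x$gcov_intercept))
  invisible(x)
}

#' Stratified (partitioned) LD score regression
#'
#' Multiple weighted regression of `z^2` on per-category LD scores,
#' `E[z_j^2] = 1 + N_j sum_c tau_c l(j, c)`, with a free intercept.  A
#' baseline all-SNPs category is appended unless one of the supplied
#' columns is already all ones.  Per-category heritability is
#' `h2_c = sum_j a_jc (sum_c' tau_c' a_jc')` and enrichment is
#' `(h2_c / h2) / (M_c / M)`; `coeff_z_c = tau_c / se(tau_c)` with a
#' one-sided upper p-value.  Jackknife as in [fit_h2()].  Collinear
#' category sets fall back to a documented ridge penalty with a warning.
#'
#' @param stats A `sumstats`.
#' @param annot SNP x category 0/1 matrix aligned with the LD universe.
#' @param ld An [ld_info].
#' @param n_blocks Jackknife blocks (default 200).
#' @param M Reference SNP count (default: LD universe size).
#' @param ridge Relative ridge weight used only on rank deficiency
#'   (default 1e-6).
#' @return An `ldsc_partitioned` object with a per-category `table`
#'   data.frame and global `h2`, `h2_se`.
#' @export
fit_partitioned <- function(stats, annot, ld, n_blocks = 200, M = NULL,
                            ridge = 1e-6) {
  annot <- as.matrix(annot)
  if (is.null(colnames(annot)))
    colnames(annot) <- paste0("cat", seq_len(ncol(annot)))
  if (is.null(M)) M <- length(ld$snp_ids)
  has_base <- any(apply(annot, 2, function(a) all(a == 1)))
  if (!has_base) annot <- cbind(annot, base = 1)
  C <- ncol(annot)
  ellc <- ld_scores_annot(ld, annot)

  al <- align_to_ld(stats, ld)
  z <- stats$data$z[al$stats_idx]
  N <- stats$data$n[al$stats_idx]
  ellc <- ellc[al$ld_idx, , drop = FALSE]
  A <- annot[al$ld_idx, , drop = FALSE]
  ell0 <- ld$ld_scores[al$ld_idx]
  y <- z^2
  ok <- is.finite(y)
  y <- y[ok]; N <- N[ok]; ellc <- ellc[ok, , drop = FALSE]
  A <- A[ok, , drop = FALSE]; ell0 <- ell0[ok]
  n_used <- length(y)
  if (n_used <= n_blocks)
    stop("fewer usable SNPs (", n_used, ") than jackknife blocks")

  X <- cbind(intercept = 1, N * ellc)
  use_ridge <- FALSE
  solve_fun <- function(blocks) {
    Asum <- Reduce(`+`, lapply(blocks, `[[`, "xtx"))
    bsum <- Reduce(`+`, lapply(blocks, `[[`, "xty"))
    lam <- if (use_ridge) ridge * mean(diag(Asum)) else 0
    drop(solve(Asum + diag(lam, nrow(Asum)), bsum))
  }
  w <- 1 / pmax(ell0, 1)
  bl1 <- wls_block_stats(X, y, w, rep(1L, n_used))
  A1 <- Reduce(`+`, lapply(bl1, `[[`, "xtx"))
  if (rcond(A1) < 1e-12) {
    use_ridge <- TRUE
    warning("collinear annotation categories: ridge fallback (relative weight ",
            ridge, ")")
  }
  beta <- solve_fun(bl1)
  fitted <- pmax(drop(X %*% beta), 0.1)
  w <- 1 / (pmax(ell0, 1) * fitted^2)

  M_c <- colSums(A)
  estimator <- function(blocks) {
    cf <- solve_fun(blocks)
    tau <- cf[-1]
    var_j <- drop(A %*% tau)
    h2_c <- drop(crossprod(A, var_j))
    h2 <- sum(var_j)
    enr <- (h2_c / h2) / (M_c / M)
    c(tau, h2, enr)
  }
  bid <- block_ids(n_used, n_blocks)
  blocks <- wls_block_stats(X, y, w, bid)
  jk <- jackknife(blocks, estimator)
  est <- unname(jk$estimate); se <- unname(jk$se)
  tau <- est[seq_len(C)]; tau_se <- se[seq_len(C)]
  h2 <- est[C + 1]; h2_se <- se[C + 1]
  enr <- est[C + 1 + seq_len(C)]; enr_se <- se[C + 1 + seq_len(C)]
  coeff_z <- tau / tau_se
  tab <- data.frame(category = colnames(annot), M_c = M_c,
                    tau = tau, tau_se = tau_se, coeff_z = coeff_z,
                    p = stats::pnorm(coeff_z, lower.tail = FALSE),
                    h2_c = unname(drop(crossprod(A, drop(A %*% tau)))),
                    enrichment = enr, enrichment_se = enr_se,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, h2 = h2, h2_se = h2_se,
                 n_snps_used = n_used, M = M, n_blocks = n_blocks,
                 ridge_used = use_ridge),
            class = "ldsc_partitioned")
}

#' @export
print.ldsc_partitioned <- function(x, ...) {
  cat(sprintf("stratified LD score regression: h2 = %.4f (se %.4f)\n",
              x$h2, x$h2_se))
  print(x$table[, c("category", "M_c", "tau", "coeff_z", "p", "enrichment",
                    "enrichment_se")], digits = 3)
  invisible(x)
}
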