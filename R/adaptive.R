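#' Sum-of-powered-score statistic for one trait
#'
#' The gamma-norm of a gene's z-score vector,
#' `SPUs(gamma; z) = (sum_j |z_j|^gamma)^(1/gamma)`.  Absolute values are
#' taken inside the norm so that odd powers remain well defined; the
#' `signed` compatibility mode instead returns the raw signed power sum
#' `sum_j z_j^gamma` (no outer root).  `gamma = Inf` returns `max |z_j|`,
#' the sup-norm limit.
#'
#' @param z Numeric vector of per-SNP z-scores for one trait.
#' @param gamma Power `>= 1` (may be `Inf`).
#' @param signed Use the signed power-sum convention (default FALSE).
#' @return Scalar statistic.
#' @export
spus <- function(z, gamma, signed = FALSE) {
  if (signed) return(sum(z^gamma))
  if (is.infinite(gamma)) return(max(abs(z)))
  stopifnot(gamma >= 1)
  sum(abs(z)^gamma)^(1 / gamma)
}

#' Multi-trait sum-of-powered-score statistic
#'
#' `MTSPUsSet(gamma1, gamma2; Z) = sum_h SPUs(gamma1; Z_h)^gamma2`, the
#' second power weighting traits as the first weights SNPs.
#'
#' @param Z Traits x SNPs z-score matrix.
#' @param gamma1,gamma2 SNP and trait powers (`>= 1`).
#' @return Scalar statistic.
#' @export
mtspusset <- function(Z, gamma1, gamma2) {
  sum(apply(rbind(Z), 1, spus, gamma = gamma1)^gamma2)
}

# row-wise SPUs over a stacked matrix, one column per gamma
spus_rows <- function(W, gammas) {
  A <- abs(W)
  out <- matrix(NA_real_, nrow(W), length(gammas))
  for (k in seq_along(gammas)) {
    g <- gammas[k]
    out[, k] <- if (is.infinite(g)) Reduce(pmax, asplit(A, 2))
                else rowSums(A^g)^(1 / g)
  }
  out
}

#' Estimate the among-trait correlation of null z-scores
#'
#' Pearson correlation of trait z-scores across LD-pruned SNPs after
#' excluding SNPs with any `|z| >= z_cap` (signal exclusion; under the null
#' the cross-trait z correlation estimates the noise correlation induced by
#' sample overlap).  The result is eigenvalue-floored to a proper
#' correlation matrix.
#'
#' @param z_matrix Traits x SNPs matrix (column names are SNP ids).
#' @param keep_snps Optional character vector of pruned SNP ids to use.
#' @param z_cap Exclusion threshold on `|z|` (default 2).
#' @param min_snps Minimum usable SNPs (default 500; hard error below).
#' @return Traits x traits correlation matrix.
#' @export
estimate_trait_correlation <- function(z_matrix, keep_snps = NULL,
                                       z_cap = 2, min_snps = 500) {
  sel <- rep(TRUE, ncol(z_matrix))
  if (!is.null(keep_snps)) sel <- colnames(z_matrix) %in% keep_snps
  sel <- sel & apply(abs(z_matrix) < z_cap, 2, all)
  if (sum(sel) < min_snps)
    stop("only ", sum(sel), " pruned null SNPs available (need >= ",
         min_snps, ")")
  if (nrow(z_matrix) == 1L) return(matrix(1, 1, 1))
  V <- stats::cor(t(z_matrix[, sel, drop = FALSE]))
  # the |z| < z_cap truncation attenuates correlations by the truncated
  # second moment; undo it to first order (exact as rho -> 0)
  att <- 1 - 2 * z_cap * stats::dnorm(z_cap) /
    (2 * stats::pnorm(z_cap) - 1)
  V <- V / att
  V[V > 1] <- 1; V[V < -1] <- -1
  diag(V) <- 1
  psd_floor(V)
}

#' Draw a matrix-normal null bank
#'
#' Null z-score matrices for a gene: `Z_b = L_V X_b L_R'` with `X_b` an
#' m x d standard normal matrix, so that the vectorized draw has covariance
#' `kron(R, V)` (among-trait covariance `V`, among-SNP covariance `R`).
#' Draws are generated in chunks; with a fixed seed the bank is
#' bit-reproducible.
#'
#' @param R d x d SNP correlation matrix (eigenvalue-floored internally).
#' @param V m x m trait correlation matrix.
#' @param B Number of draws.
#' @param seed RNG seed.
#' @param chunk Draws per chunk (memory bound).
#' @return B x (m*d) matrix; row b is `vec(Z_b)` (column-major: trait index
#'   fastest).
#' @export
simulate_null_bank <- function(R, V, B, seed = 1, chunk = 20000L) {
  m <- nrow(V); d <- nrow(R)
  Lr_t <- chol(psd_floor(R))           # upper: Y = X %*% Lr_t has rows N(0,R)
  Lv <- t(chol(psd_floor(V)))
  out <- matrix(NA_real_, B, m * d)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  done <- 0L
  while (done < B) {
    C <- as.integer(min(chunk, B - done))
    Z <- draw_bank_chunk(C, m, d, Lr_t, Lv)$Z
    for (cc in seq_len(C))
      out[done + cc, ] <- as.vector(Z[(cc - 1L) * m + seq_len(m), ,
                                      drop = FALSE])
    done <- done + C
  }
  out
}

# one chunk of C draws: Z is (C*m) x d with rows stacked draw-major,
# trait index fastest; Y holds the pre-mixing rows (each ~ N(0, R))
draw_bank_chunk <- function(C, m, d, Lr_t, Lv) {
  X <- matrix(stats::rnorm(C * m * d), C * m, d)
  Y <- X %*% Lr_t
  if (m == 1L) return(list(Z = Y, Y = Y))
  Z <- matrix(0, C * m, d)
  for (h in seq_len(m)) {
    acc <- 0
    for (hp in seq_len(h))
      acc <- acc + Lv[h, hp] * Y[seq(hp, C * m, by = m), , drop = FALSE]
    Z[seq(h, C * m, by = m), ] <- acc
  }
  list(Z = Z, Y = Y)
}

# Monte-Carlo core shared by aspus/mtaspusset/staged scans.
#
# One null bank serves every statistic of the gene (the double Monte-Carlo
# reuses the bank: each draw's per-cell p is its >= -rank among all draws,
# with the +1 correction guaranteeing valid p-values).  Per-trait aSPUs
# statistics are ranked against a single shared SPUs null stream (the
# pre-mixing rows, each marginally N(0, R)), which makes single-trait
# results invariant to trait order.
gene_mc_test <- function(Z, R, V, gamma1 = c(1, 2, 4, 8),
                         gamma2 = c(1, 2, 4, 8), B = 1000, seed = 1,
                         chunk = 20000L) {
  Z <- rbind(Z)
  m <- nrow(Z); d <- ncol(Z)
  stopifnot(nrow(R) == d, nrow(V) == m)
  n1 <- length(gamma1); n2 <- length(gamma2)
  Lr_t <- chol(psd_floor(R))
  Lv <- t(chol(psd_floor(V)))

  S_obs <- spus_rows(Z, gamma1)                     # m x n1
  mt_obs <- vapply(seq_len(n2), function(k2)
    colSums(S_obs^gamma2[k2]), numeric(n1))         # n1 x n2
  mt_null <- matrix(NA_real_, B, n1 * n2)
  tr_null <- matrix(NA_real_, B, n1)                # shared SPUs stream

  old <- local_seed(seed)
  done <- 0L
  while (done < B) {
    C <- as.integer(min(chunk, B - done))
    ch <- draw_bank_chunk(C, m, d, Lr_t, Lv)
    S <- spus_rows(ch$Z, gamma1)                    # (C*m) x n1
    rows <- done + seq_len(C)
    for (k1 in seq_len(n1)) {
      Sm <- matrix(S[, k1], m, C)
      for (k2 in seq_len(n2))
        mt_null[rows, (k2 - 1L) * n1 + k1] <- colSums(Sm^gamma2[k2])
    }
    tr_null[rows, ] <- spus_rows(ch$Y[seq(1L, C * m, by = m), ,
                                      drop = FALSE], gamma1)
    done <- done + C
  }
  restore_seed(old)

  mt <- adaptive_p(mt_null, as.vector(mt_obs))
  p_cells <- matrix(mt$p_obs, n1, n2,
                    dimnames = list(paste0("g1_", gamma1),
                                    paste0("g2_", gamma2)))
  amin <- arrayInd(which.min(mt$p_obs), c(n1, n2))
  p_aspus <- numeric(m)
  p_aspus_gamma <- matrix(NA_real_, m, n1,
                          dimnames = list(rownames(Z), paste0("g1_", gamma1)))
  aspus_argmin <- numeric(m)
  for (h in seq_len(m)) {
    tr <- adaptive_p(tr_null, S_obs[h, ])
    p_aspus[h] <- tr$p_adapt
    p_aspus_gamma[h, ] <- tr$p_obs
    aspus_argmin[h] <- gamma1[which.min(tr$p_obs)]
  }
  list(p_mt = mt$p_adapt, p_cells = p_cells,
       argmin = c(gamma1 = gamma1[amin[1]], gamma2 = gamma2[amin[2]]),
       p_aspus = p_aspus, p_aspus_gamma = p_aspus_gamma,
       aspus_argmin = aspus_argmin, B = B,
       min_attainable_p = 1 / (B + 1))
}

# adaptive minimum-p combination over a bank of null statistics:
# p_obs per column, per-draw minimum p via >= ranks, +1 corrections
adaptive_p <- function(Tnull, Tobs) {
  B <- nrow(Tnull)
  K <- ncol(Tnull)
  p_obs <- numeric(K)
  minp_b <- rep(Inf, B)
  for (k in seq_len(K)) {
    col <- Tnull[, k]
    p_obs[k] <- (1 + sum(col >= Tobs[k])) / (B + 1)
    r <- rank(col, ties.method = "max")
    minp_b <- pmin(minp_b, (B - r + 1) / B)
  }
  p_adapt <- (1 + sum(minp_b <= min(p_obs))) / (B + 1)
  list(p_obs = p_obs, p_adapt = p_adapt)
}

#' Adaptive single-trait gene test (aSPUs)
#'
#' Monte-Carlo p-value of the minimum over a gamma grid of SPUs p-values,
#' using one matrix-normal null bank of size `B`; each candidate power's
#' p-value and the adaptive combination share the bank, and all p-values
#' lie in `[1/(B+1), 1]`.
#'
#' @param z d-vector of the gene's z-scores.
#' @param R d x d SNP correlation matrix.
#' @param gamma1 Power grid (default `c(1, 2, 4, 8)`).
#' @param B Null draws (default 1000).
#' @param seed RNG seed.
#' @return List: `p` (adaptive), `p_gamma` (per power), `argmin_gamma`, `B`.
#' @export
aspus <- function(z, R, gamma1 = c(1, 2, 4, 8), B = 1000, seed = 1) {
  res <- gene_mc_test(matrix(z, 1), R, matrix(1, 1, 1), gamma1,
                      gamma2 = 1, B = B, seed = seed)
  list(p = res$p_aspus[1], p_gamma = unname(drop(res$p_aspus_gamma)),
       argmin_gamma = res$aspus_argmin[1], B = B)
}

#' Adaptive multi-trait gene test (MTaSPUsSet)
#'
#' Monte-Carlo p-value of the minimum over the `gamma1 x gamma2` grid of
#' MTSPUsSet p-values, with the single-bank double Monte-Carlo scheme;
#' per-trait aSPUs p-values from the same bank are returned alongside.
#'
#' @param Z m traits x d SNPs z-score matrix.
#' @param R d x d SNP correlation matrix (reference panel LD).
#' @param V m x m trait correlation matrix
#'   (see [estimate_trait_correlation()]).
#' @param gamma1,gamma2 SNP and trait power grids (default `c(1, 2, 4, 8)`).
#' @param B Null draws (default 1000).
#' @param seed RNG seed.
#' @param gene_id Optional label carried into the result.
#' @return A `gene_test` object: `p_mtaspusset`, `p_cells`, `argmin`,
#'   `p_aspus` (per trait), `B_used`, `min_attainable_p`.
#' @export
mtaspusset <- function(Z, R, V, gamma1 = c(1, 2, 4, 8),
                       gamma2 = c(1, 2, 4, 8), B = 1000, seed = 1,
                       gene_id = NA_character_) {
  res <- gene_mc_test(Z, R, V, gamma1, gamma2, B, seed)
  structure(list(gene_id = gene_id, p_mtaspusset = res$p_mt,
                 p_cells = res$p_cells, argmin = res$argmin,
                 p_aspus = res$p_aspus,
                 p_aspus_gamma = res$p_aspus_gamma,
                 aspus_argmin = res$aspus_argmin,
                 B_used = res$B, min_attainable_p = res$min_attainable_p),
            class = "gene_test")
}

#' @export
print.gene_test <- function(x, ...) {
  cat(sprintf("gene %s: MTaSPUsSet p = %.3g (B = %d, argmin gamma = %g,%g)\n",
              x$gene_id, x$p_mtaspusset, x$B_used, x$argmin[1], x$argmin[2]))
  cat("  per-trait aSPUs p:", signif(x$p_aspus, 3), "\n")
  invisible(x)
}

#' Staged Monte-Carlo escalation of the gene test
#'
#' Runs [mtaspusset()] at each replicate size in `schedule`, escalating to
#' the next stage only while the smallest p-value (multi-trait or any
#' per-trait) is below `escalate_factor / B` — i.e. while it is too close
#' to the attainable floor `1/(B+1)` to be resolved.  Each stage draws a
#' fresh bank with seed `seed + stage - 1`.
#'
#' @inheritParams mtaspusset
#' @param schedule Increasing replicate sizes
#'   (default `c(1e3, 1e4, 1e5, 1e6)`).
#' @param escalate_factor Escalation threshold multiplier (default 5).
#' @return A `gene_test` with `B_used` set to the stopping stage.
#' @export
staged_mtaspusset <- function(Z, R, V, gamma1 = c(1, 2, 4, 8),
                              gamma2 = c(1, 2, 4, 8),
                              schedule = c(1e3, 1e4, 1e5, 1e6),
                              escalate_factor = 5, seed = 1,
                              gene_id = NA_character_) {
  schedule <- as.integer(sort(schedule))
  res <- NULL
  for (s in seq_along(schedule)) {
    B <- schedule[s]
    res <- mtaspusset(Z, R, V, gamma1, gamma2, B = B, seed = seed + s - 1L,
                      gene_id = gene_id)
    if (min(res$p_mtaspusset, res$p_aspus) >= escalate_factor / B) break
  }
  res
}

gene_seed <- function(master, gene_id) {
  h <- 0
  for (ch in utf8ToInt(as.character(gene_id)))
    h <- (h * 31 + ch) %% 2147483647
  as.integer((master * 1000003 + h) %% 2147483647)
}

#' Genome scan for pleiotropic genes
#'
#' Runs the staged multi-trait adaptive test on every gene, with per-trait
#' aSPUs p-values from the same null banks, and classifies genes: the
#' per-test significance threshold is `alpha / G` (G = genes tested); a
#' gene is flagged *pleiotropic* when its multi-trait p is significant and
#' at least one single-trait p is significant, and *novel* when it is
#' pleiotropic and absent from the optional known-association table.
#' Per-gene seeds are derived from `seed` and a hash of the gene id, so the
#' scan result does not depend on gene order.
#'
#' @param z_matrix Traits x SNPs harmonized z matrix (from [harmonize()]).
#' @param gene_map Named list of SNP indices per gene
#'   (from [map_snps_to_genes()]).
#' @param ld An [ld_info] over the same SNP universe (same order).
#' @param V Trait correlation matrix; estimated from pruned SNPs via
#'   [estimate_trait_correlation()] when `NULL`.
#' @param gamma1,gamma2 Power grids.
#' @param schedule Replicate escalation schedule (default `c(1e3, 1e4)`;
#'   extend to `1e6` for publication-resolution floors).
#' @param alpha Family-wise error target (default 0.05).
#' @param known_genes Optional character vector of genes with established
#'   associations (drives the `novel` flag).
#' @param d_cap Maximum SNPs per gene (default 500; excess SNPs dropped
#'   with an audit entry).
#' @param seed Master seed.
#' @return A `gene_scan` object: per-gene `table` (gene, d, MTaSPUsSet p,
#'   per-trait aSPUs p, B used, flags), `threshold`, `audit`.
#' @export
gene_scan <- function(z_matrix, gene_map, ld, V = NULL,
                      gamma1 = c(1, 2, 4, 8), gamma2 = c(1, 2, 4, 8),
                      schedule = c(1e3, 1e4), alpha = 0.05,
                      known_genes = NULL, d_cap = 500, seed = 1) {
  if (ncol(z_matrix) != length(ld$snp_ids))
    stop("z matrix and LD universe disagree")
  traits <- rownames(z_matrix)
  if (is.null(traits)) traits <- paste0("trait", seq_len(nrow(z_matrix)))
  if (is.null(V)) {
    kept <- ld_prune(ld)
    V <- estimate_trait_correlation(z_matrix, keep_snps = kept)
  }
  genes <- names(gene_map)
  audit <- character()
  rows <- list()
  for (g in genes) {
    idx <- gene_map[[g]]
    if (length(idx) == 0L) {
      audit <- c(audit, paste0(g, ": no SNPs, skipped")); next
    }
    if (length(idx) > d_cap) {
      audit <- c(audit, paste0(g, ": ", length(idx), " SNPs capped at ",
                               d_cap))
      idx <- idx[seq_len(d_cap)]
    }
    R <- ld_submatrix(ld, idx)
    res <- staged_mtaspusset(z_matrix[, idx, drop = FALSE], R, V,
                             gamma1, gamma2, schedule = schedule,
                             seed = gene_seed(seed, g), gene_id = g)
    row <- data.frame(gene = g, d = length(idx),
                      p_mtaspusset = res$p_mtaspusset,
                      B_used = res$B_used, stringsAsFactors = FALSE)
    for (h in seq_along(traits))
      row[[paste0("p_", traits[h])]] <- res$p_aspus[h]
    rows[[g]] <- row
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  G <- nrow(tab)
  thr <- alpha / G
  pcols <- paste0("p_", traits)
  tab$pleiotropic <- tab$p_mtaspusset < thr &
    apply(tab[, pcols, drop = FALSE] < thr, 1, any)
  tab$novel <- tab$pleiotropic &
    !(tab$gene %in% (known_genes %||% character()))
  structure(list(table = tab, traits = traits, alpha = alpha,
                 threshold = thr, G = G, V = V, audit = audit),
            class = "gene_scan")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gene_scan <- function(x, ...) {
  cat(sprintf("gene scan: %d genes, per-test threshold %.3g (alpha %.2f)\n",
              x$G, x$threshold, x$alpha))
  np <- sum(x$table$pleiotropic)
  cat(sprintf("  %d pleiotropic gene%s", np, if (np == 1) "" else "s"))
  if (np > 0)
    cat(":", paste(x$table$gene[x$table$pleiotropic], collapse = ", "))
  cat("\n")
  if (length(x$audit)) cat("  audit:", length(x$audit), "entries\n")
  invisible(x)
}
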