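#' @title LD information objects
#' @description An `ld_info` object carries the SNP-SNP correlation structure
#' used throughout the package: either a dense window-limited correlation
#' matrix estimated from a reference panel ([compute_ld()]) or an analytic
#' block-equicorrelated structure ([ld_block_structure()]).  It also carries
#' per-SNP LD scores and a binned histogram of neighbor r-squared values
#' (counts and per-bin mean r-squared), the sufficient statistic for the
#' causal-mixture likelihood.
#' @name ld_info
NULL

new_ld_info <- function(snp_ids, meta, ld_scores, r2_edges, r2_counts,
                        r2_mean, r = NULL, block_of = NULL, rho_of = NULL,
                        window = NA_integer_, n_samples = NA_integer_) {
  structure(list(snp_ids = snp_ids, meta = meta, ld_scores = ld_scores,
                 r2_edges = r2_edges, r2_counts = r2_counts,
                 r2_mean = r2_mean, r = r, block_of = block_of,
                 rho_of = rho_of, window = window, n_samples = n_samples),
            class = "ld_info")
}

#' @export
print.ld_info <- function(x, ...) {
  cat("LD structure over", length(x$snp_ids), "SNPs;",
      if (is.null(x$r)) "block-analytic" else "panel-estimated", "\n")
  cat("  mean LD score:", round(mean(x$ld_scores), 3), "\n")
  invisible(x)
}

#' Compute LD matrices, LD scores and r-squared histograms from a panel
#'
#' Pearson correlations between dosage columns are computed within a window
#' of `window_snps` SNPs on the same chromosome; missing dosages are
#' mean-imputed per SNP.  The LD score of SNP j is `1 + sum of r^2` over its
#' window neighbors; with `bias_correct = TRUE` each off-diagonal r-squared
#' is first replaced by the unbiased `r^2 - (1 - r^2) / (n - 2)`, floored at
#' zero.  The histogram always bins the raw r-squared values so that the
#' per-SNP counts sum to the neighbor count.
#'
#' @param panel A `geno_panel`.
#' @param window_snps Window half-width in SNPs (default 50).
#' @param bias_correct Apply the finite-sample r-squared correction to the
#'   LD scores (default FALSE).
#' @param n_bins Number of equal-width r-squared histogram bins on `[0, 1]`.
#' @return An [ld_info] object with a dense (window-zeroed) correlation
#'   matrix.
#' @export
compute_ld <- function(panel, window_snps = 50, bias_correct = FALSE,
                       n_bins = 8) {
  stopifnot(window_snps >= 1)
  n <- panel$n_samples
  if (bias_correct && n < 3)
    stop("bias correction requires at least 3 panel samples")
  g <- panel$dosages
  for (j in seq_len(ncol(g))) {
    miss <- is.na(g[, j])
    if (any(miss)) g[miss, j] <- mean(g[!miss, j])
  }
  r <- stats::cor(g)
  M <- ncol(g)
  idx <- seq_len(M)
  off <- abs(outer(idx, idx, "-"))
  same_chr <- outer(panel$meta$chr, panel$meta$chr, "==")
  in_win <- off <= window_snps & same_chr
  r[!in_win] <- 0
  diag(r) <- 1
  neigh <- in_win & off > 0
  r2 <- r^2
  r2s <- r2
  if (bias_correct) r2s <- pmax(r2 - (1 - r2) / (n - 2), 0)
  ld_scores <- 1 + rowSums(r2s * neigh)
  hist <- r2_histogram(r2, neigh, n_bins)
  new_ld_info(panel$meta$snp, panel$meta[, c("chr", "bp")], ld_scores,
              hist$edges, hist$counts, hist$mean, r = r,
              window = window_snps, n_samples = n)
}

r2_histogram <- function(r2, neigh, n_bins) {
  M <- nrow(r2)
  edges <- seq(0, 1, length.out = n_bins + 1)
  counts <- matrix(0L, M, n_bins)
  means <- matrix(NA_real_, M, n_bins)
  for (j in seq_len(M)) {
    v <- r2[j, neigh[j, ]]
    if (!length(v)) next
    b <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1), n_bins)
    counts[j, ] <- tabulate(b, n_bins)
    sums <- vapply(seq_len(n_bins), function(k) sum(v[b == k]), 0)
    means[j, ] <- ifelse(counts[j, ] > 0, sums / counts[j, ], NA_real_)
  }
  list(edges = edges, counts = counts, mean = means)
}

#' Analytic block-equicorrelated LD structure
#'
#' Builds an [ld_info] for `M` SNPs partitioned into contiguous blocks of
#' `block_size` SNPs with a common within-block correlation and zero
#' correlation between blocks.  The block correlation is either the constant
#' `rho` or, when `rho_range` is given, drawn once per block from
#' `Uniform(rho_range[1], rho_range[2])` under `seed` — the latter gives the
#' spread of LD scores that an LD score regression needs.
#'
#' @param M Number of SNPs.
#' @param block_size SNPs per block (last block may be shorter).
#' @param rho Constant within-block correlation.
#' @param rho_range Optional length-2 range for per-block correlations.
#' @param rho_levels Optional discrete set of correlations sampled uniformly
#'   per block; gives LD-score spread while keeping the number of distinct
#'   per-SNP LD profiles small (which the mixture likelihood exploits).
#' @param seed RNG seed used when `rho_range` or `rho_levels` is given.
#' @param n_bins r-squared histogram bins.
#' @param chr,bp_step Chromosome label and base-pair spacing for the
#'   synthetic SNP coordinates.
#' @return An [ld_info] with block-analytic structure (no dense matrix).
#' @export
ld_block_structure <- function(M, block_size = 10, rho = 0.6,
                               rho_range = NULL, rho_levels = NULL,
                               seed = 1, n_bins = 8,
                               chr = "1", bp_step = 1000L) {
  stopifnot(M >= 1, block_size >= 1)
  n_blocks <- ceiling(M / block_size)
  block_of <- rep(seq_len(n_blocks), each = block_size)[seq_len(M)]
  if (!is.null(rho_range)) {
    old <- local_seed(seed)
    rho_b <- stats::runif(n_blocks, rho_range[1], rho_range[2])
    restore_seed(old)
  } else if (!is.null(rho_levels)) {
    old <- local_seed(seed)
    rho_b <- sample(rho_levels, n_blocks, replace = TRUE)
    restore_seed(old)
  } else rho_b <- rep(rho, n_blocks)
  rho_of <- rho_b[block_of]
  size_of <- tabulate(block_of, n_blocks)[block_of]
  ld_scores <- 1 + (size_of - 1) * rho_of^2
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin_of <- pmin(pmax(findInterval(rho_of^2, edges, rightmost.closed = TRUE),
                      1), n_bins)
  counts <- matrix(0L, M, n_bins)
  means <- matrix(NA_real_, M, n_bins)
  counts[cbind(seq_len(M), bin_of)] <- size_of - 1L
  means[cbind(seq_len(M), bin_of)] <- ifelse(size_of > 1, rho_of^2, NA_real_)
  ids <- sprintf("snp%06d", seq_len(M))
  meta <- data.frame(chr = chr, bp = seq_len(M) * bp_step,
                     stringsAsFactors = FALSE)
  new_ld_info(ids, meta, ld_scores, edges, counts, means,
              block_of = block_of, rho_of = rho_of, window = block_size)
}

#' Extract the SNP correlation submatrix for a set of SNP indices
#'
#' @param ld An [ld_info].
#' @param idx Integer indices into the LD universe.
#' @return Dense correlation matrix of the selected SNPs.
#' @export
ld_submatrix <- function(ld, idx) {
  if (!is.null(ld$r)) return(ld$r[idx, idx, drop = FALSE])
  same <- outer(ld$block_of[idx], ld$block_of[idx], "==")
  r <- same * sqrt(outer(ld$rho_of[idx], ld$rho_of[idx]))
  diag(r) <- 1
  r
}

#' Greedy windowed LD pruning
#'
#' Mirrors the conventional `(window step r2)` pruning triple counted in
#' SNPs: windows of `window_snps` SNPs advance by `step_snps`; within each
#' window, scanned left to right, the later-position SNP of any surviving
#' pair with `r^2 > r2_threshold` is removed.  Deterministic.
#'
#' @param ld An [ld_info].
#' @param window_snps,step_snps,r2_threshold Pruning parameters
#'   (defaults 50, 5, 0.1).
#' @return Character vector of kept SNP ids, in position order.
#' @export
ld_prune <- function(ld, window_snps = 50, step_snps = 5, r2_threshold = 0.1) {
  stopifnot(window_snps >= 1, step_snps >= 1,
            r2_threshold > 0, r2_threshold <= 1)
  M <- length(ld$snp_ids)
  alive <- rep(TRUE, M)
  starts <- seq(1L, M, by = step_snps)
  for (s in starts) {
    e <- min(s + window_snps - 1L, M)
    if (e <= s) next
    idx <- s:e
    r2 <- ld_submatrix(ld, idx)^2
    for (ii in seq_along(idx)) {
      i <- idx[ii]
      if (!alive[i] || ii == length(idx)) next
      jj <- (ii + 1L):length(idx)
      kill <- jj[alive[idx[jj]] & r2[ii, jj] > r2_threshold]
      if (length(kill)) alive[idx[kill]] <- FALSE
    }
  }
  ld$snp_ids[alive]
}

#' Per-category LD scores for stratified regression
#'
#' `l(j, c) = sum_k r_jk^2 a_kc`, the self term included (`r_jj = 1`).
#'
#' @param ld An [ld_info].
#' @param annot SNP x category 0/1 matrix aligned with the LD universe.
#' @return SNP x category matrix of category LD scores.
#' @export
ld_scores_annot <- function(ld, annot) {
  annot <- as.matrix(annot)
  if (nrow(annot) != length(ld$snp_ids))
    stop("annotation rows do not match the LD universe")
  if (!is.null(ld$r)) return(ld$r^2 %*% annot)
  M <- nrow(annot)
  n_blocks <- max(ld$block_of)
  out <- matrix(0, M, ncol(annot))
  block_sums <- rowsum(annot, ld$block_of)       # n_blocks x C
  out <- ld$rho_of^2 * (block_sums[ld$block_of, , drop = FALSE] - annot) +
    annot
  colnames(out) <- colnames(annot)
  out
}

#' Floor the eigenvalues of a symmetric matrix and rescale to a correlation
#'
#' @param m Symmetric matrix.
#' @param floor Eigenvalue floor (default 1e-8).
#' @param rescale Rescale to unit diagonal (default TRUE).
#' @return Positive-definite (correlation) matrix.
#' @export
psd_floor <- function(m, floor = 1e-8, rescale = TRUE) {
  e <- eigen(m, symmetric = TRUE)
  v <- pmax(e$values, floor)
  out <- e$vectors %*% (v * t(e$vectors))
  if (rescale) out <- stats::cov2cor(out)
  (out + t(out)) / 2
}

# seed handling: run under a local seed, then restore global RNG state
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible()
}
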