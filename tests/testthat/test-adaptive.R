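test_that("SPUs statistics follow the powered-norm conventions", {
  expect_equal(spus(c(3, 4), 2), 5)
  expect_equal(spus(c(1, -1), 1), 2)            # absolute-value norm
  expect_equal(spus(c(1, -1), 1, signed = TRUE), 0)  # signed power sum
  expect_lt(abs(spus(c(1, 2, 5), 64) - 5), 1e-2)     # sup-norm limit
  expect_equal(spus(c(1, 2, 5), Inf), 5)
  expect_equal(mtspusset(matrix(c(3, 0, 4, 0), 2), 2, 2), 25)
  Z <- matrix(rnorm(12), 3)
  expect_equal(mtspusset(Z, 4, 2), mtspusset(Z[c(2, 3, 1), ], 4, 2))
})

test_that("trait correlation is recovered from pruned null z-scores", {
  M <- 4000
  ld <- ld_block_structure(M, 10, rho = 0.3)
  s0 <- simulate_zscores(matrix(0, 3, M), ld, n = 1e4, r0 = 0, seed = 1)
  zm <- do.call(rbind, lapply(s0, function(s) s$data$z))
  V0 <- estimate_trait_correlation(zm)
  expect_lt(max(abs(V0[upper.tri(V0)])), 3 * 3 / sqrt(M))

  s3 <- simulate_zscores(matrix(0, 3, M), ld, n = 1e4, r0 = 0.3, seed = 2)
  zm3 <- do.call(rbind, lapply(s3, function(s) s$data$z))
  V3 <- estimate_trait_correlation(zm3)
  expect_lt(max(abs(V3[upper.tri(V3)] - 0.3)), 0.05)

  zdup <- rbind(zm3[1, ], zm3[1, ])
  expect_gte(estimate_trait_correlation(zdup)[1, 2], 0.99)
  expect_error(estimate_trait_correlation(zm[, 1:100, drop = FALSE]),
               "need >= 500")
})

test_that("the null bank is matrix-normal with Kronecker covariance", {
  R <- outer(1:5, 1:5, function(i, j) 0.6^abs(i - j))
  V <- matrix(0.4, 3, 3); diag(V) <- 1
  bank <- simulate_null_bank(R, V, B = 20000, seed = 3)
  # white case moments
  bw <- simulate_null_bank(diag(3), diag(2), B = 20000, seed = 4)
  expect_lt(abs(mean(bw)), 0.01)
  expect_lt(abs(var(as.vector(bw)) - 1), 0.02)
  # covariance of vec(Z) targets kron(R, V) (trait index fastest)
  emp <- cov(bank)
  tgt <- kronecker(R, V)
  expect_lt(norm(emp - tgt, "F") / norm(tgt, "F"), 0.05)
  # bit-identical reproduction under the seed
  expect_identical(bank, simulate_null_bank(R, V, 20000, seed = 3))
})

test_that("a singleton gamma grid reduces aSPUs to the plain SPUs p-value", {
  set.seed(5)
  d <- 6
  R <- outer(1:d, 1:d, function(i, j) 0.5^abs(i - j))
  z <- drop(rnorm(d) %*% chol(R)) + 1
  a <- aspus(z, R, gamma1 = 2, B = 2000, seed = 6)
  # independent reference: same bank statistics recomputed directly
  bank <- simulate_null_bank(R, matrix(1, 1, 1), 2000, seed = 6)
  stat_null <- apply(bank, 1, function(v) spus(v, 2))
  expect_equal(a$p, aspus_ref_p(spus(z, 2), stat_null))
  expect_equal(a$p, a$p_gamma)
})

test_that("Monte-Carlo p converges to the exact chi-square tail (d=m=1)", {
  for (z in c(1.2, 2.5)) {
    a <- aspus(z, matrix(1, 1, 1), gamma1 = 2, B = 1e4, seed = 7)
    exact <- pchisq(z^2, 1, lower.tail = FALSE)
    expect_lt(abs(a$p - exact), 3 * sqrt(exact * (1 - exact) / 1e4) + 2e-4)
  }
})

test_that("adaptive p respects the min-p sandwich and the attainable floor", {
  set.seed(8)
  d <- 8
  R <- outer(1:d, 1:d, function(i, j) 0.4^abs(i - j))
  for (r in 1:20) {
    z <- drop(rnorm(d) %*% chol(R)) + rnorm(1)
    a <- aspus(z, R, B = 500, seed = r)
    expect_gte(a$p, min(a$p_gamma))
    expect_lte(a$p, 4 * min(a$p_gamma) + 2 / 501)
    expect_gte(a$p, 1 / 501)
    expect_lte(a$p, 1)
  }
})

test_that("single-trait reduction: mtaspusset equals aspus exactly", {
  set.seed(9)
  d <- 5
  R <- outer(1:d, 1:d, function(i, j) 0.5^abs(i - j))
  z <- drop(rnorm(d) %*% chol(R))
  mt <- mtaspusset(matrix(z, 1), R, matrix(1, 1, 1), gamma2 = 1,
                   B = 1000, seed = 10)
  a <- aspus(z, R, B = 1000, seed = 10)
  expect_equal(mt$p_mtaspusset, a$p)
})

test_that("trait exchange permutes aSPUs output, MTaSPUsSet unchanged", {
  set.seed(11)
  d <- 6; m <- 3
  R <- outer(1:d, 1:d, function(i, j) 0.5^abs(i - j))
  V <- matrix(0.3, m, m); diag(V) <- 1  # exchangeable trait correlation
  Z <- matrix(rnorm(m * d), m) %*% chol(R)
  r1 <- mtaspusset(Z, R, V, B = 500, seed = 12)
  r2 <- mtaspusset(Z[c(3, 1, 2), ], R, V, B = 500, seed = 12)
  expect_equal(r2$p_mtaspusset, r1$p_mtaspusset)
  expect_equal(r2$p_aspus, r1$p_aspus[c(3, 1, 2)])
})

test_that("power adapts: dense signals favor low gamma, sparse favor high", {
  d <- 8; m <- 3
  R <- diag(d); V <- diag(m)
  dense_low <- 0; sparse_high <- 0; track_dense <- 0; track_sparse <- 0
  n_rep <- 20
  for (r in 1:n_rep) {
    set.seed(100 + r)
    # dense diffuse signal: every SNP and trait slightly inflated
    Zd <- matrix(rnorm(m * d, sd = 1.35), m)
    rd <- mtaspusset(Zd, R, V, B = 500, seed = 200 + r)
    if (min(rd$p_cells[1:2, ]) <= min(rd$p_cells[3:4, ]))
      dense_low <- dense_low + 1
    if (rd$p_mtaspusset <= 4 * min(rd$p_cells) + 2 / 501)
      track_dense <- track_dense + 1
    Zs <- matrix(rnorm(m * d, sd = 0.8), m)
    Zs[1, 1] <- 6                                    # one big hit
    rs <- mtaspusset(Zs, R, V, B = 500, seed = 300 + r)
    if (min(rs$p_cells[3:4, ]) <= min(rs$p_cells[1:2, ]))
      sparse_high <- sparse_high + 1
    if (rs$p_mtaspusset <= 2 * min(rs$p_cells) + 2 / 501)
      track_sparse <- track_sparse + 1
  }
  expect_gt(dense_low, n_rep / 2)
  expect_gt(sparse_high, n_rep / 2)
  expect_gte(track_dense, 0.9 * n_rep)
  expect_gte(track_sparse, 0.9 * n_rep)
})

test_that("null per-cell p-values are close to uniform", {
  d <- 6; m <- 2
  R <- outer(1:d, 1:d, function(i, j) 0.5^abs(i - j))
  V <- matrix(0.4, m, m); diag(V) <- 1
  Lr <- chol(psd_floor(R)); Lv <- t(chol(V))
  set.seed(13)
  pvals <- replicate(400, {
    Z <- Lv %*% matrix(rnorm(m * d), m) %*% Lr
    mtaspusset(Z, R, V, gamma1 = 2, gamma2 = 2, B = 300,
               seed = sample.int(1e6, 1))$p_cells[1, 1]
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("more replicates do not worsen Monte-Carlo accuracy", {
  z <- 2.2; exact <- pchisq(z^2, 1, lower.tail = FALSE)
  err <- sapply(c(100, 400), function(B) {
    mean(sapply(1:40, function(s)
      abs(aspus(z, matrix(1, 1, 1), gamma1 = 2, B = B, seed = s)$p -
            exact)))
  })
  expect_lt(err[2], err[1])
})

test_that("staged escalation stops early on null genes, floors on signals", {
  d <- 5
  R <- outer(1:d, 1:d, function(i, j) 0.5^abs(i - j))
  V <- matrix(1, 1, 1)
  # strong signal: escalates through the schedule and reports the floor
  Zs <- matrix(10, 1, d)
  rs <- staged_mtaspusset(Zs, R, V, schedule = c(1000, 5000), seed = 14)
  expect_equal(rs$B_used, 5000)
  expect_equal(rs$p_mtaspusset, 1 / 5001)
  # null genes: stop at the first stage in >= 95% of replicates
  set.seed(15)
  Lr <- chol(psd_floor(R))
  stops <- replicate(40, {
    Z <- matrix(rnorm(d), 1) %*% Lr
    staged_mtaspusset(Z, R, V, schedule = c(1000, 5000),
                      seed = sample.int(1e6, 1))$B_used
  })
  expect_gte(mean(stops == 1000), 0.95)
  # stopping-stage p agrees with a direct run at that B and stage seed
  Z0 <- matrix(rnorm(d), 1) %*% Lr
  st <- staged_mtaspusset(Z0, R, V, schedule = c(1000, 5000), seed = 16)
  direct <- mtaspusset(Z0, R, V, B = st$B_used,
                       seed = 16 + match(st$B_used, c(1000, 5000)) - 1)
  expect_equal(st$p_mtaspusset, direct$p_mtaspusset)
})

test_that("gene scan classifies an engineered pleiotropic gene", {
  M <- 1500; m <- 3; N <- 5e4
  ld <- ld_block_structure(M, 10, rho = 0.3)
  beta <- matrix(0, m, M)
  beta[, 105] <- 0.032                      # shared causal SNP in gene 11
  ss <- simulate_zscores(beta, ld, n = N, seed = 17)
  zm <- do.call(rbind, lapply(ss, function(s) s$data$z))
  colnames(zm) <- ld$snp_ids
  snps <- data.frame(snp = ld$snp_ids, chr = ld$meta$chr, bp = ld$meta$bp)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:30), chr = "1",
                      start = (0:29) * 10000 + 1000,
                      end = (0:29) * 10000 + 10000)
  gmap <- map_snps_to_genes(snps, genes)
  scan <- gene_scan(zm, gmap, ld, schedule = c(1000, 10000), seed = 18)
  expect_equal(scan$G, 30)
  expect_equal(scan$threshold, 0.05 / 30)
  tab <- scan$table
  expect_true(tab$pleiotropic[tab$gene == "g11"])
  expect_lte(sum(tab$pleiotropic), 2)       # no wholesale false flagging
  # classification rule: MT significance alone is not enough
  fake <- tab
  expect_true(all(!(fake$p_mtaspusset < scan$threshold &
                      !apply(fake[, paste0("p_trait", 1:3)] <
                               scan$threshold, 1, any)) |
                    !fake$pleiotropic |
                    apply(fake[, paste0("p_trait", 1:3)] <
                            scan$threshold, 1, any)))
  # novel flag honors the known-association lookup
  scan2 <- gene_scan(zm, gmap, ld, schedule = c(1000, 10000), seed = 18,
                     known_genes = "g11")
  expect_false(scan2$table$novel[scan2$table$gene == "g11"])
  expect_true(scan2$table$pleiotropic[scan2$table$gene == "g11"])
})

test_that("gene scans are order-independent via per-gene seed streams", {
  M <- 500
  ld <- ld_block_structure(M, 10, rho = 0.3)
  ss <- simulate_zscores(matrix(0, 2, M), ld, n = 1e4, seed = 19)
  zm <- do.call(rbind, lapply(ss, function(s) s$data$z))
  colnames(zm) <- ld$snp_ids
  snps <- data.frame(snp = ld$snp_ids, chr = ld$meta$chr, bp = ld$meta$bp)
  genes <- data.frame(gene_id = c("a", "b", "c"), chr = "1",
                      start = c(1000, 101000, 201000),
                      end = c(100000, 200000, 300000))
  gmap <- map_snps_to_genes(snps, genes)
  V <- diag(2)
  s1 <- gene_scan(zm, gmap, ld, V = V, schedule = 500, seed = 20)
  s2 <- gene_scan(zm, gmap[c(3, 1, 2)], ld, V = V, schedule = 500,
                  seed = 20)
  m1 <- s1$table[order(s1$table$gene), ]
  m2 <- s2$table[order(s2$table$gene), ]
  rownames(m1) <- rownames(m2) <- NULL
  expect_equal(m1, m2)
})
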