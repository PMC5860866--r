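test_that("partial correlation matches closed forms", {
  set.seed(60)
  n <- 100
  x <- rnorm(n); y <- 0.5 * x + rnorm(n); z <- rnorm(n)

  # no covariates: zero-order Pearson
  expect_equal(partial_correlation(y, x, list()), cor(y, x))

  # single covariate: the textbook first-order identity
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  expect_equal(partial_correlation(y, x, list(z)),
               (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2)),
               tolerance = 1e-12)

  # covariates orthogonal to both: unchanged (orthogonalize explicitly)
  q <- qr.resid(qr(cbind(1, x, y)), z)
  expect_equal(partial_correlation(y, x, list(q)), cor(y, x), tolerance = 1e-10)

  # y fully explained by a covariate: nothing left to correlate
  expect_equal(partial_correlation(y, x, list(y)), 0)

  expect_error(partial_correlation(y, x, list(z, 2 * z)), "collinear")
  expect_error(partial_correlation(rep(1, n), x, list(z)), "zero-variance")
})

test_that("variance partitioning obeys its limiting cases", {
  set.seed(61)
  n <- 435
  a <- rnorm(n); b <- rnorm(n); cc <- rnorm(n)

  # y = A with independent B, C: everything loads on u_A
  vp <- variance_partition(a, a, b, cc)
  expect_equal(vp$components[["u_A"]], vp$r2_full, tolerance = 0.02)
  expect_lt(max(abs(vp$components[c("u_B", "u_C", "s_AB", "s_AC", "s_BC",
                                    "s_ABC")])), 0.02)

  # full redundancy: A == B exactly, their shared term carries the variance
  y <- a + rnorm(n, sd = 0.3)
  vp2 <- variance_partition(y, a, a, cc)
  expect_equal(vp2$components[["u_A"]], 0, tolerance = 1e-10)
  expect_equal(vp2$components[["u_B"]], 0, tolerance = 1e-10)
  expect_gt(vp2$components[["s_AB"]], 0.8)
})

test_that("commonality components match a normal-equations oracle and sum to r2", {
  oracle_r2 <- function(y, xs) {
    x <- cbind(1, xs)
    beta <- solve(t(x) %*% x, t(x) %*% y)
    1 - sum((y - x %*% beta)^2) / sum((y - mean(y))^2)
  }
  for (seed in 1:25) {
    set.seed(100 + seed)
    n <- 60
    a <- rnorm(n); b <- rnorm(n); cc <- rnorm(n)
    y <- 0.8 * a + 0.4 * b + 0.1 * cc + rnorm(n)
    vp <- variance_partition(y, a, b, cc)

    r2 <- c(A = oracle_r2(y, cbind(a)), B = oracle_r2(y, cbind(b)),
            C = oracle_r2(y, cbind(cc)), AB = oracle_r2(y, cbind(a, b)),
            AC = oracle_r2(y, cbind(a, cc)), BC = oracle_r2(y, cbind(b, cc)),
            ABC = oracle_r2(y, cbind(a, b, cc)))
    expect_equal(vp$r2, r2, tolerance = 1e-10)
    oc <- c(u_A = r2[["ABC"]] - r2[["BC"]], u_B = r2[["ABC"]] - r2[["AC"]],
            u_C = r2[["ABC"]] - r2[["AB"]],
            s_AB = r2[["AC"]] + r2[["BC"]] - r2[["ABC"]] - r2[["C"]],
            s_AC = r2[["AB"]] + r2[["BC"]] - r2[["ABC"]] - r2[["B"]],
            s_BC = r2[["AB"]] + r2[["AC"]] - r2[["ABC"]] - r2[["A"]],
            s_ABC = r2[["A"]] + r2[["B"]] + r2[["C"]] - r2[["AB"]] -
              r2[["AC"]] - r2[["BC"]] + r2[["ABC"]])
    expect_equal(vp$components, oc, tolerance = 1e-10)
    expect_equal(sum(vp$components), vp$r2_full, tolerance = 1e-12)
    # percentage view sums to >= 100 only through clipping; unclipped sums to 100
    if (!any(vp$clipped)) expect_equal(sum(vp$percent), 100, tolerance = 1e-8)
  }
})

test_that("signed-rank test matches its extremes, symmetry and wilcox.test", {
  expect_equal(signed_rank_test(abs(rnorm(20)) + 0.01)$W, 210)

  set.seed(62)
  x <- rnorm(15, 0.3)
  a <- signed_rank_test(x); b <- signed_rank_test(-x)
  expect_equal(a$W + b$W, 15 * 16 / 2)

  # tie-free exact p agrees with the reference implementation
  for (seed in 1:5) {
    set.seed(seed)
    v <- rnorm(12, 0.4)
    expect_equal(signed_rank_test(v, sided = "two")$p,
                 wilcox.test(v, exact = TRUE)$p.value)
    expect_equal(signed_rank_test(v, sided = "one")$p,
                 wilcox.test(v, alternative = "greater", exact = TRUE)$p.value)
  }

  # tied data go through the tie-corrected normal approximation
  v <- c(0.5, 0.5, -0.5, 1, 1, 1, -2, 3, 3, 2.5, -1.5, 0.7)
  ours <- signed_rank_test(v, sided = "two")
  ref <- wilcox.test(v, exact = FALSE, correct = FALSE)
  expect_false(ours$exact)
  expect_equal(ours$W, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)

  # paired mode tests the difference
  y <- rnorm(15)
  expect_equal(signed_rank_test(x + y, paired_with = y, sided = "two")$W,
               signed_rank_test(x, sided = "two")$W)

  expect_error(signed_rank_test(rep(0, 6)), "all differences are zero")
})

test_that("exact signed-rank p equals exhaustive sign enumeration", {
  set.seed(63)
  d <- rnorm(12, 0.5)
  d <- d[d != 0]
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 12)))
  w_all <- signs %*% r
  p_oracle <- mean(w_all >= w_obs)
  expect_equal(signed_rank_test(d, sided = "one")$p, p_oracle)
})

test_that("BH adjustment matches the hand formula and is monotone", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.04, 0.05)),
               c(0.04, 0.04, 0.05, 0.05))
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(rep(0.02, 5)), rep(0.02, 5))

  set.seed(64)
  p <- runif(30)
  expect_true(all(fdr_adjust(p) >= p))

  # families are adjusted independently
  fam <- rep(c("roi1", "roi2"), each = 4)
  p2 <- c(0.01, 0.02, 0.04, 0.05, 0.01, 0.02, 0.04, 0.05)
  expect_equal(fdr_adjust(p2, fam), rep(c(0.04, 0.04, 0.05, 0.05), 2))

  expect_error(fdr_adjust(numeric(0)), "empty")
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("noise ceiling brackets the group-average correlation", {
  x <- random_rdm(8, seed = 65)
  same <- noise_ceiling(list(x, x, x))
  expect_equal(same$upper, 1)
  expect_equal(same$lower, 1)

  # heterogeneous set: both bounds equal the loop-written oracle
  rdms <- lapply(1:10, function(s) random_rdm(8, seed = 70 + s))
  nc <- noise_ceiling(rdms)
  vecs <- sapply(rdms, rdm_vectorize)
  up <- mean(sapply(1:10, function(i) cor(vecs[, i], rowMeans(vecs))))
  lo <- mean(sapply(1:10, function(i) cor(vecs[, i], rowMeans(vecs[, -i]))))
  expect_equal(nc$upper, up)
  expect_equal(nc$lower, lo)
  expect_lte(nc$lower, nc$upper)

  # two anti-correlated halves push the lower bound well below the upper
  base <- rdm_vectorize(x)
  g <- c(lapply(1:3, function(i) rdm_unvectorize(base + rnorm(28, sd = 0.1))),
         lapply(1:3, function(i) rdm_unvectorize(max(base) - base + rnorm(28, sd = 0.1))))
  nc2 <- noise_ceiling(g)
  expect_lt(nc2$lower, nc2$upper)

  expect_error(noise_ceiling(list(x, x)), "3 participants")
})

test_that("reproducibility test: maximal observed statistic and exhaustive null", {
  g1 <- lapply(1:4, function(s) random_rdm(6, seed = 80 + s))
  rt <- reproducibility_test(g1, g1, n_perm = 500, n_boot = 100, rng_seed = 1)
  expect_equal(rt$r, 1)
  expect_equal(rt$p, 1 / 501)

  # 3-category toy: the exhaustive permutation distribution is exactly the
  # 5 non-identity relabelings, enumerated here by hand
  a <- rdm(matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3), labels = c("x", "y", "z"))
  b <- rdm(matrix(c(0, 2, 4, 2, 0, 5, 4, 5, 0), 3), labels = c("x", "y", "z"))
  rt2 <- reproducibility_test(list(a), list(b), exhaustive = TRUE, n_boot = 0)
  perms <- list(c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  va <- rdm_vectorize(a)
  null_oracle <- sapply(perms, function(p) {
    m <- unclass(b)[p, p]
    cor(va, m[upper.tri(m)])
  })
  expect_equal(sort(rt2$perm_distribution), sort(null_oracle))
  expect_equal(rt2$p,
               (1 + sum(null_oracle >= cor(va, rdm_vectorize(b)))) / 6)

  expect_warning(reproducibility_test(g1, g1, n_perm = 10, n_boot = 0,
                                      rng_seed = 1), "coarse")
})

test_that("reproducibility CI brackets r for well-behaved groups", {
  set.seed(81)
  base <- random_rdm(10, seed = 82)
  jitter_rdm <- function() {
    rdm_unvectorize(rdm_vectorize(base) + rnorm(45, sd = 0.2),
                    labels = rdm_labels(base))
  }
  g1 <- replicate(6, jitter_rdm(), simplify = FALSE)
  g2 <- replicate(6, jitter_rdm(), simplify = FALSE)
  rt <- reproducibility_test(g1, g2, n_perm = 300, n_boot = 300, rng_seed = 2)
  expect_lt(rt$p, 0.05)
  # percentile bootstrap CIs can sit slightly off the point estimate with
  # few participants; require bracketing up to a small slack
  expect_true(rt$ci[1] - 0.05 <= rt$r && rt$r <= rt$ci[2] + 0.05)
  expect_lt(rt$ci[1], rt$ci[2])
})
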