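test_that("VanRaden GRM matches hand computation and HWE expectations", {
  # 3 individuals, 2 markers, worked by hand
  g <- rbind(a = c(0L, 2L), b = c(1L, 1L), c = c(2L, 0L))
  p <- colMeans(g) / 2                      # (0.5, 0.5)
  z <- sweep(g, 2, 2 * p)
  expected <- tcrossprod(z) / sum(2 * p * (1 - p))
  G <- vanraden_grm(g)
  expect_equal(unname(G), unname(expected), ignore_attr = TRUE)

  # duplicated individuals: off-diagonal equals both diagonals
  g2 <- rbind(x = c(0L, 2L, 1L, 1L), y = c(0L, 2L, 1L, 1L),
              z = c(2L, 0L, 1L, 0L))
  G2 <- vanraden_grm(g2)
  expect_equal(G2["x", "y"], G2["x", "x"])
  expect_equal(G2["x", "y"], G2["y", "y"])

  # random-mating HWE: mean diagonal near 1
  set.seed(50)
  gh <- sim_hwe_geno(400, 800)
  Gh <- vanraden_grm(gh)
  dv <- diag(Gh)
  expect_lt(abs(mean(dv) - 1), 3 * sd(dv) / sqrt(length(dv)))
  expect_error(vanraden_grm(rbind(c(0L, 0L), c(0L, 0L))), "monomorphic")
})

test_that("moment inbreeding coefficients hit the closed-form cases", {
  # fully homozygous individual among heterozygotes: F = 1
  g <- rbind(h = rep(c(0L, 2L), 10), i = rep(1L, 20), j = rep(1L, 20),
             k = rep(c(2L, 0L), 10))
  f <- moment_inbreeding(g)
  expect_equal(unname(f["h"]), 1)
  # fully heterozygous at p = 0.5: F = (0 - m/2)/(m - m/2) = -1
  expect_equal(unname(f["i"]), -1)
  # HWE population: mean F near 0
  set.seed(51)
  gh <- sim_hwe_geno(500, 600)
  fh <- moment_inbreeding(gh)
  expect_lt(abs(mean(fh)), 3 * sd(fh) / sqrt(length(fh)))
})

test_that("heritability and repeatability arithmetic is consistent", {
  # components consistent with a printed Vp = 14.2, Ve = 11.7, h2 = 0.11
  r <- varcomp_ratios(1.56, 0.94, 11.7)
  expect_equal(r$Vp, 14.2)
  expect_equal(round(r$h2, 2), 0.11)
  expect_equal(round(r$t, 3), 0.176)
})

test_that("REML on pure noise with identity GRM finds no heritability", {
  set.seed(52)
  q <- 200
  G <- diag(q)
  rownames(G) <- colnames(G) <- sprintf("id%03d", 1:q)
  pheno <- data.frame(fid = rep(rownames(G), each = 5),
                      cc = rnorm(q * 5))
  fit <- fit_repeatability(pheno, G, trait = "cc")
  expect_lt(fit$h2, 2 * max(fit$se["h2"], 1e-3))
  expect_true(fit$converged)
})

test_that("REML recovers simulated variance components within 2 SE", {
  set.seed(53)
  G <- vanraden_grm(sim_hwe_geno(400, 700))
  pheno <- sim_repeat_pheno(G, 8, va = 0.3, vpe = 0.1, ve = 0.6)
  fit <- fit_repeatability(pheno, G, trait = "cc")
  expect_lt(abs(fit$Va - 0.3), 2 * fit$se["Va"])
  expect_lt(abs(fit$Vpe - 0.1), 2 * fit$se["Vpe"])
  expect_lt(abs(fit$Ve - 0.6), 2 * fit$se["Ve"])
  # structural invariants of every fit
  expect_true(all(c(fit$Va, fit$Vpe, fit$Ve) >= 0))
  expect_true(fit$h2 <= fit$t && fit$t <= 1)
  expect_equal(fit$Vp, fit$Va + fit$Vpe + fit$Ve)
  # the restricted likelihood never decreased over the iterate path
  expect_false(is.unsorted(fit$logL_path))
})

test_that("inbreeding covariate handling drops unmatched observations", {
  set.seed(54)
  G <- vanraden_grm(sim_hwe_geno(100, 300))
  pheno <- sim_repeat_pheno(G, 4, 0.3, 0.1, 0.6)
  f <- moment_inbreeding(sim_hwe_geno(100, 300))
  names(f) <- rownames(G)
  f[1] <- NA
  expect_message(fit_repeatability(pheno, G, f, trait = "cc"), "dropped")
})

test_that("bivariate REML separates into univariate fits for unlinked traits", {
  set.seed(55)
  q <- 120
  G <- diag(2 * q)
  rownames(G) <- colnames(G) <- sprintf("id%03d", 1:(2 * q))
  ids1 <- rownames(G)[1:q]; ids2 <- rownames(G)[q + 1:q]
  p1 <- sim_repeat_pheno(G[ids1, ids1], 5, 0.4, 0.1, 0.5)
  p2 <- sim_repeat_pheno(G[ids2, ids2], 5, 0.2, 0.2, 0.6)
  u1 <- fit_repeatability(p1, G[ids1, ids1], trait = "cc")
  u2 <- fit_repeatability(p2, G[ids2, ids2], trait = "cc")
  b <- fit_bivariate(p1, p2, G)
  # block-diagonal GRM: the joint likelihood factorises, so the bivariate
  # diagonals agree with the univariate optima up to optimiser tolerance
  expect_equal(b$Va1, u1$Va, tolerance = 1e-3)
  expect_equal(b$Va2, u2$Va, tolerance = 1e-3)
  expect_equal(b$Ve1, u1$Ve, tolerance = 1e-3)
  expect_equal(b$Ve2, u2$Ve, tolerance = 1e-3)
  expect_false(is.unsorted(b$logL_path))
})

test_that("bivariate REML recovers cross-sex genetic correlations", {
  sim_cross <- function(seed, rg) {
    set.seed(seed)
    q <- 250; m <- 500
    X <- sim_hwe_geno(2 * q, m)
    G <- vanraden_grm(X)
    L <- chol(G + diag(1e-4, 2 * q))
    z1 <- crossprod(L, rnorm(2 * q)); z2 <- crossprod(L, rnorm(2 * q))
    a1 <- z1 * sqrt(0.3)
    a2 <- (rg * z1 + sqrt(1 - rg^2) * z2) * sqrt(0.3)
    ids1 <- rownames(X)[1:q]; ids2 <- rownames(X)[q + 1:q]
    mk <- function(av, ids) data.frame(
      fid = rep(ids, each = 6),
      cc = rep(av + rnorm(length(ids), 0, sqrt(0.1)), each = 6) +
        rnorm(length(ids) * 6, 0, sqrt(0.6)))
    fit_bivariate(mk(a1[seq_len(q)], ids1), mk(a2[q + seq_len(q)], ids2),
                  G)
  }
  f0 <- sim_cross(1, 0)
  expect_lt(abs(f0$r_g), 2 * f0$r_g_se)
  f8 <- sim_cross(2, 0.8)
  expect_lt(abs(f8$r_g - 0.8), 2 * f8$r_g_se)

  # duplicated trait: genetic correlation driven to its upper bound
  set.seed(56)
  G1 <- vanraden_grm(sim_hwe_geno(120, 300))
  pd <- sim_repeat_pheno(G1, 5, 0.3, 0.1, 0.6)
  fd <- fit_bivariate(pd, pd, G1)
  expect_gt(fd$r_g, 0.95)
})

test_that("phenotypic correlations are Pearson on FID means", {
  pheno <- data.frame(fid = rep(c("a", "b", "c"), each = 2),
                      cc = c(1, 3, 4, 6, 7, 9),
                      rbar = c(2, 2, 5, 5, 8, 8) / 100)
  expect_equal(phenotypic_correlation(pheno), 1)
})
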