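#' @name quantgen
#' @title Genomic relationships and REML variance components
#'
#' @description
#' The repeatability animal model for per-meiosis phenotypes y of an FID,
#' `y = Xb + a + pe + e`, with additive values `a ~ N(0, G Va)` on a
#' genomic relationship matrix, permanent-environment effects
#' `pe ~ N(0, I Vpe)` and residuals `e ~ N(0, I Ve)`, is fitted by
#' restricted maximum likelihood with an average-information (AI)
#' algorithm after an EM warm-up.  Because the random effects are indexed
#' by FID, the likelihood factorises exactly into a within-FID residual
#' part (a scaled chi-square carrying `N - q` degrees of freedom for Ve)
#' and a between-FID part on the FID means, whose covariance is
#' `Va G + Vpe I + Ve diag(1/n_i)`; all matrix work is therefore q x q.
NULL

#' VanRaden (method 1) genomic relationship matrix
#'
#' `G = Z Z' / sum(2 p_j (1 - p_j))` with `Z` the dosage matrix centred at
#' `2 p_j`; allele frequencies are taken from the supplied sample and
#' missing dosages are mean-imputed per marker.  Monomorphic markers are
#' dropped.
#'
#' @param geno individuals x markers dosage matrix (rownames = ids).
#' @return symmetric GRM with dimnames; allele frequencies in attribute
#'   `"freq"`.
#' @export
vanraden_grm <- function(geno) {
  stopifnot(nrow(geno) >= 2)
  p <- colMeans(geno, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  if (!any(keep)) stop("all markers monomorphic")
  g <- geno[, keep, drop = FALSE]
  p <- p[keep]
  z <- sweep(g, 2, 2 * p)
  z[is.na(z)] <- 0  # mean imputation after centring
  G <- tcrossprod(z) / sum(2 * p * (1 - p))
  dimnames(G) <- list(rownames(geno), rownames(geno))
  attr(G, "freq") <- p
  G
}

#' Method-of-moments inbreeding coefficients
#'
#' `F = (O_hom - E_hom) / (m_obs - E_hom)` per individual, with
#' `E_hom = sum_j (1 - 2 p_j (1 - p_j))` over that individual's
#' non-missing markers with frequency in (0, 1).
#'
#' @param geno dosage matrix.
#' @return named numeric vector of F (NA when no usable marker).
#' @export
moment_inbreeding <- function(geno) {
  p <- colMeans(geno, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  g <- geno[, keep, drop = FALSE]
  p <- p[keep]
  ehet <- 2 * p * (1 - p)
  obs <- !is.na(g)
  o_hom <- rowSums(g != 1L, na.rm = TRUE)
  e_hom <- obs %*% (1 - ehet)
  m_obs <- rowSums(obs)
  f <- as.numeric((o_hom - e_hom) / (m_obs - e_hom))
  f[m_obs == 0] <- NA_real_
  stats::setNames(f, rownames(geno))
}

# ---- generic AI-REML on a linear covariance structure ------------------

# V(theta) = sum_k theta_k * A_k  (all q x q), optional per-parameter
# within-group chi-square information: logL += -0.5*(df*log(th) + ss/th).
# EM warm-up, then AI steps with fall-back and step-halving so the
# restricted log-likelihood never decreases.
reml_engine <- function(y, X, structures, within = NULL, init,
                        var_params = rep(TRUE, length(structures)),
                        cov_pairs = NULL, tol = 1e-8, maxit = 200,
                        floor = 1e-10, em_iter = 3) {
  q <- length(y)
  K <- length(structures)
  within_df <- numeric(K); within_ss <- numeric(K)
  if (!is.null(within)) for (w in within) {
    within_df[w$k] <- w$df; within_ss[w$k] <- w$ss
  }
  clamp <- function(th) {
    th[var_params] <- pmax(th[var_params], floor)
    if (!is.null(cov_pairs)) for (cp in cov_pairs) {
      lim <- 0.999 * sqrt(th[cp[2]] * th[cp[3]])
      th[cp[1]] <- max(min(th[cp[1]], lim), -lim)
    }
    th
  }
  eval_fit <- function(th) {
    V <- matrix(0, q, q)
    for (k in seq_len(K)) V <- V + th[k] * structures[[k]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vi <- chol2inv(ch)
    W <- Vi %*% X
    XtViX <- crossprod(X, W)
    chx <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chx)) return(NULL)
    XtViX_inv <- chol2inv(chx)
    Py <- Vi %*% y - W %*% (XtViX_inv %*% crossprod(W, y))
    logL <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                      sum(y * Py))
    for (k in seq_len(K)) if (within_df[k] > 0)
      logL <- logL - 0.5 * (within_df[k] * log(th[k]) +
                              within_ss[k] / th[k])
    list(th = th, Vi = Vi, W = W, XtViX_inv = XtViX_inv, Py = Py,
         logL = logL)
  }
  score_ai <- function(fit) {
    th <- fit$th
    APy <- lapply(structures, function(A) A %*% fit$Py)
    PAPy <- lapply(APy, function(v)
      fit$Vi %*% v - fit$W %*% (fit$XtViX_inv %*% crossprod(fit$W, v)))
    sc <- numeric(K)
    AI <- matrix(0, K, K)
    for (k in seq_len(K)) {
      trPA <- sum(fit$Vi * structures[[k]]) -
        sum(fit$XtViX_inv * (crossprod(fit$W, structures[[k]] %*% fit$W)))
      sc[k] <- -0.5 * (trPA - sum(fit$Py * APy[[k]]))
      if (within_df[k] > 0)
        sc[k] <- sc[k] - 0.5 * (within_df[k] / th[k] -
                                  within_ss[k] / th[k]^2)
      for (j in seq_len(k)) {
        AI[k, j] <- AI[j, k] <- 0.5 * sum(APy[[k]] * PAPy[[j]])
      }
      if (within_df[k] > 0)
        AI[k, k] <- AI[k, k] + 0.5 * within_df[k] / th[k]^2
    }
    list(score = sc, AI = AI, trPA_term = sc)
  }
  em_step <- function(fit) {
    th <- fit$th
    for (k in seq_len(K)) {
      if (!var_params[k]) next
      APy <- structures[[k]] %*% fit$Py
      trPA <- sum(fit$Vi * structures[[k]]) -
        sum(fit$XtViX_inv * (crossprod(fit$W, structures[[k]] %*% fit$W)))
      g <- (sum(fit$Py * APy) - trPA)
      if (within_df[k] > 0)
        g <- g + (within_ss[k] / th[k]^2 - within_df[k] / th[k])
      denom <- q + within_df[k]
      th[k] <- th[k] + th[k]^2 * g / denom
    }
    clamp(th)
  }
  th <- clamp(init)
  fit <- eval_fit(th)
  if (is.null(fit)) stop("initial covariance matrix not positive definite")
  logL_path <- fit$logL
  converged <- FALSE
  # try a candidate point, shrinking the step toward the current iterate
  # until the restricted likelihood does not decrease; NULL if hopeless
  try_step <- function(fit, cand) {
    for (s in 2^-(0:14)) {
      trial <- clamp(fit$th + s * (cand - fit$th))
      nf <- eval_fit(trial)
      if (!is.null(nf) && nf$logL >= fit$logL - 1e-12) return(nf)
    }
    NULL
  }
  for (it in seq_len(maxit)) {
    new_fit <- NULL
    used_ai <- FALSE
    if (it > em_iter) {
      sa <- score_ai(fit)
      # AI can be singular (e.g. exactly duplicated parameter directions);
      # use the minimum-norm pseudo-inverse step
      step <- tryCatch({
        sv <- svd(sa$AI)
        pos <- sv$d > max(sv$d) * 1e-10
        drop(sv$v[, pos, drop = FALSE] %*%
               ((crossprod(sv$u[, pos, drop = FALSE], sa$score)) /
                  sv$d[pos]))
      }, error = function(e) NULL)
      if (!is.null(step)) {
        new_fit <- try_step(fit, clamp(fit$th + step))
        used_ai <- !is.null(new_fit)
      }
    }
    em_cand <- em_step(fit)
    if (is.null(new_fit)) new_fit <- try_step(fit, em_cand)
    if (is.null(new_fit)) {
      converged <- TRUE  # no uphill direction left
      break
    }
    # an AI step that stalls may still leave EM progress on the table
    delta <- new_fit$logL - fit$logL
    if (used_ai && it > em_iter && abs(delta) < tol) {
      em_fit <- try_step(new_fit, em_step(new_fit))
      if (!is.null(em_fit) && em_fit$logL > new_fit$logL + tol) {
        new_fit <- em_fit
        delta <- new_fit$logL - fit$logL
      }
    }
    fit <- new_fit
    logL_path <- c(logL_path, fit$logL)
    if (it > em_iter && abs(delta) < tol) {
      converged <- TRUE
      break
    }
  }
  sa <- score_ai(fit)
  # pseudo-inverse: the AI matrix can be singular when parameters are
  # confounded (e.g. an identity-like GRM makes Va and Vpe collinear)
  ai_inv <- tryCatch({
    sv <- svd(sa$AI)
    pos <- sv$d > max(sv$d) * 1e-10
    sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) /
                                     sv$d[pos])
  }, error = function(e) matrix(NA_real_, K, K))
  list(theta = fit$th, logL = fit$logL, logL_path = logL_path,
       converged = converged, ai_inv = ai_inv, iterations =
         length(logL_path) - 1L)
}

.ridge_psd <- function(G, ridge = 1e-6) {
  ev <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < ridge) G + diag(ridge - min(ev, 0) + ridge, nrow(G)) else G
}

# collapse per-meiosis records of one trait to FID sufficient statistics
.suff_stats <- function(pheno, trait) {
  y <- pheno[[trait]]
  fid <- pheno$fid
  n_i <- tapply(y, fid, length)
  ybar <- tapply(y, fid, mean)
  ssw <- sum(tapply(y, fid, function(v) sum((v - mean(v))^2)))
  list(fid = names(n_i), n = as.numeric(n_i), ybar = as.numeric(ybar),
       ssw = ssw, df_w = length(y) - length(n_i))
}

#' Fit the univariate repeatability animal model
#'
#' @param pheno data frame with columns `fid` and the response named by
#'   `trait` (one row per meiosis).
#' @param grm GRM over (at least) the FIDs in `pheno`.
#' @param f named inbreeding coefficients; used as a fixed regression
#'   covariate.  FIDs with missing F are dropped with a message.
#' @param trait response column name (default `"cc"`).
#' @param tol,maxit,em_iter REML controls.
#' @return a `varcomp` object: variance components `Va`, `Vpe`, `Ve`,
#'   derived `Vp`, `h2`, `t` with standard errors (inverse-AI, delta
#'   method), the restricted log-likelihood path and convergence flag.
#' @export
fit_repeatability <- function(pheno, grm, f = NULL, trait = "cc",
                              tol = 1e-8, maxit = 200, em_iter = 3) {
  stopifnot(trait %in% names(pheno))
  keep <- pheno$fid %in% rownames(grm)
  if (!is.null(f)) {
    has_f <- pheno$fid %in% names(f)[!is.na(f)]
    if (any(!has_f))
      message(sum(!has_f), " observation(s) dropped for missing F")
    keep <- keep & has_f
  }
  pheno <- pheno[keep, , drop = FALSE]
  ss <- .suff_stats(pheno, trait)
  q <- length(ss$fid)
  if (q < 2 || !any(ss$n > 1))
    stop("need >= 2 FIDs and repeated observations")
  G <- .ridge_psd(grm[ss$fid, ss$fid])
  D <- diag(1 / ss$n)
  X <- if (is.null(f)) matrix(1, q, 1) else cbind(1, f[ss$fid])
  ve0 <- if (ss$df_w > 0) ss$ssw / ss$df_w else stats::var(ss$ybar) / 2
  vb <- max(stats::var(ss$ybar) - ve0 * mean(1 / ss$n), ve0 / 10)
  fit <- reml_engine(
    y = ss$ybar, X = X,
    structures = list(G, diag(q), D),
    within = list(list(k = 3, df = ss$df_w, ss = ss$ssw)),
    init = c(vb / 2, vb / 2, ve0),
    tol = tol, maxit = maxit, em_iter = em_iter)
  th <- fit$theta
  vp <- sum(th)
  h2 <- th[1] / vp
  t_rep <- (th[1] + th[2]) / vp
  g_h2 <- c(vp - th[1], -th[1], -th[1]) / vp^2
  g_t <- c(th[3], th[3], -(th[1] + th[2])) / vp^2
  se <- sqrt(pmax(diag(fit$ai_inv), 0))
  h2_se <- sqrt(max(t(g_h2) %*% fit$ai_inv %*% g_h2, 0))
  t_se <- sqrt(max(t(g_t) %*% fit$ai_inv %*% g_t, 0))
  structure(list(Va = th[1], Vpe = th[2], Ve = th[3], Vp = vp,
                 h2 = h2, t = t_rep,
                 se = c(Va = se[1], Vpe = se[2], Ve = se[3],
                        h2 = h2_se, t = t_se),
                 n_fids = q, n_obs = nrow(pheno),
                 logL = fit$logL, logL_path = fit$logL_path,
                 converged = fit$converged,
                 iterations = fit$iterations, trait = trait),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat("Repeatability model (", x$trait, "): ", x$n_obs,
      " observations on ", x$n_fids, " FIDs\n", sep = "")
  cat(sprintf("  Va = %.4g (%.3g)  Vpe = %.4g (%.3g)  Ve = %.4g (%.3g)\n",
              x$Va, x$se["Va"], x$Vpe, x$se["Vpe"], x$Ve, x$se["Ve"]))
  cat(sprintf("  Vp = %.4g  h2 = %.3f (%.3f)  t = %.3f (%.3f)\n",
              x$Vp, x$h2, x$se["h2"], x$t, x$se["t"]))
  cat(sprintf("  logL = %.4f  converged: %s (%d iterations)\n",
              x$logL, x$converged, x$iterations))
  invisible(x)
}

#' Heritability and repeatability from variance components
#'
#' @param va,vpe,ve additive, permanent-environment and residual variances.
#' @return list with `Vp`, `h2`, `t`.
#' @export
varcomp_ratios <- function(va, vpe, ve) {
  vp <- va + vpe + ve
  list(Vp = vp, h2 = va / vp, t = (va + vpe) / vp)
}

#' Bivariate REML for the genetic correlation between two traits
#'
#' Fits a two-trait repeatability model with a 2x2 additive (co)variance
#' on the GRM, trait-specific permanent-environment and residual
#' variances, and no residual covariance (exact for traits measured on
#' disjoint FID sets, e.g. the same trait in the two sexes).
#'
#' @param pheno1,pheno2 per-meiosis data frames (`fid` + trait column).
#' @param grm GRM covering all FIDs involved.
#' @param trait1,trait2 response column names.
#' @param tol,maxit,em_iter REML controls.
#' @return list with the 7 components, `r_g`, `r_g_se` (delta method),
#'   per-trait `h2`, `logL_path` and `converged`; `r_g` is `NA` with a
#'   flag when either additive variance is at the floor.
#' @export
fit_bivariate <- function(pheno1, pheno2, grm, trait1 = "cc",
                          trait2 = trait1, tol = 1e-8, maxit = 200,
                          em_iter = 3) {
  s1 <- .suff_stats(pheno1[pheno1$fid %in% rownames(grm), ], trait1)
  s2 <- .suff_stats(pheno2[pheno2$fid %in% rownames(grm), ], trait2)
  q1 <- length(s1$fid); q2 <- length(s2$fid); q <- q1 + q2
  Gfull <- .ridge_psd(grm[c(s1$fid, s2$fid), c(s1$fid, s2$fid)])
  i1 <- seq_len(q1); i2 <- q1 + seq_len(q2)
  blk <- function(rows, cols, M) {
    A <- matrix(0, q, q); A[rows, cols] <- M[rows, cols]
    if (!identical(rows, cols)) A[cols, rows] <- M[cols, rows]
    A
  }
  A_va1 <- blk(i1, i1, Gfull)
  A_va2 <- blk(i2, i2, Gfull)
  A_ca <- blk(i1, i2, Gfull)
  dg <- function(rows, vals) {
    A <- matrix(0, q, q); A[cbind(rows, rows)] <- vals; A
  }
  structures <- list(A_va1, A_ca, A_va2,
                     dg(i1, 1), dg(i2, 1),
                     dg(i1, 1 / s1$n), dg(i2, 1 / s2$n))
  X <- matrix(0, q, 2); X[i1, 1] <- 1; X[i2, 2] <- 1
  y <- c(s1$ybar, s2$ybar)
  ve10 <- if (s1$df_w > 0) s1$ssw / s1$df_w else stats::var(s1$ybar) / 2
  ve20 <- if (s2$df_w > 0) s2$ssw / s2$df_w else stats::var(s2$ybar) / 2
  vb1 <- max(stats::var(s1$ybar) - ve10 * mean(1 / s1$n), ve10 / 10)
  vb2 <- max(stats::var(s2$ybar) - ve20 * mean(1 / s2$n), ve20 / 10)
  fit <- reml_engine(
    y = y, X = X, structures = structures,
    within = list(list(k = 6, df = s1$df_w, ss = s1$ssw),
                  list(k = 7, df = s2$df_w, ss = s2$ssw)),
    init = c(vb1 / 2, 0, vb2 / 2, vb1 / 2, vb2 / 2, ve10, ve20),
    var_params = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    cov_pairs = list(c(2, 1, 3)),
    tol = tol, maxit = maxit, em_iter = em_iter)
  th <- fit$theta
  floor_hit <- th[1] <= 1e-9 || th[3] <= 1e-9
  r_g <- if (floor_hit) NA_real_ else
    max(min(th[2] / sqrt(th[1] * th[3]), 1), -1)
  r_g_se <- NA_real_
  if (!floor_hit && all(is.finite(fit$ai_inv[1:3, 1:3]))) {
    gr <- c(-th[2] / (2 * th[1]), 1, -th[2] / (2 * th[3])) /
      sqrt(th[1] * th[3])
    r_g_se <- sqrt(max(t(gr) %*% fit$ai_inv[1:3, 1:3] %*% gr, 0))
  }
  list(Va1 = th[1], Ca = th[2], Va2 = th[3], Vpe1 = th[4], Vpe2 = th[5],
       Ve1 = th[6], Ve2 = th[7], r_g = r_g, r_g_se = r_g_se,
       h2_1 = th[1] / (th[1] + th[4] + th[6]),
       h2_2 = th[3] / (th[3] + th[5] + th[7]),
       floor_flag = floor_hit, logL = fit$logL,
       logL_path = fit$logL_path, converged = fit$converged)
}

#' Phenotypic correlation of FID means between two traits
#'
#' @param pheno per-meiosis phenotype table containing both traits.
#' @param trait1,trait2 column names.
#' @return Pearson correlation of per-FID means.
#' @export
phenotypic_correlation <- function(pheno, trait1 = "cc", trait2 = "rbar") {
  m1 <- tapply(pheno[[trait1]], pheno$fid, mean)
  m2 <- tapply(pheno[[trait2]], pheno$fid, mean)
  stats::cor(m1, m2)
}
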