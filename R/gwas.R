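#' @name gwas
#' @title Weighted leave-one-chromosome-out mixed-model association
#'
#' @description
#' Association of per-FID mean phenotypes with SNP dosages under
#' `ybar = a + b x + g + e`, `g ~ N(0, G_loco Va)`,
#' `e ~ N(0, D Ve)`, where `G_loco` is a genomic relationship matrix
#' built without the focal SNP's chromosome (LOCO, avoiding proximal
#' contamination) and `D = diag(d_i)` carries observation-count weights:
#' with heritability `h2` and repeatability `t` of the per-meiosis trait,
#' the FID-mean residual scale is
#' `d_i = ((t - h2) + (1 - t)/n_i) / (1 - h2)`,
#' the repeatability decomposition of `Var(ybar) = Va + Vpe + Ve/n`
#' normalised so `d = 1` for a single observation.  Null variance
#' components are re-estimated by REML for every left-out chromosome;
#' each SNP is then tested by generalised least squares with a 1-df Wald
#' chi-square.
NULL

#' Collapse per-meiosis phenotypes to weighted FID means
#'
#' @param pheno per-meiosis data frame (`fid` + trait column).
#' @param h2,t trait heritability and repeatability (0 <= h2 <= t < 1).
#' @param trait response column name.
#' @return data frame: `fid`, `ybar`, `n`, `d` (residual-variance scale).
#' @export
collapse_and_weight <- function(pheno, h2, t, trait = "cc") {
  if (t < h2) stop("repeatability t must be >= h2")
  stopifnot(h2 >= 0, t < 1)
  n_i <- tapply(pheno[[trait]], pheno$fid, length)
  ybar <- tapply(pheno[[trait]], pheno$fid, mean)
  d <- ((t - h2) + (1 - t) / as.numeric(n_i)) / (1 - h2)
  data.frame(fid = names(n_i), ybar = as.numeric(ybar),
             n = as.numeric(n_i), d = as.numeric(d),
             stringsAsFactors = FALSE)
}

#' Bonferroni significance threshold
#'
#' @param m number of tests (>= 1).
#' @param alpha family-wise error rate.
#' @return per-test p-value threshold `alpha / m`.
#' @export
bonferroni_threshold <- function(m, alpha = 0.05) {
  if (any(m < 1)) stop("m must be >= 1")
  alpha / m
}

#' Mixed-model association with leave-one-chromosome-out GRMs
#'
#' @param means weighted FID means from [collapse_and_weight()].
#' @param geno dosage matrix over the FIDs (rownames = ids).
#' @param panel `marker_panel` matching `geno` columns.
#' @param weighted use the `d` column as residual weights; `FALSE` sets
#'   `D = I` (single-record analysis).
#' @param alpha family-wise level for the Bonferroni flag.
#' @return data frame per SNP: `marker_id`, `chrom`, `pos_bp`, `beta`,
#'   `se`, `p`, `significant`, `skipped`; attributes `"threshold"` and
#'   `"varcomp"` (per-chromosome null Va/Ve).
#' @export
mlma_loco <- function(means, geno, panel, weighted = TRUE, alpha = 0.05) {
  chroms <- unique(panel$chrom)
  if (length(chroms) < 2)
    stop("LOCO needs at least 2 chromosomes")
  ids <- intersect(means$fid, rownames(geno))
  means <- means[match(ids, means$fid), , drop = FALSE]
  g <- geno[ids, , drop = FALSE]
  q <- nrow(means)
  y <- means$ybar
  d_w <- if (weighted) means$d else rep(1, q)
  D <- diag(d_w)
  ones <- matrix(1, q, 1)
  res <- vector("list", length(chroms))
  vc <- matrix(NA_real_, length(chroms), 2,
               dimnames = list(chroms, c("Va", "Ve")))
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    on_c <- panel$chrom == ch
    G <- .ridge_psd(vanraden_grm(g[, !on_c, drop = FALSE]))
    v0 <- stats::var(y)
    fit <- reml_engine(y, ones, list(G, D),
                       init = c(v0 / 2, v0 / 2), em_iter = 3,
                       tol = 1e-6, maxit = 100)
    vc[ci, ] <- fit$theta
    V <- fit$theta[1] * G + fit$theta[2] * D
    Vi <- chol2inv(chol(V))
    snp_idx <- which(on_c)
    beta <- se <- p <- rep(NA_real_, length(snp_idx))
    skipped <- logical(length(snp_idx))
    Vi1 <- Vi %*% ones
    a11 <- sum(ones * Vi1)
    Viy <- Vi %*% y
    b1y <- sum(ones * Viy)
    for (k in seq_along(snp_idx)) {
      x <- g[, snp_idx[k]]
      x[is.na(x)] <- mean(x, na.rm = TRUE)
      if (stats::var(x) < 1e-12) {
        skipped[k] <- TRUE
        next
      }
      Vix <- Vi %*% x
      a12 <- sum(ones * Vix)
      a22 <- sum(x * Vix)
      det <- a11 * a22 - a12^2
      if (det <= 1e-12 * a11 * a22) {
        skipped[k] <- TRUE
        next
      }
      b2y <- sum(x * Viy)
      beta[k] <- (a11 * b2y - a12 * b1y) / det
      se[k] <- sqrt(a11 / det)
      p[k] <- stats::pchisq((beta[k] / se[k])^2, 1, lower.tail = FALSE)
    }
    res[[ci]] <- data.frame(marker_id = panel$marker_id[snp_idx],
                            chrom = ch, pos_bp = panel$pos_bp[snp_idx],
                            beta = beta, se = se, p = p,
                            skipped = skipped, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out <- out[match(panel$marker_id, out$marker_id), , drop = FALSE]
  rownames(out) <- NULL
  thr <- bonferroni_threshold(sum(!is.na(out$p)), alpha)
  out$significant <- !is.na(out$p) & out$p < thr
  attr(out, "threshold") <- thr
  attr(out, "varcomp") <- vc
  out
}
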