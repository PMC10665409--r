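# Shared fixture builders.  Everything is generated in code under fixed
# seeds passed by the calling test.

# fully informative single-family design: sire heterozygous at every
# marker, dam homozygous for the reference allele, so every offspring
# resolves the sire-transmitted allele at every marker.  Returns genotypes,
# pedigree and the true per-meiosis gamete crossover positions.
sim_fully_informative <- function(genome, panel, n_offspring,
                                  lambda_per_chrom, dens = NULL,
                                  obligate = FALSE) {
  chroms <- genome$chrom
  m <- nrow(panel)
  if (is.null(dens)) dens <- pl_density(c(0, 1), c(1, 1))
  sire_hap <- rbind(rep(1L, m), rep(0L, m))
  off_ids <- sprintf("O%04d", seq_len(n_offspring))
  geno <- matrix(0L, n_offspring + 2L, m,
                 dimnames = list(c("SIRE", "DAM", off_ids),
                                 panel$marker_id))
  geno["SIRE", ] <- 1L
  truth <- vector("list", n_offspring)
  for (o in seq_len(n_offspring)) {
    gam <- integer(m)
    xov <- list()
    for (k in seq_along(chroms)) {
      idx <- which(panel$chrom == chroms[k])
      chi <- sample_chiasmata(genome$length_bp[k], dens,
                              lambda_per_chrom, 1, obligate)
      res <- meiosis(sire_hap[, idx, drop = FALSE], panel$pos_bp[idx],
                     chi, genome$length_bp[k])
      gam[idx] <- res$gamete
      xov[[chroms[k]]] <- res$crossovers
    }
    geno[off_ids[o], ] <- gam  # dam contributes allele 0 everywhere
    truth[[o]] <- xov
  }
  ped <- data.frame(
    id = c("SIRE", "DAM", off_ids),
    sire = c(NA, NA, rep("SIRE", n_offspring)),
    dam = c(NA, NA, rep("DAM", n_offspring)),
    sex = c("male", "female", rep("unknown", n_offspring)),
    stringsAsFactors = FALSE)
  list(pedigree = ped, geno = geno, truth = truth, off_ids = off_ids)
}

# random SNP genotypes in Hardy-Weinberg proportions
sim_hwe_geno <- function(n, m, maf = stats::runif(m, 0.1, 0.9)) {
  g <- matrix(stats::rbinom(n * m, 2, rep(maf, each = n)), n, m)
  rownames(g) <- sprintf("id%04d", seq_len(n))
  colnames(g) <- sprintf("snp%04d", seq_len(m))
  g
}

# phenotypes simulated from the repeatability model given a GRM
sim_repeat_pheno <- function(G, n_rep, va, vpe, ve) {
  q <- nrow(G)
  L <- chol(G + diag(1e-6, q))
  a <- as.numeric(crossprod(L, stats::rnorm(q))) * sqrt(va)
  pe <- stats::rnorm(q, 0, sqrt(vpe))
  data.frame(fid = rep(rownames(G), each = n_rep),
             cc = rep(a + pe, each = n_rep) +
               stats::rnorm(q * n_rep, 0, sqrt(ve)),
             stringsAsFactors = FALSE)
}

# exhaustive minimum-recombination phasing oracle: tries every orientation
# of the J informative markers and returns the minimum total number of
# origin switches over offspring (consecutive non-missing pairs)
exhaustive_min_switches <- function(t_mat) {
  J <- ncol(t_mat)
  best <- Inf
  for (mask in 0:(2^J - 1)) {
    flips <- as.integer(intToBits(mask))[seq_len(J)]
    v <- sweep(t_mat, 2, flips, function(a, f) ifelse(f == 1L, 1L - a, a))
    sw <- 0L
    for (i in seq_len(nrow(v))) {
      o <- v[i, !is.na(v[i, ])]
      if (length(o) > 1) sw <- sw + sum(diff(o) != 0)
    }
    if (sw < best) best <- sw
  }
  best
}

# total switches of a phased origin matrix
count_switches <- function(origins) {
  sw <- 0L
  for (i in seq_len(nrow(origins))) {
    o <- origins[i, !is.na(origins[i, ])]
    if (length(o) > 1) sw <- sw + sum(diff(o) != 0)
  }
  sw
}
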