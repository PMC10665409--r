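#' @name simulator
#' @title Gamete-level meiosis simulator with sex-dimorphic landscapes
#'
#' @description
#' The simulator works at the bivalent level: chiasma counts per chromosome
#' are Poisson (optionally forced to at least one, the obligate-chiasma
#' rule), chiasma positions are drawn from a sex-specific piecewise-linear
#' positional density, and each chiasma is transmitted to the sampled gamete
#' independently with probability 1/2 (two of four chromatids, no chromatid
#' interference).  This two-step construction is what makes a single
#' obligate chiasma per bivalent correspond to a 50 cM linkage map: the
#' gamete sees the crossover in only half of meioses.
#'
#' Individual variation in recombination rate is multiplicative on the
#' chiasma intensity (log link), with an additive polygenic component over
#' causal founder loci and a permanent-environment component, so simulated
#' crossover counts are heritable and repeatable by construction.
NULL

# ---- piecewise-linear positional density ------------------------------

#' Piecewise-linear density over relative chromosome position
#'
#' @param x knot positions in `[0, 1]`, increasing, covering 0 and 1.
#' @param y non-negative density values at the knots (normalised internally
#'   to integrate to 1).
#' @return a `pl_density` object.
#' @export
pl_density <- function(x, y) {
  stopifnot(length(x) == length(y), !is.unsorted(x), all(y >= 0))
  stopifnot(abs(x[1]) < 1e-12, abs(x[length(x)] - 1) < 1e-12)
  area <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  if (area <= 0) stop("density integrates to zero")
  y <- y / area
  cdf <- c(0, cumsum(diff(x) * (utils::head(y, -1) +
                                  utils::tail(y, -1)) / 2))
  cdf[length(cdf)] <- 1
  structure(list(x = x, y = y, cdf = cdf), class = "pl_density")
}

#' Inverse-CDF sampling from a piecewise-linear density
#'
#' @param n number of draws.
#' @param dens a `pl_density`.
#' @return `n` relative positions in `[0, 1]`.
#' @export
pl_sample <- function(n, dens) {
  if (n == 0) return(numeric(0))
  u <- stats::runif(n)
  seg <- findInterval(u, dens$cdf, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), length(dens$x) - 1L)
  x1 <- dens$x[seg]; x2 <- dens$x[seg + 1L]
  y1 <- dens$y[seg]; y2 <- dens$y[seg + 1L]
  du <- u - dens$cdf[seg]
  a <- (y2 - y1) / (2 * (x2 - x1))
  t <- ifelse(abs(a) < 1e-14,
              du / pmax(y1, 1e-300),
              (-y1 + sqrt(pmax(y1^2 + 4 * a * du, 0))) / (2 * a))
  pmin(pmax(x1 + t, 0), 1)
}

# ---- landscape --------------------------------------------------------

.default_density <- function(sex, acrocentric) {
  if (sex == "male") {
    if (acrocentric) {
      # crossovers confined to the distal (sub-telomeric) ~10%
      pl_density(c(0, 0.9, 0.93, 1), c(0, 0, 1, 1.3))
    } else {
      # sub-telomeric at both chromosome ends
      pl_density(c(0, 0.07, 0.1, 0.9, 0.93, 1), c(1.3, 1, 0, 0, 1, 1.3))
    }
  } else {
    if (acrocentric) {
      # pericentromere-biased but broad; rare at the telomeric end
      pl_density(c(0, 0.05, 0.25, 0.7, 1), c(0.6, 1.6, 1.4, 0.6, 0.05))
    } else {
      pl_density(c(0, 0.15, 0.5, 0.85, 1), c(0.1, 1.4, 0.9, 1.4, 0.1))
    }
  }
}

#' Expected gamete crossovers for a chiasma intensity
#'
#' With chiasma count `N ~ Poisson(lambda_k)` (replaced by `max(N, 1)` under
#' the obligate rule) and binomial(1/2) transmission, the expected gamete
#' crossover count per chromosome is `(lambda_k + exp(-lambda_k)) / 2` with
#' the obligate rule and `lambda_k / 2` without.
#'
#' @param lambda_k per-chromosome chiasma intensities.
#' @param obligate logical.
#' @return expected gamete crossovers per chromosome.
#' @export
expected_gamete_cc <- function(lambda_k, obligate = TRUE) {
  if (obligate) (lambda_k + exp(-lambda_k)) / 2 else lambda_k / 2
}

#' Calibrate the genome-wide chiasma intensity to a target crossover count
#'
#' Solves for the genome-wide intensity `lambda` such that the expected
#' total gamete crossover count equals `target_cc`, given per-chromosome
#' weights.
#'
#' @param target_cc target mean gamete crossover count (per meiosis).
#' @param weights per-chromosome weights summing to 1.
#' @param obligate logical.
#' @return genome-wide `lambda` (expected chiasmata per meiosis).
#' @export
calibrate_lambda <- function(target_cc, weights, obligate = TRUE) {
  stopifnot(abs(sum(weights) - 1) < 1e-8, target_cc > 0)
  f <- function(l) sum(expected_gamete_cc(l * weights, obligate)) - target_cc
  if (!obligate) return(2 * target_cc)
  # the obligate rule puts a floor of one chiasma per bivalent, hence a
  # minimum expected gamete crossover count of n_chrom / 2
  if (target_cc <= length(weights) / 2 + 1e-9)
    stop("target_cc at or below the obligate minimum of ",
         length(weights) / 2, " crossovers for ", length(weights),
         " chromosomes")
  lo <- 1e-8
  hi <- 2 * target_cc + 2 * length(weights)
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Sex-specific crossover landscape model
#'
#' @param genome a `genome_spec`.
#' @param female_cc,male_cc target mean gamete crossover counts per meiosis
#'   used to calibrate the per-sex chiasma intensities.
#' @param obligate enforce at least one chiasma per bivalent.
#' @param weights per-chromosome chiasma weights (default proportional to
#'   physical length).
#' @param densities optional list `list(female = list(...), male = ...)` of
#'   `pl_density` objects per chromosome; defaults depend on sex and the
#'   acrocentric flag.
#' @return a `landscape_model`.
#' @export
landscape_model <- function(genome, female_cc = 19.6, male_cc = 12.1,
                            obligate = TRUE, weights = NULL,
                            densities = NULL) {
  stopifnot(inherits(genome, "genome_spec"))
  if (is.null(weights)) weights <- genome$length_bp / sum(genome$length_bp)
  stopifnot(length(weights) == nrow(genome))
  weights <- weights / sum(weights)
  if (is.null(densities)) {
    densities <- list(
      female = lapply(genome$acrocentric, function(a)
        .default_density("female", a)),
      male = lapply(genome$acrocentric, function(a)
        .default_density("male", a)))
  }
  lambda <- c(female = calibrate_lambda(female_cc, weights, obligate),
              male = calibrate_lambda(male_cc, weights, obligate))
  structure(list(genome = genome, lambda = lambda, weights = weights,
                 densities = densities, obligate = obligate),
            class = "landscape_model")
}

#' Sample chiasma positions for one chromosome
#'
#' Chiasma count is `Poisson(lambda_k * rate_multiplier)`, replaced by
#' `max(N, 1)` under the obligate rule; positions are i.i.d. draws from the
#' positional density, returned sorted in bp.
#'
#' @param length_bp chromosome physical length (> 0).
#' @param dens a `pl_density` over relative position.
#' @param lambda_k chiasma intensity for this chromosome.
#' @param rate_multiplier positive individual rate multiplier.
#' @param obligate logical.
#' @return sorted numeric vector of chiasma positions in bp.
#' @export
sample_chiasmata <- function(length_bp, dens, lambda_k,
                             rate_multiplier = 1, obligate = TRUE) {
  if (length_bp <= 0) stop("zero-length chromosome")
  if (rate_multiplier <= 0) stop("rate_multiplier must be positive")
  n <- stats::rpois(1, lambda_k * rate_multiplier)
  if (obligate) n <- max(n, 1L)
  sort(pl_sample(n, dens)) * length_bp
}

#' One meiosis on one chromosome
#'
#' Each chiasma is included in the sampled gamete independently with
#' probability 1/2 (no chromatid interference); included chiasmata toggle
#' the copied parental strand at their position, and the starting strand is
#' uniform.  `include` and `start_strand` can be supplied to make the
#' transmission deterministic (used by exhaustive enumeration tests).
#'
#' @param happair 2 x m matrix of parental haplotype alleles (rows = the two
#'   homologues) at the chromosome's markers.
#' @param pos_bp marker positions (ascending) matching `happair` columns.
#' @param chiasmata sorted chiasma positions in bp.
#' @param length_bp chromosome length; positions outside `[0, length_bp]`
#'   are an error.
#' @param include optional logical vector, one per chiasma.
#' @param start_strand optional 1 or 2.
#' @return list with `gamete` (allele vector), `origin` (strand index per
#'   marker) and `crossovers` (bp positions of chiasmata present in this
#'   gamete).
#' @export
meiosis <- function(happair, pos_bp, chiasmata, length_bp = NULL,
                    include = NULL, start_strand = NULL) {
  if (is.unsorted(chiasmata)) stop("chiasmata must be sorted")
  if (!is.null(length_bp) && length(chiasmata) &&
      (any(chiasmata < 0) || any(chiasmata > length_bp)))
    stop("chiasma position outside chromosome")
  if (is.null(include))
    include <- stats::runif(length(chiasmata)) < 0.5
  if (is.null(start_strand)) start_strand <- sample(1:2, 1)
  kept <- chiasmata[include]
  # strand at marker = start toggled once per crossover to its left
  nleft <- findInterval(pos_bp, kept)
  origin <- 1L + (start_strand - 1L + nleft) %% 2L
  gamete <- happair[cbind(origin, seq_along(pos_bp))]
  list(gamete = gamete, origin = origin, crossovers = kept)
}

# ---- founders ---------------------------------------------------------

#' Simulate founder haplotypes
#'
#' Allele frequencies are drawn uniformly in `maf_range`; haplotype alleles
#' are independent Bernoulli draws, two haplotypes per founder.
#'
#' @param panel a `marker_panel`.
#' @param n_founders number of founders (>= 2).
#' @param maf_range frequency interval in `(0, 0.5]` (a degenerate interval
#'   like `c(0.5, 0.5)` is allowed).
#' @return list with `freq` (per-marker A1 frequency) and `haps`
#'   (2*n_founders x m 0/1 matrix; rows 2i-1 and 2i belong to founder i).
#' @export
simulate_founder_haplotypes <- function(panel, n_founders,
                                        maf_range = c(0.1, 0.5)) {
  if (nrow(panel) == 0) stop("empty marker panel")
  if (n_founders < 2) stop("need at least 2 founders")
  stopifnot(maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  m <- nrow(panel)
  freq <- stats::runif(m, maf_range[1], maf_range[2])
  haps <- matrix(stats::rbinom(2L * n_founders * m, 1L,
                               rep(freq, each = 2L * n_founders)),
                 nrow = 2L * n_founders, ncol = m)
  colnames(haps) <- panel$marker_id
  list(freq = freq, haps = haps)
}

#' Trait architecture for individual recombination rate
#'
#' @param sigma2_a named additive variances of the log rate multiplier,
#'   `c(female = , male = )`.
#' @param sigma2_pe permanent-environment variances, same shape.
#' @param r_g cross-sex genetic correlation of the causal effects.
#' @param n_causal number of causal loci drawn from the marker panel.
#' @return a `trait_architecture` list.
#' @export
trait_architecture <- function(sigma2_a = c(female = 0.005, male = 0.005),
                               sigma2_pe = c(female = 0.003, male = 0.003),
                               r_g = 0, n_causal = 100L) {
  stopifnot(all(sigma2_a >= 0), all(sigma2_pe >= 0), abs(r_g) <= 1)
  structure(list(sigma2_a = sigma2_a, sigma2_pe = sigma2_pe,
                 r_g = r_g, n_causal = as.integer(n_causal)),
            class = "trait_architecture")
}

# ---- whole-population simulation --------------------------------------

.genomewide_meiosis <- function(happair, panel_idx, genome, dens_list,
                                lambda_k, mult, obligate) {
  m_tot <- sum(lengths(panel_idx))
  gamete <- integer(m_tot)
  xov <- vector("list", nrow(genome))
  names(xov) <- genome$chrom
  for (k in seq_len(nrow(genome))) {
    idx <- panel_idx[[k]]
    chi <- sample_chiasmata(genome$length_bp[k], dens_list[[k]],
                            lambda_k[k], mult, obligate)
    res <- meiosis(happair[, idx, drop = FALSE],
                   attr(panel_idx, "pos")[[k]], chi,
                   length_bp = genome$length_bp[k])
    gamete[idx] <- res$gamete
    xov[[k]] <- res$crossovers
  }
  list(gamete = gamete, crossovers = xov)
}

.true_rbar <- function(xov_list, genome) {
  L <- genome$length_bp / sum(genome$length_bp)
  r <- 0
  for (k in seq_len(nrow(genome))) {
    br <- xov_list[[k]]
    seg <- diff(c(0, br, genome$length_bp[k]))
    p <- sum(seg[seq_along(seg) %% 2 == 1]) / genome$length_bp[k]
    r <- r + 2 * p * (1 - p) * L[k]^2
  }
  r
}

.format_xov <- function(xov_list) {
  paste(vapply(names(xov_list), function(ch) {
    paste0(ch, ":", paste(round(xov_list[[ch]]), collapse = ","))
  }, character(1)), collapse = ";")
}

#' Parse a truth-table crossover-position string
#'
#' @param s string as written by `simulate_population()`
#'   (`"chr1:123,456;chr2:"`).
#' @return named list of numeric bp position vectors per chromosome.
#' @export
parse_truth_positions <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  out <- lapply(parts, function(p) {
    bits <- strsplit(p, ":", fixed = TRUE)[[1]]
    if (length(bits) < 2 || bits[2] == "") numeric(0)
    else as.numeric(strsplit(bits[2], ",", fixed = TRUE)[[1]])
  })
  names(out) <- vapply(strsplit(parts, ":", fixed = TRUE), `[`, "", 1)
  out
}

#' Simulate a three-generation full-sib population
#'
#' Builds founder grandparents, focal parents (FIDs) as their offspring,
#' and full-sib families of FID offspring.  Every meiosis in an FID is
#' recorded in a truth table with the chiasma-derived gamete crossover
#' positions, true crossover count and true intra-chromosomal shuffling,
#' so every downstream stage has an exact oracle.
#'
#' @param genome a `genome_spec`.
#' @param panel a `marker_panel` on that genome.
#' @param landscape a `landscape_model`.
#' @param trait_arch a `trait_architecture`.
#' @param design list with `n_sires`, `n_dams`, `offspring_per_family`,
#'   `grandparents_genotyped` (fraction).  Families pair sire i with dam i
#'   cyclically, one family per distinct pair.
#' @param error_rate symmetric per-allele genotyping error probability.
#' @param missing_rate per-genotype missingness probability.
#' @param maf_range founder allele-frequency interval.
#' @return list with `pedigree`, `geno` (dosage matrix over genotyped
#'   individuals), `truth` (one row per meiosis: fid, offspring,
#'   parent_sex, cc, rbar, positions), `breeding_values`, `panel`,
#'   `genome`, `landscape`.
#' @export
simulate_population <- function(genome, panel, landscape = NULL,
                                trait_arch = trait_architecture(),
                                design = list(n_sires = 60, n_dams = 60,
                                              offspring_per_family = 20,
                                              grandparents_genotyped = 0.5),
                                error_rate = 0.001, missing_rate = 0.003,
                                maf_range = c(0.1, 0.5)) {
  if (is.null(landscape)) landscape <- landscape_model(genome)
  stopifnot(design$n_sires >= 1, design$n_dams >= 1,
            design$offspring_per_family >= 1,
            error_rate >= 0, error_rate < 1,
            missing_rate >= 0, missing_rate < 1)
  chroms <- genome$chrom
  panel_idx <- lapply(chroms, function(ch) which(panel$chrom == ch))
  attr(panel_idx, "pos") <- lapply(chroms, function(ch)
    panel$pos_bp[panel$chrom == ch])
  m <- nrow(panel)

  n_s <- design$n_sires; n_d <- design$n_dams
  n_fid <- n_s + n_d
  founders <- simulate_founder_haplotypes(panel, 2L * n_fid, maf_range)

  sire_ids <- sprintf("S%03d", seq_len(n_s))
  dam_ids <- sprintf("D%03d", seq_len(n_d))
  fid_ids <- c(sire_ids, dam_ids)
  fid_sex <- c(rep("male", n_s), rep("female", n_d))
  gs_ids <- sprintf("GS%03d", seq_len(n_fid))   # grandsires
  gd_ids <- sprintf("GD%03d", seq_len(n_fid))   # granddams

  lam_k <- list(female = landscape$lambda["female"] * landscape$weights,
                male = landscape$lambda["male"] * landscape$weights)

  # FID haplotypes: one gamete from each founder parent (multiplier 1)
  fid_haps <- vector("list", n_fid)
  for (i in seq_len(n_fid)) {
    gs_pair <- founders$haps[c(4L * i - 3L, 4L * i - 2L), , drop = FALSE]
    gd_pair <- founders$haps[c(4L * i - 1L, 4L * i), , drop = FALSE]
    hp <- .genomewide_meiosis(gs_pair, panel_idx, genome,
                              landscape$densities$male, lam_k$male, 1,
                              landscape$obligate)$gamete
    hm <- .genomewide_meiosis(gd_pair, panel_idx, genome,
                              landscape$densities$female, lam_k$female, 1,
                              landscape$obligate)$gamete
    fid_haps[[i]] <- rbind(hp, hm)
  }

  # polygenic rate multipliers on the log scale
  fid_dosage <- t(vapply(fid_haps, colSums, numeric(m)))
  causal <- sample.int(m, min(trait_arch$n_causal, m))
  sig <- matrix(c(1, trait_arch$r_g, trait_arch$r_g, 1), 2)
  ch_s <- chol(sig + diag(1e-10, 2))
  eff <- matrix(stats::rnorm(2 * length(causal)), ncol = 2) %*% ch_s
  a_raw <- cbind(
    female = as.numeric(scale(fid_dosage[, causal, drop = FALSE] %*%
                                eff[, 1], scale = FALSE)),
    male = as.numeric(scale(fid_dosage[, causal, drop = FALSE] %*%
                              eff[, 2], scale = FALSE)))
  a <- numeric(n_fid); pe <- numeric(n_fid)
  for (sx in c("female", "male")) {
    sel <- fid_sex == sx
    s2 <- trait_arch$sigma2_a[[sx]]
    if (s2 > 0 && sum(sel) > 1 && isTRUE(stats::sd(a_raw[sel, sx]) > 0))
      a[sel] <- a_raw[sel, sx] / stats::sd(a_raw[sel, sx]) * sqrt(s2)
    if (trait_arch$sigma2_pe[[sx]] > 0)
      pe[sel] <- stats::rnorm(sum(sel), 0,
                              sqrt(trait_arch$sigma2_pe[[sx]]))
  }
  mult <- exp(a + pe)

  # families: sire i x dam i, cycled to max(n_s, n_d) distinct pairs
  n_fam <- max(n_s, n_d)
  fam_sire <- ((seq_len(n_fam) - 1L) %% n_s) + 1L
  fam_dam <- ((seq_len(n_fam) - 1L) %% n_d) + 1L
  n_off <- design$offspring_per_family

  off_ids <- character(n_fam * n_off)
  off_geno <- matrix(0L, n_fam * n_off, m)
  truth <- vector("list", 2L * n_fam * n_off)
  off_sire <- character(n_fam * n_off); off_dam <- character(n_fam * n_off)
  row <- 0L; trow <- 0L
  for (f in seq_len(n_fam)) {
    si <- fam_sire[f]; di <- n_s + fam_dam[f]
    for (o in seq_len(n_off)) {
      row <- row + 1L
      oid <- sprintf("F%03dO%03d", f, o)
      off_ids[row] <- oid
      off_sire[row] <- fid_ids[si]; off_dam[row] <- fid_ids[di]
      gp <- .genomewide_meiosis(fid_haps[[si]], panel_idx, genome,
                                landscape$densities$male, lam_k$male,
                                mult[si], landscape$obligate)
      gm <- .genomewide_meiosis(fid_haps[[di]], panel_idx, genome,
                                landscape$densities$female, lam_k$female,
                                mult[di], landscape$obligate)
      off_geno[row, ] <- gp$gamete + gm$gamete
      trow <- trow + 1L
      truth[[trow]] <- data.frame(
        fid = fid_ids[si], offspring = oid, parent_sex = "male",
        cc = sum(lengths(gp$crossovers)),
        rbar = .true_rbar(gp$crossovers, genome),
        positions = .format_xov(gp$crossovers), stringsAsFactors = FALSE)
      trow <- trow + 1L
      truth[[trow]] <- data.frame(
        fid = fid_ids[di], offspring = oid, parent_sex = "female",
        cc = sum(lengths(gm$crossovers)),
        rbar = .true_rbar(gm$crossovers, genome),
        positions = .format_xov(gm$crossovers), stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)

  # pedigree: founders -> FIDs -> offspring
  pedigree <- rbind(
    data.frame(id = gs_ids, sire = NA_character_, dam = NA_character_,
               sex = "male", stringsAsFactors = FALSE),
    data.frame(id = gd_ids, sire = NA_character_, dam = NA_character_,
               sex = "female", stringsAsFactors = FALSE),
    data.frame(id = fid_ids, sire = gs_ids, dam = gd_ids,
               sex = fid_sex, stringsAsFactors = FALSE),
    data.frame(id = off_ids, sire = off_sire, dam = off_dam,
               sex = "unknown", stringsAsFactors = FALSE))

  # genotyped set: all FIDs and offspring, a fraction of grandparents
  gp_geno_sel <- stats::runif(n_fid) < design$grandparents_genotyped
  founder_dosage_gs <- t(vapply(seq_len(n_fid), function(i)
    colSums(founders$haps[c(4L * i - 3L, 4L * i - 2L), , drop = FALSE]),
    numeric(m)))
  founder_dosage_gd <- t(vapply(seq_len(n_fid), function(i)
    colSums(founders$haps[c(4L * i - 1L, 4L * i), , drop = FALSE]),
    numeric(m)))
  geno <- rbind(founder_dosage_gs[gp_geno_sel, , drop = FALSE],
                founder_dosage_gd[gp_geno_sel, , drop = FALSE],
                fid_dosage, off_geno)
  rownames(geno) <- c(gs_ids[gp_geno_sel], gd_ids[gp_geno_sel],
                      fid_ids, off_ids)
  colnames(geno) <- panel$marker_id
  storage.mode(geno) <- "integer"

  if (error_rate > 0) {
    n_cell <- length(geno)
    f12 <- matrix(stats::rbinom(n_cell, pmax(geno, 0L), error_rate),
                  nrow(geno))
    f21 <- matrix(stats::rbinom(n_cell, pmax(2L - geno, 0L), error_rate),
                  nrow(geno))
    geno <- geno - f12 + f21
  }
  if (missing_rate > 0)
    geno[matrix(stats::runif(length(geno)) < missing_rate,
                nrow(geno))] <- NA_integer_

  bv <- data.frame(id = fid_ids, sex = fid_sex, a = a, pe = pe,
                   multiplier = mult, stringsAsFactors = FALSE)
  list(pedigree = pedigree, geno = geno, truth = truth,
       breeding_values = bv, panel = panel, genome = genome,
       landscape = landscape)
}
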