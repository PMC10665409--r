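#' @name recomb_phenotypes
#' @title Per-meiosis recombination phenotypes
#'
#' @description
#' Converts phased origin vectors into two phenotypes per meiosis, assigned
#' to the focal parent in which the meiosis took place: the crossover count
#' CC (number of origin switches summed over chromosomes) and the
#' intra-chromosomal allelic shuffling
#' \deqn{\bar r = \sum_k 2 p_k (1 - p_k) L_k^2,}
#' the probability that a randomly chosen pair of loci on the same
#' chromosome received different grandparental origins, where \eqn{p_k} is
#' the fraction of chromosome k carrying one origin label and \eqn{L_k} is
#' the chromosome's length as a fraction of total genome length.
NULL

#' Detect crossovers in one origin vector
#'
#' Runs of identical origin shorter than `min_support` markers that are
#' flanked on both sides by the opposite origin are set missing (treated as
#' genotyping error); each remaining origin change then emits one crossover
#' event localised to the bracketing informative-marker interval.
#'
#' @param origin integer vector of origin labels (1/2, NA allowed) at the
#'   informative markers of one chromosome, in genome order.
#' @param pos_bp marker positions matching `origin`.
#' @param min_support integer >= 1.
#' @return list with `origin` (cleaned vector, same length) and `events`
#'   (data frame: left_bp, right_bp, left_idx, right_idx).
#' @export
detect_crossovers <- function(origin, pos_bp, min_support = 3) {
  if (min_support < 1) stop("min_support must be >= 1")
  cleaned <- origin
  obs <- which(!is.na(origin))
  if (length(obs) >= 2 && min_support > 1) {
    r <- rle(origin[obs])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    short <- which(r$lengths < min_support &
                     seq_along(r$lengths) > 1 &
                     seq_along(r$lengths) < length(r$lengths))
    for (s in short) cleaned[obs[starts[s]:ends[s]]] <- NA_integer_
    obs <- which(!is.na(cleaned))
  }
  if (length(obs) < 2) {
    ev <- data.frame(left_bp = numeric(0), right_bp = numeric(0),
                     left_idx = integer(0), right_idx = integer(0))
    return(list(origin = cleaned, events = ev))
  }
  o <- cleaned[obs]
  sw <- which(diff(o) != 0)
  ev <- data.frame(left_bp = pos_bp[obs[sw]], right_bp = pos_bp[obs[sw + 1]],
                   left_idx = obs[sw], right_idx = obs[sw + 1])
  list(origin = cleaned, events = ev)
}

#' Crossover count from detected events
#' @param events event data frame(s) from [detect_crossovers()], one per
#'   chromosome (a list).
#' @return list with `total` and per-chromosome counts.
#' @export
crossover_count <- function(events) {
  per <- vapply(events, nrow, 0L)
  list(total = sum(per), per_chrom = per)
}

#' Intra-chromosomal shuffling of one gamete
#'
#' Each chromosome is segmented by placing a breakpoint at the physical
#' midpoint of every crossover interval; chromosome ends extend the nearest
#' observed origin.  `p_k` is the physical-length fraction carrying one
#' origin label (or the marker fraction in `"marker"` mode), and
#' `rbar = sum_k 2 p_k (1-p_k) L_k^2`.  Chromosomes without informative
#' markers contribute zero and raise a coverage flag.
#'
#' @param origins list per chromosome of cleaned origin vectors (as from
#'   [detect_crossovers()]), named by chromosome.
#' @param positions list per chromosome of marker positions.
#' @param events list per chromosome of event data frames.
#' @param genome a `genome_spec` covering all chromosomes present.
#' @param mode `"physical"` (default) or `"marker"`.
#' @return list with `rbar`, `p_k` (named), `covered` (logical per
#'   chromosome).
#' @export
shuffling_rbar <- function(origins, positions, events, genome,
                           mode = c("physical", "marker")) {
  mode <- match.arg(mode)
  if (!all(names(origins) %in% genome$chrom))
    stop("unknown chromosome: ",
         setdiff(names(origins), genome$chrom)[1])
  Lbp <- stats::setNames(genome$length_bp, genome$chrom)
  L <- Lbp / sum(genome$length_bp)
  p_k <- stats::setNames(rep(NA_real_, nrow(genome)), genome$chrom)
  covered <- stats::setNames(rep(FALSE, nrow(genome)), genome$chrom)
  rbar <- 0
  for (ch in names(origins)) {
    o <- origins[[ch]]
    obs <- which(!is.na(o))
    if (!length(obs)) next
    covered[ch] <- TRUE
    if (mode == "marker") {
      p <- mean(o[obs] == 1L)
    } else {
      br <- if (nrow(events[[ch]])) {
        (events[[ch]]$left_bp + events[[ch]]$right_bp) / 2
      } else numeric(0)
      seg <- diff(c(0, br, Lbp[ch]))
      first_origin <- o[obs[1]]
      lab <- rep(c(first_origin, 3L - first_origin),
                 length.out = length(seg))
      p <- sum(seg[lab == 1L]) / Lbp[ch]
    }
    p_k[ch] <- p
    rbar <- rbar + 2 * p * (1 - p) * L[ch]^2
  }
  list(rbar = unname(rbar), p_k = p_k, covered = covered)
}

#' Per-meiosis phenotypes for a whole phased population
#'
#' @param om origin matrices from [origin_matrices()].
#' @param genome a `genome_spec`.
#' @param panel the `marker_panel` the matrices were built on.
#' @param min_support passed to [detect_crossovers()].
#' @param mode passed to [shuffling_rbar()].
#' @return data frame with one row per meiosis: `fid`, `offspring`,
#'   `parent_sex`, `cc`, `rbar`, `n_chrom_covered`, plus per-chromosome
#'   crossover counts in attribute `"cc_per_chrom"`.
#' @export
gamete_phenotypes <- function(om, genome, panel, min_support = 3,
                              mode = "physical") {
  n <- nrow(om$meta)
  chroms <- names(om$mats)
  pos <- lapply(chroms, function(ch) panel$pos_bp[panel$chrom == ch])
  names(pos) <- chroms
  cc <- integer(n); rbar <- numeric(n); ncov <- integer(n)
  ccpc <- matrix(0L, n, length(chroms), dimnames = list(NULL, chroms))
  for (i in seq_len(n)) {
    origins <- list(); events <- list()
    for (ch in chroms) {
      dc <- detect_crossovers(om$mats[[ch]][i, ], pos[[ch]], min_support)
      origins[[ch]] <- dc$origin
      events[[ch]] <- dc$events
      ccpc[i, ch] <- nrow(dc$events)
    }
    cc[i] <- sum(ccpc[i, ])
    sh <- shuffling_rbar(origins, pos, events, genome, mode)
    rbar[i] <- sh$rbar
    ncov[i] <- sum(sh$covered)
  }
  out <- cbind(om$meta,
               data.frame(cc = cc, rbar = rbar, n_chrom_covered = ncov))
  attr(out, "cc_per_chrom") <- ccpc
  out
}

#' Per-sex summary of recombination phenotypes
#'
#' @param pheno per-meiosis phenotype table from [gamete_phenotypes()].
#' @return data frame with one row per (trait, sex): number of FIDs,
#'   number of observations (meioses), mean and SD.
#' @export
phenotype_summary <- function(pheno) {
  stopifnot(nrow(pheno) >= 1)
  out <- list()
  for (trait in c("cc", "rbar")) {
    for (sx in unique(pheno$parent_sex)) {
      d <- pheno[pheno$parent_sex == sx, ]
      out[[length(out) + 1L]] <- data.frame(
        trait = trait, sex = sx, n_fids = length(unique(d$fid)),
        n_obs = nrow(d), mean = mean(d[[trait]]), sd = stats::sd(d[[trait]]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Clean origin matrices for linkage mapping
#'
#' Applies the short-run mask of [detect_crossovers()] to every meiosis of
#' every chromosome, so isolated origin flips from genotyping error do not
#' inflate interval recombination fractions (and hence map lengths).
#'
#' @param om origin matrices from [origin_matrices()].
#' @param panel the `marker_panel`.
#' @param min_support passed to [detect_crossovers()].
#' @return `om` with cleaned matrices.
#' @export
clean_origin_matrices <- function(om, panel, min_support = 3) {
  for (ch in names(om$mats)) {
    pos <- panel$pos_bp[panel$chrom == ch]
    mat <- om$mats[[ch]]
    for (i in seq_len(nrow(mat)))
      mat[i, ] <- detect_crossovers(mat[i, ], pos, min_support)$origin
    om$mats[[ch]] <- mat
  }
  om
}
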