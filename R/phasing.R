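#' @name phasing
#' @title Gamete phasing in three-generation full-sib families
#'
#' @description
#' For each distinct sire-by-dam mating (the focal individuals, FIDs) a
#' three-generation family is built from the pedigree: the two FIDs, their
#' genotyped offspring and, when available, the FIDs' own genotyped
#' parents.  Within a family, the gametes each FID transmitted are phased
#' at the FID's heterozygous markers by resolving which parental allele
#' each offspring received, then chaining marker orientations along the
#' chromosome so that the majority of offspring keep their previous origin
#' (greedy minimum-recombination phasing; the very large families of this
#' design make the majority vote essentially exact).
NULL

# transmissible A1-allele count range for a parental dosage (NA = unknown)
.tmin <- function(p) ifelse(is.na(p), 0L, ifelse(p == 2L, 1L, 0L))
.tmax <- function(p) ifelse(is.na(p), 1L, ifelse(p == 0L, 0L, 1L))

#' Check a pedigree for cycles
#' @param pedigree data frame with `id`, `sire`, `dam`.
#' @return `TRUE` invisibly; error if an individual is its own ancestor.
#' @export
check_pedigree <- function(pedigree) {
  idx <- seq_len(nrow(pedigree))
  names(idx) <- pedigree$id
  state <- integer(nrow(pedigree))  # 0 unvisited, 1 in stack, 2 done
  visit <- function(i) {
    if (state[i] == 1L) stop("pedigree cycle involving ", pedigree$id[i])
    if (state[i] == 2L) return(invisible())
    state[i] <<- 1L
    for (p in c(pedigree$sire[i], pedigree$dam[i])) {
      if (!is.na(p) && !is.na(idx[p])) visit(idx[[p]])
    }
    state[i] <<- 2L
  }
  for (i in seq_along(state)) if (state[i] == 0L) visit(i)
  invisible(TRUE)
}

#' Build full-sib families from a pedigree
#'
#' One family per distinct sire-by-dam pair with at least one genotyped
#' offspring and both parents genotyped.  An individual may be an FID in
#' several families (one per mate); each meiosis belongs to exactly one
#' family.
#'
#' @param pedigree data frame with `id`, `sire`, `dam`, `sex`.
#' @param genotyped character vector of genotyped individual ids.
#' @return list of families, each a list with `sire`, `dam`, `offspring`
#'   (genotyped ids) and `grandparents` (named: sire_sire, sire_dam,
#'   dam_sire, dam_dam; only genotyped ones, else `NA`).  Families dropped
#'   for ungenotyped parents are reported in attribute `"excluded"`.
#' @export
build_families <- function(pedigree, genotyped) {
  check_pedigree(pedigree)
  has_par <- !is.na(pedigree$sire) & !is.na(pedigree$dam)
  off <- pedigree[has_par & pedigree$id %in% genotyped, , drop = FALSE]
  if (nrow(off) == 0) return(structure(list(), excluded = character(0)))
  key <- paste(off$sire, off$dam, sep = "\r")
  fams <- split(off$id, key)
  excluded <- character(0)
  out <- list()
  lookup <- function(id) {
    i <- match(id, pedigree$id)
    if (is.na(i)) c(NA_character_, NA_character_)
    else c(pedigree$sire[i], pedigree$dam[i])
  }
  for (k in names(fams)) {
    pr <- strsplit(k, "\r", fixed = TRUE)[[1]]
    if (pr[1] == pr[2]) stop("selfing mating (sire == dam): ", pr[1])
    if (!(pr[1] %in% genotyped) || !(pr[2] %in% genotyped)) {
      excluded <- c(excluded, paste0(pr[1], "x", pr[2],
                                     ": parent not genotyped"))
      next
    }
    gp_s <- lookup(pr[1]); gp_d <- lookup(pr[2])
    gp <- c(sire_sire = gp_s[1], sire_dam = gp_s[2],
            dam_sire = gp_d[1], dam_dam = gp_d[2])
    gp[!(gp %in% genotyped)] <- NA_character_
    out[[length(out) + 1L]] <- list(sire = pr[1], dam = pr[2],
                                    offspring = fams[[k]],
                                    grandparents = gp)
  }
  structure(out, excluded = excluded)
}

#' Mendelian-consistency check within one family
#'
#' Offspring genotypes impossible given the two parental genotypes (the
#' offspring dosage cannot be written as a sum of transmissible alleles)
#' are set missing in that offspring; parents are never modified.
#'
#' @param family a family from [build_families()].
#' @param geno dosage matrix (rows = individuals).
#' @return list with `geno` (cleaned copy), `n_flagged`, and `per_marker`
#'   flag counts.
#' @export
mendel_check <- function(family, geno) {
  p1 <- geno[family$sire, ]
  p2 <- geno[family$dam, ]
  lo <- .tmin(p1) + .tmin(p2)
  hi <- .tmax(p1) + .tmax(p2)
  per_marker <- integer(ncol(geno))
  n_flagged <- 0L
  for (o in family$offspring) {
    d <- geno[o, ]
    bad <- !is.na(d) & (d < lo | d > hi)
    if (any(bad)) {
      geno[o, bad] <- NA_integer_
      per_marker <- per_marker + bad
      n_flagged <- n_flagged + sum(bad)
    }
  }
  list(geno = geno, n_flagged = n_flagged, per_marker = per_marker)
}

# Mendelian offspring-dosage distribution given parental dosages
.mendel_probs <- function(p1, p2) {
  t1 <- if (p1 == 0) c(1, 0) else if (p1 == 1) c(0.5, 0.5) else c(0, 1)
  t2 <- if (p2 == 0) c(1, 0) else if (p2 == 1) c(0.5, 0.5) else c(0, 1)
  pr <- numeric(3)
  for (i in 0:1) for (j in 0:1) pr[i + j + 1] <- pr[i + j + 1] +
      t1[i + 1] * t2[j + 1]
  pr
}

#' Segregation-distortion filter within one family
#'
#' Chi-square goodness of fit of offspring genotype counts against the
#' Mendelian expectation given the parental genotypes; markers with
#' p < `alpha` are masked (set missing) in the family's offspring.
#' Markers without a computable expectation (a missing parent) and markers
#' with fewer than 2 informative offspring or fewer than 2 expected
#' genotype classes are left untouched.
#'
#' @param family a family from [build_families()].
#' @param geno dosage matrix.
#' @param alpha significance level in (0, 1), default 0.01.
#' @return list with `keep` (logical per marker), `p_value` (NA where not
#'   tested) and `geno` (masked copy).
#' @export
segregation_filter <- function(family, geno, alpha = 0.01) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  p1 <- geno[family$sire, ]
  p2 <- geno[family$dam, ]
  offg <- geno[family$offspring, , drop = FALSE]
  m <- ncol(geno)
  keep <- rep(TRUE, m)
  pval <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    if (is.na(p1[j]) || is.na(p2[j])) next
    pr <- .mendel_probs(p1[j], p2[j])
    d <- offg[, j]
    d <- d[!is.na(d)]
    cls <- which(pr > 0)
    if (length(cls) < 2 || length(d) < 2) next
    obs <- tabulate(d + 1L, 3L)[cls]
    incons <- sum(tabulate(d + 1L, 3L)[-cls])
    if (sum(obs) < 2) next
    e <- pr[cls] * sum(obs)
    x2 <- sum((obs - e)^2 / e)
    pval[j] <- stats::pchisq(x2, df = length(cls) - 1, lower.tail = FALSE)
    if (pval[j] < alpha) keep[j] <- FALSE
  }
  geno[family$offspring, !keep] <- NA_integer_
  list(keep = keep, p_value = pval, geno = geno)
}

# transmitted-allele matrix for one chromosome: offspring x markers,
# entries = A1 count transmitted by the focal parent (0/1/NA)
.transmitted <- function(offg, other) {
  t <- matrix(NA_integer_, nrow(offg), ncol(offg))
  t[offg == 0L] <- 0L
  t[offg == 2L] <- 1L
  het <- which(offg == 1L, arr.ind = TRUE)
  if (nrow(het)) {
    q <- other[het[, 2]]
    t[het[q == 0L & !is.na(q), , drop = FALSE]] <- 1L
    t[het[q == 2L & !is.na(q), , drop = FALSE]] <- 0L
  }
  t
}

#' Phase the gametes one focal parent transmitted to a family
#'
#' Informative markers are those where the focal parent is heterozygous;
#' each offspring's received parental allele is resolved where possible
#' (offspring homozygous, or the other parent homozygous).  A binary
#' orientation chain over the informative markers in genome order then
#' assigns each allele to parental haplotype H1 or H2, choosing at each
#' marker the orientation that keeps the majority of offspring origins
#' unchanged; ties keep the previous orientation.  Haplotype labels are
#' anchored to grandparental origin where the parent's own parents are
#' genotyped, otherwise labels are arbitrary per chromosome (crossover
#' count and shuffling are label-invariant).
#'
#' @param family a family from [build_families()].
#' @param geno dosage matrix.
#' @param panel a `marker_panel`.
#' @param parent `"sire"` or `"dam"`.
#' @param min_offspring smallest number of genotyped offspring for which a
#'   family is phased (default 4); below it `NULL` is returned.
#' @return a `phased_family`: list with `fid`, `parent_sex`,
#'   `offspring`, and `chrom`, a per-chromosome list with `marker_idx`
#'   (panel row indices of the informative markers), `pos_bp`, `origins`
#'   (offspring x informative-marker matrix of 1/2/NA) and `anchored`.
#' @export
phase_gametes <- function(family, geno, panel,
                          parent = c("sire", "dam"), min_offspring = 4) {
  parent <- match.arg(parent)
  fid <- family[[parent]]
  other_id <- family[[setdiff(c("sire", "dam"), parent)]]
  if (!fid %in% rownames(geno)) stop("parent not genotyped: ", fid)
  if (length(family$offspring) < min_offspring) return(NULL)
  gp_keys <- if (parent == "sire") c("sire_sire", "sire_dam") else
    c("dam_sire", "dam_dam")
  gp <- family$grandparents[gp_keys]
  chroms <- unique(panel$chrom)
  res <- vector("list", length(chroms))
  names(res) <- chroms
  for (ch in chroms) {
    idx <- which(panel$chrom == ch)
    P <- geno[fid, idx]
    inf <- which(!is.na(P) & P == 1L)
    if (!length(inf)) {
      res[[ch]] <- list(marker_idx = integer(0), pos_bp = numeric(0),
                        origins = matrix(NA_integer_,
                                         length(family$offspring), 0),
                        anchored = FALSE)
      next
    }
    midx <- idx[inf]
    offg <- geno[family$offspring, midx, drop = FALSE]
    other <- geno[other_id, midx]
    t <- .transmitted(offg, other)
    J <- ncol(t)
    flip <- logical(J)
    r_last <- rep(NA_integer_, nrow(t))
    v1 <- t[, 1]
    r_last[!is.na(v1)] <- v1[!is.na(v1)]
    if (J > 1) for (j in 2:J) {
      tj <- t[, j]
      ok <- !is.na(tj) & !is.na(r_last)
      m_keep <- sum(tj[ok] == r_last[ok])
      m_flip <- sum((1L - tj[ok]) == r_last[ok])
      flip[j] <- if (m_flip > m_keep) TRUE
        else if (m_keep > m_flip) FALSE
        else flip[j - 1]
      vj <- if (flip[j]) 1L - tj else tj
      r_last[!is.na(vj)] <- vj[!is.na(vj)]
    }
    oriented <- sweep(t, 2, as.integer(flip), function(a, f)
      ifelse(f == 1L, 1L - a, a))
    origins <- matrix(NA_integer_, nrow(t), J)
    origins[!is.na(oriented)] <- 2L - oriented[!is.na(oriented)]
    rownames(origins) <- family$offspring

    anchored <- FALSE
    if (!any(is.na(gp))) {
      # A1-allele source at parent-het markers, where determinable
      g_s <- geno[gp[[1]], midx]; g_d <- geno[gp[[2]], midx]
      a1_from_s <- ifelse(!is.na(g_s) & g_s == 2L, TRUE,
                          ifelse(!is.na(g_d) & g_d == 2L, FALSE,
                                 ifelse(!is.na(g_s) & g_s == 0L, FALSE,
                                        ifelse(!is.na(g_d) & g_d == 0L,
                                               TRUE, NA))))
      # H1 carries A1 where the orientation is unflipped
      h1_from_s <- ifelse(is.na(a1_from_s), NA, a1_from_s == !flip)
      votes <- table(h1_from_s)
      if (length(votes)) {
        anchored <- TRUE
        if (names(which.max(votes))[1] == "FALSE") {
          # relabel so H1 = grandsire haplotype
          origins <- 3L - origins
        }
      }
    }
    res[[ch]] <- list(marker_idx = midx, pos_bp = panel$pos_bp[midx],
                      origins = origins, anchored = anchored)
  }
  structure(list(fid = fid,
                 parent_sex = if (parent == "sire") "male" else "female",
                 offspring = family$offspring, chrom = res),
            class = "phased_family")
}

#' Phase every family in a population
#'
#' Runs the Mendel check, the segregation-distortion filter and
#' [phase_gametes()] for both parents of every family.
#'
#' @param pedigree,geno,panel population data.
#' @param min_offspring passed to [phase_gametes()].
#' @param seg_alpha segregation-filter level; `NULL` disables the filter.
#' @param mendel apply the Mendelian-consistency mask first.
#' @return list of `phased_family` objects (two per family when both
#'   parents are heterozygous somewhere).
#' @export
phase_families <- function(pedigree, geno, panel, min_offspring = 4,
                           seg_alpha = 0.01, mendel = TRUE) {
  fams <- build_families(pedigree, rownames(geno))
  out <- list()
  for (fam in fams) {
    g <- geno[c(fam$sire, fam$dam, fam$offspring,
                fam$grandparents[!is.na(fam$grandparents)]), ,
              drop = FALSE]
    if (mendel) g <- mendel_check(fam, g)$geno
    if (!is.null(seg_alpha)) g <- segregation_filter(fam, g, seg_alpha)$geno
    for (par in c("sire", "dam")) {
      ph <- phase_gametes(fam, g, panel, par, min_offspring)
      if (!is.null(ph)) out[[length(out) + 1L]] <- ph
    }
  }
  out
}

#' Per-chromosome origin matrices across all phased meioses
#'
#' Reshapes a list of `phased_family` objects into, per chromosome, one
#' meiosis-by-marker matrix of origin labels over all panel markers on the
#' chromosome (NA where the meiosis is uninformative), plus a meiosis
#' metadata table.  This is the substrate for phenotype extraction and
#' linkage mapping.
#'
#' @param phased list of `phased_family` objects.
#' @param panel a `marker_panel`.
#' @return list with `meta` (data frame: fid, offspring, parent_sex) and
#'   `mats` (named list per chromosome; columns follow panel order).
#' @export
origin_matrices <- function(phased, panel) {
  chroms <- unique(panel$chrom)
  meta <- do.call(rbind, lapply(phased, function(ph)
    data.frame(fid = ph$fid, offspring = ph$offspring,
               parent_sex = ph$parent_sex, stringsAsFactors = FALSE)))
  n <- if (is.null(meta)) 0L else nrow(meta)
  mats <- list()
  for (ch in chroms) {
    idx <- which(panel$chrom == ch)
    mat <- matrix(NA_integer_, n, length(idx))
    colnames(mat) <- panel$marker_id[idx]
    row0 <- 0L
    for (ph in phased) {
      blk <- ph$chrom[[ch]]
      rows <- row0 + seq_along(ph$offspring)
      if (length(blk$marker_idx))
        mat[rows, match(blk$marker_idx, idx)] <- blk$origins
      row0 <- row0 + length(ph$offspring)
    }
    mats[[ch]] <- mat
  }
  list(meta = meta, mats = mats)
}

#' Write/read origin vectors as a long table
#'
#' The stage-exchange format between phasing and the downstream stages:
#' one row per (meiosis, informative marker) with the origin label.
#'
#' @param om origin matrices from [origin_matrices()].
#' @param panel the `marker_panel`.
#' @return data frame with `fid`, `offspring`, `parent_sex`, `chrom`,
#'   `pos_bp`, `origin`.
#' @export
origins_to_table <- function(om, panel) {
  out <- list()
  for (ch in names(om$mats)) {
    mat <- om$mats[[ch]]
    pos <- panel$pos_bp[panel$chrom == ch]
    nz <- which(!is.na(mat), arr.ind = TRUE)
    if (!nrow(nz)) next
    out[[ch]] <- data.frame(
      fid = om$meta$fid[nz[, 1]],
      offspring = om$meta$offspring[nz[, 1]],
      parent_sex = om$meta$parent_sex[nz[, 1]],
      chrom = ch, pos_bp = pos[nz[, 2]],
      origin = mat[nz], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' @rdname origins_to_table
#' @param tab long table as produced by [origins_to_table()].
#' @return an origin-matrices list (`meta` + `mats`).
#' @export
origins_from_table <- function(tab, panel) {
  key <- paste(tab$fid, tab$offspring, tab$parent_sex, sep = "\r")
  meta_keys <- unique(key)
  meta <- do.call(rbind, strsplit(meta_keys, "\r", fixed = TRUE))
  meta <- data.frame(fid = meta[, 1], offspring = meta[, 2],
                     parent_sex = meta[, 3], stringsAsFactors = FALSE)
  row_i <- match(key, meta_keys)
  mats <- list()
  for (ch in unique(panel$chrom)) {
    pos <- panel$pos_bp[panel$chrom == ch]
    mat <- matrix(NA_integer_, nrow(meta), length(pos))
    colnames(mat) <- panel$marker_id[panel$chrom == ch]
    sel <- tab$chrom == ch
    if (any(sel))
      mat[cbind(row_i[sel], match(tab$pos_bp[sel], pos))] <-
        as.integer(tab$origin[sel])
    mats[[ch]] <- mat
  }
  list(meta = meta, mats = mats)
}
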