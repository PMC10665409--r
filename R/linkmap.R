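#' @name linkage_map
#' @title Sex-specific linkage maps with the Haldane mapping function
#'
#' @description
#' Marker order is taken from the genome (no de-novo ordering).  For each
#' pair of adjacent informative markers the recombination fraction is the
#' share of recombinant meioses among meioses with a non-missing origin at
#' both markers (pairwise-complete convention), converted to map distance
#' with the Haldane function \eqn{d = -50 \ln(1 - 2\hat r)} cM and
#' accumulated along the chromosome.  Markers never informative get cM
#' positions interpolated by physical position.
NULL

#' Haldane mapping function and inverse
#' @param r recombination fraction (< 0.5).
#' @return distance in cM.
#' @export
haldane_cm <- function(r) -50 * log(1 - 2 * r)

#' @rdname haldane_cm
#' @param d distance in cM.
#' @export
haldane_r <- function(d) (1 - exp(-d / 50)) / 2

#' Estimate the linkage map for one sex
#'
#' @param om origin matrices from [origin_matrices()] (already restricted
#'   to, or filtered by, `sex`).
#' @param panel the `marker_panel`.
#' @param sex optional: restrict to meioses of this parent sex.
#' @param r_cap cap applied to interval recombination fractions (Haldane is
#'   undefined at r >= 0.5); capped intervals raise a warning.
#' @return a `linkage_map`: data frame with `chrom`, `marker_id`, `pos_bp`,
#'   `cM`, `informative` (meioses informative at the marker pair ending
#'   there, NA for the first marker of a chromosome).
#' @export
estimate_sex_map <- function(om, panel, sex = NULL, r_cap = 0.49) {
  rows <- if (is.null(sex)) seq_len(nrow(om$meta)) else
    which(om$meta$parent_sex == sex)
  if (!length(rows)) stop("no meioses for requested sex")
  out <- list()
  capped <- 0L
  for (ch in names(om$mats)) {
    mat <- om$mats[[ch]][rows, , drop = FALSE]
    idx <- which(panel$chrom == ch)
    pos <- panel$pos_bp[idx]
    ids <- panel$marker_id[idx]
    inf_cols <- which(colSums(!is.na(mat)) > 0)
    if (!length(inf_cols)) {
      warning("chromosome ", ch, " has no informative meioses; omitted")
      next
    }
    J <- length(inf_cols)
    d_cm <- numeric(J)
    n_inf <- rep(NA_real_, J)
    if (J > 1) {
      q <- pos[inf_cols]
      len <- diff(q)
      # informative marker sets differ between meioses (families), so a
      # meiosis's consecutive informative pair may span several union
      # intervals: it contributes coverage to each spanned interval and,
      # when recombinant, recombination mass proportional to physical
      # length (difference-array range updates).
      d_cov <- numeric(J)
      d_dens <- numeric(J)
      sub <- mat[, inf_cols, drop = FALSE]
      for (i in seq_len(nrow(sub))) {
        obs <- which(!is.na(sub[i, ]))
        if (length(obs) < 2) next
        i1 <- obs[-length(obs)]
        i2 <- obs[-1]
        ones <- rep(1, length(i1))
        d_cov[i1] <- d_cov[i1] + ones
        d_cov[i2] <- d_cov[i2] - ones
        rec <- sub[i, i1] != sub[i, i2]
        if (any(rec)) {
          w <- 1 / (q[i2[rec]] - q[i1[rec]])
          d_dens[i1[rec]] <- d_dens[i1[rec]] + w
          d_dens[i2[rec]] <- d_dens[i2[rec]] - w
        }
      }
      ncov <- cumsum(d_cov)[-J]
      rec_mass <- cumsum(d_dens)[-J] * len
      r_hat <- ifelse(ncov > 0, rec_mass / ncov, 0)
      over <- r_hat > r_cap
      capped <- capped + sum(over)
      r_hat[over] <- r_cap
      d_cm[-1] <- haldane_cm(r_hat)
      n_inf[-1] <- ncov
    }
    cm_inf <- cumsum(d_cm)
    # interpolate never-informative markers by physical position
    cm_all <- stats::approx(pos[inf_cols], cm_inf, xout = pos,
                            rule = 2, ties = "ordered")$y
    out[[ch]] <- data.frame(chrom = ch, marker_id = ids, pos_bp = pos,
                            cM = cm_all,
                            informative = {
                              v <- rep(NA_real_, length(pos))
                              v[inf_cols] <- n_inf
                              v
                            },
                            stringsAsFactors = FALSE)
  }
  if (capped > 0)
    warning(capped, " interval(s) with r-hat > ", r_cap, " capped")
  map <- do.call(rbind, out)
  rownames(map) <- NULL
  class(map) <- c("linkage_map", "data.frame")
  map
}

#' Chromosome-level map summary for two sexes
#'
#' Per chromosome and in total: physical length (Mb), male and female map
#' length (cM), female/male ratio and cM/Mb rates.  The totals row uses
#' column sums (rates and ratio recomputed from the totals).
#'
#' @param male_map,female_map `linkage_map` objects covering the same
#'   chromosomes.
#' @param genome a `genome_spec`.
#' @return data frame with one row per chromosome plus a `"Total"` row.
#' @export
map_summary <- function(male_map, female_map, genome) {
  chroms <- genome$chrom
  len_cm <- function(map, ch) {
    x <- map$cM[map$chrom == ch]
    if (!length(x)) NA_real_ else max(x)
  }
  mb <- genome$length_bp / 1e6
  m_cm <- vapply(chroms, function(ch) len_cm(male_map, ch), 0)
  f_cm <- vapply(chroms, function(ch) len_cm(female_map, ch), 0)
  ratio <- ifelse(!is.na(m_cm) & m_cm > 0, f_cm / m_cm, NA_real_)
  out <- data.frame(chrom = chroms, mb = mb, male_cM = m_cm,
                    female_cM = f_cm, fm_ratio = ratio,
                    male_rate = m_cm / mb, female_rate = f_cm / mb,
                    stringsAsFactors = FALSE)
  tot_m <- sum(m_cm, na.rm = TRUE); tot_f <- sum(f_cm, na.rm = TRUE)
  tot_mb <- sum(mb)
  out <- rbind(out, data.frame(
    chrom = "Total", mb = tot_mb, male_cM = tot_m, female_cM = tot_f,
    fm_ratio = if (tot_m > 0) tot_f / tot_m else NA_real_,
    male_rate = tot_m / tot_mb, female_rate = tot_f / tot_mb,
    stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Aggregate a chromosome-level map table into a totals row
#'
#' Utility for published chromosome-level summaries: sums the per-
#' chromosome cM and Mb columns and recomputes the female/male ratio and
#' the cM/Mb rates from the totals.
#'
#' @param tab data frame with columns `length_mb`, `male_cM`, `female_cM`.
#' @return one-row data frame: `male_cM`, `female_cM`, `fm_ratio`,
#'   `male_rate`, `female_rate`.
#' @export
aggregate_map_table <- function(tab) {
  tot_m <- sum(tab$male_cM); tot_f <- sum(tab$female_cM)
  tot_mb <- sum(tab$length_mb)
  data.frame(male_cM = tot_m, female_cM = tot_f, fm_ratio = tot_f / tot_m,
             male_rate = tot_m / tot_mb, female_rate = tot_f / tot_mb)
}

#' Binned cM/Mb recombination rates
#'
#' Markers are assigned to half-open 1 Mb bins by physical position; each
#' bin's rate is the cM difference divided by the Mb difference between the
#' first and last marker inside the bin, missing when the bin holds fewer
#' than 2 markers or spans zero Mb.
#'
#' @param map a `linkage_map`.
#' @param bin_width bin width in bp (default 1e6).
#' @return data frame: `chrom`, `bin_start_bp`, `bin_end_bp`, `n_markers`,
#'   `rate` (cM/Mb or NA).
#' @export
bin_rates <- function(map, bin_width = 1e6) {
  stopifnot(nrow(map) > 0)
  out <- list()
  for (ch in unique(map$chrom)) {
    d <- map[map$chrom == ch, ]
    bin <- floor((d$pos_bp - 1) / bin_width)
    for (b in sort(unique(bin))) {
      sel <- bin == b
      n <- sum(sel)
      rate <- NA_real_
      if (n >= 2) {
        span_mb <- (max(d$pos_bp[sel]) - min(d$pos_bp[sel])) / 1e6
        if (span_mb > 0)
          rate <- (d$cM[sel][which.max(d$pos_bp[sel])] -
                     d$cM[sel][which.min(d$pos_bp[sel])]) / span_mb
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, bin_start_bp = b * bin_width + 1,
        bin_end_bp = (b + 1) * bin_width, n_markers = n, rate = rate,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Relative-position recombination profile
#'
#' For acrocentric chromosomes, maps each 1 Mb bin midpoint to a relative
#' position in [0, 1] with 0 at the centromere and 1 at the telomeric end
#' (the end farther from the centromere), then averages bin rates across
#' chromosomes within `n_bins` equal relative-position bins.
#'
#' @param binned per-sex list or single data frame from [bin_rates()].
#' @param genome a `genome_spec` with `acrocentric` flags.
#' @param n_bins number of relative-position bins (default 40).
#' @return data frame: `rel_mid`, and one mean-rate column per supplied
#'   sex (or `rate` for a single input).
#' @export
relative_profile <- function(binned, genome, n_bins = 40) {
  if (is.data.frame(binned)) binned <- list(rate = binned)
  acro <- genome$chrom[genome$acrocentric]
  breaks <- seq(0, 1, length.out = n_bins + 1)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  out <- data.frame(rel_mid = mids)
  for (nm in names(binned)) {
    d <- binned[[nm]]
    d <- d[d$chrom %in% acro & !is.na(d$rate), ]
    cen <- genome$centromere_bp[match(d$chrom, genome$chrom)]
    len <- genome$length_bp[match(d$chrom, genome$chrom)]
    telo <- ifelse(cen < len / 2, len, 0)
    mid_bp <- (d$bin_start_bp + d$bin_end_bp) / 2
    rel <- (mid_bp - cen) / (telo - cen)
    rel <- pmin(pmax(rel, 0), 1)
    grp <- pmin(findInterval(rel, breaks, rightmost.closed = TRUE), n_bins)
    means <- rep(NA_real_, n_bins)
    agg <- tapply(d$rate, grp, mean)
    means[as.integer(names(agg))] <- agg
    out[[nm]] <- means
  }
  out
}
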