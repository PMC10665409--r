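#' Genome specification
#'
#' A genome specification holds, for each chromosome, its physical length,
#' the centromere position and whether the chromosome is acrocentric.  The
#' physical lengths provide the `L_k` denominators of the intra-chromosomal
#' shuffling statistic (each chromosome's length as a fraction of the total
#' genome length) and the centromere positions anchor relative-position
#' recombination profiles (0 = centromere, 1 = telomeric end).
#'
#' @param chrom character vector of unique chromosome identifiers.
#' @param length_bp positive integer physical lengths in base pairs.
#' @param centromere_bp centromere positions, within `[0, length_bp]`.
#' @param acrocentric logical; centromere effectively at one chromosome end.
#'
#' @return A `genome_spec`: a data frame with one row per chromosome and an
#'   attribute `total_length_bp`.
#' @export
genome_spec <- function(chrom, length_bp, centromere_bp = NULL,
                        acrocentric = NULL) {
  chrom <- as.character(chrom)
  if (anyDuplicated(chrom)) stop("duplicate chromosome ids")
  length_bp <- as.numeric(length_bp)
  if (any(!is.finite(length_bp)) || any(length_bp <= 0))
    stop("chromosome lengths must be positive")
  if (is.null(centromere_bp)) centromere_bp <- rep(0, length(chrom))
  centromere_bp <- as.numeric(centromere_bp)
  if (any(centromere_bp < 0 | centromere_bp > length_bp))
    stop("centromere_bp outside [0, length_bp]")
  if (is.null(acrocentric))
    acrocentric <- centromere_bp <= 0.25 * length_bp |
      centromere_bp >= 0.75 * length_bp
  g <- data.frame(chrom = chrom, length_bp = length_bp,
                  centromere_bp = centromere_bp,
                  acrocentric = as.logical(acrocentric),
                  stringsAsFactors = FALSE)
  attr(g, "total_length_bp") <- sum(length_bp)
  class(g) <- c("genome_spec", "data.frame")
  g
}

#' Total genome length of a genome_spec
#' @param genome a `genome_spec`.
#' @return total physical length in bp.
#' @export
total_length <- function(genome) {
  stopifnot(inherits(genome, "genome_spec"))
  sum(genome$length_bp)
}

#' Read a genome specification from TSV
#'
#' Expects a tab-separated file with header columns `chrom`, `length_bp`,
#' `centromere_bp` and optionally `acrocentric`.
#'
#' @param path file path.
#' @return a `genome_spec`.
#' @export
read_genome <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "length_bp", "centromere_bp")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("genome file is missing required column(s): ",
         paste(miss, collapse = ", "))
  acro <- if ("acrocentric" %in% names(x)) {
    as.logical(x$acrocentric)
  } else NULL
  genome_spec(x$chrom, x$length_bp, x$centromere_bp, acro)
}

#' Bundled Atlantic-salmon-like genome specification
#'
#' 29 chromosomes with the published physical lengths of the Atlantic salmon
#' autosomes (Ssal_v3.1).  Centromere positions are synthetic placements:
#' chromosomes 8-29 are treated as acrocentric with a centromere 2 Mb from
#' the start; chromosomes 1-7 get a mid-chromosome centromere.
#'
#' @return a `genome_spec` with 29 chromosomes.
#' @export
salmon_genome <- function() {
  read_genome(system.file("extdata", "salmon_genome_synthetic.tsv",
                          package = "meiomap", mustWork = TRUE))
}

#' Desk-scale genome for simulation and tests
#'
#' @param n_chrom number of chromosomes.
#' @param length_bp chromosome length (recycled).
#' @param acrocentric logical, recycled; acrocentric chromosomes get the
#'   centromere at position 0, metacentric at the midpoint.
#' @return a `genome_spec`.
#' @export
desk_genome <- function(n_chrom = 5, length_bp = 4e7, acrocentric = TRUE) {
  length_bp <- rep_len(length_bp, n_chrom)
  acrocentric <- rep_len(acrocentric, n_chrom)
  genome_spec(paste0("chr", seq_len(n_chrom)), length_bp,
              ifelse(acrocentric, 0, round(length_bp / 2)), acrocentric)
}

#' Marker panel
#'
#' Ordered biallelic SNP panel.  Markers are sorted by (chromosome, position)
#' in the chromosome order of first appearance; positions are 1-based and
#' unique within a chromosome.
#'
#' @param marker_id character marker names.
#' @param chrom chromosome id per marker.
#' @param pos_bp 1-based physical position.
#' @param a1,a2 allele codes (defaults "A"/"B").  Dosages elsewhere count
#'   copies of `a1`.
#' @return a `marker_panel` data frame.
#' @export
marker_panel <- function(marker_id, chrom, pos_bp, a1 = "A", a2 = "B") {
  chrom <- as.character(chrom)
  p <- data.frame(marker_id = as.character(marker_id), chrom = chrom,
                  pos_bp = as.numeric(pos_bp),
                  a1 = rep_len(as.character(a1), length(marker_id)),
                  a2 = rep_len(as.character(a2), length(marker_id)),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(p$marker_id)) stop("duplicate marker ids")
  ord <- order(match(p$chrom, unique(p$chrom)), p$pos_bp)
  p <- p[ord, , drop = FALSE]
  rownames(p) <- NULL
  if (any(unlist(tapply(p$pos_bp, p$chrom, anyDuplicated)) > 0))
    stop("duplicate marker positions within a chromosome")
  class(p) <- c("marker_panel", "data.frame")
  p
}

#' Evenly spaced marker panel over a genome
#'
#' @param genome a `genome_spec`.
#' @param markers_per_chrom number of markers per chromosome (recycled).
#' @param span fraction of the chromosome covered by the panel; markers run
#'   from position 1 to `span * length_bp`, evenly spaced.
#' @return a `marker_panel`.
#' @export
make_panel <- function(genome, markers_per_chrom = 200, span = 1) {
  m <- rep_len(markers_per_chrom, nrow(genome))
  rows <- lapply(seq_len(nrow(genome)), function(i) {
    pos <- round(seq(1, genome$length_bp[i] * span, length.out = m[i]))
    pos <- unique(pos)
    data.frame(marker_id = sprintf("%s_m%04d", genome$chrom[i],
                                   seq_along(pos)),
               chrom = genome$chrom[i], pos_bp = pos,
               stringsAsFactors = FALSE)
  })
  x <- do.call(rbind, rows)
  marker_panel(x$marker_id, x$chrom, x$pos_bp)
}

# ---- configuration ----------------------------------------------------

#' Default pipeline configuration
#'
#' Every tunable stage parameter with its default.  `read_config()` overlays
#' a YAML file on these defaults and rejects unknown keys so that typos in a
#' config cannot silently fall back to defaults.
#'
#' @return named list of parameters.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    min_offspring = 4L,          # phasing: smallest usable family
    min_support = 3L,            # crossover QC: shortest believable run
    seg_alpha = 0.01,            # segregation-distortion filter p-value
    bin_width = 1e6,             # cM/Mb bin width in bp
    profile_bins = 40L,          # relative-position profile resolution
    rbar_mode = "physical",      # p_k weighting: physical | marker
    gwas_alpha = 0.05,           # Bonferroni family-wise level
    reml_tol = 1e-8,             # |delta logL| convergence tolerance
    reml_maxit = 200L
  )
}

#' Read and validate a YAML pipeline configuration
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return full parameter list (defaults overlaid with the file's values).
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  cfg
}

#' Read genome spec and configuration together
#'
#' @param genome_path genome TSV path.
#' @param config_path YAML config path or `NULL`.
#' @return list with elements `genome` and `config`.
#' @export
read_tables <- function(genome_path, config_path = NULL) {
  list(genome = read_genome(genome_path), config = read_config(config_path))
}
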