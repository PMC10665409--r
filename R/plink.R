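#' @name plink_io
#' @title PLINK genotype file input/output
#'
#' @description
#' Readers and writers for PLINK 1.x text (`.ped`/`.map`) and binary
#' (`.bed`/`.bim`/`.fam`) genotype files.  Genotypes are represented
#' internally as an individuals-by-markers integer matrix of allele dosages
#' counting copies of the A1 allele (`0`, `1`, `2`, `NA` = missing).
#'
#' The binary writer emits the standard SNP-major `.bed` layout: magic bytes
#' `0x6c 0x1b 0x01`, then one block of `ceiling(n/4)` bytes per marker with
#' two bits per individual (`00` = homozygous A1, `01` = missing, `10` =
#' heterozygous, `11` = homozygous A2), trailing slots zero-padded.
#'
#' For the text dialect the `.map` file carries no allele codes, so on
#' reading, A1 is taken as the minor allele of each marker (ties broken by
#' allele code order); supply a `marker_panel` with alleles to fix the
#' coding explicitly.
NULL

.sex_to_plink <- function(sex) {
  c(male = 1L, female = 2L, unknown = 0L)[match(sex, c("male", "female",
                                                       "unknown"))]
}

.sex_from_plink <- function(code) {
  out <- rep("unknown", length(code))
  out[code == 1] <- "male"
  out[code == 2] <- "female"
  out
}

.na0 <- function(x) ifelse(is.na(x) | x == "0" | x == "", NA_character_, x)

#' Write genotypes to PLINK files
#'
#' @param panel a `marker_panel` (alleles used for coding).
#' @param pedigree data frame with columns `id`, `sire`, `dam`, `sex`.
#' @param geno individuals x markers dosage matrix (A1 counts; `NA` missing),
#'   rownames = individual ids, colnames = marker ids.
#' @param prefix output path prefix.
#' @param dialect `"ped_map"` or `"bed_bim_fam"`.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(panel, pedigree, geno, prefix,
                        dialect = c("bed_bim_fam", "ped_map")) {
  dialect <- match.arg(dialect)
  stopifnot(ncol(geno) == nrow(panel))
  stopifnot(nrow(geno) == nrow(pedigree))
  ids <- rownames(geno)
  if (is.null(ids)) ids <- pedigree$id
  ped6 <- data.frame(fid = ids, iid = ids,
                     pat = ifelse(is.na(pedigree$sire), "0", pedigree$sire),
                     mat = ifelse(is.na(pedigree$dam), "0", pedigree$dam),
                     sex = .sex_to_plink(pedigree$sex), pheno = -9L,
                     stringsAsFactors = FALSE)
  if (dialect == "ped_map") {
    mapdf <- data.frame(panel$chrom, panel$marker_id, 0, panel$pos_bp)
    utils::write.table(mapdf, paste0(prefix, ".map"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    n <- nrow(geno)
    alle <- matrix("0", n, 2L * ncol(geno))
    for (j in seq_len(ncol(geno))) {
      d <- geno[, j]
      a <- ifelse(is.na(d), "0", ifelse(d >= 1, panel$a1[j], panel$a2[j]))
      b <- ifelse(is.na(d), "0", ifelse(d == 2, panel$a1[j], panel$a2[j]))
      alle[, 2L * j - 1L] <- a
      alle[, 2L * j] <- b
    }
    out <- cbind(as.matrix(ped6), alle)
    utils::write.table(out, paste0(prefix, ".ped"), sep = " ",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.table(ped6, paste0(prefix, ".fam"), sep = " ",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    bim <- data.frame(panel$chrom, panel$marker_id, 0, panel$pos_bp,
                      panel$a1, panel$a2)
    utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    con <- file(paste0(prefix, ".bed"), "wb")
    on.exit(close(con))
    writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
    n <- nrow(geno)
    nbyte <- ceiling(n / 4)
    # 2-bit code per dosage: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
    code <- matrix(0L, 4L * nbyte, ncol(geno))
    d <- geno
    cd <- ifelse(is.na(d), 1L, ifelse(d == 2, 0L, ifelse(d == 1, 2L, 3L)))
    code[seq_len(n), ] <- cd
    shift <- rep(c(1L, 4L, 16L, 64L), nbyte)
    idx <- rep(seq_len(nbyte), each = 4L)
    bytes <- rowsum(code * shift, idx)
    writeBin(as.raw(as.vector(bytes)), con)
  }
  invisible(prefix)
}

#' Read genotypes from PLINK files
#'
#' @param prefix path prefix (without extension).
#' @param dialect `"ped_map"` or `"bed_bim_fam"`.
#' @param panel optional `marker_panel` providing allele codes for the text
#'   dialect; ignored for the binary dialect (alleles come from `.bim`).
#' @return list with `panel` (marker_panel), `pedigree` (data frame) and
#'   `geno` (dosage matrix).
#' @export
read_plink <- function(prefix, dialect = c("bed_bim_fam", "ped_map"),
                       panel = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "bed_bim_fam") {
    bim <- utils::read.table(paste0(prefix, ".bim"),
                             colClasses = "character")
    names(bim) <- c("chrom", "marker_id", "cm", "pos_bp", "a1", "a2")
    if (anyDuplicated(bim$marker_id))
      stop("duplicate marker id in .bim: ",
           bim$marker_id[anyDuplicated(bim$marker_id)])
    fam <- utils::read.table(paste0(prefix, ".fam"),
                             colClasses = "character")
    names(fam) <- c("fid", "iid", "pat", "mat", "sex", "pheno")
    bedpath <- paste0(prefix, ".bed")
    raw <- readBin(bedpath, "raw", n = file.info(bedpath)$size)
    if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
      stop("not a PLINK bed file (bad magic at byte offset 0): ", bedpath)
    if (raw[3] != as.raw(0x01))
      stop("only SNP-major bed files are supported (byte offset 2)")
    n <- nrow(fam); m <- nrow(bim)
    nbyte <- ceiling(n / 4)
    expected <- 3 + nbyte * m
    if (length(raw) != expected)
      stop(sprintf("truncated or oversized bed payload: %d bytes, expected %d (error at byte offset %d)",
                   length(raw), expected, min(length(raw), expected)))
    body <- as.integer(raw[-(1:3)])
    codes <- matrix(0L, 4L * nbyte, m)
    b <- matrix(body, nbyte, m)
    codes[seq(1, 4 * nbyte, by = 4), ] <- b %% 4L
    codes[seq(2, 4 * nbyte, by = 4), ] <- (b %/% 4L) %% 4L
    codes[seq(3, 4 * nbyte, by = 4), ] <- (b %/% 16L) %% 4L
    codes[seq(4, 4 * nbyte, by = 4), ] <- (b %/% 64L) %% 4L
    codes <- codes[seq_len(n), , drop = FALSE]
    geno <- matrix(NA_integer_, n, m)
    geno[codes == 0L] <- 2L
    geno[codes == 2L] <- 1L
    geno[codes == 3L] <- 0L
    rownames(geno) <- fam$iid
    out_panel <- marker_panel(bim$marker_id, bim$chrom,
                              as.numeric(bim$pos_bp), bim$a1, bim$a2)
  } else {
    mappath <- paste0(prefix, ".map")
    mapdf <- if (file.info(mappath)$size > 0) {
      x <- utils::read.table(mappath, colClasses = "character")
      names(x) <- c("chrom", "marker_id", "cm", "pos_bp")
      x
    } else {
      data.frame(chrom = character(), marker_id = character(),
                 cm = character(), pos_bp = character(),
                 stringsAsFactors = FALSE)
    }
    if (anyDuplicated(mapdf$marker_id))
      stop("duplicate marker id in .map: ",
           mapdf$marker_id[anyDuplicated(mapdf$marker_id)])
    m <- nrow(mapdf)
    pedpath <- paste0(prefix, ".ped")
    lines <- readLines(pedpath)
    fields <- strsplit(trimws(lines), "[ \t]+")
    n <- length(fields)
    bad <- which(vapply(fields, length, 1L) != 6 + 2 * m)
    if (length(bad))
      stop("malformed .ped line ", bad[1], ": expected ", 6 + 2 * m,
           " fields")
    fam <- t(vapply(fields, function(f) f[1:6], character(6)))
    fam <- as.data.frame(fam, stringsAsFactors = FALSE)
    names(fam) <- c("fid", "iid", "pat", "mat", "sex", "pheno")
    geno <- matrix(NA_integer_, n, m)
    a1 <- a2 <- character(m)
    if (m > 0) {
      allemat <- t(vapply(fields, function(f) f[-(1:6)], character(2 * m)))
      for (j in seq_len(m)) {
        x1 <- .na0(allemat[, 2 * j - 1]); x2 <- .na0(allemat[, 2 * j])
        obs <- c(x1, x2)
        if (!is.null(panel)) {
          a1[j] <- panel$a1[match(mapdf$marker_id[j], panel$marker_id)]
          a2[j] <- panel$a2[match(mapdf$marker_id[j], panel$marker_id)]
        } else {
          tab <- sort(table(obs[!is.na(obs)]))
          alle <- names(tab)
          if (length(alle) > 2)
            stop("marker ", mapdf$marker_id[j], " is not biallelic")
          if (length(alle) == 0) alle <- c("A", "B")
          if (length(alle) == 1) alle <- c(alle, setdiff(c("A", "B"),
                                                         alle)[1])
          # minor allele first; ties resolved by code order
          if (length(tab) == 2 && tab[1] == tab[2]) alle <- sort(alle)
          a1[j] <- alle[1]; a2[j] <- alle[2]
        }
        d <- (x1 == a1[j]) + (x2 == a1[j])
        d[is.na(x1) | is.na(x2)] <- NA_integer_
        geno[, j] <- as.integer(d)
      }
    }
    rownames(geno) <- fam$iid
    out_panel <- if (m > 0) {
      marker_panel(mapdf$marker_id, mapdf$chrom, as.numeric(mapdf$pos_bp),
                   a1, a2)
    } else {
      p <- data.frame(marker_id = character(), chrom = character(),
                      pos_bp = numeric(), a1 = character(),
                      a2 = character(), stringsAsFactors = FALSE)
      class(p) <- c("marker_panel", "data.frame")
      p
    }
  }
  geno <- geno[, match(out_panel$marker_id,
                       if (dialect == "bed_bim_fam") bim$marker_id
                       else mapdf$marker_id), drop = FALSE]
  colnames(geno) <- out_panel$marker_id
  pedigree <- data.frame(id = fam$iid, sire = .na0(fam$pat),
                         dam = .na0(fam$mat),
                         sex = .sex_from_plink(as.integer(fam$sex)),
                         stringsAsFactors = FALSE)
  list(panel = out_panel, pedigree = pedigree, geno = geno)
}

#' Genotyping call rate of a dosage matrix
#' @param geno dosage matrix.
#' @return fraction of non-missing calls.
#' @export
call_rate <- function(geno) mean(!is.na(geno))
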