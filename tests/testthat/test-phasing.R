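test_that("families are one per sire-dam pair and match a brute-force scan", {
  ped <- data.frame(
    id = c("S", "D1", "D2", "o1", "o2", "o3"),
    sire = c(NA, NA, NA, "S", "S", "S"),
    dam = c(NA, NA, NA, "D1", "D1", "D2"),
    sex = c("male", "female", "female", rep("unknown", 3)),
    stringsAsFactors = FALSE)
  fams <- build_families(ped, ped$id)
  expect_length(fams, 2)
  expect_setequal(vapply(fams, `[[`, "", "dam"), c("D1", "D2"))
  expect_true(all(vapply(fams, `[[`, "", "sire") == "S"))

  # single trio
  trio <- ped[c(1, 2, 4), ]
  f1 <- build_families(trio, trio$id)
  expect_length(f1, 1)
  expect_equal(f1[[1]]$offspring, "o1")

  # ungenotyped parent excludes the family with a logged reason
  f2 <- build_families(ped, setdiff(ped$id, "D2"))
  expect_length(f2, 1)
  expect_match(attr(f2, "excluded"), "not genotyped")

  # 10 random matings: exhaustive pair enumeration gives the same set
  set.seed(5)
  sires <- sprintf("S%d", 1:4); dams <- sprintf("D%d", 1:4)
  off <- data.frame(id = sprintf("o%02d", 1:10),
                    sire = sample(sires, 10, TRUE),
                    dam = sample(dams, 10, TRUE), sex = "unknown")
  ped2 <- rbind(data.frame(id = c(sires, dams), sire = NA, dam = NA,
                           sex = rep(c("male", "female"), each = 4)), off)
  fams2 <- build_families(ped2, ped2$id)
  brute <- unique(paste(off$sire, off$dam))
  got <- vapply(fams2, function(f) paste(f$sire, f$dam), "")
  expect_setequal(got, brute)
  for (f in fams2)
    expect_setequal(f$offspring,
                    off$id[off$sire == f$sire & off$dam == f$dam])
})

test_that("pedigree cycles are rejected", {
  ped <- data.frame(id = c("a", "b"), sire = c("b", "a"),
                    dam = c(NA, NA), sex = "male")
  expect_error(build_families(ped, ped$id), "cycle")
})

test_that("Mendelian-impossible offspring genotypes are masked", {
  fam <- list(sire = "S", dam = "D", offspring = c("o1", "o2"),
              grandparents = c(sire_sire = NA, sire_dam = NA,
                               dam_sire = NA, dam_dam = NA))
  geno <- rbind(S = c(0L, 1L, 2L), D = c(0L, 1L, 0L),
                o1 = c(2L, 1L, 1L), o2 = c(0L, 2L, 0L))
  res <- mendel_check(fam, geno)
  expect_true(is.na(res$geno["o1", 1]))  # dosage 2 from 0 x 0
  expect_true(is.na(res$geno["o2", 3]))  # dosage 0 from 2 x 0
  expect_false(is.na(res$geno["o2", 2]))
  expect_equal(res$n_flagged, 2L)
  # fully consistent family: zero flags
  ok <- rbind(S = c(1L, 1L), D = c(1L, 0L), o1 = c(2L, 1L),
              o2 = c(0L, 0L))
  expect_equal(mendel_check(list(sire = "S", dam = "D",
                                 offspring = c("o1", "o2")), ok)$n_flagged,
               0L)
})

test_that("flagged error fraction matches the detectable-fraction oracle", {
  # parents homozygous 0 x 0: a symmetric allele flip in an offspring is
  # detectable unless both alleles flip back; detectable probability per
  # genotype is 1 - (1-e)^2 - e^2 (dosage 1 from one flip is invalid,
  # dosage 2 from two flips is also invalid, so detectable = 1-(1-e)^2)
  set.seed(6)
  e <- 0.01
  n_off <- 200; m <- 500
  fam <- list(sire = "S", dam = "D",
              offspring = sprintf("o%03d", 1:n_off))
  geno <- matrix(0L, n_off + 2, m,
                 dimnames = list(c("S", "D", fam$offspring), NULL))
  flips <- matrix(rbinom(n_off * m, 2, e), n_off, m)
  geno[fam$offspring, ] <- flips
  res <- mendel_check(fam, geno)
  p_detect <- 1 - (1 - e)^2
  n <- n_off * m
  expect_lt(abs(res$n_flagged / n - p_detect),
            3 * sqrt(p_detect * (1 - p_detect) / n))
})

test_that("segregation-distortion filter masks distorted markers only", {
  n_each <- c(25, 50, 25)
  off <- sprintf("o%03d", 1:100)
  fam <- list(sire = "S", dam = "D", offspring = off,
              grandparents = c(sire_sire = NA, sire_dam = NA,
                               dam_sire = NA, dam_dam = NA))
  # marker 1: perfect 1:2:1 from het x het; marker 2: all dosage 0
  g <- cbind(c(1L, 1L, rep(0:2, n_each)), c(1L, 1L, rep(0L, 100)))
  rownames(g) <- c("S", "D", off)
  res <- segregation_filter(fam, g, alpha = 0.01)
  expect_true(res$keep[1])
  expect_false(res$keep[2])
  expect_true(all(is.na(res$geno[off, 2])))
  # single offspring: degrees-of-freedom guard keeps the marker
  fam1 <- list(sire = "S", dam = "D", offspring = "o001")
  g1 <- g[c("S", "D", "o001"), , drop = FALSE]
  res1 <- segregation_filter(fam1, g1, alpha = 0.01)
  expect_true(all(res1$keep))
  expect_error(segregation_filter(fam, g, alpha = 1.5), "alpha")
})

test_that("a homozygous parent yields no informative markers", {
  g <- desk_genome(1, 1e6)
  panel <- make_panel(g, 10)
  off <- sprintf("o%d", 1:4)
  geno <- rbind(matrix(0L, 1, 10), matrix(1L, 1, 10),
                matrix(0L, 4, 10))
  rownames(geno) <- c("S", "D", off)
  fam <- list(sire = "S", dam = "D", offspring = off,
              grandparents = c(sire_sire = NA, sire_dam = NA,
                               dam_sire = NA, dam_dam = NA))
  ph <- phase_gametes(fam, geno, panel, "sire")
  expect_equal(length(ph$chrom[[1]]$marker_idx), 0)
})

test_that("greedy chain equals exhaustive minimum-recombination phasing", {
  # random small families (<= 12 informative markers) with realistic
  # crossover counts; the greedy majority-vote chain must reach the
  # global minimum switch count found by enumerating all orientations
  set.seed(20)
  g <- desk_genome(1, 1e7)
  for (rep in 1:15) {
    J <- sample(6:12, 1)
    n_off <- sample(6:10, 1)
    panel <- make_panel(g, J)
    dens <- pl_density(c(0, 1), c(1, 1))
    sire_hap <- rbind(sample(0:1, J, TRUE), NA)
    sire_hap[2, ] <- 1L - sire_hap[1, ]  # heterozygous everywhere
    off <- sprintf("o%d", seq_len(n_off))
    geno <- matrix(0L, n_off + 2, J,
                   dimnames = list(c("S", "D", off), panel$marker_id))
    geno["S", ] <- 1L
    for (o in off) {
      chi <- sample_chiasmata(1e7, dens, 1.2, 1, FALSE)
      geno[o, ] <- meiosis(sire_hap, panel$pos_bp, chi, 1e7)$gamete
    }
    fam <- list(sire = "S", dam = "D", offspring = off,
                grandparents = c(sire_sire = NA, sire_dam = NA,
                                 dam_sire = NA, dam_dam = NA))
    ph <- phase_gametes(fam, geno, panel, "sire", min_offspring = 1)
    blk <- ph$chrom[[1]]
    t_mat <- geno[off, blk$marker_idx, drop = FALSE]  # dam contributes 0
    expect_equal(count_switches(blk$origins),
                 exhaustive_min_switches(t_mat))
  }
})

test_that("phasing is invariant to offspring ordering", {
  set.seed(21)
  g <- desk_genome(2, 1e7)
  panel <- make_panel(g, 40)
  sim <- sim_fully_informative(g, panel, 12, 1, obligate = FALSE)
  fams <- build_families(sim$pedigree, rownames(sim$geno))
  ph1 <- phase_gametes(fams[[1]], sim$geno, panel, "sire")
  fam2 <- fams[[1]]
  perm <- rev(fam2$offspring)
  fam2$offspring <- perm
  ph2 <- phase_gametes(fam2, sim$geno, panel, "sire")
  for (ch in names(ph1$chrom)) {
    o1 <- ph1$chrom[[ch]]$origins
    o2 <- ph2$chrom[[ch]]$origins[match(rownames(ph1$chrom[[ch]]$origins),
                                        perm), , drop = FALSE]
    same <- all(o1 == o2, na.rm = TRUE)
    flipped <- all(o1 == 3L - o2, na.rm = TRUE)
    expect_true(same || flipped)
  }
})

test_that("recovered origin switches localise true crossovers exactly", {
  # zero genotyping error, families of >= 10 offspring: between any two
  # consecutive resolved markers of a meiosis, the origin changes exactly
  # when an odd number of true crossovers lies in the interval
  set.seed(22)
  g <- desk_genome(3, 2e7)
  panel <- make_panel(g, 80)
  sim <- sim_fully_informative(g, panel, 15, 0.8, obligate = FALSE)
  fams <- build_families(sim$pedigree, rownames(sim$geno))
  ph <- phase_gametes(fams[[1]], sim$geno, panel, "sire")
  for (o in seq_along(sim$off_ids)) {
    for (ch in g$chrom) {
      blk <- ph$chrom[[ch]]
      ovec <- blk$origins[sim$off_ids[o], ]
      obs <- which(!is.na(ovec))
      truth_pos <- sim$truth[[o]][[ch]]
      if (length(obs) < 2) next
      for (j in seq_len(length(obs) - 1)) {
        a <- obs[j]; b <- obs[j + 1]
        n_in <- sum(truth_pos > blk$pos_bp[a] & truth_pos < blk$pos_bp[b])
        expect_equal(ovec[a] != ovec[b], n_in %% 2 == 1)
      }
    }
  }
})
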