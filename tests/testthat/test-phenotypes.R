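test_that("crossover detection localises switches and masks short runs", {
  pos <- c(10, 20, 30, 40, 50)
  r <- detect_crossovers(c(1L, 1L, 1L, 2L, 2L), pos, min_support = 1)
  expect_equal(nrow(r$events), 1)
  expect_equal(r$events$left_bp, 30)
  expect_equal(r$events$right_bp, 40)

  # isolated switch removed when min_support = 2
  r2 <- detect_crossovers(c(1L, 2L, 1L), pos[1:3], min_support = 2)
  expect_equal(nrow(r2$events), 0)
  expect_true(is.na(r2$origin[2]))

  # alternating origins, min_support 1: three crossovers
  r3 <- detect_crossovers(c(1L, 2L, 1L, 2L), pos[1:4], min_support = 1)
  expect_equal(nrow(r3$events), 3)
  expect_equal(crossover_count(list(r3$events))$total, 3L)

  expect_error(detect_crossovers(c(1L, 2L), pos[1:2], min_support = 0),
               "min_support")
})

test_that("rbar matches closed forms and is label-flip invariant", {
  g1 <- genome_spec("c1", 1e6, 0)
  pos <- list(c1 = c(1, 4e5, 6e5, 1e6))
  # one crossover with interval midpoint exactly at the chromosome middle
  ov <- c(1L, 1L, 2L, 2L)
  dc <- detect_crossovers(ov, pos$c1, 1)
  sh <- shuffling_rbar(list(c1 = dc$origin), pos, list(c1 = dc$events), g1)
  expect_equal(sh$p_k[["c1"]], 0.5)
  expect_equal(sh$rbar, 0.5)

  # no crossovers anywhere: rbar 0
  dc0 <- detect_crossovers(c(1L, 1L, 1L, 1L), pos$c1, 1)
  sh0 <- shuffling_rbar(list(c1 = dc0$origin), pos, list(c1 = dc0$events),
                        g1)
  expect_equal(sh0$rbar, 0)

  # flipping H1/H2 labels leaves rbar unchanged (2p(1-p) symmetry)
  dcf <- detect_crossovers(3L - ov, pos$c1, 1)
  shf <- shuffling_rbar(list(c1 = dcf$origin), pos, list(c1 = dcf$events),
                        g1)
  expect_equal(shf$rbar, sh$rbar)

  # uncovered chromosome contributes zero and clears the coverage flag
  g2 <- genome_spec(c("c1", "c2"), c(1e6, 1e6), c(0, 0))
  sh2 <- shuffling_rbar(list(c1 = dc$origin,
                             c2 = rep(NA_integer_, 4)),
                        list(c1 = pos$c1, c2 = pos$c1),
                        list(c1 = dc$events,
                             c2 = dc$events[0, ]), g2)
  expect_false(sh2$covered[["c2"]])
  expect_equal(sh2$rbar, 2 * 0.5 * 0.5 * 0.25)
  expect_error(shuffling_rbar(list(cX = ov), pos, list(cX = dc$events),
                              g1), "unknown chromosome")
})

test_that("rbar upper bound holds for random origin vectors", {
  set.seed(30)
  g <- desk_genome(4, c(4e7, 3e7, 2e7, 1e7))
  bound <- sum((g$length_bp / sum(g$length_bp))^2) / 2
  pos <- lapply(g$chrom, function(ch) seq(1, g$length_bp[match(ch, g$chrom)],
                                          length.out = 30))
  names(pos) <- g$chrom
  for (i in 1:25) {
    origins <- list(); events <- list()
    for (ch in g$chrom) {
      ov <- sample(1:2, 30, TRUE)
      dc <- detect_crossovers(as.integer(ov), pos[[ch]], 1)
      origins[[ch]] <- dc$origin; events[[ch]] <- dc$events
    }
    sh <- shuffling_rbar(origins, pos, events, g)
    expect_gte(sh$rbar, 0)
    expect_lte(sh$rbar, bound + 1e-12)
  }
})

test_that("rbar formula agrees with a Monte-Carlo locus-pair oracle", {
  # 50 random gametes; for each, sample 1e5 uniform genome locus pairs and
  # count pairs that fall on the same chromosome with different origins
  set.seed(31)
  g <- desk_genome(3, c(5e7, 4e7, 3e7))
  tot <- sum(g$length_bp)
  cum0 <- c(0, cumsum(g$length_bp))
  n_mark <- 40
  pos <- lapply(seq_len(3), function(k) seq(1, g$length_bp[k],
                                            length.out = n_mark))
  names(pos) <- g$chrom
  for (rep in 1:50) {
    origins <- list(); events <- list(); seg_break <- list()
    for (k in seq_len(3)) {
      ch <- g$chrom[k]
      n_x <- rpois(1, 1.2)
      xpos <- sort(runif(n_x, 1, g$length_bp[k]))
      start <- sample(1:2, 1)
      ov <- as.integer(1 + (start - 1 + findInterval(pos[[ch]], xpos)) %% 2)
      dc <- detect_crossovers(ov, pos[[ch]], 1)
      origins[[ch]] <- dc$origin; events[[ch]] <- dc$events
      seg_break[[ch]] <- if (nrow(dc$events))
        (dc$events$left_bp + dc$events$right_bp) / 2 else numeric(0)
    }
    sh <- shuffling_rbar(origins, pos, events, g)
    # oracle: uniform pairs over the whole genome
    n_pair <- 4e5
    u1 <- runif(n_pair, 0, tot); u2 <- runif(n_pair, 0, tot)
    k1 <- findInterval(u1, cum0, rightmost.closed = TRUE)
    k2 <- findInterval(u2, cum0, rightmost.closed = TRUE)
    same <- k1 == k2
    lab <- function(k, u) {
      x <- u - cum0[k]
      out <- integer(length(k))
      for (kk in unique(k)) {
        ch <- g$chrom[kk]
        sel <- k == kk
        first <- origins[[ch]][which(!is.na(origins[[ch]]))[1]]
        out[sel] <- 1 + (first - 1 +
                           findInterval(x[sel], seg_break[[ch]])) %% 2
      }
      out
    }
    diff_origin <- same
    diff_origin[same] <- lab(k1[same], u1[same]) != lab(k2[same], u2[same])
    expect_lt(abs(mean(diff_origin) - sh$rbar), 0.002)
  }
})

test_that("error-free pipeline reproduces the true crossover count", {
  set.seed(32)
  g <- desk_genome(3, 2e7)
  panel <- make_panel(g, 150)
  sim <- sim_fully_informative(g, panel, 25, 0.8, obligate = FALSE)
  ph <- phase_families(sim$pedigree, sim$geno, panel, min_offspring = 4,
                       seg_alpha = NULL, mendel = FALSE)
  om <- origin_matrices(ph, panel)
  pheno <- gamete_phenotypes(om, g, panel, min_support = 1)
  pheno <- pheno[pheno$parent_sex == "male", ]
  true_cc <- vapply(sim$truth, function(x) sum(lengths(x)), 0L)
  got <- pheno$cc[match(sim$off_ids, pheno$offspring)]
  expect_equal(got, true_cc)
})

test_that("phenotype summaries aggregate per sex and FID", {
  pheno <- data.frame(fid = c("A", "A", "B"),
                      offspring = c("o1", "o2", "o3"),
                      parent_sex = "male",
                      cc = c(2, 4, 6), rbar = c(0.01, 0.02, 0.03),
                      n_chrom_covered = 3)
  s <- phenotype_summary(pheno)
  cc_row <- s[s$trait == "cc" & s$sex == "male", ]
  expect_equal(cc_row$n_fids, 2)
  expect_equal(cc_row$n_obs, 3)
  expect_equal(cc_row$mean, 4)
  expect_equal(cc_row$sd, sd(c(2, 4, 6)))
})
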