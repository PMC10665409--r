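test_that("piecewise-linear density sampling respects its support", {
  set.seed(1)
  dens <- pl_density(c(0, 0.9, 0.95, 1), c(0, 0, 1, 1))
  x <- pl_sample(5000, dens)
  expect_true(all(x >= 0.9 & x <= 1))
  # uniform density inverse-CDF is the identity on quantiles
  u <- pl_density(c(0, 1), c(1, 1))
  expect_equal(mean(pl_sample(20000, u)), 0.5, tolerance = 0.02)
})

test_that("chiasma counts are Poisson with an obligate floor", {
  set.seed(2)
  dens <- pl_density(c(0, 1), c(1, 1))
  # obligate with lambda 0 -> exactly one chiasma
  n1 <- replicate(200, length(sample_chiasmata(1e6, dens, 0, 1, TRUE)))
  expect_true(all(n1 == 1))
  # lambda 2, obligate off: mean within 3 SE of 2
  n2 <- replicate(10000, length(sample_chiasmata(1e6, dens, 2, 1, FALSE)))
  expect_lt(abs(mean(n2) - 2), 3 * sqrt(2 / 10000))
  expect_error(sample_chiasmata(0, dens, 1), "zero-length")
  expect_error(sample_chiasmata(1e6, dens, 1, rate_multiplier = 0),
               "positive")
})

test_that("meiosis transmits chiasmata with probability one half", {
  hap <- rbind(rep(1L, 4), rep(0L, 4))
  pos <- c(10, 20, 30, 40)
  # no chiasmata: gamete is one intact parental haplotype
  set.seed(3)
  res <- meiosis(hap, pos, numeric(0), 100)
  expect_true(all(res$gamete == 1L) || all(res$gamete == 0L))
  expect_length(res$crossovers, 0)

  # exhaustive enumeration over inclusion patterns and start strands for
  # 2 chiasmata: gamete crossover count distributed {0: 1/4, 1: 1/2, 2: 1/4}
  counts <- integer(0)
  for (i1 in c(TRUE, FALSE)) for (i2 in c(TRUE, FALSE))
    for (s in 1:2) {
      r <- meiosis(hap, pos, c(15, 25), 100, include = c(i1, i2),
                   start_strand = s)
      counts <- c(counts, length(r$crossovers))
    }
  expect_equal(as.numeric(table(counts) / length(counts)),
               c(0.25, 0.5, 0.25))

  # one obligate chiasma: transmitted in exactly half the outcomes,
  # which is the origin of the 50 cM minimum map length
  cc1 <- vapply(c(TRUE, FALSE), function(i)
    length(meiosis(hap, pos, 15, 100, include = i,
                   start_strand = 1)$crossovers), 0L)
  expect_equal(mean(cc1), 0.5)
  expect_error(meiosis(hap, pos, 500, 100), "outside")
})

test_that("founder haplotypes are reproducible and match the MAF range", {
  g <- desk_genome(2, 1e6)
  panel <- make_panel(g, 50)
  set.seed(7)
  h1 <- simulate_founder_haplotypes(panel, 20)
  set.seed(7)
  h2 <- simulate_founder_haplotypes(panel, 20)
  expect_identical(h1, h2)
  expect_equal(ncol(h1$haps), nrow(panel))

  # degenerate maf interval: realised frequencies near 0.5 at n = 500
  set.seed(8)
  h <- simulate_founder_haplotypes(panel, 500, c(0.5, 0.5))
  freq <- colMeans(h$haps)
  se <- sqrt(0.25 / 1000)
  expect_lt(abs(mean(freq) - 0.5), 3 * se / sqrt(nrow(panel)))
  expect_true(all(abs(freq - 0.5) < 5 * se))
  expect_error(simulate_founder_haplotypes(panel[0, ], 10), "empty")
})

test_that("calibrated chiasma intensity hits the target crossover count", {
  w <- rep(0.2, 5)
  for (target in c(3, 4, 19.6, 12.1)) {
    lam <- calibrate_lambda(target, w, obligate = TRUE)
    expect_equal(sum(expected_gamete_cc(lam * w, TRUE)), target,
                 tolerance = 1e-6)
  }
  expect_equal(calibrate_lambda(5, w, obligate = FALSE), 10)
  # the obligate rule caps the floor at n_chrom / 2 crossovers
  expect_error(calibrate_lambda(2.5, w, obligate = TRUE), "obligate")
  # without the floor any positive target is reachable
  lam29 <- calibrate_lambda(12.1, rep(1 / 29, 29), obligate = FALSE)
  expect_equal(sum(expected_gamete_cc(lam29 * rep(1 / 29, 29), FALSE)),
               12.1)
})

test_that("population simulation is deterministic with ground truth", {
  g <- desk_genome(3, 2e7)
  panel <- make_panel(g, 60)
  ls <- landscape_model(g, female_cc = 2.4, male_cc = 1.8)
  des <- list(n_sires = 4, n_dams = 4, offspring_per_family = 6,
              grandparents_genotyped = 0.5)
  set.seed(10)
  s1 <- simulate_population(g, panel, ls, design = des)
  set.seed(10)
  s2 <- simulate_population(g, panel, ls, design = des)
  expect_identical(s1$geno, s2$geno)
  expect_identical(s1$truth, s2$truth)
  # one truth row per meiosis: 2 per offspring
  expect_equal(nrow(s1$truth), 2 * 4 * 6)
  # truth CC equals the number of recorded crossover positions
  pos_n <- vapply(s1$truth$positions, function(s)
    sum(lengths(parse_truth_positions(s))), 0L, USE.NAMES = FALSE)
  expect_equal(s1$truth$cc, pos_n)

  # zero trait variance: all rate multipliers equal 1
  arch0 <- trait_architecture(sigma2_a = c(female = 0, male = 0),
                              sigma2_pe = c(female = 0, male = 0))
  set.seed(11)
  s3 <- simulate_population(g, panel, ls, trait_arch = arch0, design = des)
  expect_true(all(s3$breeding_values$multiplier == 1))
})

test_that("realised crossover counts match the analytic expectation", {
  set.seed(12)
  g <- desk_genome(4, 3e7)
  panel <- make_panel(g, 40)
  ls <- landscape_model(g, female_cc = 4, male_cc = 2.5)
  arch0 <- trait_architecture(sigma2_a = c(female = 0, male = 0),
                              sigma2_pe = c(female = 0, male = 0))
  sim <- simulate_population(g, panel, ls, trait_arch = arch0,
                             design = list(n_sires = 10, n_dams = 10,
                                           offspring_per_family = 25,
                                           grandparents_genotyped = 0),
                             error_rate = 0, missing_rate = 0)
  for (sx in c("female", "male")) {
    cc <- sim$truth$cc[sim$truth$parent_sex == sx]
    target <- if (sx == "female") 4 else 2.5
    expect_lt(abs(mean(cc) - target), 3 * sd(cc) / sqrt(length(cc)))
  }
  # crossover positions lie inside the positional density support:
  # male chiasmata only in the distal region of acrocentric chromosomes
  male_pos <- unlist(lapply(
    sim$truth$positions[sim$truth$parent_sex == "male"],
    parse_truth_positions))
  expect_true(all(male_pos > 0.9 * 3e7))
})

test_that("heterochiasmic landscapes shuffle far more in females", {
  # male crossovers confined to the distal 10%, female broad and
  # pericentromere-biased, female:male crossover ratio 1.6
  set.seed(13)
  g <- desk_genome(5, 4e7)
  panel <- make_panel(g, 30)
  ls <- landscape_model(g, female_cc = 4.8, male_cc = 3)
  sim <- simulate_population(g, panel, ls,
                             design = list(n_sires = 12, n_dams = 12,
                                           offspring_per_family = 15,
                                           grandparents_genotyped = 0),
                             error_rate = 0, missing_rate = 0)
  mean_by <- tapply(sim$truth$rbar, sim$truth$parent_sex, mean)
  cc_by <- tapply(sim$truth$cc, sim$truth$parent_sex, mean)
  rbar_ratio <- mean_by["female"] / mean_by["male"]
  cc_ratio <- cc_by["female"] / cc_by["male"]
  expect_gt(rbar_ratio, cc_ratio)
  expect_gt(rbar_ratio, 4)
})
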