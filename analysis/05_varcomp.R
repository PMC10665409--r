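# Stage 5: genomic relationship matrix over the FIDs, method-of-moments
# inbreeding, per-sex AI-REML repeatability models for CC and rbar, and
# genetic/phenotypic correlations (within sex CC-rbar, cross-sex per
# trait).

source("analysis/00_common.R")

pl <- read_plink(file.path(out_dir, "population"), "bed_bim_fam")
pheno <- read.delim(file.path(out_dir, "phenotypes.tsv"),
                    stringsAsFactors = FALSE)

fids <- unique(pheno$fid)
G <- vanraden_grm(pl$geno[fids, , drop = FALSE])
f <- moment_inbreeding(pl$geno[fids, , drop = FALSE])

rows <- list(); cors <- list()
fits <- list()
for (trait in c("cc", "rbar")) {
  for (sx in c("female", "male")) {
    d <- pheno[pheno$parent_sex == sx, ]
    fit <- fit_repeatability(d, G, f, trait = trait)
    fits[[paste(trait, sx)]] <- fit
    rows[[length(rows) + 1L]] <- data.frame(
      trait = trait, sex = sx, n_fids = fit$n_fids, n_obs = fit$n_obs,
      mean = mean(d[[trait]]), sd = sd(d[[trait]]),
      h2 = fit$h2, h2_se = fit$se[["h2"]],
      t = fit$t, t_se = fit$se[["t"]],
      Va = fit$Va, Vpe = fit$Vpe, Ve = fit$Ve, Vp = fit$Vp,
      converged = fit$converged)
    log_line(trait, sx, ": h2 =", round(fit$h2, 3), "(",
             round(fit$se[["h2"]], 3), "), t =", round(fit$t, 3))
  }
  # cross-sex genetic correlation for this trait
  bf <- fit_bivariate(pheno[pheno$parent_sex == "female", ],
                      pheno[pheno$parent_sex == "male", ], G,
                      trait1 = trait)
  cors[[length(cors) + 1L]] <- data.frame(
    pair = paste0(trait, ": female vs male"), type = "genetic",
    r = bf$r_g, se = bf$r_g_se, flagged = bf$floor_flag)
  log_line(trait, "cross-sex r_g =", round(bf$r_g, 3), "(",
           round(bf$r_g_se, 3), ")")
}
# within-sex phenotypic correlations between the two traits
for (sx in c("female", "male"))
  cors[[length(cors) + 1L]] <- data.frame(
    pair = paste0(sx, ": cc vs rbar"), type = "phenotypic",
    r = phenotypic_correlation(pheno[pheno$parent_sex == sx, ]),
    se = NA, flagged = FALSE)

vc <- do.call(rbind, rows)
write.table(vc, file.path(out_dir, "varcomp.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, cors), file.path(out_dir, "correlations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(vc)

# sanity: estimated additive values vs simulated breeding values
bv <- read.delim(file.path(out_dir, "breeding_values.tsv"),
                 stringsAsFactors = FALSE)
log_line("simulated rate multipliers span",
         paste(round(range(bv$multiplier), 3), collapse = " - "))
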