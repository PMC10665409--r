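# Stage 1: simulate a three-generation full-sib population with
# sex-dimorphic crossover landscapes and heritable individual crossover
# rates, and write the genotypes (PLINK binary), pedigree, genome spec and
# per-meiosis ground truth.

source("analysis/00_common.R")

set.seed(seed)
ps <- preset_spec(preset)
panel <- make_panel(ps$genome, ps$markers_per_chrom)
landscape <- landscape_model(ps$genome, female_cc = ps$female_cc,
                             male_cc = ps$male_cc,
                             obligate = ps$obligate)
log_line("chiasma intensity lambda: female",
         round(landscape$lambda["female"], 2), " male",
         round(landscape$lambda["male"], 2))

sim <- simulate_population(ps$genome, panel, landscape,
                           trait_arch = trait_architecture(),
                           design = ps$design,
                           error_rate = 0.001, missing_rate = 0.003)

write_plink(panel, sim$pedigree[match(rownames(sim$geno),
                                      sim$pedigree$id), ],
            sim$geno, file.path(out_dir, "population"), "bed_bim_fam")
write.csv(sim$pedigree, file.path(out_dir, "pedigree.csv"),
          row.names = FALSE)
write.table(sim$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$breeding_values, file.path(out_dir, "breeding_values.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(as.data.frame(ps$genome), file.path(out_dir, "genome.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(yaml::as.yaml(cfg), file.path(out_dir, "config_echo.yaml"))

log_line("individuals genotyped:", nrow(sim$geno),
         " markers:", ncol(sim$geno),
         " call rate:", round(call_rate(sim$geno), 4))
log_line("meioses:", nrow(sim$truth))
log_line("true mean CC: female",
         round(mean(sim$truth$cc[sim$truth$parent_sex == "female"]), 2),
         " male",
         round(mean(sim$truth$cc[sim$truth$parent_sex == "male"]), 2))
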