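# Stage 3: per-meiosis recombination phenotypes (crossover count and
# intra-chromosomal shuffling), with a truth-table comparison on the
# simulated data.

source("analysis/00_common.R")

pl <- read_plink(file.path(out_dir, "population"), "bed_bim_fam")
genome <- read_genome(file.path(out_dir, "genome.tsv"))
tab <- read.delim(file.path(out_dir, "origins.tsv"),
                  stringsAsFactors = FALSE)
om <- origins_from_table(tab, pl$panel)

pheno <- gamete_phenotypes(om, genome, pl$panel,
                           min_support = cfg$min_support,
                           mode = cfg$rbar_mode)
write.table(pheno, file.path(out_dir, "phenotypes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
summ <- phenotype_summary(pheno)
write.table(summ, file.path(out_dir, "phenotype_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(summ)

truth <- read.delim(file.path(out_dir, "truth.tsv"),
                    stringsAsFactors = FALSE)
key <- paste(truth$fid, truth$offspring, truth$parent_sex)
idx <- match(paste(pheno$fid, pheno$offspring, pheno$parent_sex), key)
cc_err <- pheno$cc - truth$cc[idx]
log_line("pipeline CC equals truth CC for",
         round(100 * mean(cc_err == 0, na.rm = TRUE), 1),
         "% of meioses (mean bias", round(mean(cc_err, na.rm = TRUE), 3),
         ")")
log_line("rbar correlation with truth:",
         round(cor(pheno$rbar, truth$rbar[idx], use = "complete"), 3))
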