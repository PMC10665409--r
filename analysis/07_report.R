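# Stage 7: compact report over the stage outputs, next to the published
# Atlantic salmon reference values bundled with the package.

source("analysis/00_common.R")

summ <- read.delim(file.path(out_dir, "phenotype_summary.tsv"))
ms <- read.delim(file.path(out_dir, "map_summary.tsv"))
vc <- read.delim(file.path(out_dir, "varcomp.tsv"))
cors <- read.delim(file.path(out_dir, "correlations.tsv"))

cat("== Per-meiosis phenotypes ==\n")
print(summ, digits = 3)
rb <- summ[summ$trait == "rbar", ]
cc <- summ[summ$trait == "cc", ]
cat(sprintf("female:male CC ratio   %.2f\n",
            cc$mean[cc$sex == "female"] / cc$mean[cc$sex == "male"]))
cat(sprintf("female:male rbar ratio %.2f\n",
            rb$mean[rb$sex == "female"] / rb$mean[rb$sex == "male"]))

cat("\n== Linkage map (totals row) ==\n")
print(ms[ms$chrom == "Total", ], digits = 4)

cat("\n== Variance components ==\n")
print(vc[, c("trait", "sex", "n_fids", "n_obs", "mean", "h2", "h2_se",
             "t", "Vp", "Ve")], digits = 3)

cat("\n== Correlations ==\n")
print(cors, digits = 3)

cat("\n== Published reference (Atlantic salmon breeding population) ==\n")
ref <- aggregate_map_table(salmon_map_table())
cat(sprintf("map totals: male %.2f cM, female %.2f cM, ratio %.2f\n",
            ref$male_cM, ref$female_cM, ref$fm_ratio))
print(salmon_trait_table(), digits = 3)
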