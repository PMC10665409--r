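# Stage 6: weighted leave-one-chromosome-out mixed-model GWAS of mean CC
# and mean rbar per FID, separately by sex, with Bonferroni control.

source("analysis/00_common.R")

pl <- read_plink(file.path(out_dir, "population"), "bed_bim_fam")
pheno <- read.delim(file.path(out_dir, "phenotypes.tsv"),
                    stringsAsFactors = FALSE)
vc <- read.delim(file.path(out_dir, "varcomp.tsv"),
                 stringsAsFactors = FALSE)

all_hits <- list()
for (trait in c("cc", "rbar")) {
  for (sx in c("female", "male")) {
    v <- vc[vc$trait == trait & vc$sex == sx, ]
    d <- pheno[pheno$parent_sex == sx, ]
    means <- collapse_and_weight(d, h2 = v$h2, t = v$t, trait = trait)
    res <- mlma_loco(means, pl$geno, pl$panel, alpha = cfg$gwas_alpha)
    res$trait <- trait; res$sex <- sx
    write.table(res, file.path(out_dir,
                               sprintf("gwas_%s_%s.tsv", trait, sx)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    n_sig <- sum(res$significant, na.rm = TRUE)
    log_line(trait, sx, ": threshold",
             signif(attr(res, "threshold"), 3), ",", n_sig,
             "significant markers, min p",
             signif(min(res$p, na.rm = TRUE), 3))
    top <- res[order(res$p), ][1:5, c("marker_id", "chrom", "pos_bp",
                                      "beta", "se", "p", "trait", "sex")]
    all_hits[[paste(trait, sx)]] <- top
  }
}
write.table(do.call(rbind, all_hits), file.path(out_dir, "gwas_top.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
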