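# Stage 2: build full-sib families from the pedigree and phase the
# gametes each focal parent transmitted, writing the grandparental-origin
# calls as a long TSV.

source("analysis/00_common.R")
set.seed(seed)

pl <- read_plink(file.path(out_dir, "population"), "bed_bim_fam")
ped <- read.csv(file.path(out_dir, "pedigree.csv"),
                stringsAsFactors = FALSE)

t0 <- Sys.time()
phased <- phase_families(ped, pl$geno, pl$panel,
                         min_offspring = cfg$min_offspring,
                         seg_alpha = cfg$seg_alpha)
om <- origin_matrices(phased, pl$panel)
log_line("phased", length(phased), "parent-family combinations,",
         nrow(om$meta), "meioses in",
         round(as.numeric(Sys.time() - t0, units = "secs"), 1), "s")

tab <- origins_to_table(om, pl$panel)
write.table(tab, file.path(out_dir, "origins.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
log_line("origin calls written:", nrow(tab))
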