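# Stage 4: sex-specific Haldane linkage maps, chromosome-level summary,
# 1 Mb cM/Mb landscapes and the relative-position profile over
# acrocentric chromosomes.

source("analysis/00_common.R")

pl <- read_plink(file.path(out_dir, "population"), "bed_bim_fam")
genome <- read_genome(file.path(out_dir, "genome.tsv"))
tab <- read.delim(file.path(out_dir, "origins.tsv"),
                  stringsAsFactors = FALSE)
om <- origins_from_table(tab, pl$panel)
om <- clean_origin_matrices(om, pl$panel, cfg$min_support)

map_m <- estimate_sex_map(om, pl$panel, sex = "male")
map_f <- estimate_sex_map(om, pl$panel, sex = "female")
maps <- merge(map_m[, c("chrom", "marker_id", "pos_bp", "cM")],
              map_f[, c("chrom", "marker_id", "pos_bp", "cM")],
              by = c("chrom", "marker_id", "pos_bp"),
              suffixes = c("_male", "_female"))
maps <- maps[order(match(maps$chrom, genome$chrom), maps$pos_bp), ]
write.table(maps, file.path(out_dir, "linkage_map.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

summ <- map_summary(map_m, map_f, genome)
write.table(summ, file.path(out_dir, "map_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(summ)

bins <- list(male = bin_rates(map_m, cfg$bin_width),
             female = bin_rates(map_f, cfg$bin_width))
for (sx in names(bins))
  write.table(bins[[sx]], file.path(out_dir, paste0("rates_", sx, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
prof <- relative_profile(bins, genome, cfg$profile_bins)
write.table(prof, file.path(out_dir, "relative_profile.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

tot <- summ[summ$chrom == "Total", ]
log_line("map totals: male", round(tot$male_cM, 1), "cM, female",
         round(tot$female_cM, 1), "cM, ratio",
         round(tot$fm_ratio, 2))
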