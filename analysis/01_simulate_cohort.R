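#!/usr/bin/env Rscript
# Build the synthetic study cohort with known ground truth: an 8-founder SNP
# panel, 50 recombinant inbred strain genomes, per-animal echo records with a
# planted LVD QTL, a rupture-survival log driven by a second QTL, and an
# annotated variant table for candidate prioritization. All downstream
# drivers read the files written here.

suppressMessages(library(ccmiqtl))
dir.create("results", showWarnings = FALSE)

panel <- simulate_founders(n_snps_per_chrom = 150, n_chroms = 2, seed = 101)
cohort <- simulate_cc_cohort(panel, n_strains = 50,
                             expected_breakpoints_per_chrom = 3,
                             genotype_error_rate = 0.002, seed = 102)
write_genotype_tsv(panel, cohort$genotypes, "results/genotypes.tsv")

# the LVSD/HF phenotype (concordant delta-EF and LVD) is driven by a
# PWK-effect QTL in the middle of chr1 at h2 = 0.5; rupture survival by a
# CAST-effect QTL on chr2
pos1 <- panel$map$pos[panel$map$chrom == "chr1"]
pos2 <- panel$map$pos[panel$map$chrom == "chr2"]
qtl_lvd <- qtl_spec("chr1", pos1[75], effects = c(0, 0, 0, 0, 0, 0, 2.5, 0),
                    h2 = 0.5, trait = "both")
qtl_rupture <- qtl_spec("chr2", pos2[75],
                        effects = c(0, 0, 0, 0, 0, -2, 0, 0), h2 = 0)

records <- simulate_cohort_traits(cohort, qtl = qtl_lvd,
                                  n_animals_per_strain = 6, seed = 103)
write.csv(records, "results/echo_records.csv", row.names = FALSE)

survival <- simulate_survival_log(cohort, base_prob = 0.25,
                                  qtl = qtl_rupture,
                                  n_animals_per_strain = 6, seed = 104)
write.csv(survival, "results/survival_log.csv", row.names = FALSE)

# annotated variants around the LVD QTL: one missense SNP private to the
# conferring founder (G = PWK), plus shared and benign neighbours
mkvar <- function(id, pos, cons, alleles, sift) {
  v <- data.frame(snp_id = id, chrom = "chr1", pos = pos,
                  consequence = cons, sift = sift)
  v[names(cc_founders)] <- as.list(alleles)
  v
}
variants <- rbind(
  mkvar("rs_causal_missense", pos1[75] + 2e3, "missense_variant",
        c(0, 0, 0, 0, 0, 0, 1, 0), 0.01),
  mkvar("rs_shared_missense", pos1[74], "missense_variant",
        c(0, 1, 0, 0, 0, 1, 1, 0), 0.03),
  mkvar("rs_private_synonymous", pos1[76], "synonymous_variant",
        c(0, 0, 0, 0, 0, 0, 1, 0), NA),
  mkvar("rs_tolerated_missense", pos1[73], "missense_variant",
        c(0, 0, 0, 0, 0, 0, 1, 0), 0.64),
  mkvar("rs_distal", pos1[10], "missense_variant",
        c(0, 0, 0, 0, 0, 0, 1, 0), 0.01)
)
write.table(variants, "results/variants.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- attr(records, "truth")
write_truth_json(list(
  qtl_lvd = unclass(qtl_lvd), qtl_rupture = unclass(qtl_rupture),
  strain_id = truth$strain_id, strain_LVD = truth$strain_LVD,
  strain_delta_EF = truth$strain_delta_EF,
  rupture_prob = attr(survival, "truth")$rupture_prob
), "results/cohort_truth.json")

message("Cohort: 50 strains x 6 animals, 300 SNPs on 2 chromosomes")
message("Planted LVD QTL: chr1:", pos1[75], " (founder G, h2 = 0.5)")
message("Planted rupture QTL: chr2:", pos2[75], " (founder F protective)")
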