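#!/usr/bin/env Rscript
# Quantify scar structure on synthetic polarized/brightfield image pairs for
# eight strains spanning weak to strong fiber alignment: collagen area
# fraction, fiber orientation field, per-sample circular summaries, and the
# per-strain group alignment t-test. Wall thickness is measured on synthetic
# serial-section stacks.

suppressMessages(library(ccmiqtl))
dir.create("results", showWarnings = FALSE)

# strain-level alignment truth: two strongly aligned strains (as observed for
# the well-aligned strains), the rest weakly concentrated with scattered
# orientations
strains <- data.frame(
  strain_id = sprintf("CC%03d", 1:8),
  mu = c(5, 170, 40, 90, 120, 60, 20, 150),
  kappa = c(8, 8, 1, 1, 0.5, 1, 0.5, 1)
)
n_samples <- 4

per_sample <- list()
per_strain <- list()
set.seed(301)
for (i in seq_len(nrow(strains))) {
  summaries <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    # per-sample mean orientation scatters around the strain mean only for
    # weakly aligned strains
    mu_s <- if (strains$kappa[i] >= 4) strains$mu[i]
            else (strains$mu[i] + rnorm(1, 0, 40)) %% 180
    tr <- fiber_truth(mu = mu_s, kappa = strains$kappa[i], fiber_density = 4)
    pair <- simulate_scar_image_pair(tr, c(256, 256), noise_sd = 0.02,
                                     seed = 301 + 10 * i + s)
    res <- analyze_scar_pair(pair)
    # synthetic serial-section stack: tissue span proportional to a
    # strain-specific wall thickness between ~100 and ~250 um
    n_tissue <- round((100 + 20 * i) / 7)
    stack <- c(rep(FALSE, 3), rep(TRUE, n_tissue + 1), rep(FALSE, 3))
    summaries[[s]] <- res$summary
    per_sample[[length(per_sample) + 1]] <- data.frame(
      strain_id = strains$strain_id[i], sample = s,
      area_fraction = res$area_fraction,
      theta_m = res$summary$theta_m, MVL = res$summary$MVL,
      wall_thickness_um = wall_thickness(stack),
      n_midwall_sections = length(select_midwall(stack))
    )
  }
  at <- alignment_significance(summaries)
  per_strain[[i]] <- data.frame(
    strain_id = strains$strain_id[i], true_mu = strains$mu[i],
    true_kappa = strains$kappa[i], group_theta_m = at$theta_m,
    t = at$t, df = at$df, p_value = at$p_value
  )
}

sample_tab <- do.call(rbind, per_sample)
strain_tab <- do.call(rbind, per_strain)
write.table(sample_tab, "results/scar_samples.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(strain_tab, "results/scar_alignment_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("Collagen area fraction: %.2f to %.2f across samples",
                min(sample_tab$area_fraction), max(sample_tab$area_fraction)))
sig <- strain_tab$strain_id[strain_tab$p_value < 0.05]
message("Strains with significant group alignment (p < 0.05): ",
        paste(sig, collapse = ", "))
message("(planted strongly aligned strains: CC001, CC002)")
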