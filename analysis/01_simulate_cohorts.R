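#!/usr/bin/env Rscript
# Generate the three synthetic study cohorts (binary drug response, 3-subtype
# lymphoma plus a covariate-shifted sibling, skewed IC50 regression) and
# write them as TSV + JSON sidecars under results/data/. Downstream drivers
# regenerate from the same specs, so these files are for inspection and
# external reuse, not a hidden dependency.

library(conformalgx)

out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 20260101L

binary <- generate_classification(spec_infliximab_cohort(seed = seed))
# one double-size draw; the second half becomes the covariate-shifted
# sibling cohort (same class-conditional population, fresh samples)
big <- generate_classification(spec_lymphoma_cohort(seed = seed + 1L,
                                                    n_samples = 2064))
lymphoma <- subset_dataset(big, samples = 1:1032)
external <- apply_shift(
  subset_dataset(big, samples = 1033:2064),
  shift_spec(mean_shift = 0.15, scale_factor = 1.08,
             fraction_shifted_features = 0.3, seed = seed))
ic50 <- generate_regression(spec_ic50_cohort(seed = seed + 3L))

write_dataset(binary, file.path(out_dir, "binary_response.tsv"))
write_dataset(lymphoma, file.path(out_dir, "lymphoma_subtypes.tsv"))
write_dataset(external, file.path(out_dir, "lymphoma_external_shifted.tsv"))
write_dataset(ic50, file.path(out_dir, "ic50_response.tsv"))

cat("binary cohort:   ", n_samples(binary), "samples;",
    paste(capture.output(print(table(binary$labels))), collapse = " "), "\n")
cat("lymphoma cohort: ", n_samples(lymphoma), "samples;",
    paste(names(table(lymphoma$labels)), table(lymphoma$labels),
          collapse = ", "), "\n")
cat("external cohort: ", n_samples(external),
    "samples (mean shift 0.15 / scale 1.08 on 30% of the features)\n")
cat(sprintf("ic50 cohort:      %d samples; response range [%.5g, %.5g]\n",
            n_samples(ic50), min(ic50$labels), max(ic50$labels)))

# sanity: the unshifted cohorts look exchangeable, the concatenation of the
# internal and shifted external cohorts does not (sequential split)
p_iid <- exchangeability_check(lymphoma, n_splits = 5, seed = seed)
both <- labeled_dataset(rbind(lymphoma$features, external$features),
                        c(lymphoma$labels, external$labels),
                        sample_ids = c(lymphoma$sample_ids,
                                       paste0("EXT_", external$sample_ids)))
p_seq <- exchangeability_check(both, seed = seed, split = "sequential")
cat(sprintf("exchangeability diagnostic: internal median p = %.3f, internal+external sequential p = %.3f\n",
            as.numeric(p_iid), as.numeric(p_seq)))
cat("wrote cohorts under", out_dir, "\n")
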