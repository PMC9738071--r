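#!/usr/bin/env Rscript
# Step 1: build the synthetic study material.
#
# The clinical radiographs behind the corticalization analysis are available
# only on request, so the workflow runs on simulated material with the same
# structure: standardized 476 x 620 intraoral frames (70 um/px) carrying an
# implant silhouette, a corticalized peri-implant collar and a distant
# reference ROI (1500 px each), plus a longitudinal cohort of 500 implants
# whose CI and MBL marginals, zero-inflated bone-loss structure and weak
# positive CI-MBL coupling follow the published cohort-level summaries.

suppressPackageStartupMessages(library(cortindex))

out <- "results/simulated"
files <- run_simulate(run_config(seed = 20260917L, n_frames = 4,
                                 n_implants = 500, output_dir = out))

cohort <- read_cohort_table(file.path(out, "cohort.csv"))
cat(sprintf("wrote %d files to %s\n", length(files), out))
cat(sprintf("cohort: %d implants; CI means %.0f / %.0f / %.0f; MBL zero fractions %.2f / %.2f / %.2f\n",
            nrow(cohort),
            mean(cohort$ci_initial), mean(cohort$ci_y5), mean(cohort$ci_y10),
            mean(cohort$mbl_initial == 0), mean(cohort$mbl_y5 == 0),
            mean(cohort$mbl_y10 == 0)))
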