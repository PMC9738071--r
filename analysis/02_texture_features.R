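#!/usr/bin/env Rscript
# Step 2: texture features and corticalization index per ROI.
#
# Every frame in results/simulated is normalized (mu +/- 3 sigma), quantized
# to 6 bits and measured: mean optical density, difference entropy and
# long-run emphasis averaged over the four standard directions at a pair
# spacing of 5 px, combined into CI = mean_od * LngREmph / DifEntr.
# The peri-implant collar should score a higher CI than the distant
# trabecular reference — the direction the clinical study reports.

suppressPackageStartupMessages(library(cortindex))

run_analyze(run_config(seed = 20260917L, input_dir = "results/simulated",
                       output_dir = "results"))
feats <- read_feature_table("results/features.csv")

cat(sprintf("analyzed %d ROIs from %d frames\n", nrow(feats),
            nrow(feats) / 2L))
for (lab in c("peri_implant", "reference")) {
  f <- feats[feats$label == lab, ]
  cat(sprintf("  %-12s median CI %6.1f  (DifEntr %.3f, LngREmph %.3f, mean OD %.1f)\n",
              lab, median(f$ci), median(f$difentr_avg),
              median(f$lngremph_avg), median(f$mean_od)))
}
stopifnot(median(feats$ci[feats$label == "peri_implant"]) >
            median(feats$ci[feats$label == "reference"]))
cat("peri-implant CI exceeds reference CI, as expected for corticalized bone\n")
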