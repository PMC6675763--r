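#!/usr/bin/env Rscript
# Runs the whole analysis chain (simulate -> code -> sequences -> profiles ->
# features -> segmentation models). Each stage reads only what earlier stages
# wrote under results/.

stages <- c("01_simulate.R", "02_code_shifts.R", "03_detect_sequences.R",
            "04_profile_shapes.R", "05_video_features.R",
            "06_segmentation_models.R")
for (s in stages) {
  cat("\n==", s, "==\n")
  status <- system2("Rscript", file.path("analysis", s))
  if (status != 0) stop("stage failed: ", s)
}
cat("\nall stages complete; outputs under results/\n")
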