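#!/usr/bin/env Rscript
# Runs the whole workflow in order (simulate -> preprocess -> features ->
# forecast -> evaluate), each stage in its own R process so that the bulky
# signal stages release their memory. Roughly 5 min on one CPU.
stages <- sprintf("analysis/0%d_%s.R", 1:5,
                  c("simulate", "preprocess", "features", "forecast",
                    "evaluate"))
for (s in stages) {
  cat("\n=== ", s, " ===\n")
  status <- system2("Rscript", s)
  if (status != 0) stop(sprintf("stage %s failed (exit %d)", s, status))
}
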