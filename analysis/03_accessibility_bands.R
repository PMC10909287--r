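#!/usr/bin/env Rscript
# Static population accessibility by travel-time band and urban class
# (the national accessibility table of the analysis).

library(dynaccess)

res <- run_pipeline(pipeline_config())
write.csv(res$band_summary, "results/03_band_summary.csv", row.names = FALSE)
print(as.data.frame(res$band_summary), row.names = FALSE)

tot <- res$band_summary[res$band_summary$class == "Total", ]
cat(sprintf("\n%.1f%% of the synthetic population lives within 10 min of an ED; %.1f%% within 30 min.\n",
            tot$share_pct[tot$band == "0-10"],
            sum(tot$share_pct[tot$band %in% c("0-10", "10-20", "20-30")])))
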