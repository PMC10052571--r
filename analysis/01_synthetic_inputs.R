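#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study inputs: per-cultivar phytomer
# descriptor tables, light-response parameter sets with noisy A-Q
# observations, and a 60-day post-silking hourly weather series.
#
# Writes: results/inputs/{phytomer_tables,light_response_params,
#         aq_observations,weather_hourly}.csv

library(maizecanopy)

seed <- 1L
out <- "results/inputs"
paths <- generate_all_inputs(out, seed = seed, doys = 228:287)

plants <- read_phytomer_table(file.path(out, "phytomer_tables.csv"))
cat("Generated cultivars:", paste(names(plants), collapse = ", "), "\n")
for (cv in c("JNK728", "J2416", "JMC01")) {
  pl <- plants[[cv]]
  area <- sum(vapply(pl$phytomers, function(p)
    blade_area(p$LL, p$max_width), numeric(1))) * 1e-4
  hdbtop <- vapply(pl$phytomers, function(p) p$HDBTop, numeric(1))
  cat(sprintf(
    "  %-7s height %6.1f cm, ear rank %2d, leaf area %.2f m2, HDBTop peak %5.2f cm at rank %d\n",
    cv, pl$plant_height, pl$ear_rank, area, max(hdbtop),
    which.max(hdbtop)))
}
wx <- read.csv(file.path(out, "weather_hourly.csv"))
dp <- daily_par_totals(wx)
cat(sprintf("Weather: %d days, mean daily PAR %.1f MJ m-2 (clear-sky sinusoid, noon peak %.0f umol m-2 s-1)\n",
            nrow(dp), mean(dp$PAR_MJ_m2), max(wx$PAR_total)))
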