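#!/usr/bin/env Rscript
# Calibration surfaces of the single MSN cell: the f-I curve over the
# network drive window, rheobase, first-spike latency, and the single-spike
# IPSP amplitude across the inhibition range.  Writes results/fI_curve.csv
# and results/ipsp_curve.csv.

library(msnet)
dir.create("results", showWarnings = FALSE)

drives <- seq(0.001305, 0.001325, length.out = 11)
fi <- fI_curve(drives = drives, duration = 10)
write_features(fi, "results/fI_curve.csv")
rb <- rheobase()
cat(sprintf("rheobase: %.6f drive units (base drive 0.001305 sits %.1f%% above)\n",
            rb, 100 * (0.001305 / rb - 1)))
cat(sprintf("rate at maximum drive: %.2f Hz; latency %0.f ms -> %0.f ms across the window\n",
            fi$rate[nrow(fi)], fi$latency[1], fi$latency[nrow(fi)]))

gis <- c(0.002, 0.004, 0.006, 0.008, 0.010, 0.011, 0.015, 0.02)
ip <- data.frame(g_i = gis, peak_mv = vapply(gis, ipsp_peak, numeric(1)))
write_features(ip, "results/ipsp_curve.csv")
cat("single-spike IPSP peaks (mV):\n")
print(ip, row.names = FALSE)
cat("physiological range 0.25-0.6 mV corresponds to G_I between roughly",
    "0.006 and 0.01 on this curve.\n")

tr <- simulate_cell(drive = 0.001305 + 1.5e-5, duration = 10, record = TRUE,
                    thin = 400L)   # 10 ms trace resolution keeps the file small
write_voltage_trace(tr, "results/example_trace.tsv")
cat(sprintf("example trace at G_E = 1.5e-5: first spike after %.2f s, %d spikes in 10 s\n",
            tr$latency / 1000, length(tr$spikes)))
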