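#!/usr/bin/env Rscript
# Long-latency-reflex extension: a constant 50% GC activation in a 100-ms
# window starting 100 ms after tilt onset, added to the MPC command.
# Compares the 10-Hz-filtered GC traces with and without the reflex term.
suppressPackageStartupMessages(library(posturempc))
dir.create("results", showWarnings = FALSE)

tr_on <- run_trial(scenario(llr = llr_config(TRUE)), seed = 5)
tr_off <- run_trial(scenario(), seed = 5)
g_on <- gc_display(tr_on)
g_off <- gc_display(tr_off)
out <- data.frame(t = g_on$t, gc_llr = g_on$gc_pct, gc_mpc = g_off$gc_pct,
                  com_llr = tr_on$series$com_mm,
                  com_mpc = tr_off$series$com_mm)
write.csv(out[seq(1, nrow(out), by = 10), ], "results/llr_traces.csv",
          row.names = FALSE)

lat <- first_peak_latency(g_on$gc_pct, g_on$t, onset = 15,
                          prominence = 5, baseline_window = 1)
win <- g_on$t >= 15.1 & g_on$t < 15.2
cat(sprintf("LLR run: fell = %s; first GC peak %.0f ms after tilt onset\n",
            tr_on$fell, lat))
cat(sprintf("peak GC in the reflex window: %.1f%% (LLR) vs %.1f%% (MPC only)\n",
            max(g_on$gc_pct[win]), max(g_off$gc_pct[win])))
cat("The reflex term produces an impulse-like GC burst that plain\n")
cat("predictive control does not, while the trial remains stable.\n")
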