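#!/usr/bin/env Rscript
# Step 3: ratiometric image analysis of the synthetic BRET time-lapse.
#
# Pipeline: cosmic-ray removal -> median denoising -> background
# subtraction -> yellow/cyan ratio -> IMD rendering -> per-cell traces
# normalized to baseline. Also demonstrates that a substrate decay
# common to both channels leaves the ratio traces unchanged.
# Reads results/inputs/ (run 01 first); writes results/imaging/*

suppressMessages(library(hybret))
inp <- "results/inputs"
out <- "results/imaging"
stopifnot(dir.exists(inp))
dir.create(out, recursive = TRUE, showWarnings = FALSE)

stack <- read_stack(file.path(inp, c("stack_cyan.tif", "stack_yellow.tif")),
                    layout = "separate")
lab_df <- utils::read.csv(file.path(inp, "stack_labels.csv"))
labels <- matrix(0L, dim(stack$cyan)[1], dim(stack$cyan)[2])
labels[cbind(lab_df$row, lab_df$col)] <- lab_df$cell_id
truth <- utils::read.csv(file.path(inp, "stack_truth.csv"))

st <- preprocess_stack(stack, spike_z = 8, filter_radius = 1)
st <- compute_ratio(st, min_denominator = 50)
st$labels <- labels
cat(sprintf("background estimates (cyan, frame 1): %.0f counts\n",
            st$background$cyan[1]))

imd <- render_imd(st, r_min = 0.35, r_max = 0.65)
write_imd(imd, file.path(out, "imd_frame1.png"), frame = 1)

tr <- cell_traces(st)
tr$normalized_ratio <- NA_real_
for (id in unique(tr$cell_id)) {
  sel <- tr$cell_id == id
  tr$normalized_ratio[sel] <- normalize_timecourse(tr$ratio[sel], 1:3)
}
utils::write.csv(tr, file.path(out, "cell_traces.csv"), row.names = FALSE)

est <- as.numeric(tapply(tr$ratio, tr$cell_id, mean))
cmp <- data.frame(cell_id = truth$cell_id, true = truth$true_ratio,
                  estimated = est,
                  rel_error = (est - truth$true_ratio) / truth$true_ratio)
utils::write.csv(cmp, file.path(out, "ratio_recovery.csv"),
                 row.names = FALSE)
cat("per-cell ratio recovery:\n")
print(cmp, digits = 3)
cat(sprintf("max |relative error| = %.3g (substrate half-life 9 min)\n",
            max(abs(cmp$rel_error))))

## Decay-robustness demonstration on a noise-free twin stack: scaling
## both channels by a common exponential decay moves no ratio trace.
g <- gen_ratio_stack(n_cells = 5, T = 10, noise = "none", spike_rate = 0,
                     background = 0, half_life_min = Inf, seed = 99)
tr0 <- cell_traces(compute_ratio(g$stack, min_denominator = 1))
decay <- 0.5^((seq_len(10) - 1) / 9)
cy <- g$stack$cyan; ye <- g$stack$yellow
for (t in 1:10) {
  cy[, , t] <- cy[, , t] * decay[t]; ye[, , t] <- ye[, , t] * decay[t]
}
tr1 <- cell_traces(compute_ratio(ratio_stack(cy, ye,
                                             labels = g$stack$labels),
                                 min_denominator = 0))
cat(sprintf(
  "ratio deviation under common 9-min decay: max %.2e (machine precision)\n",
  max(abs(tr1$ratio - tr0$ratio))))

write_manifest(run_manifest(
  r_min = 0.35, r_max = 0.65, min_denominator = 50, spike_z = 8,
  filter_radius = 1,
  inputs = file.path(inp, c("stack_cyan.tif", "stack_yellow.tif"))),
  file.path(out, "imaging.manifest.json"))
cat("wrote", out, "\n")
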