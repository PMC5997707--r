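#!/usr/bin/env Rscript
# Step 1: generate the synthetic study inputs with recorded ground truth.
#
# The raw spectra, image stacks and plate tables of the original screens
# are not publicly deposited, so every downstream step runs on seeded
# synthetic stand-ins whose generating truth is written alongside them.
# Outputs (results/inputs/): emission-spectrum CSVs, dual-channel TIFF
# stacks, a dose-response plate CSV, and JSON manifests.

suppressMessages(library(hybret))

seed <- 20260929L
out <- "results/inputs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

prof <- read_photophysics()
basis <- default_basis(prof)

cat("== Simulating study inputs (seed", seed, ") ==\n")

## Fluorescence spectra at the pre-/post-stimulation FRET efficiencies,
## and a bioluminescence spectrum with no direct luciferase-to-YFP route.
specs <- list(
  fret_pre  = list(truth = transfer_params(E_CY = 0.29),
                   mode = "fluorescence", s = seed + 1L),
  fret_post = list(truth = transfer_params(E_CY = 0.44),
                   mode = "fluorescence", s = seed + 2L),
  bret_pre  = list(truth = transfer_params(E_CY = 0.29, E_RC = 0.13),
                   mode = "bioluminescence", s = seed + 3L),
  bret_post = list(truth = transfer_params(E_CY = 0.44, E_RC = 0.13),
                   mode = "bioluminescence", s = seed + 4L))
for (nm in names(specs)) {
  cfg <- specs[[nm]]
  sim <- gen_biosensor_spectrum(basis, cfg$truth, cfg$mode,
                                noise = "poisson", peak_counts = 1e4,
                                seed = cfg$s)
  write_spectrum(sim$spectrum, file.path(out, paste0(nm, ".csv")))
  write_manifest(run_manifest(truth = sim$truth),
                 file.path(out, paste0(nm, ".manifest.json")))
  cat(sprintf("  %-10s E_CY=%.2f E_RC=%.2f -> %s.csv\n",
              nm, cfg$truth$E_CY, cfg$truth$E_RC, nm))
}

## Time-lapse BRET stack: 5 cells, ratios in the in vivo 0.35-0.65 band,
## 9-minute substrate half-life, photon noise, cosmic-ray spikes.
g <- gen_ratio_stack(n_cells = 5, T = 10, ratio_range = c(0.35, 0.65),
                     half_life_min = 9, spike_rate = 5e-4,
                     noise = "poisson", seed = seed + 10L)
write_stack(g$stack, file.path(out, "stack_cyan.tif"),
            file.path(out, "stack_yellow.tif"))
utils::write.csv(data.frame(cell_id = seq_along(g$truth$ratio),
                            true_ratio = g$truth$ratio),
                 file.path(out, "stack_truth.csv"), row.names = FALSE)
utils::write.csv(data.frame(which(g$truth$labels > 0, arr.ind = TRUE),
                            cell_id = g$truth$labels[g$truth$labels > 0]),
                 file.path(out, "stack_labels.csv"), row.names = FALSE)
write_manifest(run_manifest(
  truth = g$truth[c("ratio", "background", "half_life_min", "seed")]),
  file.path(out, "stack.manifest.json"))
cat(sprintf("  image stack: 5 cells, true ratios %s\n",
            paste(sprintf("%.3f", g$truth$ratio), collapse = " ")))

## Dose-response plate from the coupled ERK / live-cell model.
gp <- gen_plate(cv = 0.02, replicates = 4, seed = seed + 20L)
write_plate(gp$plate, file.path(out, "plate.csv"))
write_manifest(run_manifest(truth = gp$truth),
               file.path(out, "plate.manifest.json"))
cat(sprintf("  plate: %d wells, true IC50_ERK=%.3f IC50_L=%.3f uM\n",
            nrow(gp$plate), gp$truth$erk_params$IC50,
            gp$truth$live_params$IC50))

## Two-group Z' validation plate.
zp <- gen_zprime_plate(seed = seed + 30L)
utils::write.csv(data.frame(
  well_id = sprintf("Z%02d", seq_len(6)),
  condition = rep(c("untreated", "treated"), each = 3),
  dose = rep(c(0, 1), each = 3),
  ratio = c(zp$neg, zp$pos)),
  file.path(out, "zprime_plate.csv"), row.names = FALSE)
cat("  Z' plate: 3 + 3 wells\n")
cat("done; inputs under", out, "\n")
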