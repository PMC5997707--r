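#!/usr/bin/env Rscript
# Step 4: luminescence microplate analytics.
#
# (a) Z' factor of the two-group validation plate; (b) independent Hill
# fits of the ERK (BRET ratio) and live-cell (total counts) dose-response
# curves; (c) the coupled fit recovering both IC50s and Hill
# coefficients, plus the predicted live-vs-ERK correlation line.
# Reads results/inputs/ (run 01 first); writes results/plate/*

suppressMessages(library(hybret))
inp <- "results/inputs"
out <- "results/plate"
stopifnot(dir.exists(inp))
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## Z' factor
zp <- utils::read.csv(file.path(inp, "zprime_plate.csv"))
z <- zprime(zp$ratio[zp$condition == "untreated"],
            zp$ratio[zp$condition == "treated"])
cat(sprintf("Z' = %.3f (3 wells per group) -> %s for screening\n", z,
            if (z > 0.5) "suitable" else "not suitable"))

## Dose-response fits
plate <- read_plate(file.path(inp, "plate.csv"))
fx <- list(min_ERK = 0.30, amp_ERK = 0.30, min_L = 1000, amp_L = 9000)

erk_hill <- hill_fit(plate$dose, plate$bret_ratio,
                     fixed = list(min = fx$min_ERK, amp = fx$amp_ERK))
live_hill <- hill_fit(plate$dose, plate$total,
                      fixed = list(min = fx$min_L, amp = fx$amp_L))
cat(sprintf("ERK activity:  IC50 = %.4f uM, nH = %.2f\n",
            erk_hill$params$IC50, erk_hill$params$nH))
cat(sprintf("live cells:    IC50 = %.4f uM, nH = %.2f\n",
            live_hill$params$IC50, live_hill$params$nH))

cf <- coupled_fit(plate$bret_ratio, plate$total, plate$dose, fixed = fx)
cat(sprintf(
  "coupled model: IC50_ERK = %.4f uM (nH %.2f), IC50_L = %.4f uM (nH %.2f), %d well(s) excluded\n",
  cf$IC50_ERK, cf$nH_ERK, cf$IC50_L, cf$nH_L, cf$n_excluded))

res <- data.frame(
  quantity = c("zprime", "IC50_ERK_um", "nH_ERK", "IC50_L_um", "nH_L",
               "wells_excluded"),
  value = c(z, cf$IC50_ERK, cf$nH_ERK, cf$IC50_L, cf$nH_L, cf$n_excluded))
utils::write.csv(res, file.path(out, "plate_fits.csv"), row.names = FALSE)

## predicted live-vs-ERK correlation line (dense ERK grid)
e_grid <- seq(fx$min_ERK + 0.005, fx$min_ERK + fx$amp_ERK - 0.005,
              length.out = 120)
utils::write.csv(data.frame(erk = e_grid, live = cf$live_vs_erk(e_grid)),
                 file.path(out, "live_vs_erk_curve.csv"),
                 row.names = FALSE)
# near-equal IC50s make this relation close to linear, matching the
# observed correlation between ERK activity and live-cell counts
r2 <- summary(stats::lm(cf$live_vs_erk(e_grid) ~ e_grid))$r.squared
cat(sprintf("live-vs-ERK correlation line R^2 vs linear: %.4f\n", r2))

write_manifest(run_manifest(fixed = fx,
                            inputs = file.path(inp, "plate.csv")),
               file.path(out, "plate.manifest.json"))
cat("wrote", out, "\n")
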