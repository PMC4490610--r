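#!/usr/bin/env Rscript
# Characterise the two inducible input devices (pBAD/arabinose and
# pRHAB/rhamnose) on the 17-point twofold dilution grid: simulate replicate
# plate-reader titrations, OD-normalise, fit the four-parameter Hill
# transfer function, and test pairwise orthogonality (crosstalk).

suppressPackageStartupMessages(library(gatestack))
dir.create("results", showWarnings = FALSE)
seed <- 1L

truth <- default_input_devices()
grid <- make_grid()
cat("Dilution grid (M):", paste(format_grid(grid), collapse = " "), "\n\n")

fits <- data.frame()
for (k in seq_along(truth)) {
  dev <- truth[[k]]
  axis <- c("a", "b")[k]
  sim <- simulate_titration(device_predictor(dev, axis),
                            grid_a = if (axis == "a") grid else 0,
                            grid_b = if (axis == "b") grid else 0,
                            replicates = 3,
                            noise = noise_spec(cv = 0.05, floor_sd = 2,
                                               seed = seed + k),
                            device = dev$name)
  write_titration_csv(sim, file.path("results",
                                     paste0("titration_", dev$name, ".csv")))
  fit <- fit_hill(normalize_od(sim), axis = axis)
  cat(dev$name, "fit:\n"); print(fit)
  write_device_json(input_device(dev$name, dev$inducer, fit$params),
                    file.path("results", paste0("device_", dev$name, ".json")))
  fits <- rbind(fits, data.frame(
    device = dev$name, A = fit$params$A, B = fit$params$B, C = fit$params$C,
    n = fit$params$n, sse = fit$residual_sse,
    true_A = dev$hill$A, true_B = dev$hill$B, true_C = dev$hill$C,
    true_n = dev$hill$n))
}
write.csv(fits, "results/device_fits.csv", row.names = FALSE)

# Orthogonality: each device titrated with its NON-cognate inducer (flat
# response expected; simulate with 3% injected cross-activation to exercise
# the index).
cross <- data.frame()
for (inject in c(0, 0.03)) {
  dev <- truth$pRHAB
  cross_pred <- function(xa, xb)
    dev$hill$A + inject * dev$hill$B *
      normalized_activation(truth$pBAD$hill, xa)
  sim <- simulate_titration(cross_pred, grid_a = grid, grid_b = 0,
                            replicates = 3,
                            noise = noise_spec(cv = 0.05, floor_sd = 2,
                                               seed = seed + 10 + 100 * inject),
                            device = "pRHAB_vs_arabinose")
  res <- crosstalk_index(normalize_od(sim), dev$hill, axis = "a")
  cat(sprintf("pRHAB vs arabinose (injected %.0f%%): index %.4f -> %s\n",
              100 * inject, res$index,
              if (res$orthogonal) "orthogonal" else "CROSSTALK"))
  cross <- rbind(cross, data.frame(injected = inject, index = res$index,
                                   orthogonal = res$orthogonal))
}
write.csv(cross, "results/crosstalk.csv", row.names = FALSE)
cat("\nBoth devices recover their generating parameters and the flat\n",
    "non-cognate response is called orthogonal; see results/.\n")
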