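#!/usr/bin/env Rscript
# Binding arm of the analysis: simulates triplicate fluorescence-
# anisotropy titrations for a panel of PS oligonucleotides under Ca2+,
# Mg2+-like and EGTA-like conditions, using published dissociation
# constants as generating truths, then refits every system globally with
# the 1:1 + nonspecific model, selects the nonspecific term by AIC, and
# screens outliers. Writes the K_D table to results/binding_fits.csv.
#
# Generating truths (uM, Ca2+): 5-10 MALAT 9.3, 5-10-5 MALAT 6.3,
# PTEN 5.0, T19G 8.2. The ion-free (EGTA) condition weakens binding
# 5-fold for T19G up to 23-fold for PTEN; those ratios set the EGTA
# truths here.

suppressMessages(library(psbind))
dir.create("results", showWarnings = FALSE)

panel <- list(
  list(oligo = "5-10 MALAT PS", condition = "Ca2+", kd = 9.3),
  list(oligo = "5-10-5 MALAT PS", condition = "Ca2+", kd = 6.3),
  list(oligo = "PTEN PS", condition = "Ca2+", kd = 5.0),
  list(oligo = "T19G PS", condition = "Ca2+", kd = 8.2),
  list(oligo = "PTEN PS", condition = "EGTA", kd = 5.0 * 23),
  list(oligo = "T19G PS", condition = "EGTA", kd = 8.2 * 5))

rows <- list()
fits <- list()
for (i in seq_along(panel)) {
  sys <- panel[[i]]
  truth <- binding_params(sys$kd, a0 = 0.10, da = 0.15, ns = 2e-4)
  ser <- simulate_titration(truth, noise_sd = 0.003, seed = 40 + i,
                            oligo = sys$oligo, condition = sys$condition)
  res <- fit_binding(ser, ns = "auto")
  f <- res$fit
  key <- paste(sys$oligo, sys$condition, sep = " | ")
  fits[[key]] <- res
  rows[[i]] <- data.frame(
    oligo = sys$oligo, condition = sys$condition,
    kd_true = sys$kd, kd_fit = f$params$k_d,
    kd_se = f$std_errors[["k_d"]],
    a0 = f$params$a0, da = f$params$da,
    ns_model = f$ns_model, ns = f$params$ns,
    delta_aic = if (!is.null(res$decision)) res$decision$delta_aic else NA,
    n_points = f$n_points, n_outliers = length(res$outliers),
    converged = f$converged)
  cat(sprintf("%-28s K_D true %6.1f -> fitted %6.2f +/- %.2f uM (%s, %d outliers)\n",
              key, sys$kd, f$params$k_d, f$std_errors[["k_d"]],
              if (f$ns_model) "NS free" else "NS = 0",
              length(res$outliers)))
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/binding_fits.csv", row.names = FALSE)

ca <- tab[tab$condition == "Ca2+", ]
cat(sprintf("\nmax relative K_D recovery error (Ca2+ panel): %.1f%%\n",
            100 * max(abs(ca$kd_fit - ca$kd_true) / ca$kd_true)))
egta <- tab[tab$oligo == "PTEN PS", ]
cat(sprintf("PTEN EGTA/Ca2+ affinity ratio recovered: %.1f (generated 23.0)\n",
            egta$kd_fit[egta$condition == "EGTA"] /
              egta$kd_fit[egta$condition == "Ca2+"]))
cat(paste(
  "note: when the true K_D approaches or exceeds the top protein",
  "concentration (120 uM) the titration never saturates and K_D, dA and",
  "NS become nearly collinear; weak-binder estimates are then poorly",
  "determined and can be strongly biased on a single experiment.\n"))
dir.create("scratch", showWarnings = FALSE)
saveRDS(fits, "scratch/binding_fits.rds")  # for 05_report.R (scratch, not shipped)
cat("written: results/binding_fits.csv\n")
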