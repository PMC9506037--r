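#!/usr/bin/env Rscript
# Step 1: pure-fluid parameterization of the polyethylene glycols.
#
# Fits the co-volume and attractive-energy correlations against molar
# mass on the four glycol oligomers with directly fitted parameters,
# then predicts the full PEG parameter sets (association parameters held
# constant across the family).  Writes the predicted table and the
# correlation coefficients under results/.

suppressPackageStartupMessages(library(cpaeos))
dir.create("results", showWarnings = FALSE)

glycols <- c("ethylene_glycol", "diethylene_glycol",
             "triethylene_glycol", "tetraethylene_glycol")
anchors <- do.call(rbind, lapply(glycols, function(nm) {
  cc <- get_component(nm)
  data.frame(name = nm, mw = cc$mw, a0 = cc$a0, b = cc$b, c1 = cc$c1)
}))
cat("Anchor glycols:\n"); print(anchors, row.names = FALSE)

fit_b  <- fit_mw_correlation(anchors$mw, anchors$b, "linear", "b")
fit_a1 <- fit_mw_correlation(anchors$mw, anchors$a0, "linear", "a0")
fit_a2 <- fit_mw_correlation(anchors$mw, anchors$a0, "quadratic", "a0")
cat("\nFitted correlations (intercept first):\n")
print(fit_b); print(fit_a1); print(fit_a2)

tab <- peg_param_table(c(150, 200, 300, 400, 600))
cat("\nPredicted polyethylene-glycol parameters:\n")
print(signif(tab, 6), row.names = FALSE)
write.csv(tab, "results/peg_parameters.csv", row.names = FALSE)

coefs <- rbind(
  data.frame(parameter = "b", form = "linear",
             c0 = fit_b$coefficients[1], c1 = fit_b$coefficients[2], c2 = NA),
  data.frame(parameter = "a0", form = "linear",
             c0 = fit_a1$coefficients[1], c1 = fit_a1$coefficients[2], c2 = NA),
  data.frame(parameter = "a0", form = "quadratic",
             c0 = fit_a2$coefficients[1], c1 = fit_a2$coefficients[2],
             c2 = fit_a2$coefficients[3]))
write.csv(coefs, "results/peg_correlation_coefficients.csv", row.names = FALSE)
cat("\nWrote results/peg_parameters.csv and results/peg_correlation_coefficients.csv\n")
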