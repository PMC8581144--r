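#!/usr/bin/env Rscript
# Dose-survival modelling for the proton-beam and gamma-ray assays.
#
# The experiment's survival curves are summarised by their shoulder dose
# (Dq) and LD50: protons 754 / 1,051 Gy, gamma-rays 860 / 1,086 Gy. We
# invert each pair to single-hit multitarget parameters (D0, m), rebuild
# the noiseless survival curve on the radiation source's actual dose grid,
# refit it, and confirm the fit returns the summary statistics we started
# from. We also report the unrounded relative Dq difference between the
# sources (the protons' shoulder sits ~12.3% below the gamma shoulder).

library(radmut)

grids <- list(
  proton = c(113.7, 190.3, 280.6, 393.4, 493.4, 574.0, 682.1, 786.9,
             994.9, 1188.4),
  gamma = c(200, 400, 600, 900, 1200, 1500))
printed <- list(proton = c(dq = 754, ld50 = 1051),
                gamma = c(dq = 860, ld50 = 1086))

rows <- lapply(names(grids), function(src) {
  pars <- solve_from_dq_ld50(printed[[src]]["dq"], printed[[src]]["ld50"])
  d <- data.frame(dose_gy = grids[[src]],
                  fraction = survival_fraction(grids[[src]], pars$D0, pars$m))
  fit <- fit_multitarget(d)
  cat(sprintf("%s: D0 = %.1f Gy, m = %.3f -> Dq = %.1f Gy, LD50 = %.1f Gy\n",
              src, fit$D0, fit$m, fit$Dq, fit$LD50))
  data.frame(source = src, D0 = fit$D0, m = fit$m, Dq = fit$Dq,
             LD50 = fit$LD50, rss = fit$rss)
})
fits <- do.call(rbind, rows)

rel_dq <- (fits$Dq[fits$source == "gamma"] -
             fits$Dq[fits$source == "proton"]) /
  fits$Dq[fits$source == "gamma"]
cat(sprintf("Relative shoulder-dose difference (gamma - proton)/gamma: %.3f\n",
            rel_dq))
fits$rel_dq_vs_gamma <- c(rel_dq, 0)

dir.create("results", showWarnings = FALSE)
write.table(fits, "results/survival_fits.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat("Wrote results/survival_fits.tsv\n")
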