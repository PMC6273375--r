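#!/usr/bin/env Rscript
# Ternary phase diagrams of the NA/SA 2:1 cocrystal in solvent and
# solvent/anti-solvent mixtures, fully predictive: the solubility
# product comes from its aqueous reference value (Gibbs-Helmholtz-scaled
# at 310.15 K), never refitted per solvent.
#
# Finding: ethanol/water mixtures raise the cocrystal solubility far
# above either pure solvent (an anti-solvent strategy fails there),
# while ethanol/ethyl acetate gives a nearly symmetric diagram whose
# solubilities simply scale up with temperature - a favorable
# solvent/anti-solvent pair for cocrystallization.

library(cocrysol)

db <- load_parameter_db()
cc <- db$cocrystals[[1]]
dir.create("results", showWarnings = FALSE)

systems <- list(
  list(sv = c(ethanol = 1), T = 298.15, tag = "ethanol_298K"),
  list(sv = c(water = 1), T = 298.15, tag = "water_298K"),
  list(sv = c(ethanol = 0.5, water = 0.5), T = 298.15,
       tag = "ethanol_water_50_50_298K"),
  list(sv = c(ethanol = 0.5, ethyl_acetate = 0.5), T = 298.15,
       tag = "ethanol_etoac_50_50_298K"),
  list(sv = c(ethanol = 0.5, ethyl_acetate = 0.5), T = 310.15,
       tag = "ethanol_etoac_50_50_310K")
)

branches <- list(); eut <- list()
for (sys in systems) {
  pd <- build_phase_diagram(cc, sys$sv, sys$T, db, n_cosolute = 8,
                            ratio_grid = exp(seq(log(0.05), log(20),
                                                 length.out = 17)))
  print(pd)
  b <- rbind(pd$api_line, pd$cc_line, pd$cf_line)
  b$system <- sys$tag
  b$T_K <- sys$T
  branches[[sys$tag]] <- b
  for (nm in c("eutectic_api_cc", "eutectic_cf_cc"))
    if (!is.null(pd[[nm]]))
      eut[[paste(sys$tag, nm)]] <- data.frame(
        system = sys$tag, T_K = sys$T, which = nm,
        x_api = pd[[nm]]$x_api, x_cf = pd[[nm]]$x_cf)
}
write.csv(do.call(rbind, branches), "results/phase_diagram_branches.csv",
          row.names = FALSE)
write.csv(do.call(rbind, eut), "results/eutectic_points.csv",
          row.names = FALSE)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  dir.create("scratch", showWarnings = FALSE)
  b <- do.call(rbind, branches)
  p <- ggplot(b, aes(x_cf, x_api, color = branch)) +
    geom_path() + geom_point(size = 0.6) +
    facet_wrap(~system, scales = "free") +
    labs(x = "x(SA)", y = "x(NA)",
         title = "Predicted ternary phase diagrams, NA/SA 2:1 cocrystal") +
    theme_minimal()
  ggsave("scratch/phase_diagrams.pdf", p, width = 10, height = 7)
  cat("Plot written to scratch/phase_diagrams.pdf\n")
}
cat("Wrote results/phase_diagram_branches.csv and results/eutectic_points.csv\n")
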