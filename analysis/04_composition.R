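#!/usr/bin/env Rscript
# Formulation arithmetic worked examples: monosaccharide-unit bookkeeping,
# S/P recomputation from the preparation molarities, molar <-> mass
# water/sugar conversions, and the residual-water minimum per sugar.
# Writes results/composition.csv.

library(wabdecomp)

dir.create("results", showWarnings = FALSE)

## equal monosaccharide-unit solutions (0.8 M units)
cat("0.8 M monosaccharide units:\n")
cat(sprintf("  disaccharide %.2f M, raffinose %.2f M\n",
            sugar_molarity_from_units(0.8, sugar_spec("trehalose")),
            sugar_molarity_from_units(0.8, sugar_spec("raffinose"))))

## 2:1 water:trehalose stoichiometry as a mass ratio
cat(sprintf("2:1 water:trehalose = %.4f g/g (%.2f at two decimals)\n",
            ws_mass_ratio(2, sugar_spec("trehalose")),
            round(ws_mass_ratio(2, sugar_spec("trehalose")), 2)))

## S/P recomputed from the preparation molarities
form <- formulation_reference()
form$sugar <- ifelse(form$family == "raffinose", "raffinose", "trehalose")
form$sp_computed <- mapply(function(sug, s_mM, p_mM) {
  if (is.na(p_mM)) Inf
  else sp_ratio(s_mM / 1000, p_mM / 1000, sugar_spec(sug))
}, form$sugar, form$sugar_mM, form$protein_mM)
cat("\nS/P recomputed from molarities (label vs computed):\n")
print(form[c("family", "sp_label", "sugar_mM", "protein_mM", "sp_computed")],
      row.names = FALSE)

## residual-water minimum per sugar
ws <- ws_reference()
fin <- ws[is.finite(ws$sp), ]
mins <- vapply(names(ws)[-1], function(sugar) {
  col <- stats::setNames(fin[[sugar]], fin$sp)
  ws_minimum(col[!is.na(col)])
}, numeric(1))
cat("\nS/P at the residual-water minimum:\n")
print(mins)

utils::write.csv(form, file.path("results", "composition.csv"),
                 row.names = FALSE)
cat("wrote results/composition.csv\n")
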