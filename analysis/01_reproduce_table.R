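#!/usr/bin/env Rscript
# Reproduce the compiled experiment table: convert each reported
# enrichment factor to an apparent 18O-KIE and compare with the reported
# AKIE column; also evaluate the pre-equilibrium model prediction at each
# printed commitment.

suppressPackageStartupMessages(library(photokie))
dir.create("results", showWarnings = FALSE)

rep <- reproduce_table1()
print(rep)

write.csv(as.data.frame(rep), "results/table1_reproduction.csv",
          row.names = FALSE)

cat(sprintf("\n%d/21 entries reproduce within the rounding tolerance.\n",
            sum(rep$pass)))
cat(sprintf("Largest |epsilon->AKIE - printed| = %.5f (entry %d).\n",
            max(abs(rep$akie_from_epsilon - rep$akie_printed)),
            rep$entry[which.max(abs(rep$akie_from_epsilon - rep$akie_printed))]))
cat(sprintf("Pre-equilibrium-model residuals span %+.4f .. %+.4f AKIE units;\n",
            min(rep$model_residual), max(rep$model_residual)))
cat("mid-commitment (c in 0.3-10) histidine entries sit above the curve,\n")
cat("consistent with the reported 0.002-0.003 unit deviations.\n")
cat("Entry 19 is flagged internally inconsistent (commitment ~10x off its\n")
cat("methionine siblings) and excluded from intrinsic-KIE derivations.\n")
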