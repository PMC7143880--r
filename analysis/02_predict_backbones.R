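#!/usr/bin/env Rscript
# Step 2 — predict product backbones for the assembly-line clusters.
#
# For each type I PKS, NRPS and hybrid cluster, the colinearity rule turns
# the module organization into an ordered chain of building blocks: called
# A-domain substrates by name, "x" for uncalled substrates, "y" for
# A-less modules, "mx" for N-methylated residues, "pk" for polyketide
# units. Dissociated type II and standalone type III PKS clusters carry no
# assembly line and are skipped. Clusters with an identified product keep
# their annotation; predictions matter for the orphan clusters.

suppressPackageStartupMessages(library(bgcrep))
dir.create("results", showWarnings = FALSE)

rows <- list()
for (which in c("TP-A0598", "NBRC3934")) {
  inv <- example_inventory(which)
  for (cl in inv$clusters) {
    pred <- tryCatch(format(predict_backbone(cl)),
                     bgcrep_not_an_assembly_line = function(e) NA_character_)
    rows[[length(rows) + 1L]] <- data.frame(
      strain_id = inv$strain_id, cluster_id = cl$cluster_id,
      ctype = cl$ctype,
      known_product = ifelse(is.na(cl$known_product), "", cl$known_product),
      predicted_backbone = ifelse(is.na(pred), "", pred),
      stringsAsFactors = FALSE)
  }
}
tab <- do.call(rbind, rows)
write.table(tab, "results/backbone_predictions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

orphans <- tab[tab$known_product == "" & tab$predicted_backbone != "", ]
cat("orphan-cluster backbone predictions:\n")
for (i in seq_len(nrow(orphans))) {
  cat(sprintf("  %-9s %-11s %s\n", orphans$strain_id[i],
              orphans$cluster_id[i], orphans$predicted_backbone[i]))
}
cat("wrote results/backbone_predictions.tsv\n")
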