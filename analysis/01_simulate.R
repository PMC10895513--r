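#!/usr/bin/env Rscript
# Simulate the study cohort: 4492 mother-father-child trios drawn from the
# default 19-node ground truth (nine depression symptoms per parent on the
# ordinal 1-4 scale, six same-symptom cross-parent bridge edges, and a
# child emotional-difficulties factor measured by three 0-10 wave scores).
# Writes the data and the generating truth under results/.

library(famnet)

seed <- 2026L
outdir <- "results"
dir.create(outdir, showWarnings = FALSE)

truth <- family_truth(seed = seed)
message("Ground truth: ", length(truth$node_labels), " nodes, ",
        sum(truth$pcor[upper.tri(truth$pcor)] != 0), " edges (",
        truth$shrink_steps, " shrinkage steps applied)")

tab <- sample_family_data(truth, n_families = 4492, seed = seed + 1L)
message("Sampled ", nrow(tab$values), " families; ",
        "share of girls = ",
        sprintf("%.1f%%", 100 * mean(tab$values$child_female)))

write_true_network_json(truth, file.path(outdir, "truth.json"))
write_symptom_csv(tab, file.path(outdir, "families.csv"))
message("Wrote ", file.path(outdir, "truth.json"), " and ",
        file.path(outdir, "families.csv"))
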