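#!/usr/bin/env Rscript
# Step 2: bridge symptoms between the mother and father communities.
# Computes bridge strength for every parent symptom and flags the top 30%
# as bridges; on an all-positive network the signed variant (bridge
# expected influence) coincides with bridge strength and is omitted.
# Artifact: results/bridge_centrality.csv.

source("analysis/00_common.R")

tab <- load_families()
cfg <- analysis_config()

s1 <- run_step1_parent_network(tab, cfg)
s2 <- run_step2_bridges(s1, cfg)

message(s2$note)
message("Bridge symptoms (top ", 100 * cfg$top_prop, "% bridge strength): ",
        paste(s2$bridges, collapse = ", "))

truth <- load_truth()
tcomm <- unlist(truth$communities)
cross <- truth$edges[tcomm[truth$edges$node1] != tcomm[truth$edges$node2] &
                       truth$edges$node1 != "child_emotional" &
                       truth$edges$node2 != "child_emotional", ]
designated <- unique(c(cross$node1, cross$node2))
message("Endpoints of the true cross-parent edges: ",
        paste(sort(designated), collapse = ", "))
message("Flagged bridges among them: ",
        sum(s2$bridges %in% designated), "/", length(s2$bridges))
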