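# Shared helpers for the numbered analysis scripts: the pipeline
# configuration used throughout, and a loader for the simulated cohort
# written by 01_simulate.R.

library(famnet)

analysis_seed <- 2026L

analysis_config <- function(...) {
  pipeline_config(seed = analysis_seed, outdir = "results", ...)
}

load_families <- function() {
  truth <- jsonlite::read_json("results/truth.json", simplifyVector = TRUE)
  parent_comm <- unlist(truth$communities)
  parent_comm <- parent_comm[parent_comm != "child"]
  comm <- c(parent_comm,
            setNames(rep("child", 3), paste0("sdq_w", 1:3)),
            c(child_female = "demographic"))
  scl <- c(setNames(rep("ordinal_1_4", length(parent_comm)),
                    names(parent_comm)),
           setNames(rep("subscale_0_10", 3), paste0("sdq_w", 1:3)),
           c(child_female = "binary"))
  read_symptom_csv("results/families.csv", communities = comm, scale = scl)
}

load_truth <- function() {
  jsonlite::read_json("results/truth.json", simplifyVector = TRUE)
}
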