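#!/usr/bin/env Rscript
# Stage 2: TMM normalization and differential calling. Genes give the
# DEG set, peaks the DAC set, both with |linear FC| >= 1.5 and BH
# adjusted p <= 0.05 in at least one pairwise stage contrast.

source("analysis/00_setup.R")

load_counts <- function(name) {
  tab <- read_tsv(name)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$feature
  stage <- sub("_r\\d+$", "", colnames(m))
  count_matrix(m, stages = stage)
}

for (what in c("genes", "peaks")) {
  message("differential calling: ", what)
  cm <- load_counts(paste0("counts_", what, ".tsv"))
  cm$norm_factors <- tmm_factors(cm)
  cm <- filter_features(cm, cpm_min = 1)   # peaks carry no biotype table
  dr <- call_differential(cm, fc = 1.5, alpha = 0.05)

  truth <- read_tsv(paste0("truth_", what, ".tsv"))
  planted <- truth$feature[truth$pattern != "flat"]
  sens <- mean(planted %in% dr$differential)
  fpr <- mean(setdiff(rownames(cm$counts), planted) %in% dr$differential)
  message(sprintf("  %d/%d features differential; sensitivity %.3f, FPR %.4f",
                  length(dr$differential), nrow(cm$counts), sens, fpr))
  per_ct <- table(dr$table$contrast[dr$table$significant])
  message("  per contrast: ",
          paste(names(per_ct), per_ct, sep = "=", collapse = ", "))

  write_tsv(dr$table, paste0("differential_", what, ".tsv"))
  write_tsv(data.frame(feature = dr$differential),
            paste0(ifelse(what == "genes", "deg", "dac"), "_set.tsv"))
  write_tsv(data.frame(sample = cm$samples$sample,
                       stage = cm$samples$stage,
                       lib_size = cm$lib_sizes,
                       tmm_factor = cm$norm_factors),
            paste0("normalization_", what, ".tsv"))
}
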