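# Shared configuration for the analysis drivers. Source()d by every
# numbered script; defines the simulation conditions once so all
# stages see the same synthetic study.

library(chromodyn)

cfg <- list(
  seed         = 2026L,
  stages       = c("E9.75", "E10.5", "E11.5"),
  # genome fixture
  chrom_length = 4e6,
  n_genes      = 800,
  n_peaks      = 1000,
  peak_width   = 300,
  # planted temporal programs
  n_planted_genes = 300,
  n_planted_peaks = 450,
  n_coupled       = 150,   # peaks moved within 10 kb of a partner gene TSS
  couple_dist     = 10e3,
  # count model
  baseline_mean = 100,
  fold          = 4,
  dispersion    = 0.1,
  n_reps        = 3,
  # motifs
  pwm_width = 8,
  # phylogeny for the accelerated-region analysis
  tree  = "(((mouse:0.2,rat:0.15):0.1,human:0.25):0.15,(chicken:0.3,zebrafinch:0.25):0.1);",
  focal = "chicken",
  n_blocks = 200, block_length = 200, sub_rate = 0.05,
  accel_factor = 10, prop_accel = 0.1
)

res_dir <- file.path("results")
dir.create(res_dir, showWarnings = FALSE)

write_tsv <- function(x, name) {
  path <- file.path(res_dir, name)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("  wrote ", path, " (", nrow(x), " rows)")
  invisible(path)
}
read_tsv <- function(name) {
  read.table(file.path(res_dir, name), sep = "\t", header = TRUE,
             stringsAsFactors = FALSE, check.names = FALSE)
}

# the two source-TF motifs used throughout: sharply informative 8-mers
# standing in for the GLI and bHLH E-box binding preferences
fixture_pwms <- function() {
  mk <- function(id, codes) {
    m <- matrix(0.01, 4, length(codes))
    m[cbind(codes, seq_along(codes))] <- 0.97
    pwm(id, m)
  }
  list(GLI3 = mk("MA_GLI3", c(4, 3, 3, 3, 4, 3, 3, 2)),   # TGGGTGGC-like
       HAND2 = mk("MA_HAND2", c(2, 1, 4, 2, 4, 3, 1, 4))) # CATCTGAT-like
}
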