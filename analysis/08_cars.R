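#!/usr/bin/env Rscript
# Stage 8: accelerated conserved regions. Simulates conserved-element
# alignment blocks down the fixture phylogeny with 10% of blocks
# carrying a 10x substitution excess on the chicken branch, filters
# blocks with >50% of the focal sequence missing, tests each block's
# focal-branch substitution count against its branch-length share
# (parsimony counts, one-sided binomial), BH-selects CARs at
# FDR < 5%, and annotates them with nearby genes and DACs.

source("analysis/00_setup.R")

message("simulating ", cfg$n_blocks, " alignment blocks")
aln <- generate_alignment(cfg$tree, cfg$n_blocks, cfg$block_length,
                          cfg$sub_rate, focal = cfg$focal,
                          accel_factor = cfg$accel_factor,
                          prop_accel = cfg$prop_accel,
                          gap_species = cfg$focal, gap_fraction = 0.6,
                          gap_blocks = 1:5,  # a few unusable blocks
                          seed = cfg$seed + 80)

res <- discover_cars(aln$blocks, cfg$tree, cfg$focal, alpha = 0.05)
message(sprintf("retained %d/%d blocks after the missing-data filter",
                nrow(res), cfg$n_blocks))
both <- merge(res, aln$truth, by.x = "region_id", by.y = "block_id")
sens <- mean(both$car[both$accelerated])
fdp <- if (any(both$car)) mean(!both$accelerated[both$car]) else 0
message(sprintf("%d CARs at q < 0.05; sensitivity %.2f, FDP %.3f",
                sum(both$car), sens, fdp))

# place the merged regions on the fixture genome: one block every 15 kb
coords <- data.frame(region_id = res$region_id, chrom = "chr1",
                     start = 10e3 + (seq_len(nrow(res)) - 1) * 15e3)
coords$end <- coords$start + cfg$block_length
cars <- merge(coords, res, by = "region_id")

genes <- read_tsv("genes.tsv")
cars <- assign_car_genes(cars, genes, window = 1e6)

# species-specific DACs: reference DACs from stage 2; the second
# species' DACs are emulated as a jittered subset (liftover upstream)
dac_ids <- read_tsv("dac_set.tsv")$feature
peaks <- read_tsv("peaks.bed.tsv")
dac_a <- peaks[peaks$peak_id %in% dac_ids, c("chrom", "start", "end")]
set.seed(cfg$seed + 81)
dac_b <- dac_a[sample(nrow(dac_a), round(0.6 * nrow(dac_a))), ]
dac_b$start <- pmax(0, dac_b$start + sample(-500:500, nrow(dac_b), TRUE))
dac_b$end <- dac_b$start + cfg$peak_width
cars <- car_dac_overlap(cars, dac_a, dac_b, window = 2000,
                        labels = c("mm", "gg"))
cars$accelerated_truth <-
  aln$truth$accelerated[match(cars$region_id, aln$truth$block_id)]
# the fixture genome is ~1000x denser in genes than a real one, so the
# full 1-Mb gene list is summarized by its size in the written table
cars$n_genes_in_window <-
  ifelse(cars$genes_in_window == "", 0L,
         lengths(strsplit(cars$genes_in_window, ",")))
cars$genes_in_window <- NULL
write_tsv(cars, "cars.tsv")
message("CAR-DAC categories among called CARs:")
print(table(cars$dac_category[cars$car]))
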