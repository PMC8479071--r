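#!/usr/bin/env Rscript
# Stage 1: build the synthetic study. One genome fixture, planted
# temporal programs for genes and peaks, peak-gene coupling, count
# matrices, peak sequences with planted TF motifs. Ground truth is
# written alongside so later stages can score themselves.

source("analysis/00_setup.R")
set.seed(cfg$seed)

message("simulating genome fixture")
g <- generate_genome(1, cfg$chrom_length, cfg$n_genes, cfg$n_peaks,
                     peak_width = cfg$peak_width, seed = cfg$seed)

message("planting temporal programs")
truth_genes <- make_planted_truth(g$genes$gene_id, cfg$n_planted_genes,
                                  seed = cfg$seed + 1)
truth_peaks <- make_planted_truth(g$peaks$peak_id, cfg$n_planted_peaks,
                                  seed = cfg$seed + 2)

# couple a subset of planted peaks to planted genes: move the peak to
# within 10 kb of the partner TSS and copy the partner's pattern, so
# nearest-TSS assignment recovers the pair by construction
planted_g <- names(truth_genes)[truth_genes != "flat"]
planted_p <- names(truth_peaks)[truth_peaks != "flat"]
# partners need breathing room: the offset stays below half the
# distance to the next-nearest TSS, so the partner is the nearest
# gene by construction
spacing <- vapply(g$genes$tss, function(t) {
  d <- abs(g$genes$tss - t)
  min(d[d > 0])
}, numeric(1))
eligible <- planted_g[spacing[match(planted_g, g$genes$gene_id)] >= 500]
partners <- sample(eligible, cfg$n_coupled)
coupled <- sample(planted_p, cfg$n_coupled)
tss <- g$genes$tss[match(partners, g$genes$gene_id)]
max_off <- pmin(cfg$couple_dist,
                floor(spacing[match(partners, g$genes$gene_id)] / 2) - 10)
off <- sample(c(-1, 1), cfg$n_coupled, TRUE) *
  pmin(floor(runif(cfg$n_coupled, 100, cfg$couple_dist)), max_off)
new_start <- pmin(pmax(tss + off - cfg$peak_width %/% 2, 0),
                  cfg$chrom_length - cfg$peak_width)
idx <- match(coupled, g$peaks$peak_id)
g$peaks$start[idx] <- new_start
g$peaks$end[idx] <- new_start + cfg$peak_width
truth_peaks[coupled] <- truth_genes[partners]

message("drawing NB counts (3 stages x ", cfg$n_reps, " replicates)")
cm_genes <- generate_counts(truth_genes, cfg$baseline_mean, cfg$fold,
                            cfg$dispersion, cfg$n_reps, cfg$stages,
                            seed = cfg$seed + 3)
cm_peaks <- generate_counts(truth_peaks, cfg$baseline_mean, cfg$fold,
                            cfg$dispersion, cfg$n_reps, cfg$stages,
                            seed = cfg$seed + 4)

message("planting TF motifs into peak sequences")
pwms <- fixture_pwms()
seqs <- generate_sequences(cfg$n_peaks, cfg$peak_width,
                           names = g$peaks$peak_id, seed = cfg$seed + 5)
# GLI3 motifs go into peaks of the early-high program, HAND2 into the
# coupled subset as well, so the network stage has planted edges
early_hi <- names(truth_peaks)[truth_peaks == "100"]
pl_g <- plant_motifs(seqs[early_hi], pwms$GLI3, sites_per_seq = 2,
                     strand = "random", seed = cfg$seed + 6)
seqs[early_hi] <- pl_g$seqs
pl_h <- plant_motifs(seqs[coupled], pwms$HAND2, sites_per_seq = 1,
                     strand = "random", seed = cfg$seed + 7)
seqs[coupled] <- pl_h$seqs

message("writing fixture tables")
write_tsv(g$genes, "genes.tsv")
write_tsv(g$peaks, "peaks.bed.tsv")
write_tsv(data.frame(feature = names(truth_genes), pattern = truth_genes,
                     row.names = NULL), "truth_genes.tsv")
write_tsv(data.frame(feature = names(truth_peaks), pattern = truth_peaks,
                     row.names = NULL), "truth_peaks.tsv")
write_tsv(data.frame(peak = coupled, gene = partners, row.names = NULL),
          "truth_coupling.tsv")
write_tsv(rbind(cbind(motif = "MA_GLI3", pl_g$sites),
                cbind(motif = "MA_HAND2", pl_h$sites)),
          "truth_motif_sites.tsv")

counts_out <- function(cm) {
  data.frame(feature = rownames(cm$counts), cm$counts, check.names = FALSE)
}
write_tsv(counts_out(cm_genes), "counts_genes.tsv")
write_tsv(counts_out(cm_peaks), "counts_peaks.tsv")
Biostrings::writeXStringSet(seqs, file.path(res_dir, "peaks.fasta"))
message("  wrote ", file.path(res_dir, "peaks.fasta"))
write_meme(pwms, file.path(res_dir, "motifs.meme"))
message("  wrote ", file.path(res_dir, "motifs.meme"))

message(sprintf(
  "done: %d genes (%d planted), %d peaks (%d planted, %d coupled)",
  cfg$n_genes, cfg$n_planted_genes, cfg$n_peaks,
  sum(truth_peaks != "flat"), cfg$n_coupled))
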