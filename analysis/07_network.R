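#!/usr/bin/env Rscript
# Stage 7: TF-target networks. Builds the motif-supported GLI3/HAND2
# network over a curated target list for the simulated reference
# species, simulates a second species with partly rewired motif
# content, builds its network the same way, and compares the two
# with the connection/target similarity score. Also computes the
# ortholog-based stage correspondence between the species.

source("analysis/00_setup.R")

pwms <- fixture_pwms()
tf_motifs <- c(GLI3 = "MA_GLI3", HAND2 = "MA_HAND2")

genes <- read_tsv("genes.tsv")
map <- read_tsv("peak_gene_map.tsv")
hits <- read_tsv("motif_hits.tsv")
coupling <- read_tsv("truth_coupling.tsv")
truth_peaks <- read_tsv("truth_peaks.tsv")

# curated list: the genes engaged by the planted programs plus decoys
set.seed(cfg$seed + 70)
curated <- unique(c(coupling$gene,
                    sample(genes$gene_id, 60)))
message("curated target list: ", length(curated), " genes")

net_a <- build_network(tf_motifs, hits, map, targets = curated)
net_a <- classify_edges(net_a, c("GLI3", "HAND2"))

# closest DEG module of each target, by centroid correlation
cm_tab <- read_tsv("counts_genes.tsv")
m <- as.matrix(cm_tab[, -1]); rownames(m) <- cm_tab$feature
cm <- count_matrix(m, stages = sub("_r\\d+$", "", colnames(m)))
cm$norm_factors <- tmm_factors(cm)
cen <- read_tsv("centroids_genes.tsv")
ms_like <- list(centroids = as.matrix(cen[, grep("^stage", names(cen))]),
                labels = cen$module)
expr <- stage_means(cm, intersect(net_a$target, rownames(m)))
net_a$module <- assign_target_module(expr[net_a$target, , drop = FALSE],
                                     ms_like)
write_tsv(net_a, "network_edges.tsv")
message(sprintf("reference network: %d edges to %d targets (%d shared)",
                nrow(net_a), length(unique(net_a$target)),
                sum(net_a$class == "shared")))

## second species: one2one orthologs with a partly rewired motif content
ortho <- data.frame(gene_a = genes$gene_id,
                    gene_b = sub("^gene", "ggene", genes$gene_id),
                    homology_type = "ortholog_one2one")
o_map <- map_orthologs(ortho)

set.seed(cfg$seed + 71)
seqs_b <- generate_sequences(cfg$n_peaks, cfg$peak_width,
                             names = sub("^peak", "gpeak",
                                         read_tsv("peaks.bed.tsv")$peak_id),
                             seed = cfg$seed + 72)
# conserve ~70% of the reference planting; rewire the rest elsewhere
early_hi <- sub("^peak", "gpeak",
                truth_peaks$feature[truth_peaks$pattern == "100"])
coupled_b <- sub("^peak", "gpeak", coupling$peak)
keep_frac <- 0.7
keep_g <- sample(early_hi, round(keep_frac * length(early_hi)))
keep_h <- sample(coupled_b, round(keep_frac * length(coupled_b)))
new_g <- sample(setdiff(names(seqs_b), early_hi), 20)
pl1 <- plant_motifs(seqs_b[c(keep_g, new_g)], pwms$GLI3, 2,
                    strand = "random", seed = cfg$seed + 73)
seqs_b[c(keep_g, new_g)] <- pl1$seqs
pl2 <- plant_motifs(seqs_b[keep_h], pwms$HAND2, 1, strand = "random",
                    seed = cfg$seed + 74)
seqs_b[keep_h] <- pl2$seqs

hits_b <- do.call(rbind, lapply(pwms, function(p)
  cbind(motif = p$id, scan_sequences(p, seqs_b, 1e-4))))
map_b <- map
map_b$peak_id <- sub("^peak", "gpeak", map_b$peak_id)
map_b$gene_id <- sub("^gene", "ggene", map_b$gene_id)
net_b <- build_network(tf_motifs, hits_b, map_b,
                       targets = sub("^gene", "ggene", curated))
message(sprintf("second-species network: %d edges to %d targets",
                nrow(net_b), length(unique(net_b$target))))

cmp <- similarity_score(net_a, net_b, ortholog_map = o_map)
print(cmp)
write_tsv(data.frame(N = cmp$N, M = cmp$M, I = cmp$I, J = cmp$J,
                     D = cmp$D, S = cmp$S, S_pct = cmp$S_pct),
          "network_similarity.tsv")

## stage correspondence over orthologs: the conserved temporal program
## makes the matched stages correlate best
cm_b <- generate_counts(setNames(read_tsv("truth_genes.tsv")$pattern,
                                 sub("^gene", "ggene",
                                     read_tsv("truth_genes.tsv")$feature)),
                        cfg$baseline_mean, cfg$fold, cfg$dispersion,
                        cfg$n_reps, paste0("HH", c(20, 22, 24)),
                        seed = cfg$seed + 75)
cm_b$norm_factors <- tmm_factors(cm_b)
rho <- stage_correspondence(stage_means(cm), stage_means(cm_b), o_map)
write_tsv(data.frame(stage_a = rownames(rho), round(rho, 4),
                     check.names = FALSE), "stage_correspondence.tsv")
message("stage correspondence (Spearman rho):")
print(round(rho, 3))
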