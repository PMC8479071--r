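#!/usr/bin/env Rscript
# Stage 5: motif analysis. Scans the peak sequences with the fixture
# PWMs at the exact-p threshold p < 1e-4 (genome-wide TFBS
# prediction), verifies recovery of the planted sites, and tests
# module motif enrichment of each hi module against its dissimilar
# (complementary-pattern) lo background.

source("analysis/00_setup.R")

pwms <- read_meme(file.path(res_dir, "motifs.meme"))
seqs <- Biostrings::readDNAStringSet(file.path(res_dir, "peaks.fasta"))

message("scanning ", length(seqs), " peak sequences, ", length(pwms),
        " motifs, threshold p < 1e-4")
hits <- do.call(rbind, lapply(pwms, function(p) {
  h <- scan_sequences(p, seqs, p_threshold = 1e-4)
  cbind(motif = p$id, h)
}))
rownames(hits) <- NULL
write_tsv(hits, "motif_hits.tsv")

planted <- read_tsv("truth_motif_sites.tsv")
rec <- merge(planted, hits, by = c("motif", "seq_id", "start"))
message(sprintf("planted-site recovery: %d/%d (%.1f%%)",
                nrow(rec), nrow(planted), 100 * nrow(rec) / nrow(planted)))

# enrichment: foreground = peaks of a hi module, background = the lo
# module of the same stage (complementary temporal pattern)
dac_mod <- read_tsv("modules_peaks.tsv")
mod_of <- setNames(dac_mod$module, dac_mod$feature)
pairs <- data.frame(fg = paste0(cfg$stages, "^hi"),
                    bg = paste0(cfg$stages, "^lo"))
enr <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
  fg <- names(mod_of)[mod_of == pairs$fg[i]]
  bg <- names(mod_of)[mod_of == pairs$bg[i]]
  if (!length(fg) || !length(bg)) return(NULL)
  e <- module_motif_enrichment(seqs[fg], seqs[bg], pwms)
  cbind(foreground = pairs$fg[i], background = pairs$bg[i], e)
}))
write_tsv(enr, "motif_enrichment.tsv")
sig <- enr[enr$call != "ns", ]
for (i in seq_len(nrow(sig)))
  message(sprintf("  %s vs %s: %s %s (padj %.2e)",
                  sig$foreground[i], sig$background[i], sig$motif[i],
                  sig$call[i],
                  ifelse(sig$call[i] == "enriched", sig$padj_enrich[i],
                         sig$padj_deplete[i])))
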