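#' Assign each peak to its nearest gene TSS
#'
#' Distance is measured from the peak midpoint to the strand-aware
#' TSS; the signed distance is positive when the midpoint lies
#' downstream of the TSS in gene orientation. Exact ties go to the
#' lexicographically smallest gene id and are flagged.
#'
#' @param peaks data.frame: peak_id, chrom, start, end (0-based
#'   half-open).
#' @param genes data.frame: gene_id, chrom, tss, strand.
#' @return data.frame: peak_id, gene_id, distance, tie. Peaks on a
#'   chromosome without genes are unmapped (NA gene) with a warning.
#' @export
assign_nearest_gene <- function(peaks, genes) {
  out <- data.frame(peak_id = peaks$peak_id,
                    gene_id = NA_character_,
                    distance = NA_real_,
                    tie = FALSE, stringsAsFactors = FALSE)
  mid <- (peaks$start + peaks$end) / 2
  for (ch in unique(peaks$chrom)) {
    gi <- which(genes$chrom == ch)
    pi <- which(peaks$chrom == ch)
    if (!length(gi)) next
    g <- genes[gi, ]
    ord <- order(g$gene_id)  # lexicographic tie-break
    g <- g[ord, ]
    for (i in pi) {
      ad <- abs(mid[i] - g$tss)
      j <- which.min(ad)
      signed <- if (g$strand[j] == "+") mid[i] - g$tss[j]
                else g$tss[j] - mid[i]
      out$gene_id[i] <- g$gene_id[j]
      out$distance[i] <- signed
      out$tie[i] <- sum(ad == ad[j]) > 1
    }
  }
  if (anyNA(out$gene_id))
    warning(sum(is.na(out$gene_id)),
            " peak(s) on chromosomes without genes left unmapped")
  out
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities not
#' exceeding that of the observed table (fixed margins). The reported
#' odds ratio is the sample OR ad/bc, with 0.5 added to every cell
#' only when some cell is zero (Haldane correction).
#'
#' @param tab 2x2 matrix of non-negative integers.
#' @return List with \code{odds_ratio} and \code{p}.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0))
  if (sum(tab) == 0) stop("all-zero table: odds ratio undefined")
  p <- fisher.test(tab)$p.value
  t2 <- if (any(tab == 0)) tab + 0.5 else tab
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  list(odds_ratio = or, p = min(p, 1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment, capped at 1 and monotone in the p-value
#' ranks.
#'
#' @param p numeric p-values in [0, 1].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Module-module positional association matrix
#'
#' For every DAC-module x DEG-module pair, tests whether peaks of the
#' DAC module are positionally associated (via their nearest gene)
#' with genes of the DEG module more or less often than expected. The
#' universe is all module-assigned peaks whose mapped gene carries a
#' DEG-module label. Each cell gets a two-sided Fisher test on
#' membership in DAC module a (rows) vs mapped gene in DEG module b
#' (columns); BH adjustment is applied jointly across all cells.
#'
#' @param peak_modules named vector: peak id -> DAC module label.
#' @param gene_modules named vector: gene id -> DEG module label.
#' @param map peak-gene map from \code{\link{assign_nearest_gene}}.
#' @param alpha significance level for the direction call.
#' @return data.frame with one row per (dac_module, deg_module) cell:
#'   odds ratio, p, padj, direction (enriched/depleted/ns), signed
#'   \code{heat} value (-log10 padj, negative for depletions), and
#'   the contingency counts n11, n12, n21, n22.
#' @export
module_association <- function(peak_modules, gene_modules, map,
                               alpha = 0.05) {
  map <- map[!is.na(map$gene_id), ]
  map <- map[map$peak_id %in% names(peak_modules) &
             map$gene_id %in% names(gene_modules), ]
  if (!nrow(map)) stop("empty peak-gene universe")
  pm <- peak_modules[map$peak_id]
  gm <- gene_modules[map$gene_id]
  dac_levels <- sort(unique(peak_modules))
  deg_levels <- sort(unique(gene_modules))
  grid <- expand.grid(dac_module = dac_levels, deg_module = deg_levels,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    a <- pm == grid$dac_module[i]
    b <- gm == grid$deg_module[i]
    tab <- matrix(c(sum(a & b), sum(a & !b),
                    sum(!a & b), sum(!a & !b)), 2, byrow = TRUE)
    ft <- fisher_exact_2x2(tab)
    data.frame(grid[i, ], odds_ratio = ft$odds_ratio, p = ft$p,
               n11 = tab[1, 1], n12 = tab[1, 2],
               n21 = tab[2, 1], n22 = tab[2, 2])
  })
  res <- do.call(rbind, res)
  res$padj <- bh_adjust(res$p)
  res$direction <- ifelse(res$padj >= alpha, "ns",
                          ifelse(res$odds_ratio > 1, "enriched",
                                 ifelse(res$odds_ratio < 1, "depleted",
                                        "ns")))
  sgn <- ifelse(res$direction == "enriched", 1,
                ifelse(res$direction == "depleted", -1, 0))
  res$heat <- sgn * -log10(pmax(res$padj, .Machine$double.xmin))
  rownames(res) <- NULL
  res
}
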