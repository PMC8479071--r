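#' Filter an ortholog table to one-to-one pairs
#'
#' Keeps only rows with homology type "ortholog_one2one" and enforces
#' a bijection: genes appearing in more than one retained row are
#' dropped entirely with a warning.
#'
#' @param table data.frame with columns gene_a, gene_b,
#'   homology_type.
#' @return Named character vector mapping gene_a -> gene_b.
#' @export
map_orthologs <- function(table) {
  keep <- table[table$homology_type == "ortholog_one2one", , drop = FALSE]
  if (!nrow(keep)) return(setNames(character(0), character(0)))
  dup <- keep$gene_a %in% keep$gene_a[duplicated(keep$gene_a)] |
         keep$gene_b %in% keep$gene_b[duplicated(keep$gene_b)]
  if (any(dup))
    warning(sum(dup), " row(s) dropped: gene appears in multiple ",
            "one2one pairs")
  keep <- keep[!dup, , drop = FALSE]
  setNames(keep$gene_b, keep$gene_a)
}

#' Stage correspondence between two species
#'
#' Spearman correlation (average ranks for ties) between every pair
#' of stages over one-to-one ortholog expression (TPM or any
#' normalized measure).
#'
#' @param tpm_a,tpm_b genes x stages matrices, rownames = gene ids.
#' @param mapping named vector (gene in A -> gene in B), e.g. from
#'   \code{\link{map_orthologs}}.
#' @return Matrix of Spearman rho (rows = stages of A, columns =
#'   stages of B); NA where a vector is constant.
#' @export
stage_correspondence <- function(tpm_a, tpm_b, mapping) {
  shared <- intersect(names(mapping), rownames(tpm_a))
  shared <- shared[mapping[shared] %in% rownames(tpm_b)]
  if (length(shared) < 3) stop("need >= 3 shared one-to-one orthologs")
  a <- tpm_a[shared, , drop = FALSE]
  b <- tpm_b[mapping[shared], , drop = FALSE]
  rho <- matrix(NA_real_, ncol(a), ncol(b),
                dimnames = list(colnames(a), colnames(b)))
  for (i in seq_len(ncol(a))) for (j in seq_len(ncol(b))) {
    if (sd(a[, i]) == 0 || sd(b[, j]) == 0) next
    rho[i, j] <- cor(a[, i], b[, j], method = "spearman")
  }
  rho
}

#' Build a motif-supported TF-target regulatory network
#'
#' An edge (TF, gene) exists iff at least one hit of the TF's motif
#' lies within an accessible peak whose nearest gene is the target
#' and the target belongs to the curated gene list; the edge weight
#' is the total number of such supporting motif hits.
#'
#' @param tf_motifs named character vector: TF name -> motif id.
#' @param hits data.frame of motif hits with columns motif, seq_id
#'   (peak id), e.g. rbind-ed \code{\link{scan_sequences}} output
#'   with a motif column added.
#' @param map peak-gene map from \code{\link{assign_nearest_gene}}.
#' @param accessible character vector of accessible peak ids
#'   (default: all mapped peaks).
#' @param targets curated target gene list.
#' @return An object of class \code{regulatory_network}: data.frame
#'   (tf, target, weight).
#' @export
build_network <- function(tf_motifs, hits, map, accessible = NULL,
                          targets) {
  if (is.null(accessible)) accessible <- map$peak_id
  map <- map[!is.na(map$gene_id) & map$peak_id %in% accessible, ]
  edges <- list()
  for (tf in names(tf_motifs)) {
    h <- hits[hits$motif == tf_motifs[[tf]], , drop = FALSE]
    h <- h[h$seq_id %in% map$peak_id, , drop = FALSE]
    if (!nrow(h)) next
    gene <- map$gene_id[match(h$seq_id, map$peak_id)]
    ok <- gene %in% targets
    if (!any(ok)) next
    cnt <- table(gene[ok])
    edges[[tf]] <- data.frame(tf = tf, target = names(cnt),
                              weight = as.integer(cnt),
                              stringsAsFactors = FALSE)
  }
  out <- if (length(edges)) do.call(rbind, edges)
         else data.frame(tf = character(), target = character(),
                         weight = integer())
  rownames(out) <- NULL
  class(out) <- c("regulatory_network", "data.frame")
  out
}

#' Classify network edges as shared or TF-specific
#'
#' @param net a \code{regulatory_network}.
#' @param tf_pair the two source TFs.
#' @return The network with a \code{class} column: "shared" when both
#'   TFs target the gene, otherwise "<TF>-specific".
#' @export
classify_edges <- function(net, tf_pair) {
  stopifnot(length(tf_pair) == 2)
  shared <- intersect(net$target[net$tf == tf_pair[1]],
                      net$target[net$tf == tf_pair[2]])
  net$class <- ifelse(net$target %in% shared, "shared",
                      paste0(net$tf, "-specific"))
  net
}

#' Assign a target gene to its closest DEG module
#'
#' Pearson correlation between the gene's 3-stage mean expression and
#' each module centroid; the best-correlated module wins, ties going
#' to the lower seed index. Constant expression is unassignable.
#'
#' @param expr numeric 3-vector of stage means, or a genes x 3
#'   matrix.
#' @param ms a labelled \code{module_set} (for centroids and labels).
#' @return Module label(s); NA for constant vectors.
#' @export
assign_target_module <- function(expr, ms) {
  if (is.null(dim(expr))) expr <- rbind(expr)
  labels <- if (!is.null(ms$labels)) ms$labels
            else as.character(seq_len(nrow(ms$centroids)))
  vapply(seq_len(nrow(expr)), function(i) {
    v <- expr[i, ]
    if (sd(v) == 0) return(NA_character_)
    r <- apply(ms$centroids, 1, function(cen) {
      if (sd(cen) == 0) return(-Inf)
      cor(v, cen)
    })
    labels[which.max(r)]  # which.max takes the first = lowest index
  }, character(1))
}

#' Cross-species network similarity score
#'
#' Connections are compared as (TF, target) pairs after mapping the
#' second network's targets through the ortholog table; unmapped
#' targets always count as different. With M the number of all
#' connections (union), N the different connections (symmetric
#' difference), J all target genes and I the different target genes,
#' the difference is D = (N/M + I/(2J)) / 2 and the similarity
#' S = 1 - D (reported also as a percentage). S lies in [0.25, 1]
#' for non-empty unions.
#'
#' @param net_a,net_b \code{regulatory_network}s with shared source
#'   TF identities.
#' @param ortholog_map optional named vector translating B targets
#'   into A gene space.
#' @return An object of class \code{network_comparison}: list with
#'   N, M, I, J, D, S, S_pct.
#' @export
similarity_score <- function(net_a, net_b, ortholog_map = NULL) {
  if (nrow(net_a) + nrow(net_b) == 0)
    stop("both networks empty: similarity undefined")
  tb <- net_b$target
  if (!is.null(ortholog_map)) {
    mapped <- names(ortholog_map)[match(tb, ortholog_map)]
    tb <- ifelse(is.na(mapped), paste0("unmapped:", tb), mapped)
  }
  con_a <- unique(paste(net_a$tf, net_a$target, sep = "->"))
  con_b <- unique(paste(net_b$tf, tb, sep = "->"))
  tar_a <- unique(net_a$target)
  tar_b <- unique(tb)
  m <- length(union(con_a, con_b))
  n <- length(setdiff(con_a, con_b)) + length(setdiff(con_b, con_a))
  j <- length(union(tar_a, tar_b))
  i <- length(setdiff(tar_a, tar_b)) + length(setdiff(tar_b, tar_a))
  d <- (n / m + i / (2 * j)) / 2
  s <- 1 - d
  structure(list(N = n, M = m, I = i, J = j, D = d, S = s,
                 S_pct = 100 * s),
            class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf(
    "network_comparison: N=%d M=%d I=%d J=%d  D=%.3f  S=%.1f%%\n",
    x$N, x$M, x$I, x$J, x$D, x$S_pct))
  invisible(x)
}
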