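#' Iteratively merge nearby intervals
#'
#' Merges intervals (0-based half-open) whose gap is at most
#' \code{gap} bp, transitively until a fixpoint; the result is
#' disjoint and idempotent under re-merging.
#'
#' @param x data.frame: chrom, start, end.
#' @param gap maximum gap merged across, in bp.
#' @return Merged data.frame (chrom, start, end), sorted.
#' @export
merge_conserved <- function(x, gap = 50) {
  out <- lapply(split(x, x$chrom), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1, end = d$end),
                          min.gapwidth = gap + 1)
    data.frame(chrom = d$chrom[1], start = IRanges::start(ir) - 1,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop alignment blocks with too much focal-species sequence missing
#'
#' A block is removed when strictly more than \code{max_missing} of
#' the focal species' row is gaps (or the focal species is absent);
#' exactly 50\% missing is retained.
#'
#' @param blocks list of named character vectors (aligned rows per
#'   species).
#' @param focal focal species name.
#' @param max_missing maximum tolerated missing fraction.
#' @return The retained subset of \code{blocks}.
#' @export
filter_missing <- function(blocks, focal, max_missing = 0.5) {
  keep <- vapply(blocks, function(b) {
    if (!focal %in% names(b)) {
      warning("focal species missing from a block; block dropped")
      return(FALSE)
    }
    s <- strsplit(b[[focal]], "")[[1]]
    missing <- mean(s %in% c("-", ".", "N"))
    missing <= max_missing
  }, logical(1))
  blocks[keep]
}

# aligned block -> integer matrix (tips x columns), gap/N columns removed
block_to_codes <- function(block, tip_labels) {
  if (!all(tip_labels %in% names(block)))
    stop("alignment block missing species: ",
         paste(setdiff(tip_labels, names(block)), collapse = ", "))
  rows <- lapply(block[tip_labels], function(s) strsplit(s, "")[[1]])
  lens <- lengths(rows)
  if (length(unique(lens)) != 1) stop("alignment rows differ in length")
  m <- matrix(match(toupper(unlist(rows)), BASES),
              nrow = length(rows), byrow = TRUE)
  m[, colSums(is.na(m)) == 0, drop = FALSE]
}

#' Per-branch parsimony substitution counts
#'
#' Fitch/Sankoff parsimony per alignment column; when several
#' minimum-cost reconstructions exist, substitutions are attributed
#' fractionally to branches in proportion to how often each branch
#' changes state across all minimal reconstructions (uniform weight).
#' Columns containing a gap or N in any species are skipped.
#'
#' @param block named character vector: species -> aligned sequence.
#' @param tree an \code{ape::phylo} (or Newick string); tips must be
#'   a subset of the block's species.
#' @return Named numeric vector of expected substitution counts, one
#'   per branch, named by the branch's child node (tip label, or
#'   "node<N>" for internal nodes).
#' @export
branch_substitutions <- function(block, tree) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  ntip <- length(tree$tip.label)
  if (ntip < 3) stop("need at least 3 species")
  codes <- block_to_codes(block, tree$tip.label)
  nnode <- max(tree$edge)
  root <- ntip + 1L
  edge_names <- ifelse(tree$edge[, 2] <= ntip,
                       tree$tip.label[tree$edge[, 2]],
                       paste0("node", tree$edge[, 2]))
  nedge <- nrow(tree$edge)
  L <- ncol(codes)
  if (L == 0)
    return(setNames(numeric(nedge), edge_names))
  post <- stats::reorder(tree, "postorder")
  post_idx <- match(paste(post$edge[, 1], post$edge[, 2]),
                    paste(tree$edge[, 1], tree$edge[, 2]))
  # Sankoff bottom-up: S[[v]] 4 x L min cost given state; C[[v]] counts
  S <- vector("list", nnode); C <- vector("list", nnode)
  for (v in seq_len(ntip)) {
    s <- matrix(Inf, 4, L); cc <- matrix(0, 4, L)
    s[cbind(codes[v, ], seq_len(L))] <- 0
    cc[cbind(codes[v, ], seq_len(L))] <- 1
    S[[v]] <- s; C[[v]] <- cc
  }
  # per edge, the minimal cost and count of child's subtree given the
  # parent state; cached for the top-down pass
  edge_m <- vector("list", nedge)   # 4 x L min cost
  edge_w <- vector("list", nedge)   # list of 4 (parent state) x [4 x L]
  for (e in post_idx) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    if (is.null(S[[p]])) { S[[p]] <- matrix(0, 4, L); C[[p]] <- matrix(1, 4, L) }
    m <- matrix(0, 4, L)
    w <- vector("list", 4)
    for (s in 1:4) {
      costs <- S[[ch]] + 1
      costs[s, ] <- costs[s, ] - 1
      ms <- do.call(pmin, lapply(1:4, function(t) costs[t, ]))
      wt <- matrix(0, 4, L)
      for (t in 1:4) wt[t, ] <- C[[ch]][t, ] * (costs[t, ] == ms)
      m[s, ] <- ms
      w[[s]] <- wt
    }
    edge_m[[e]] <- m; edge_w[[e]] <- w
    S[[p]] <- S[[p]] + m
    K <- matrix(0, 4, L)
    for (s in 1:4) K[s, ] <- colSums(edge_w[[e]][[s]])
    C[[p]] <- C[[p]] * K
  }
  # top-down: marginal state distribution over minimal reconstructions
  P <- vector("list", nnode)
  smin <- do.call(pmin, lapply(1:4, function(s) S[[root]][s, ]))
  pr <- matrix(0, 4, L)
  for (s in 1:4) pr[s, ] <- C[[root]][s, ] * (S[[root]][s, ] == smin)
  P[[root]] <- sweep(pr, 2, colSums(pr), "/")
  pre_idx <- rev(post_idx)
  subs <- setNames(numeric(nedge), edge_names)
  for (e in pre_idx) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    pc <- matrix(0, 4, L)
    change <- numeric(L)
    for (s in 1:4) {
      wt <- edge_w[[e]][[s]]
      denom <- colSums(wt)
      denom[denom == 0] <- 1
      cond <- sweep(wt, 2, denom, "/")
      pc <- pc + sweep(cond, 2, P[[p]][s, ], "*")
      change <- change + P[[p]][s, ] * (1 - cond[s, ])
    }
    P[[ch]] <- pc
    subs[match(e, seq_len(nedge))] <- sum(change)
  }
  subs
}

#' Branch lengths named by child node
#'
#' @param tree an \code{ape::phylo}.
#' @return Named numeric vector matching the naming of
#'   \code{\link{branch_substitutions}}.
#' @export
branch_lengths <- function(tree) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  ntip <- length(tree$tip.label)
  setNames(tree$edge.length,
           ifelse(tree$edge[, 2] <= ntip, tree$tip.label[tree$edge[, 2]],
                  paste0("node", tree$edge[, 2])))
}

#' One-sided binomial test for focal-branch acceleration
#'
#' Tests whether the focal branch carries more substitutions than its
#' share of the total tree length predicts: the focal count against
#' Binomial(total, focal length / total length), one-sided.
#'
#' @param counts named per-branch substitution counts (fractional
#'   allowed; rounded to integers for the test).
#' @param lengths named per-branch lengths (same naming).
#' @param focal focal branch name.
#' @return One-sided p-value.
#' @export
acceleration_test <- function(counts, lengths, focal) {
  if (!focal %in% names(counts)) stop("unknown focal branch")
  tot_len <- sum(lengths)
  if (tot_len <= 0) stop("zero total tree length")
  n <- round(sum(counts))
  if (n < 1) stop("need at least one substitution")
  k <- round(counts[[focal]])
  p0 <- lengths[[focal]] / tot_len
  pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' BH-select accelerated regions
#'
#' @param p named vector of per-region acceleration p-values.
#' @param alpha FDR threshold; regions with BH q strictly below it
#'   are flagged.
#' @return data.frame: region_id, p, q, car.
#' @export
call_cars <- function(p, alpha = 0.05) {
  q <- bh_adjust(p)
  data.frame(region_id = names(p), p = unname(p), q = unname(q),
             car = unname(q < alpha), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Run the acceleration pipeline on alignment blocks
#'
#' Applies the missing-sequence filter, computes per-branch parsimony
#' substitution counts, tests focal-branch acceleration per block and
#' BH-selects candidate accelerated regions. Blocks without any
#' substitution get p = 1.
#'
#' @param blocks list of alignment blocks (named character vectors).
#' @param tree \code{ape::phylo} or Newick string with branch
#'   lengths.
#' @param focal focal species (terminal branch).
#' @param alpha FDR threshold.
#' @param max_missing missing-fraction filter for the focal row.
#' @return data.frame from \code{\link{call_cars}} over retained
#'   blocks, plus a \code{focal_count} and \code{total_count} column.
#' @export
discover_cars <- function(blocks, tree, focal, alpha = 0.05,
                          max_missing = 0.5) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  blocks <- filter_missing(blocks, focal, max_missing)
  if (!length(blocks)) stop("no blocks retained after filtering")
  bl <- branch_lengths(tree)
  stats <- lapply(blocks, function(b) {
    cnt <- branch_substitutions(b, tree)
    p <- if (round(sum(cnt)) < 1) 1 else acceleration_test(cnt, bl, focal)
    c(p = p, focal_count = cnt[[focal]], total_count = sum(cnt))
  })
  stats <- do.call(rbind, stats)
  out <- call_cars(setNames(stats[, "p"], names(blocks)), alpha)
  out$focal_count <- stats[, "focal_count"]
  out$total_count <- stats[, "total_count"]
  out
}

#' Assign nearest and 1-Mb-window genes to accelerated regions
#'
#' Nearest gene by TSS distance from the region midpoint, plus all
#' genes whose TSS lies within \code{window} bp of the midpoint
#' (boundary inclusive).
#'
#' @param cars data.frame: region_id, chrom, start, end.
#' @param genes data.frame: gene_id, chrom, tss.
#' @param window association window in bp (default 1 Mb).
#' @return \code{cars} with nearest_gene, nearest_distance and
#'   genes_in_window (comma-separated) columns.
#' @export
assign_car_genes <- function(cars, genes, window = 1e6) {
  mid <- (cars$start + cars$end) / 2
  cars$nearest_gene <- NA_character_
  cars$nearest_distance <- NA_real_
  cars$genes_in_window <- ""
  for (i in seq_len(nrow(cars))) {
    g <- genes[genes$chrom == cars$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    d <- abs(g$tss - mid[i])
    j <- which.min(d)
    cars$nearest_gene[i] <- g$gene_id[j]
    cars$nearest_distance[i] <- d[j]
    cars$genes_in_window[i] <- paste(g$gene_id[d <= window],
                                     collapse = ",")
  }
  cars
}

# gap (bp) between a region and the closest interval of a set;
# 0 when overlapping, Inf when the set is empty on that chromosome
min_gap_to_set <- function(chrom, start, end, set) {
  s <- set[set$chrom == chrom, , drop = FALSE]
  if (!nrow(s)) return(Inf)
  min(pmax(0, pmax(s$start - end, start - s$end)))
}

#' Categorize accelerated regions by nearby differential accessibility
#'
#' A region within \code{window} bp of a DAC of both species is
#' "CAR-<a>/<b>-DAC"; of one species only, "CAR-<a>-DAC" or
#' "CAR-<b>-DAC"; otherwise "CAR-no-DAC".
#'
#' @param cars data.frame: region_id, chrom, start, end.
#' @param dacs_a,dacs_b DAC intervals (chrom, start, end) of the two
#'   species, lifted to the shared coordinate system.
#' @param window distance threshold in bp (boundary inclusive).
#' @param labels two species tags used in the category names.
#' @return \code{cars} with a \code{dac_category} column.
#' @export
car_dac_overlap <- function(cars, dacs_a, dacs_b, window = 2000,
                            labels = c("mm", "gg")) {
  near_a <- vapply(seq_len(nrow(cars)), function(i)
    min_gap_to_set(cars$chrom[i], cars$start[i], cars$end[i],
                   dacs_a) <= window, logical(1))
  near_b <- vapply(seq_len(nrow(cars)), function(i)
    min_gap_to_set(cars$chrom[i], cars$start[i], cars$end[i],
                   dacs_b) <= window, logical(1))
  cars$dac_category <- ifelse(
    near_a & near_b, sprintf("CAR-%s/%s-DAC", labels[1], labels[2]),
    ifelse(near_a, sprintf("CAR-%s-DAC", labels[1]),
           ifelse(near_b, sprintf("CAR-%s-DAC", labels[2]),
                  "CAR-no-DAC")))
  cars
}
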