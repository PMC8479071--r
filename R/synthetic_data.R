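#' Generate a synthetic genome fixture
#'
#' Places genes (TSS + strand) and non-overlapping peaks uniformly on a
#' set of chromosomes. All coordinates are 0-based half-open (BED
#' convention). Deterministic for a fixed seed.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length length of each chromosome in bp (recycled).
#' @param n_genes,n_peaks total numbers of genes and peaks, split
#'   across chromosomes as evenly as possible.
#' @param peak_width width of every peak in bp.
#' @param biotype gene biotype assigned to all genes.
#' @param seed RNG seed.
#' @return An object of class \code{genome_fixture}: list with
#'   \code{chromosomes} (named lengths), \code{genes} (data.frame:
#'   gene_id, chrom, tss, strand, biotype) and \code{peaks}
#'   (data.frame: peak_id, chrom, start, end).
#' @export
generate_genome <- function(n_chrom = 1, chrom_length = 1e6,
                            n_genes = 50, n_peaks = 200,
                            peak_width = 500,
                            biotype = "protein_coding", seed = NULL) {
  stopifnot(n_chrom >= 1, n_genes >= 1, n_peaks >= 1, peak_width >= 2)
  chrom_length <- rep_len(chrom_length, n_chrom)
  chroms <- setNames(chrom_length, paste0("chr", seq_len(n_chrom)))
  per_chrom_peaks <- diff(round(seq(0, n_peaks, length.out = n_chrom + 1)))
  per_chrom_genes <- diff(round(seq(0, n_genes, length.out = n_chrom + 1)))
  need <- per_chrom_peaks * peak_width
  if (any(need > chrom_length)) {
    i <- which(need > chrom_length)[1]
    stop(sprintf(
      "cannot place %d non-overlapping peaks of width %d on a %d bp chromosome; minimum length required: %d bp",
      per_chrom_peaks[i], peak_width, chrom_length[i], need[i]))
  }
  with_seed(seed, {
    peaks <- do.call(rbind, lapply(seq_len(n_chrom), function(i) {
      k <- per_chrom_peaks[i]
      if (k == 0) return(NULL)
      slack <- chrom_length[i] - k * peak_width
      # classic stars-and-bars placement: sorted uniform gaps guarantee
      # non-overlap
      gaps <- sort(floor(runif(k, 0, slack + 1)))
      starts <- gaps + (seq_len(k) - 1L) * peak_width
      data.frame(chrom = names(chroms)[i], start = starts,
                 end = starts + peak_width, stringsAsFactors = FALSE)
    }))
    peaks$peak_id <- sprintf("peak%05d", seq_len(nrow(peaks)))
    genes <- do.call(rbind, lapply(seq_len(n_chrom), function(i) {
      k <- per_chrom_genes[i]
      if (k == 0) return(NULL)
      data.frame(chrom = names(chroms)[i],
                 tss = sort(floor(runif(k, 0, chrom_length[i]))),
                 strand = sample(c("+", "-"), k, replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    genes$gene_id <- sprintf("gene%04d", seq_len(nrow(genes)))
    genes$biotype <- biotype
    structure(list(
      chromosomes = chroms,
      genes = genes[, c("gene_id", "chrom", "tss", "strand", "biotype")],
      peaks = peaks[, c("peak_id", "chrom", "start", "end")]
    ), class = "genome_fixture")
  })
}

#' Assign planted temporal patterns to features
#'
#' Splits features between "flat" background and the six binary
#' temporal patterns (see \code{\link{seed_patterns}}), evenly across
#' patterns.
#'
#' @param feature_ids character vector of feature ids.
#' @param n_planted number of features receiving a planted pattern.
#' @param patterns patterns to plant, as pattern strings (default all
#'   six).
#' @param seed RNG seed.
#' @return Named character vector mapping feature id to a pattern
#'   string ("100", "010", ...) or "flat".
#' @export
make_planted_truth <- function(feature_ids, n_planted,
                               patterns = rownames(seed_patterns()),
                               seed = NULL) {
  stopifnot(n_planted <= length(feature_ids))
  bad <- setdiff(patterns, rownames(seed_patterns()))
  if (length(bad))
    stop("unknown pattern(s): ", paste(bad, collapse = ", "))
  with_seed(seed, {
    truth <- setNames(rep("flat", length(feature_ids)), feature_ids)
    planted <- sample(feature_ids, n_planted)
    truth[planted] <- rep_len(patterns, n_planted)
    truth
  })
}

#' Generate negative-binomial counts with planted temporal patterns
#'
#' Features with a planted binary pattern have mean
#' \code{fold * baseline_mean} at pattern-"1" stages and
#' \code{baseline_mean} at pattern-"0" stages; "flat" features keep one
#' mean throughout. Counts are NB with the given dispersion
#' (variance = mu + dispersion * mu^2); dispersion 0 degenerates to
#' Poisson.
#'
#' @param truth named pattern vector as from
#'   \code{\link{make_planted_truth}}.
#' @param baseline_mean expected count at a pattern-"0" stage.
#' @param fold fold step between "0" and "1" stages (> 1 when any
#'   feature is planted).
#' @param dispersion NB dispersion (>= 0).
#' @param n_reps replicates per stage.
#' @param stages stage names (length 3).
#' @param seed RNG seed.
#' @return A \code{\link{count_matrix}}.
#' @export
generate_counts <- function(truth, baseline_mean = 100, fold = 4,
                            dispersion = 0.1, n_reps = 3,
                            stages = c("S1", "S2", "S3"), seed = NULL) {
  stopifnot(dispersion >= 0, length(stages) == 3, n_reps >= 2)
  if (any(truth != "flat") && fold <= 1)
    stop("fold must be > 1 when features are planted")
  pat <- seed_patterns()
  mu <- t(vapply(truth, function(p) {
    if (p == "flat") rep(baseline_mean, 3)
    else baseline_mean * ifelse(pat[p, ] == 1, fold, 1)
  }, numeric(3)))
  mu_full <- mu[, rep(seq_along(stages), each = n_reps), drop = FALSE]
  with_seed(seed, {
    n <- length(mu_full)
    y <- if (dispersion == 0) rpois(n, lambda = mu_full)
         else rnbinom(n, size = 1 / dispersion, mu = mu_full)
    counts <- matrix(y, nrow = nrow(mu_full),
                     dimnames = list(names(truth), NULL))
    stage_vec <- rep(stages, each = n_reps)
    colnames(counts) <- paste0(stage_vec, "_r", rep(seq_len(n_reps),
                                                    times = length(stages)))
    count_matrix(counts, stages = stage_vec,
                 replicates = rep(seq_len(n_reps), times = length(stages)))
  })
}

#' Generate random background DNA sequences
#'
#' i.i.d. composition with configurable 0-order base frequencies
#' (uniform by default).
#'
#' @param n number of sequences.
#' @param length sequence length in bp.
#' @param freqs base frequencies in A, C, G, T order (sum to 1).
#' @param names sequence names.
#' @param seed RNG seed.
#' @return A \code{Biostrings::DNAStringSet}.
#' @export
generate_sequences <- function(n, length, freqs = rep(0.25, 4),
                               names = sprintf("seq%04d", seq_len(n)),
                               seed = NULL) {
  stopifnot(abs(sum(freqs) - 1) < 1e-6)
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(bases, length, replace = TRUE, prob = freqs),
            collapse = "")
    }, character(1))
    setNames(Biostrings::DNAStringSet(seqs), names)
  })
}

#' Plant motif instances into sequences
#'
#' Writes non-overlapping motif instances (the PWM consensus, or draws
#' from the PWM) into each sequence and records their exact 0-based
#' coordinates and strands as ground truth.
#'
#' @param seqs a \code{DNAStringSet}.
#' @param pwm a \code{\link{pwm}} object.
#' @param sites_per_seq instances per sequence (0 allowed).
#' @param strand "+" or "-", or "random".
#' @param mode "consensus" plants the consensus word; "sample" draws
#'   each base from the PWM column probabilities.
#' @param seed RNG seed.
#' @return List with \code{seqs} (modified DNAStringSet) and
#'   \code{sites} (data.frame: seq_id, start, end, strand).
#' @export
plant_motifs <- function(seqs, pwm, sites_per_seq = 1,
                         strand = "+", mode = "consensus", seed = NULL) {
  w <- ncol(pwm$mat)
  lens <- Biostrings::width(seqs)
  if (any(lens < w)) stop("sequence shorter than motif width")
  capacity <- floor(lens / w)
  if (any(sites_per_seq > capacity))
    stop(sprintf("requested %d sites exceed non-overlapping capacity %d",
                 sites_per_seq, min(capacity)))
  with_seed(seed, {
    out <- as.character(seqs)
    sites <- list()
    for (i in seq_along(out)) {
      k <- sites_per_seq
      if (k == 0) next
      # block placement on a w-grid guarantees no overlap
      slots <- sample(seq_len(floor(lens[i] / w)), k)
      starts <- (slots - 1L) * w  # 0-based
      for (s in starts) {
        st <- if (strand == "random") sample(c("+", "-"), 1) else strand
        word <- if (mode == "consensus") consensus(pwm)
                else paste(vapply(seq_len(w), function(j) {
                  sample(c("A", "C", "G", "T"), 1, prob = pwm$mat[, j])
                }, character(1)), collapse = "")
        if (st == "-")
          word <- as.character(
            Biostrings::reverseComplement(Biostrings::DNAString(word)))
        substr(out[i], s + 1, s + w) <- word
        sites[[length(sites) + 1]] <-
          data.frame(seq_id = names(seqs)[i], start = s, end = s + w,
                     strand = st, stringsAsFactors = FALSE)
      }
    }
    sites <- if (length(sites)) do.call(rbind, sites)
             else data.frame(seq_id = character(), start = integer(),
                             end = integer(), strand = character())
    list(seqs = setNames(Biostrings::DNAStringSet(out), names(seqs)),
         sites = sites)
  })
}

#' Generate per-base Tn5 cut-count profiles around motif sites
#'
#' Simulates a transposase cut-count track over a window centered on
#' each motif site. Cuts are Poisson with rate \code{flank_rate}
#' outside the motif core and \code{(1 - protection) * flank_rate}
#' inside it, emulating the occupancy drop of a bound TF footprint.
#'
#' @param sites data.frame with columns seq_id (used as chrom), start,
#'   end, strand (0-based half-open motif core).
#' @param flank_rate expected cuts per base outside the core.
#' @param protection fraction of flank rate removed inside the core,
#'   in [0, 1].
#' @param half_width bp of flank covered on each side of the core.
#' @param seed RNG seed.
#' @return data.frame (chrom, pos, count): a single-base BedGraph-style
#'   track (0-based positions).
#' @export
generate_cut_profile <- function(sites, flank_rate = 10, protection = 0.8,
                                 half_width = 100, seed = NULL) {
  stopifnot(protection >= 0, protection <= 1, flank_rate >= 0)
  with_seed(seed, {
    # one consistent track per chromosome: overlapping site windows
    # share positions, and a position inside any motif core is
    # protected
    rows <- lapply(split(sites, sites$seq_id), function(ss) {
      pos <- sort(unique(unlist(lapply(seq_len(nrow(ss)), function(i)
        (ss$start[i] - half_width):(ss$end[i] + half_width - 1)))))
      in_core <- rep(FALSE, length(pos))
      for (i in seq_len(nrow(ss)))
        in_core <- in_core | (pos >= ss$start[i] & pos < ss$end[i])
      rate <- ifelse(in_core, (1 - protection) * flank_rate, flank_rate)
      data.frame(chrom = ss$seq_id[1], pos = pos,
                 count = rpois(length(pos), rate),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate multiple alignment blocks with planted branch acceleration
#'
#' Simulates ungapped orthologous alignment blocks down a phylogeny:
#' each branch receives Poisson(rate x branch length x block length)
#' substitutions placed uniformly (multiple hits allowed). On blocks
#' flagged as accelerated, the focal branch's substitution count is
#' multiplied by \code{accel_factor}. Optionally a fraction of one
#' species' columns is replaced by gaps.
#'
#' @param tree an \code{ape::phylo} or a Newick string with branch
#'   lengths.
#' @param n_blocks number of alignment blocks.
#' @param block_length block length in bp.
#' @param rate substitutions per site per unit branch length.
#' @param focal tip label of the focal branch (the branch above that
#'   tip).
#' @param accel_factor rate multiplier on the focal branch of
#'   accelerated blocks.
#' @param prop_accel fraction of blocks planted as accelerated.
#' @param gap_species,gap_fraction,gap_blocks optionally replace
#'   \code{gap_fraction} of the columns of \code{gap_species} by "-"
#'   in the given block indices (default all blocks).
#' @param seed RNG seed.
#' @return List with \code{blocks} (list of named character vectors,
#'   one aligned sequence per species), \code{truth} (data.frame:
#'   block_id, accelerated) and \code{tree}.
#' @export
generate_alignment <- function(tree, n_blocks = 200, block_length = 200,
                               rate = 0.05, focal, accel_factor = 10,
                               prop_accel = 0.1, gap_species = NULL,
                               gap_fraction = 0, gap_blocks = NULL,
                               seed = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (!focal %in% tree$tip.label)
    stop(sprintf("unknown focal branch '%s'", focal))
  bases <- c("A", "C", "G", "T")
  ntip <- length(tree$tip.label)
  focal_node <- match(focal, tree$tip.label)
  focal_edge <- which(tree$edge[, 2] == focal_node)
  root <- ntip + 1L
  edge_order <- stats::reorder(tree, "cladewise")$edge  # parents first
  edge_idx <- match(paste(edge_order[, 1], edge_order[, 2]),
                    paste(tree$edge[, 1], tree$edge[, 2]))
  with_seed(seed, {
    n_accel <- round(prop_accel * n_blocks)
    accel <- rep(FALSE, n_blocks)
    if (n_accel > 0) accel[sample(n_blocks, n_accel)] <- TRUE
    blocks <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      seq_at <- vector("list", max(tree$edge))
      seq_at[[root]] <- sample(bases, block_length, replace = TRUE)
      for (k in seq_along(edge_idx)) {
        e <- edge_idx[k]
        parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
        lambda <- rate * tree$edge.length[e] * block_length
        if (accel[b] && e == focal_edge) lambda <- lambda * accel_factor
        s <- seq_at[[parent]]
        nsub <- rpois(1, lambda)
        if (nsub > 0) {
          pos <- sample.int(block_length, nsub, replace = TRUE)
          for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1)
        }
        seq_at[[child]] <- s
      }
      mat <- vapply(seq_len(ntip), function(i)
        paste(seq_at[[i]], collapse = ""), character(1))
      names(mat) <- tree$tip.label
      blocks[[b]] <- mat
    }
    if (!is.null(gap_species) && gap_fraction > 0) {
      if (is.null(gap_blocks)) gap_blocks <- seq_len(n_blocks)
      for (b in gap_blocks) {
        s <- strsplit(blocks[[b]][[gap_species]], "")[[1]]
        ngap <- round(gap_fraction * block_length)
        s[sample.int(block_length, ngap)] <- "-"
        blocks[[b]][[gap_species]] <- paste(s, collapse = "")
      }
    }
    names(blocks) <- sprintf("block%04d", seq_len(n_blocks))
    list(blocks = blocks,
         truth = data.frame(block_id = names(blocks), accelerated = accel,
                            stringsAsFactors = FALSE),
         tree = tree)
  })
}
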