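BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' @param id motif identifier.
#' @param mat 4 x width position probability matrix, rows A, C, G, T;
#'   columns must sum to 1 (tolerance 1e-9 relative to rounding of
#'   published matrices: columns are renormalized if within 1e-4).
#' @param bg background base frequencies (A, C, G, T), summing to 1.
#' @param pseudocount pseudocount fraction applied as
#'   \code{p + pseudocount * bg} before taking logs.
#' @return An object of class \code{pwm}.
#' @export
pwm <- function(id, mat, bg = rep(0.25, 4), pseudocount = 0.01) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) == 4, all(mat >= 0), pseudocount > 0,
            abs(sum(bg) - 1) < 1e-6, all(bg > 0))
  cs <- colSums(mat)
  if (any(abs(cs - 1) > 1e-4)) stop("PWM columns must sum to 1")
  mat <- sweep(mat, 2, cs, "/")
  rownames(mat) <- BASES
  structure(list(id = id, mat = mat, bg = bg, pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': width %d, consensus %s\n", x$id, ncol(x$mat),
              consensus(x)))
  invisible(x)
}

#' Consensus word of a PWM
#' @param x a \code{pwm}.
#' @return Character scalar (highest-probability base per column).
#' @export
consensus <- function(x) {
  paste(BASES[apply(x$mat, 2, which.max)], collapse = "")
}

#' Log-odds score matrix of a PWM
#'
#' Entry (a, j) = log2((p_aj + pseudocount * bg_a) /
#' ((1 + pseudocount) * bg_a)), in bits.
#'
#' @param x a \code{pwm}.
#' @return 4 x width real matrix.
#' @export
log_odds <- function(x) {
  log2(sweep(x$mat + x$pseudocount * x$bg, 1,
             (1 + x$pseudocount) * x$bg, "/"))
}

#' Exact null distribution of the discretized PWM score
#'
#' Scores are rounded down to a fixed grid (default 0.001 bits) and
#' the exact distribution of the window score under the i.i.d.
#' background is computed by positionwise convolution. All scanning
#' uses the same discretized scores, so p-values are exact in the
#' discretized space; rounding scores down and thresholds up keeps
#' the binning conservative.
#'
#' @param x a \code{pwm}.
#' @param step discretization step in bits.
#' @return An object of class \code{score_dist}: list with
#'   \code{step}, \code{k} (integer score matrix), \code{min_int},
#'   \code{pvals} (P(score >= s) for s = min_int, min_int+1, ...).
#' @export
score_pvalues <- function(x, step = 0.001) {
  s <- log_odds(x)
  k <- matrix(as.integer(floor(s / step + 1e-9)), nrow = 4,
              dimnames = dimnames(s))
  w <- ncol(k)
  d <- 1; cur_min <- 0L
  for (j in seq_len(w)) {
    mn <- min(k[, j]); mx <- max(k[, j])
    new <- numeric(length(d) + (mx - mn))
    for (a in 1:4) {
      sh <- k[a, j] - mn
      idx <- seq_along(d) + sh
      new[idx] <- new[idx] + d * x$bg[a]
    }
    d <- new; cur_min <- cur_min + mn
  }
  pv <- rev(cumsum(rev(d)))
  structure(list(step = step, k = k, min_int = cur_min, pvals = pv,
                 density = d),
            class = "score_dist")
}

# P(score >= k_int) under the null
score_dist_p <- function(sd, k_int) {
  i <- k_int - sd$min_int + 1L
  out <- numeric(length(k_int))
  out[i <= 0] <- 1
  inside <- i >= 1 & i <= length(sd$pvals)
  out[inside] <- sd$pvals[i[inside]]
  # i beyond support: score unattainable, p = 0
  out
}

# smallest integer score whose p-value is below the threshold;
# +Inf when even the maximum score is not significant
threshold_score <- function(sd, p_threshold) {
  ok <- which(sd$pvals < p_threshold)
  if (!length(ok)) return(Inf)
  sd$min_int + ok[1] - 1L
}

#' Scan sequences for PWM hits with exact p-values
#'
#' Scores every window on both strands with the discretized log-odds
#' matrix and reports positions whose score p-value is below the
#' threshold. Windows containing N are skipped; minus-strand hits are
#' reported as forward-axis intervals.
#'
#' @param x a \code{pwm}.
#' @param seqs a \code{DNAStringSet} or named character vector over
#'   A, C, G, T, N.
#' @param p_threshold hit threshold on the score p-value.
#' @param score_dist optional precomputed \code{\link{score_pvalues}}
#'   result.
#' @return data.frame: seq_id, start (0-based), end, strand, score
#'   (bits), pval. Sequences shorter than the motif yield no hits.
#' @export
scan_sequences <- function(x, seqs, p_threshold = 1e-4,
                           score_dist = NULL) {
  if (is.null(score_dist)) score_dist <- score_pvalues(x, 0.001)
  k <- score_dist$k
  w <- ncol(k)
  thr <- threshold_score(score_dist, p_threshold)
  if (!is.character(seqs)) {
    nm <- names(seqs)
    seqs <- as.character(seqs)
    names(seqs) <- nm
  }
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("seq%04d", seq_along(seqs))
  empty <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), pval = numeric())
  if (!is.finite(thr)) return(empty)
  scan_codes <- function(codes) {
    l <- length(codes)
    if (l < w) return(NULL)
    n <- l - w + 1L
    sc <- rep(0L, n)
    for (j in seq_len(w)) {
      sc <- sc + k[(j - 1L) * 4L + codes[j:(j + n - 1L)]]
    }
    which(!is.na(sc) & sc >= thr) - 1L  # 0-based starts; NA = window with N
  }
  res <- list()
  for (i in seq_along(seqs)) {
    codes <- match(strsplit(seqs[[i]], "")[[1]], BASES)
    l <- length(codes)
    fwd <- scan_codes(codes)
    rc <- rev(5L - codes)
    rv <- scan_codes(rc)
    starts <- c(fwd, if (length(rv)) l - rv - w)
    strands <- c(rep("+", length(fwd)), rep("-", length(rv)))
    if (!length(starts)) next
    # recompute integer scores for reporting
    sc <- vapply(seq_along(starts), function(h) {
      s0 <- starts[h]
      cd <- if (strands[h] == "+") codes[(s0 + 1):(s0 + w)]
            else 5L - rev(codes[(s0 + 1):(s0 + w)])
      sum(k[cbind(cd, seq_len(w))])
    }, numeric(1))
    res[[length(res) + 1]] <- data.frame(
      seq_id = names(seqs)[i], start = as.integer(starts),
      end = as.integer(starts + w), strand = strands,
      score = sc * score_dist$step,
      pval = score_dist_p(score_dist, sc),
      stringsAsFactors = FALSE)
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out[order(out$seq_id, out$start, out$strand), , drop = FALSE]
}

#' Motif enrichment between foreground and background peak sets
#'
#' A sequence counts as a hit sequence for a motif iff it carries at
#' least one hit at the scanning threshold. Enrichment is a one-sided
#' Fisher test of hit-sequence counts (foreground vs background);
#' the reversed test gives depletion. BH adjustment is applied across
#' motifs within each direction.
#'
#' @param fg_seqs,bg_seqs foreground and background sequences
#'   (\code{DNAStringSet} or character). Background sets should come
#'   from modules with a complementary temporal pattern to the
#'   foreground (hi vs lo at the same stage).
#' @param pwms list of \code{pwm} objects.
#' @param p_threshold scanner threshold.
#' @param alpha significance level for the call.
#' @return data.frame: motif, fg_hits, fg_n, bg_hits, bg_n,
#'   p_enrich, p_deplete, padj_enrich, padj_deplete, call.
#' @export
module_motif_enrichment <- function(fg_seqs, bg_seqs, pwms,
                                    p_threshold = 1e-4, alpha = 0.05) {
  nf <- length(fg_seqs); nb <- length(bg_seqs)
  if (nf == 0 || nb == 0) stop("empty foreground or background set")
  rows <- lapply(pwms, function(x) {
    sd <- score_pvalues(x)
    a <- length(unique(scan_sequences(x, fg_seqs, p_threshold, sd)$seq_id))
    b <- length(unique(scan_sequences(x, bg_seqs, p_threshold, sd)$seq_id))
    tab <- matrix(c(a, nf - a, b, nb - b), 2, byrow = TRUE)
    data.frame(motif = x$id, fg_hits = a, fg_n = nf,
               bg_hits = b, bg_n = nb,
               p_enrich = fisher.test(tab, alternative = "greater")$p.value,
               p_deplete = fisher.test(tab, alternative = "less")$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj_enrich <- bh_adjust(out$p_enrich)
  out$padj_deplete <- bh_adjust(out$p_deplete)
  out$call <- ifelse(out$padj_enrich < alpha, "enriched",
                     ifelse(out$padj_deplete < alpha, "depleted", "ns"))
  rownames(out) <- NULL
  out
}

#' Read motifs from a MEME-format text file
#'
#' Supports the minimal MEME motif format: version line, optional
#' alphabet/background lines, and one letter-probability matrix per
#' MOTIF block.
#'
#' @param path file path.
#' @param pseudocount pseudocount passed to \code{\link{pwm}}.
#' @return Named list of \code{pwm} objects.
#' @export
read_meme <- function(path, pseudocount = 0.01) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    tok <- strsplit(trimws(lines[bg_at[1] + 1]), "\\s+")[[1]]
    bg <- as.numeric(tok[c(FALSE, TRUE)])
    names(bg) <- tok[c(TRUE, FALSE)]
    bg <- unname(bg[BASES])
  }
  starts <- grep("^MOTIF ", lines)
  out <- list()
  for (s in starts) {
    id <- strsplit(trimws(sub("^MOTIF ", "", lines[s])), "\\s+")[[1]][1]
    hdr <- s + grep("letter-probability matrix", lines[(s + 1):length(lines)])[1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    mat <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4)))
    dimnames(mat) <- NULL
    out[[id]] <- pwm(id, t(mat), bg = bg, pseudocount = pseudocount)
  }
  out
}

#' Write motifs to a MEME-format text file
#'
#' @param pwms list of \code{pwm} objects (sharing one background).
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_meme <- function(pwms, path) {
  bg <- pwms[[1]]$bg
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       bg[1], bg[2], bg[3], bg[4]), ""), con)
  for (x in pwms) {
    writeLines(sprintf("MOTIF %s", x$id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      ncol(x$mat)), con)
    apply(x$mat, 2, function(col)
      writeLines(sprintf(" %.6f %.6f %.6f %.6f",
                         col[1], col[2], col[3], col[4]), con))
    writeLines("", con)
  }
  invisible(path)
}
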