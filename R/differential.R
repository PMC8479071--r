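#' TMM normalization factors
#'
#' Trimmed mean of M-values: for each sample against a reference
#' sample, gene-wise log2 ratios (M) of library-size-scaled counts are
#' trimmed by 30% on M and 5% on absolute intensity (A), and the
#' remaining M-values are averaged with inverse delta-method variance
#' weights. Factors are rescaled so their geometric mean is 1.
#'
#' @param cm a \code{\link{count_matrix}}.
#' @param ref reference sample (column index); default: the sample
#'   whose 75th-percentile count share is closest to the mean across
#'   samples.
#' @param trim_m,trim_a two-sided trim fractions for M and A.
#' @return Numeric vector of per-sample factors (geometric mean 1).
#' @export
tmm_factors <- function(cm, ref = NULL, trim_m = 0.3, trim_a = 0.05) {
  x <- cm$counts
  lib <- cm$lib_sizes
  zero <- which(lib == 0 | colSums(x > 0) == 0)
  if (length(zero))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(x)[zero], collapse = ", "))
  if (is.null(ref)) {
    uq <- apply(x, 2, function(y) quantile(y, 0.75)) / lib
    ref <- which.min(abs(uq - mean(uq)))
  }
  f <- vapply(seq_len(ncol(x)), function(j) {
    tmm_pair(x[, j], x[, ref], lib[j], lib[ref], trim_m, trim_a)
  }, numeric(1))
  f / exp(mean(log(f)))
}

# one sample against the reference; returns the unscaled factor
tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  # delta-method variance of M for binomial counts
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  keep2 <- rank(m) >= lo_m & rank(m) <= hi_m &
           rank(a) >= lo_a & rank(a) <= hi_a
  f <- sum(m[keep2] / w[keep2]) / sum(1 / w[keep2])
  if (!is.finite(f)) f <- 0
  if (abs(f) < 1e-6) f <- 0
  2^f
}

#' Counts per million (CPM)
#'
#' \code{count / (library size x normalization factor) x 1e6}.
#'
#' @param cm a \code{\link{count_matrix}}.
#' @return Real matrix of the same shape as the counts.
#' @export
cpm <- function(cm) {
  eff <- effective_lib_sizes(cm)
  if (any(eff <= 0)) stop("library sizes must be positive")
  sweep(cm$counts, 2, eff, "/") * 1e6
}

#' Filter features by biotype and expression level
#'
#' Removes small-ncRNA biotypes (genes only) and keeps a feature iff
#' its CPM is >= \code{cpm_min} in all replicates of at least one
#' stage.
#'
#' @param cm a \code{\link{count_matrix}}.
#' @param biotypes optional named character vector (feature id ->
#'   biotype). Features missing from the table are retained with a
#'   warning. NULL skips the biotype filter (peak matrices).
#' @param drop_biotypes biotypes removed outright.
#' @param cpm_min CPM threshold; NULL skips the expression filter.
#' @return The filtered \code{count_matrix}.
#' @export
filter_features <- function(cm,
                            biotypes = NULL,
                            drop_biotypes = c("snoRNA", "miRNA", "miscRNA",
                                              "scRNA", "scaRNA"),
                            cpm_min = 1) {
  keep <- rep(TRUE, nrow(cm$counts))
  ids <- rownames(cm$counts)
  if (!is.null(biotypes)) {
    known <- ids %in% names(biotypes)
    if (any(!known))
      warning(sum(!known), " feature(s) with unknown biotype retained")
    keep[known] <- !(biotypes[ids[known]] %in% drop_biotypes)
  }
  if (!is.null(cpm_min)) {
    z <- cpm(cm) >= cpm_min
    stage <- cm$samples$stage
    ok_stage <- vapply(unique(stage), function(s) {
      rowSums(!z[, stage == s, drop = FALSE]) == 0
    }, logical(nrow(z)))
    keep <- keep & rowSums(ok_stage) > 0
  }
  subset_features(cm, keep)
}

#' Moment-based NB dispersion estimates with shrinkage
#'
#' Per-feature method-of-moments dispersion (pooled over stages),
#' shrunk toward the common (median) dispersion and floored at 0.
#'
#' @param cm a \code{\link{count_matrix}} with >= 2 replicates per
#'   stage.
#' @param shrink weight on the common dispersion in [0, 1].
#' @return Named numeric vector of per-feature dispersions.
#' @export
estimate_dispersion <- function(cm, shrink = 0.5) {
  eff <- effective_lib_sizes(cm)
  # rescale all samples to the mean effective depth so that within-stage
  # mean/variance are comparable
  y <- sweep(cm$counts, 2, mean(eff) / eff, "*")
  stage <- cm$samples$stage
  num <- 0; den <- 0
  for (s in unique(stage)) {
    ys <- y[, stage == s, drop = FALSE]
    if (ncol(ys) < 2) stop("need >= 2 replicates per stage")
    m <- rowMeans(ys)
    v <- apply(ys, 1, var)
    num <- num + (v - m)
    den <- den + m^2
  }
  raw <- ifelse(den > 0, num / den, 0)
  common <- max(0, median(raw))
  phi <- pmax(0, (1 - shrink) * pmax(0, raw) + shrink * common)
  setNames(phi, rownames(cm$counts))
}

#' NB exact-style pairwise test between two stages
#'
#' For each feature, tests the group-A sum against its conditional
#' distribution given the two-group total, modelling group sums as
#' independent negative binomials (size = replicates / dispersion)
#' with null means proportional to the effective library sizes. The
#' two-sided p-value sums conditional probabilities not exceeding that
#' of the observed split (Fisher-style). At dispersion 0 this is the
#' exact binomial conditional (Poisson) test. The log2 fold change
#' (B over A) uses factor-normalized group means with a 0.5 prior
#' count.
#'
#' @param cm a \code{\link{count_matrix}}.
#' @param contrast character of length 2: (stage A, stage B).
#' @param dispersion per-feature dispersion vector (recycled).
#' @param prior_count prior added to each group sum for the fold
#'   change.
#' @return data.frame: feature, logFC, pvalue.
#' @export
nb_pairwise_test <- function(cm, contrast, dispersion = 0,
                             prior_count = 0.5) {
  stopifnot(length(contrast) == 2)
  stage <- cm$samples$stage
  if (!all(contrast %in% stage))
    stop("stage absent from matrix: ",
         paste(setdiff(contrast, stage), collapse = ", "))
  ia <- stage == contrast[1]; ib <- stage == contrast[2]
  eff <- effective_lib_sizes(cm)
  la <- sum(eff[ia]); lb <- sum(eff[ib])
  na <- sum(ia); nb <- sum(ib)
  sa <- rowSums(cm$counts[, ia, drop = FALSE])
  sb <- rowSums(cm$counts[, ib, drop = FALSE])
  phi <- rep_len(dispersion, length(sa))
  p_null <- la / (la + lb)
  pv <- vapply(seq_along(sa), function(i) {
    cond_test_p(sa[i], sb[i], phi[i], p_null, na, nb)
  }, numeric(1))
  lfc <- log2(((sb + prior_count) / lb) / ((sa + prior_count) / la))
  data.frame(feature = rownames(cm$counts), logFC = lfc, pvalue = pv,
             stringsAsFactors = FALSE, row.names = NULL)
}

# conditional two-sided p for observed split (sa, sb) of total t
cond_test_p <- function(sa, sb, phi, p_null, na, nb) {
  t <- sa + sb
  if (t == 0) return(1)
  k <- 0:t
  if (phi <= 0) {
    logp <- dbinom(k, t, p_null, log = TRUE)
  } else {
    mu_a <- t * p_null; mu_b <- t * (1 - p_null)
    logp <- dnbinom(k, size = na / phi, mu = mu_a, log = TRUE) +
            dnbinom(t - k, size = nb / phi, mu = mu_b, log = TRUE)
    logp <- logp - log(sum(exp(logp - max(logp)))) - max(logp)
  }
  obs <- logp[sa + 1]
  # relative tolerance guards against ties broken by roundoff
  min(1, sum(exp(logp[logp <= obs + 1e-7])))
}

#' Call differential features across all stage pairs
#'
#' Runs \code{\link{nb_pairwise_test}} on every pair of stages,
#' BH-adjusts p-values within each contrast, and flags a feature as
#' significant in a contrast iff |linear fold change| >= \code{fc}
#' and adjusted p <= \code{alpha}. The differential set (DEGs/DACs)
#' is the union over contrasts.
#'
#' @param cm a \code{\link{count_matrix}} with three stages.
#' @param fc linear fold-change threshold.
#' @param alpha adjusted-p threshold.
#' @param dispersion per-feature dispersions; "auto" estimates them
#'   with \code{\link{estimate_dispersion}}.
#' @return An object of class \code{differential_result}: list with
#'   \code{table} (feature, contrast, logFC, pvalue, padj,
#'   significant) and \code{differential} (union feature ids).
#' @export
call_differential <- function(cm, fc = 1.5, alpha = 0.05,
                              dispersion = "auto") {
  st <- stages_of(cm)
  if (length(st) != 3) stop("expected exactly three stages")
  if (identical(dispersion, "auto")) dispersion <- estimate_dispersion(cm)
  pairs <- list(st[c(1, 2)], st[c(2, 3)], st[c(1, 3)])
  tabs <- lapply(pairs, function(ct) {
    r <- nb_pairwise_test(cm, ct, dispersion)
    r$contrast <- paste(ct, collapse = "/")
    r$padj <- p.adjust(r$pvalue, method = "BH")
    r$significant <- abs(r$logFC) >= log2(fc) & r$padj <= alpha
    r
  })
  tab <- do.call(rbind, tabs)
  structure(list(
    table = tab[, c("feature", "contrast", "logFC", "pvalue", "padj",
                    "significant")],
    differential = unique(tab$feature[tab$significant])
  ), class = "differential_result")
}

#' @export
print.differential_result <- function(x, ...) {
  cat(sprintf("differential_result: %d contrasts, %d differential features\n",
              length(unique(x$table$contrast)), length(x$differential)))
  invisible(x)
}
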