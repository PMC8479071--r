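#' Construct a count matrix with stage/replicate metadata
#'
#' Container for integer feature-by-sample counts (genes or ATAC peaks)
#' together with the per-sample developmental stage, replicate index,
#' library sizes and normalization factors.
#'
#' @param counts integer matrix, features x samples, with rownames
#'   (feature ids) and colnames (sample ids).
#' @param stages character or factor of length \code{ncol(counts)}
#'   giving the developmental stage of each sample.
#' @param replicates optional integer replicate index per sample;
#'   defaults to 1..n within each stage in column order.
#' @param norm_factors optional positive per-sample normalization
#'   factors (default 1; see \code{\link{tmm_factors}}).
#' @return An object of class \code{count_matrix}: a list with elements
#'   \code{counts}, \code{samples} (data.frame of sample, stage,
#'   replicate), \code{lib_sizes} and \code{norm_factors}.
#' @export
count_matrix <- function(counts, stages, replicates = NULL,
                         norm_factors = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("f%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  if (any(counts < 0)) stop("counts must be non-negative")
  stages <- as.character(stages)
  if (length(stages) != ncol(counts))
    stop("length(stages) must equal ncol(counts)")
  if (is.null(replicates)) {
    replicates <- stats::ave(seq_along(stages), stages, FUN = seq_along)
  }
  if (is.null(norm_factors)) norm_factors <- rep(1, ncol(counts))
  if (any(norm_factors <= 0)) stop("norm_factors must be positive")
  structure(list(
    counts = counts,
    samples = data.frame(sample = colnames(counts), stage = stages,
                         replicate = as.integer(replicates),
                         stringsAsFactors = FALSE),
    lib_sizes = colSums(counts),
    norm_factors = as.numeric(norm_factors)
  ), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples (%d stages)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$samples$stage))))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

stages_of <- function(cm) unique(cm$samples$stage)

# subset features, keeping metadata consistent
subset_features <- function(cm, keep) {
  cm$counts <- cm$counts[keep, , drop = FALSE]
  # library sizes reflect the original sequencing depth, not the subset
  cm
}

# effective library sizes: raw depth times TMM factor
effective_lib_sizes <- function(cm) cm$lib_sizes * cm$norm_factors
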