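#' The six binary temporal seed patterns
#'
#' With two signal states (on/off) and three stages there are 2^3
#' trajectories; the two non-differential ones, (0,0,0) and (1,1,1),
#' are excluded and the remaining six are the k-means seeds, in fixed
#' order.
#'
#' @param n_stages must be 3.
#' @return 6 x 3 binary matrix with pattern-string rownames
#'   ("100", "010", "001", "011", "101", "110").
#' @export
seed_patterns <- function(n_stages = 3) {
  if (n_stages != 3) stop("only 3 stages are supported")
  m <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
             c(0, 1, 1), c(1, 0, 1), c(1, 1, 0))
  rownames(m) <- apply(m, 1, paste, collapse = "")
  colnames(m) <- paste0("stage", 1:3)
  m
}

#' Min-max scale stage trajectories to [0, 1]
#'
#' Per feature, subtracts the minimum across the three stages and
#' divides by the maximum of the shifted values. Constant trajectories
#' map to (0, 0, 0).
#'
#' @param x numeric 3-vector, or a features x 3 matrix.
#' @return Scaled object of the same shape.
#' @export
scale_trajectory <- function(x) {
  if (is.null(dim(x))) return(drop(scale_trajectory(rbind(x))))
  lo <- apply(x, 1, min)
  shifted <- x - lo
  hi <- apply(shifted, 1, max)
  hi[hi == 0] <- 1  # constant rows -> zeros
  out <- shifted / hi
  dimnames(out) <- dimnames(x)
  out
}

#' Per-stage mean signal from a count matrix
#'
#' Mean over replicates of log2(CPM + 1), one column per stage.
#'
#' @param cm a \code{\link{count_matrix}}.
#' @param features optional subset of feature ids.
#' @return features x stages real matrix.
#' @export
stage_means <- function(cm, features = NULL) {
  z <- log2(cpm(cm) + 1)
  if (!is.null(features)) z <- z[features, , drop = FALSE]
  st <- cm$samples$stage
  out <- vapply(unique(st), function(s)
    rowMeans(z[, st == s, drop = FALSE]), numeric(nrow(z)))
  colnames(out) <- unique(st)
  out
}

#' Seeded k-means on scaled trajectories
#'
#' Lloyd iterations with Euclidean distance starting from the six
#' fixed binary seeds: a single deterministic run with no random
#' restarts. A cluster left empty keeps its seed as centroid;
#' assignment ties go to the lowest seed index.
#'
#' @param x features x 3 matrix of scaled trajectories.
#' @param seeds initial centroids (default \code{\link{seed_patterns}()}).
#' @param max_iter,tol convergence controls (maximum iterations;
#'   centroid-shift tolerance).
#' @return An object of class \code{module_set}: list with
#'   \code{assignment} (named integer, 1..k), \code{centroids},
#'   \code{seeds}, \code{iterations}, \code{converged}.
#' @export
seeded_kmeans <- function(x, seeds = seed_patterns(), max_iter = 300,
                          tol = 1e-6) {
  x <- as.matrix(x)
  k <- nrow(seeds)
  if (nrow(x) < k) stop("fewer features than clusters")
  centroids <- unname(seeds)
  assign_step <- function(cen) {
    d <- outer(rowSums(x^2), rep(1, k)) -
      2 * x %*% t(cen) + outer(rep(1, nrow(x)), rowSums(cen^2))
    max.col(-d, ties.method = "first")  # lowest index wins ties
  }
  iter <- 0; converged <- FALSE
  repeat {
    iter <- iter + 1
    cl <- assign_step(centroids)
    new_cen <- centroids
    for (j in seq_len(k)) {
      if (any(cl == j)) new_cen[j, ] <- colMeans(x[cl == j, , drop = FALSE])
      else new_cen[j, ] <- seeds[j, ]  # empty cluster keeps its seed
    }
    shift <- max(abs(new_cen - centroids))
    centroids <- new_cen
    if (shift < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  cl <- assign_step(centroids)
  structure(list(
    assignment = setNames(cl, rownames(x)),
    centroids = centroids,
    seeds = seeds,
    iterations = iter,
    converged = converged
  ), class = "module_set")
}

#' Label modules from their initializing seeds
#'
#' A single-1 seed at stage s is labelled "s^hi" (highest relative
#' signal at s); a single-0 seed at stage s is labelled "s^lo".
#'
#' @param ms a \code{module_set}.
#' @param stage_names character of length 3.
#' @return The \code{module_set} with \code{labels} (per cluster) and
#'   \code{module} (per feature label vector) added.
#' @export
label_modules <- function(ms, stage_names) {
  stopifnot(length(stage_names) == 3)
  labels <- apply(ms$seeds, 1, function(p) {
    if (sum(p) == 1) paste0(stage_names[which(p == 1)], "^hi")
    else if (sum(p) == 2) paste0(stage_names[which(p == 0)], "^lo")
    else stop("seed is not a single-1 or single-0 pattern")
  })
  ms$labels <- unname(labels)
  ms$module <- setNames(ms$labels[ms$assignment], names(ms$assignment))
  ms
}

#' Silhouette scores for a clustering
#'
#' Standard silhouette s = (b - a) / max(a, b) with Euclidean
#' distance, where a is the mean distance to the point's own cluster
#' and b the smallest mean distance to another cluster. Members of
#' singleton clusters score 0.
#'
#' @param x feature matrix (rows = points).
#' @param assignment integer cluster labels.
#' @return List with \code{scores} (per point) and \code{average}.
#' @export
silhouette_scores <- function(x, assignment) {
  x <- as.matrix(x)
  n <- nrow(x)
  cls <- sort(unique(assignment))
  if (length(cls) < 2) stop("need >= 2 non-empty clusters")
  d <- as.matrix(dist(x))
  sizes <- table(factor(assignment, levels = cls))
  # mean distance from every point to every cluster
  md <- vapply(cls, function(j)
    rowSums(d[, assignment == j, drop = FALSE]) / sizes[[as.character(j)]],
    numeric(n))
  s <- numeric(n)
  for (i in seq_len(n)) {
    j <- match(assignment[i], cls)
    nj <- sizes[[j]]
    if (nj == 1) { s[i] <- 0; next }
    a <- md[i, j] * nj / (nj - 1)  # exclude self
    b <- min(md[i, -j])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  list(scores = setNames(s, rownames(x)), average = mean(s))
}

#' Cluster stage trajectories into labelled temporal modules
#'
#' Convenience wrapper: min-max scaling, seeded k-means, module
#' labelling and silhouette validation in one call.
#'
#' @param means features x 3 matrix of per-stage mean signal
#'   (e.g. from \code{\link{stage_means}}).
#' @param stage_names stage names for labelling (default: column
#'   names of \code{means}).
#' @param ... passed to \code{\link{seeded_kmeans}}.
#' @return A labelled \code{module_set} with \code{silhouette} and
#'   \code{avg_silhouette} fields and the scaled matrix in
#'   \code{scaled}.
#' @export
cluster_trajectories <- function(means, stage_names = colnames(means),
                                 ...) {
  scaled <- scale_trajectory(means)
  ms <- seeded_kmeans(scaled, ...)
  ms <- label_modules(ms, stage_names)
  sil <- silhouette_scores(scaled, ms$assignment)
  ms$silhouette <- sil$scores
  ms$avg_silhouette <- sil$average
  ms$scaled <- scaled
  ms
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set: %d features in %d modules",
              length(x$assignment), nrow(x$centroids)))
  if (!is.null(x$avg_silhouette))
    cat(sprintf(", average silhouette %.3f", x$avg_silhouette))
  cat("\n")
  invisible(x)
}
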