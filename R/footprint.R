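#' Motif-centered aggregate cut-count profile
#'
#' Averages a per-base cut-count track over windows centered on motif
#' sites (half-width flank on each side of the motif core).
#' Minus-strand windows are reversed before averaging; positions
#' absent from the track count as 0.
#'
#' @param track data.frame (chrom, pos, count): single-base cut
#'   counts, 0-based positions.
#' @param sites data.frame (seq_id or chrom, start, end, strand) of
#'   motif cores, 0-based half-open.
#' @param half_width flank width in bp on each side (default 100,
#'   i.e. a 200-bp window plus the motif core).
#' @param smooth_window moving-average window for the smoothed
#'   profile.
#' @return An object of class \code{aggregate_profile}: list with
#'   \code{profile}, \code{smoothed}, \code{positions} (relative to
#'   core start), \code{n_sites}, \code{half_width},
#'   \code{motif_width}.
#' @export
aggregate_profile <- function(track, sites, half_width = 100,
                              smooth_window = 5) {
  if (!nrow(sites)) stop("zero sites")
  chrom_col <- if ("chrom" %in% names(sites)) "chrom" else "seq_id"
  widths <- sites$end - sites$start
  if (length(unique(widths)) != 1)
    stop("sites must share one motif width")
  w <- widths[1]
  len <- 2L * half_width + w
  lookup <- split(track[c("pos", "count")], track$chrom)
  acc <- numeric(len)
  for (i in seq_len(nrow(sites))) {
    pos <- (sites$start[i] - half_width):(sites$end[i] + half_width - 1)
    tr <- lookup[[sites[[chrom_col]][i]]]
    v <- numeric(len)
    if (!is.null(tr)) {
      j <- match(pos, tr$pos)
      v[!is.na(j)] <- tr$count[j[!is.na(j)]]
    }
    if (!is.null(sites$strand) && sites$strand[i] == "-") v <- rev(v)
    acc <- acc + v
  }
  profile <- acc / nrow(sites)
  structure(list(
    profile = profile,
    smoothed = smooth_profile(profile, smooth_window),
    positions = seq(-half_width, w + half_width - 1),
    n_sites = nrow(sites),
    half_width = half_width,
    motif_width = w
  ), class = "aggregate_profile")
}

#' Centered moving average
#'
#' @param x numeric vector.
#' @param window odd window size; edges use truncated windows.
#' @return Smoothed vector of the same length.
#' @export
smooth_profile <- function(x, window = 5) {
  if (window %% 2 != 1) stop("window must be odd")
  n <- length(x)
  if (window > n) stop("window larger than profile")
  h <- (window - 1) / 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Footprint depth of an aggregate profile
#'
#' depth = 1 - (mean cuts in the motif core) / (mean cuts in the
#' flanks), where the flank is the outermost \code{flank} bp on each
#' side of the window. 0 means no protection, 1 a fully protected
#' core.
#'
#' @param ap an \code{\link{aggregate_profile}}.
#' @param flank flank width in bp used on each side.
#' @return List with \code{flank_mean}, \code{core_mean},
#'   \code{depth}.
#' @export
footprint_depth <- function(ap, flank = 50) {
  n <- length(ap$profile)
  stopifnot(flank >= 1, 2 * flank < n)
  core_idx <- which(ap$positions >= 0 & ap$positions < ap$motif_width)
  flank_idx <- c(seq_len(flank), seq(n - flank + 1, n))
  fm <- mean(ap$profile[flank_idx])
  cm <- mean(ap$profile[core_idx])
  if (fm <= 0) stop("zero flank signal: depth undefined")
  list(flank_mean = fm, core_mean = cm, depth = 1 - cm / fm)
}
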