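# shared fixture builders; everything is generated in code

# count matrix over 2 stages x 3 reps with realistic library depth:
# `feature_rows` is a named list of per-sample count vectors that get
# stacked on top of a Poisson background so library sizes are not
# dominated by the features under test
two_stage_matrix <- function(feature_rows, n_background = 500,
                             bg_mean = 100, seed = 99) {
  withr::with_seed(seed, {
    bg <- matrix(rpois(n_background * 6, bg_mean), n_background)
    rownames(bg) <- sprintf("bg%04d", seq_len(n_background))
    m <- rbind(do.call(rbind, feature_rows), bg)
    count_matrix(m, stages = rep(c("A", "B"), each = 3))
  })
}

# a sharply informative PWM of the given width (useful for planting)
strong_pwm <- function(id = "m1", width = 8, p = 0.97,
                       consensus_codes = rep(1, width)) {
  mat <- matrix((1 - p) / 3, 4, width)
  mat[cbind(consensus_codes, seq_len(width))] <- p
  pwm(id, mat)
}

# deterministic PWM (probability-1 columns)
det_pwm <- function(id = "d", width = 6, codes = rep(1, width)) {
  mat <- matrix(0, 4, width)
  mat[cbind(codes, seq_len(width))] <- 1
  pwm(id, mat)
}

# five-taxon tree used across alignment tests; chicken is the focal
# terminal branch
fixture_tree <- function() {
  "(((mouse:0.2,rat:0.15):0.1,human:0.25):0.15,(chicken:0.3,zebrafinch:0.25):0.1);"
}

# brute-force score distribution over all 4^w words (oracle for the DP)
enumerate_scores <- function(k_mat, bg = rep(0.25, 4)) {
  w <- ncol(k_mat)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- rowSums(matrix(k_mat[cbind(as.vector(words),
                                   rep(seq_len(w), each = nrow(words)))],
                       nrow(words)))
  pr <- apply(words, 1, function(cd) prod(bg[cd]))
  list(scores = sc, probs = pr)
}
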