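test_that("TMM factors are 1 for identical or purely depth-scaled libraries", {
  withr::with_seed(1, {
    y <- matrix(rpois(1000 * 2, 100), 1000)
    cm <- count_matrix(cbind(y[, 1], y[, 1]), stages = c("A", "B"))
    expect_equal(tmm_factors(cm), c(1, 1))
    cm2 <- count_matrix(cbind(y[, 1], 2L * y[, 1]), stages = c("A", "B"))
    expect_equal(tmm_factors(cm2), c(1, 1))
  })
})

test_that("TMM factor matches a straightforward trimmed-mean oracle on a spiked library", {
  withr::with_seed(2, {
    n <- 2000
    base <- rpois(n, 100)
    spiked <- base
    spike_idx <- 1:100  # 5% of features get a compositional spike
    spiked[spike_idx] <- round(base[spike_idx] * 1.1 * 10)
    cm <- count_matrix(cbind(base, spiked), stages = c("A", "B"))
    f <- tmm_factors(cm, ref = 1)

    # independent plain-R restatement of the doubly-trimmed weighted mean
    obs <- spiked; ref <- base
    n_obs <- sum(obs); n_ref <- sum(ref)
    keep <- obs > 0 & ref > 0
    obs <- obs[keep]; ref <- ref[keep]
    m <- log2((obs / n_obs) / (ref / n_ref))
    a <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
    w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
    nn <- length(m)
    lo_m <- floor(nn * 0.3) + 1; hi_m <- nn + 1 - lo_m
    lo_a <- floor(nn * 0.05) + 1; hi_a <- nn + 1 - lo_a
    kk <- rank(m) >= lo_m & rank(m) <= hi_m &
      rank(a) >= lo_a & rank(a) <= hi_a
    f2_raw <- 2^(sum(m[kk] / w[kk]) / sum(1 / w[kk]))
    expected <- c(1, f2_raw) / exp(mean(log(c(1, f2_raw))))
    expect_equal(f, expected, tolerance = 1e-10)
  })
})

test_that("TMM agrees with the edgeR reference implementation", {
  skip_if_not_installed("edgeR")
  withr::with_seed(3, {
    y <- matrix(rpois(3000, 80), 1000)
    y[1:50, 2] <- rpois(50, 2000)
    cm <- count_matrix(y, stages = c("A", "A", "B"))
    expect_equal(tmm_factors(cm),
                 unname(edgeR::calcNormFactors(y, method = "TMM")),
                 tolerance = 1e-8)
  })
})

test_that("all-zero samples are rejected by name", {
  y <- cbind(s_ok = c(5L, 3L), s_bad = c(0L, 0L))
  cm <- count_matrix(y, stages = c("A", "B"))
  expect_error(tmm_factors(cm), "s_bad")
})

test_that("CPM has the stated scale and invariances", {
  y <- rbind(f1 = c(100L, 0L), f2 = c(999900L, 1000000L))
  cm <- count_matrix(y, stages = c("A", "B"))
  z <- cpm(cm)
  expect_equal(z["f1", 1], 100)  # effective library 1e6
  expect_equal(z["f1", 2], 0)
  # doubling counts (and hence library size) leaves CPM unchanged
  cm2 <- count_matrix(2L * y, stages = c("A", "B"))
  expect_equal(cpm(cm2), cpm(cm))
  # columns sum to 1e6
  expect_equal(unname(colSums(z)), c(1e6, 1e6))
})

test_that("feature filter applies the biotype and per-stage CPM rules", {
  # library size fixed at 1e6 so stored values read directly as CPM
  counts <- rbind(
    kept    = c(1.2, 1.5, 2.0, 0, 0, 0),    # >=1 in all reps of stage A
    removed = c(1.2, 0.9, 2.0, 1.2, 0.9, 2.0),  # a failing rep in each stage
    mirna   = c(500, 500, 500, 500, 500, 500)
  )
  counts <- rbind(counts, filler = 1e6 - colSums(counts))
  cm <- count_matrix(counts, stages = rep(c("A", "B"), each = 3))
  bio <- c(kept = "protein_coding", removed = "protein_coding",
           mirna = "miRNA", filler = "protein_coding")
  out <- filter_features(cm, biotypes = bio)
  expect_true("kept" %in% rownames(out$counts))
  expect_false("removed" %in% rownames(out$counts))
  expect_false("mirna" %in% rownames(out$counts))
  # unknown biotype warns but retains
  expect_warning(res <- filter_features(cm, biotypes = bio[-1]),
                 "unknown biotype")
  expect_true("kept" %in% rownames(res$counts))
})

test_that("dispersion estimates recover the simulation truth", {
  ids <- sprintf("f%04d", 1:2000)
  flat <- setNames(rep("flat", 2000), ids)
  cm0 <- generate_counts(flat, dispersion = 0, seed = 4)
  expect_lt(median(estimate_dispersion(cm0)), 0.02)

  cm2 <- generate_counts(flat, dispersion = 0.2, seed = 5)
  expect_lt(abs(median(estimate_dispersion(cm2)) - 0.2), 0.05)

  # constant counts -> zero dispersion
  cmc <- count_matrix(matrix(5L, 3, 6), stages = rep(c("A", "B", "C"), each = 2))
  expect_equal(unname(estimate_dispersion(cmc)), rep(0, 3))
})

test_that("NB pairwise test matches the binomial conditional oracle at dispersion 0", {
  cm <- two_stage_matrix(list(f1 = c(3L, 5L, 4L, 30L, 28L, 35L)))
  r <- nb_pairwise_test(cm, c("A", "B"), dispersion = 0)
  # oracle: conditional binomial on the group sums with the library share
  eff <- cm$lib_sizes * cm$norm_factors
  la <- sum(eff[1:3]); lb <- sum(eff[4:6])
  t <- 12L + 93L
  pr <- dbinom(0:t, t, la / (la + lb))
  p_oracle <- sum(pr[pr <= pr[12 + 1] * (1 + 1e-7)])
  expect_equal(r$pvalue[1], p_oracle, tolerance = 1e-12)
  expect_lt(r$pvalue[1], 0.01)
})

test_that("identical groups give p = 1 and logFC 0; contrast swap negates logFC", {
  cm <- two_stage_matrix(list(f1 = c(7L, 7L, 7L, 7L, 7L, 7L)),
                         seed = 6)
  # make both effective libraries equal by construction
  cm$counts[2, ] <- cm$counts[2, 1]
  cm$counts[-c(1, 2), ] <- cm$counts[-c(1, 2), 1]
  cm <- count_matrix(cm$counts, stages = rep(c("A", "B"), each = 3))
  r <- nb_pairwise_test(cm, c("A", "B"), dispersion = 0.1)
  expect_equal(r$pvalue[1], 1)
  expect_equal(r$logFC[1], 0)

  cm2 <- two_stage_matrix(list(f1 = c(3L, 5L, 4L, 30L, 28L, 35L)), seed = 7)
  ab <- nb_pairwise_test(cm2, c("A", "B"), dispersion = 0.05)
  ba <- nb_pairwise_test(cm2, c("B", "A"), dispersion = 0.05)
  expect_equal(ab$logFC, -ba$logFC)
  expect_equal(ab$pvalue, ba$pvalue)
})

test_that("the fold-change gate keeps sub-1.5x features out regardless of p", {
  withr::with_seed(8, {
    ids <- sprintf("f%04d", 1:300)
    truth <- setNames(rep("flat", 300), ids)
    cm <- generate_counts(truth, baseline_mean = 2000, dispersion = 0,
                          seed = 9)
    # impose an exact 1.4x shift on one feature: highly significant p,
    # but below the linear FC threshold
    st <- cm$samples$stage
    cm$counts[1, st != "S1"] <- round(cm$counts[1, st != "S1"] * 1.38)
    dr <- call_differential(cm, dispersion = 0)
    tab <- dr$table[dr$table$feature == ids[1], ]
    expect_true(any(tab$pvalue < 1e-6))
    expect_true(all(abs(tab$logFC) < log2(1.5)))
    expect_false(ids[1] %in% dr$differential)
  })
})

test_that("a feature significant in one contrast joins the union", {
  withr::with_seed(10, {
    ids <- sprintf("f%04d", 1:500)
    truth <- setNames(rep("flat", 500), ids)
    cm <- generate_counts(truth, baseline_mean = 100, dispersion = 0,
                          seed = 11)
    st <- cm$samples$stage
    # 4x only at stage S3: significant in S1/S3 and S2/S3
    cm$counts[1, st == "S3"] <- rpois(3, 400)
    dr <- call_differential(cm, dispersion = 0)
    tab <- dr$table[dr$table$feature == ids[1], ]
    expect_true(any(tab$significant))
    expect_false(all(tab$significant))
    expect_true(ids[1] %in% dr$differential)
  })
})

test_that("BH-adjusted p-values are monotone and bounded in every contrast", {
  ids <- sprintf("f%04d", 1:400)
  truth <- make_planted_truth(ids, 60, seed = 12)
  cm <- generate_counts(truth, dispersion = 0.1, seed = 13)
  dr <- call_differential(cm)
  for (ct in unique(dr$table$contrast)) {
    tab <- dr$table[dr$table$contrast == ct, ]
    expect_true(all(tab$padj >= tab$pvalue))
    expect_true(all(tab$padj <= 1))
    o <- order(tab$pvalue)
    expect_true(all(diff(tab$padj[o]) >= -1e-12))
  }
})
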