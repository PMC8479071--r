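test_that("nearest-gene assignment uses midpoint, sign and tie conventions", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      tss = c(160, 500), strand = c("+", "+"))
  peaks <- data.frame(peak_id = "p1", chrom = "chr1",
                      start = 100, end = 200)
  m <- assign_nearest_gene(peaks, genes)
  expect_equal(m$gene_id, "gA")
  expect_equal(m$distance, -10)  # midpoint 150 is upstream of TSS 160
  expect_false(m$tie)

  # minus-strand gene flips the sign
  genes2 <- genes; genes2$strand <- c("-", "-")
  expect_equal(assign_nearest_gene(peaks, genes2)$distance, 10)

  # exact tie: lexicographically smaller id wins, flagged
  genes3 <- data.frame(gene_id = c("gB", "gA"), chrom = "chr1",
                       tss = c(100, 200), strand = "+")
  peaks3 <- data.frame(peak_id = "p1", chrom = "chr1",
                       start = 100, end = 200)
  m3 <- assign_nearest_gene(peaks3, genes3)
  expect_equal(m3$gene_id, "gA")
  expect_true(m3$tie)

  # peak on a gene-less chromosome: unmapped with warning
  peaks4 <- rbind(peaks3, data.frame(peak_id = "p2", chrom = "chr2",
                                     start = 0, end = 10))
  expect_warning(m4 <- assign_nearest_gene(peaks4, genes3), "unmapped")
  expect_true(is.na(m4$gene_id[m4$peak_id == "p2"]))
})

test_that("planted peak-gene coupling is recovered exactly", {
  withr::with_seed(30, {
    g <- generate_genome(1, 2e6, n_genes = 40, n_peaks = 120,
                         peak_width = 400, seed = 31)
    # plant: move 30 peaks within 10 kb of a partner TSS
    partners <- sample(g$genes$gene_id, 30)
    tss <- g$genes$tss[match(partners, g$genes$gene_id)]
    g$peaks$start[1:30] <- pmax(0, tss + sample(c(-5000, 5000), 30,
                                                replace = TRUE))
    g$peaks$end[1:30] <- g$peaks$start[1:30] + 400
    # ensure no other TSS closer: separation of random genes on 2 Mb is
    # typically >> 10 kb; verify against the truth only where unambiguous
    m <- assign_nearest_gene(g$peaks, g$genes)
    hit <- m$gene_id[1:30] == partners
    d_true <- abs((g$peaks$start[1:30] + g$peaks$end[1:30]) / 2 - tss)
    other_ok <- vapply(1:30, function(i) {
      d_all <- abs((g$peaks$start[i] + g$peaks$end[i]) / 2 - g$genes$tss)
      sum(d_all <= d_true[i]) == 1
    }, logical(1))
    expect_true(all(hit[other_ok]))
    expect_gt(mean(other_ok), 0.5)
  })
})

test_that("Fisher 2x2 matches hypergeometric enumeration", {
  r <- fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2))
  expect_equal(r$p, 0.1, tolerance = 1e-12)

  r2 <- fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2))
  expect_equal(r2$odds_ratio, 1)
  expect_equal(r2$p, 1)

  tab <- matrix(c(10, 90, 5, 895), 2, byrow = TRUE)
  r3 <- fisher_exact_2x2(tab)
  expect_equal(r3$odds_ratio, (10 * 895) / (90 * 5))
  # brute-force enumeration over all tables with the observed margins
  rs <- 100; cs <- 15; n <- 1000
  ks <- max(0, rs + cs - n):min(rs, cs)
  pr <- dhyper(ks, cs, n - cs, rs)
  p_bf <- sum(pr[pr <= pr[ks == 10] * (1 + 1e-7)])
  expect_equal(r3$p, p_bf, tolerance = 1e-12)

  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "all-zero")
})

test_that("2x2 invariances: transpose keeps p, row swap inverts OR", {
  withr::with_seed(32, {
    for (i in 1:20) {
      tab <- matrix(rpois(4, 20) + 1, 2)
      a <- fisher_exact_2x2(tab)
      b <- fisher_exact_2x2(t(tab))
      cc <- fisher_exact_2x2(tab[2:1, ])
      expect_equal(a$p, b$p, tolerance = 1e-9)
      expect_equal(a$odds_ratio * cc$odds_ratio, 1, tolerance = 1e-9)
    }
  })
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.7), 0.7)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("module association recovers planted coupling and stays null under permutation", {
  withr::with_seed(33, {
    mods <- paste0("m", 1:6)
    gene_modules <- setNames(sample(mods, 300, replace = TRUE),
                             sprintf("g%04d", 1:300))
    peak_modules <- setNames(sample(mods, 600, replace = TRUE),
                             sprintf("p%05d", 1:600))
    map <- data.frame(peak_id = names(peak_modules),
                      gene_id = sample(names(gene_modules), 600,
                                       replace = TRUE),
                      distance = 0, tie = FALSE)
    m1p <- names(peak_modules)[peak_modules == "m1"]
    m1g <- names(gene_modules)[gene_modules == "m1"]
    map$gene_id[map$peak_id %in% m1p] <- sample(m1g, length(m1p),
                                                replace = TRUE)
    am <- module_association(peak_modules, gene_modules, map)
    cell <- am[am$dac_module == "m1" & am$deg_module == "m1", ]
    expect_equal(cell$direction, "enriched")
    expect_lt(cell$padj, 0.05)
    expect_gt(cell$heat, 0)
    # contingency conservation: every cell's table sums to the universe
    expect_true(all(rowSums(am[, c("n11", "n12", "n21", "n22")]) ==
                      nrow(map)))
    # the coupled module's row is depleted (or ns) away from its partner:
    # all its peaks point at m1 genes, so no spurious enrichment elsewhere
    row_m1 <- am[am$dac_module == "m1" & am$deg_module != "m1", ]
    expect_false(any(row_m1$direction == "enriched"))

    sig <- replicate(50, {
      pm <- map
      pm$gene_id <- sample(pm$gene_id)
      mean(module_association(peak_modules, gene_modules, pm)$padj < 0.05)
    })
    expect_lte(mean(sig), 0.05)
  })
})

test_that("a module with zero mapped peaks yields an ns row, not an error", {
  gene_modules <- setNames(rep(c("m1", "m2"), each = 10),
                           sprintf("g%03d", 1:20))
  peak_modules <- setNames(c(rep("m1", 20), "m3"),
                           sprintf("p%03d", 1:21))
  map <- data.frame(peak_id = names(peak_modules)[1:20],
                    gene_id = rep(names(gene_modules), 1),
                    distance = 0, tie = FALSE)
  am <- module_association(peak_modules, gene_modules, map)
  m3row <- am[am$dac_module == "m3", ]
  expect_equal(nrow(m3row), 2)
  expect_true(all(is.finite(m3row$odds_ratio)))
})
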