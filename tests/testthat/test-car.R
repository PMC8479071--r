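test_that("interval merging is transitive, bounded by the gap, and idempotent", {
  x <- data.frame(chrom = "chr1", start = c(0, 15), end = c(10, 25))
  m <- merge_conserved(x, gap = 10)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(0, 25))

  x2 <- data.frame(chrom = "chr1", start = c(0, 21), end = c(10, 31))
  expect_equal(nrow(merge_conserved(x2, gap = 10)), 2)  # gap 11 > 10

  # chain of 5 elements 8 bp apart collapses to one; re-merge is a no-op
  starts <- cumsum(c(0, rep(10 + 8, 4)))
  x3 <- data.frame(chrom = "chr1", start = starts, end = starts + 10)
  m3 <- merge_conserved(x3, gap = 10)
  expect_equal(nrow(m3), 1)
  expect_equal(merge_conserved(m3, gap = 10), m3)
  # order-invariant
  expect_equal(merge_conserved(x3[sample(5), ], gap = 10), m3)
})

test_that("missing-sequence filter applies the strict >50% rule to the focal row", {
  mk <- function(gapfrac) {
    n <- 100; ngap <- round(gapfrac * n)
    s <- c(rep("-", ngap), rep("A", n - ngap))
    list(b = c(mouse = paste(rep("A", n), collapse = ""),
               chicken = paste(s, collapse = "")))
  }
  expect_equal(length(filter_missing(mk(0.6), "chicken")), 0)
  expect_equal(length(filter_missing(mk(0.5), "chicken")), 1)
  expect_equal(length(filter_missing(mk(0), "chicken")), 1)
  expect_warning(
    out <- filter_missing(list(b = c(mouse = "AAAA")), "chicken"),
    "focal species missing")
  expect_equal(length(out), 0)
})

test_that("parsimony counts match hand-resolved histories", {
  tr <- "((a:1,b:1):1,(c:1,d:1):1);"
  # identical rows: no substitutions anywhere
  expect_equal(sum(branch_substitutions(
    c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT"), tr)), 0)

  # only one leaf differs: one substitution forced onto its terminal branch
  s1 <- branch_substitutions(c(a = "A", b = "C", c = "A", d = "A"), tr)
  expect_equal(s1[["b"]], 1)
  expect_equal(sum(s1), 1)

  # AA|GG split: one change, ambiguous between the two internal branches,
  # attributed half to each
  s2 <- branch_substitutions(c(a = "A", b = "A", c = "G", d = "G"), tr)
  expect_equal(sum(s2), 1)
  internal <- setdiff(names(s2), c("a", "b", "c", "d"))
  expect_equal(unname(s2[internal]), c(0.5, 0.5))

  # two-column block combining both situations
  s3 <- branch_substitutions(c(a = "AA", b = "CA", c = "AG", d = "AG"), tr)
  expect_equal(sum(s3), 2)
  expect_equal(s3[["b"]], 1)

  # gap columns are skipped entirely
  s4 <- branch_substitutions(c(a = "A-G", b = "C-G", c = "A-G", d = "A-G"),
                             tr)
  expect_equal(sum(s4), 1)
  expect_error(branch_substitutions(c(a = "A", b = "A"),
                                    "(a:1,b:1);"), "3 species")
})

test_that("acceleration test matches the binomial tail closed form", {
  lens <- c(a = 2.25, b = 2.25, c = 1, d = 2.25,
            node6 = 1.125, node7 = 1.125)  # focal share exactly 0.1
  cnt0 <- c(a = 0, b = 0, c = 20, d = 0, node6 = 0, node7 = 0)
  expect_equal(log10(acceleration_test(cnt0, lens, "c")), -20,
               tolerance = 1e-9)

  # counts proportional to branch lengths: no acceleration signal
  cnt1 <- round(lens * 8)
  expect_gte(acceleration_test(cnt1, lens, "c"), 0.5)

  expect_error(acceleration_test(cnt0 * 0, lens, "c"),
               "at least one substitution")
  expect_error(acceleration_test(cnt0, lens * 0, "c"), "zero total")
})

test_that("BH selection of accelerated regions uses a strict threshold", {
  p <- setNames(rep(1, 100), sprintf("r%03d", 1:100))
  expect_equal(sum(call_cars(p)$car), 0)

  p["r001"] <- 1e-6
  cc <- call_cars(p)
  expect_true(cc$car[cc$region_id == "r001"])
  expect_equal(sum(cc$car), 1)
  expect_equal(cc$q[cc$region_id == "r001"], 1e-6 * 100)

  # q exactly at the threshold is NOT flagged (single p: q = p)
  expect_false(call_cars(setNames(0.05, "x"))$car)
})

test_that("planted accelerated blocks are recovered at controlled FDR", {
  tree <- fixture_tree()
  # FDR is an expectation: average the false-discovery proportion over
  # replicate simulations rather than judging a single quantized FDP
  reps <- vapply(70:72, function(s) {
    aln <- generate_alignment(tree, n_blocks = 200, block_length = 200,
                              rate = 0.05, focal = "chicken",
                              accel_factor = 10, prop_accel = 0.1,
                              seed = s)
    res <- discover_cars(aln$blocks, tree, "chicken")
    both <- merge(res, aln$truth, by.x = "region_id", by.y = "block_id")
    c(sens = mean(both$car[both$accelerated]),
      fdp = if (any(both$car)) mean(!both$accelerated[both$car]) else 0)
  }, numeric(2))
  expect_gte(mean(reps["sens", ]), 0.9)
  expect_lte(mean(reps["fdp", ]), 0.05)

  # null generator (factor 1): false positives within the nominal FDR
  aln0 <- generate_alignment(tree, n_blocks = 200, block_length = 200,
                             rate = 0.05, focal = "chicken",
                             accel_factor = 1, prop_accel = 0.1, seed = 73)
  res0 <- discover_cars(aln0$blocks, tree, "chicken")
  expect_lte(mean(res0$car), 0.05)
})

test_that("gene assignment respects the 1-Mb inclusive window", {
  cars <- data.frame(region_id = c("r1", "r2"), chrom = "chr1",
                     start = c(1e6, 9e6), end = c(1e6 + 200, 9e6 + 200))
  genes <- data.frame(gene_id = c("gNear", "gFar", "gEdge"),
                      chrom = "chr1",
                      tss = c(1e6 + 100 + 1e4, 3.5e6, 9e6 + 100 + 1e6))
  out <- assign_car_genes(cars, genes, window = 1e6)
  expect_equal(out$nearest_gene, c("gNear", "gEdge"))
  expect_equal(out$genes_in_window[1], "gNear")
  # boundary at exactly 1 Mb is included
  expect_equal(out$genes_in_window[2], "gEdge")
  # region with no gene within the window still reports a nearest gene
  cars3 <- data.frame(region_id = "r3", chrom = "chr1",
                      start = 6e6, end = 6e6 + 200)
  out3 <- assign_car_genes(cars3, genes, window = 1e6)
  expect_equal(out3$nearest_gene, "gFar")
  expect_equal(out3$genes_in_window, "")
})

test_that("DAC overlap categories partition the regions", {
  cars <- data.frame(region_id = sprintf("r%d", 1:4), chrom = "chr1",
                     start = c(1000, 5000, 9000, 20000),
                     end = c(1200, 5200, 9200, 20200))
  dac_mm <- data.frame(chrom = "chr1", start = 1500, end = 1600)
  dac_gg <- data.frame(chrom = "chr1", start = c(1300, 5500),
                       end = c(1400, 5600))
  out <- car_dac_overlap(cars, dac_mm, dac_gg, window = 2000)
  expect_equal(out$dac_category,
               c("CAR-mm/gg-DAC", "CAR-gg-DAC", "CAR-no-DAC",
                 "CAR-no-DAC"))
  # every region gets exactly one category
  expect_false(anyNA(out$dac_category))
})
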