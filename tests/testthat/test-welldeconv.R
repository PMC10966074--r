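test_that("top_barcodes ranks by units with lexicographic ties", {
  counts <- tibble::tibble(barcode = c("A", "B", "C", "D"),
                           units = c(10, 8, 3, 1))
  expect_equal(top_barcodes(counts, 3)$barcode, c("A", "B", "C"))
  # ties broken lexicographically
  tied <- tibble::tibble(barcode = c("B", "A"), units = c(5, 5))
  expect_equal(top_barcodes(tied, 1)$barcode, "A")
  # n larger than population: return all, message
  expect_message(all_bc <- top_barcodes(counts, 10), "4 barcodes")
  expect_equal(nrow(all_bc), 4L)
})

test_that("feature sets deduplicate and honour assay semantics", {
  rna <- tibble::tibble(
    bead_barcode = c("X", "X", "X"),
    feature_tag = c("t1", "t1", "t2")
  )
  fs <- build_feature_sets(rna, "rna")
  expect_equal(nrow(fs), 2L)  # set semantics
  expect_equal(attr(fs, "units")$units, 3L)

  atac <- tibble::tibble(
    bead_barcode = c("X", "Y"),
    chrom = "chr1", start = 100L, end = 250L,
    spikein_tag = NA_character_
  )
  fs_a <- build_feature_sets(atac, "atac")
  expect_equal(sort(unique(fs_a$bead_barcode)), c("X", "Y"))
  expect_equal(unique(fs_a$feature), "chr1:100:250")  # shared across beads

  # union mode pools fragments and spike-ins
  atac_u <- tibble::tibble(
    bead_barcode = "X",
    chrom = c("chr1", NA), start = c(100L, NA), end = c(250L, NA),
    spikein_tag = c(NA, "AAAACCCCGGGGTT")
  )
  expect_equal(nrow(build_feature_sets(atac_u, "atac", "union")), 2L)
  expect_error(build_feature_sets(rna, "atac"), "atac")
})

test_that("jaccard_pairs matches hand-computed examples", {
  fs <- tibble::tibble(
    bead_barcode = rep(c("X", "Y", "Z"), each = 3),
    feature = c("f1", "f2", "f3", "f2", "f3", "f4", "f1", "f2", "f3")
  )
  pairs <- jaccard_pairs(fs)
  xy <- pairs[pairs$bead_a == "X" & pairs$bead_b == "Y", ]
  expect_equal(xy$jaccard, 0.5)  # |∩|=2, |∪|=4
  xz <- pairs[pairs$bead_a == "X" & pairs$bead_b == "Z", ]
  expect_equal(xz$jaccard, 1)    # identical sets
  # disjoint pair absent
  fs2 <- tibble::tibble(bead_barcode = c("P", "Q"), feature = c("u", "v"))
  expect_equal(nrow(jaccard_pairs(fs2, min_shared = 1)), 0L)
  expect_error(jaccard_pairs(fs2[1, ]), "2 beads")
})

test_that("sparse Jaccard equals the brute-force double loop exactly", {
  for (seed in 1:10) {
    set.seed(seed)
    n_beads <- 100L
    feats <- tibble::tibble(
      bead_barcode = sprintf("b%03d", sample.int(n_beads, 2000, replace = TRUE)),
      feature = sprintf("f%03d", sample.int(300L, 2000, replace = TRUE))
    ) |> dplyr::distinct()
    got <- jaccard_pairs(feats)
    want <- jaccard_brute(feats)
    expect_identical(got$bead_a, want$bead_a)
    expect_identical(got$bead_b, want$bead_b)
    expect_identical(got$shared, want$shared)
    expect_equal(got$jaccard, want$jaccard)
  }
})

test_that("knee threshold isolates a planted high mode", {
  set.seed(7)
  high <- runif(100, 0.38, 0.42)
  low <- runif(5000, 0.0015, 0.0025)
  thr <- knee_threshold(c(high, low))
  expect_gt(as.numeric(thr), max(low) - 1e-12)
  expect_lt(as.numeric(thr), min(high))
  retained <- c(high, low)[c(high, low) > as.numeric(thr)]
  expect_setequal(retained, high)  # exactly the planted pairs
})

test_that("knee threshold is stable under more background values", {
  set.seed(8)
  high <- runif(80, 0.3, 0.5)
  low <- runif(3000, 0.001, 0.004)
  thr1 <- as.numeric(knee_threshold(c(high, low)))
  more_low <- c(low, runif(4000, 0.001, 0.004))
  thr2 <- as.numeric(knee_threshold(c(high, more_low)))
  r1 <- high[high > thr1]
  r2 <- high[high > thr2]
  expect_setequal(r1, r2)
  expect_setequal(r1, high)
})

test_that("constant knee input retains nothing, with a warning", {
  expect_warning(thr <- knee_threshold(rep(0.2, 50)), "no knee")
  vals <- rep(0.2, 50)
  expect_equal(sum(vals > as.numeric(thr)), 0L)
  expect_error(knee_threshold(0.5), "at least 2")
  expect_error(knee_threshold(c(0.1, -0.2)), "positive")
})

test_that("second-difference knee strategy also splits a bimodal input", {
  set.seed(9)
  high <- runif(50, 0.3, 0.4)
  low <- runif(2000, 0.001, 0.002)
  thr <- as.numeric(knee_threshold(c(high, low), strategy = "second_diff"))
  # the cut lands at the mode boundary: no background pair survives it
  expect_true(all(low <= thr))
  expect_lte(thr, max(high))
})

test_that("merge_beads takes connected components and drops overloads", {
  pairs <- tibble::tibble(
    bead_a = c("A", "B"), bead_b = c("B", "C"),
    shared = 5L, union = 10L, jaccard = c(0.5, 0.5)
  )
  part <- merge_beads(pairs, threshold = 0.1)
  expect_equal(unique(part$well_id), "A")  # transitive closure, smallest rep
  expect_equal(nrow(part), 3L)

  # a 7-bead component is dropped entirely as overloaded
  beads7 <- sprintf("b%d", 1:7)
  chain <- tibble::tibble(bead_a = beads7[-7], bead_b = beads7[-1],
                          shared = 1L, union = 2L, jaccard = 0.5)
  part7 <- merge_beads(chain, threshold = 0.1, max_beads = 6)
  expect_true(all(!part7$retained))
  expect_true(all(part7$drop_reason == "overloaded"))

  # no pairs above threshold: every bead a singleton well
  none <- merge_beads(chain, threshold = 0.9, beads = beads7)
  expect_equal(none$well_id, none$bead_barcode)
  expect_true(all(none$retained))
})

test_that("partitions cover each retained bead exactly once", {
  set.seed(11)
  wl <- tiny_whitelist()
  sim <- simulate_chip(chip_params(n_wells = 60, whitelist = wl, seed = 5))
  dec <- deconvolve_wells(sim$tags, assay = "rna", top_n = 10000)
  part <- dec$partition
  expect_equal(anyDuplicated(part$bead_barcode), 0L)
  sizes <- table(part$well_id[part$retained])
  expect_true(all(sizes <= attr(part, "max_beads")))
  # determinism: identical inputs give identical partitions
  dec2 <- deconvolve_wells(sim$tags, assay = "rna", top_n = 10000)
  expect_identical(tidy(part), tidy(dec2$partition))
})

test_that("assign_cells splits co-resident nuclei by preindex", {
  part <- merge_beads(
    tibble::tibble(bead_a = "A", bead_b = "B", shared = 3L, union = 4L,
                   jaccard = 0.75),
    threshold = 0.5
  )
  tags <- tibble::tibble(
    bead_barcode = c("A", "B", "B"),
    preindex = c("p1", "p2", "p2"),
    gene = c("g1", "g1", "g1"),
    umi = c("AAAAAA", "CCCCCC", "CCCCCC")
  )
  asg <- assign_cells(tags, part, assay = "rna")
  expect_equal(nrow(asg$cells), 2L)  # (p1, A) and (p2, A)
  expect_equal(asg$cells$well_id, c("A", "A"))
  # same gene, cell, UMI: one molecule after deduplication
  expect_equal(as.numeric(asg$counts["g1", "p2+A"]), 1)
  expect_equal(sum(asg$counts), 2)
})

test_that("reads on dropped wells are excluded from all matrices", {
  beads7 <- sprintf("b%d", 1:7)
  chain <- tibble::tibble(bead_a = beads7[-7], bead_b = beads7[-1],
                          shared = 1L, union = 2L, jaccard = 0.5)
  part <- merge_beads(chain, threshold = 0.1, max_beads = 6)
  tags <- tibble::tibble(
    bead_barcode = c(beads7, "z_solo"),
    preindex = "p1", gene = "g1",
    umi = sprintf("UMI%03d", 1:8)
  )
  part2 <- merge_beads(chain, threshold = 0.1, max_beads = 6,
                       beads = c(beads7, "z_solo"))
  asg <- assign_cells(tags, part2, assay = "rna")
  expect_equal(asg$n_dropped_reads, 7L)
  expect_equal(nrow(asg$cells), 1L)
  expect_equal(asg$cells$well_id, "z_solo")
})
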