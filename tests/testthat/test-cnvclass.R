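# small deterministic study shared across blocks
small_study <- function(seed = 5, ...) {
  simulate_cnv_study(cnv_study_params(
    n_genes = 300L, cells = c(tumor = 120L, adjacent = 60L, normal = 60L),
    seed = seed, ...
  ))
}

test_that("pseudobulk profiles are exact column sums, then normalized", {
  study <- small_study()
  pb <- build_pseudobulks(study$counts,
                          dplyr::select(study$cells, cell, group),
                          c(tumor = 20, adjacent = 10, normal = 10),
                          normalization_total = 1e7)
  # conservation: raw profile equals the sum of member-cell columns
  for (p in sample(colnames(pb$raw), 5)) {
    members <- pb$members$cell[pb$members$pseudobulk == p]
    expect_equal(pb$raw[, p],
                 rowSums(study$counts[, members, drop = FALSE]))
  }
  # membership is a partition of the clustered cells
  expect_equal(anyDuplicated(pb$members$cell), 0L)
  # normalization: every column total equals the constant within 1e-6 rel.
  expect_true(all(abs(colSums(pb$profiles) - 1e7) <= 1e-6 * 1e7))
})

test_that("undersized groups are dropped; n = 1 sums the whole group", {
  counts <- matrix(rpois(50 * 8, 10), nrow = 50,
                   dimnames = list(sprintf("g%d", 1:50),
                                   sprintf("c%d", 1:8)))
  groups <- tibble::tibble(cell = colnames(counts),
                           group = rep(c("small", "big"), c(3, 5)))
  pb <- build_pseudobulks(counts, groups, c(small = 5, big = 1))
  expect_equal(pb$dropped$group, "small")
  expect_equal(ncol(pb$raw), 1L)
  expect_equal(pb$raw[, 1],
               rowSums(counts[, groups$cell[groups$group == "big"]]))
  expect_error(build_pseudobulks(counts[, 0], groups, 1), "empty")
})

test_that("windowed CNV is zero for reference-identical expression", {
  genes <- tibble::tibble(gene = sprintf("g%d", 1:100), chrom = "chr1",
                          start = seq_len(100) * 1000L)
  prof <- matrix(rep(runif(100, 50, 150), 4), ncol = 4,
                 dimnames = list(genes$gene, paste0("pb", 1:4)))
  cnv <- estimate_cnv_windowed(prof, genes, reference = c("pb1", "pb2"),
                               window = 11)
  expect_true(all(cnv$values == 0))
})

test_that("a noiseless gain shows the log2 plateau before scaling", {
  n <- 900
  genes <- tibble::tibble(gene = sprintf("g%03d", seq_len(n)), chrom = "chr1",
                          start = seq_len(n) * 1000L)
  base <- rep(100, n)
  gained <- base
  gained[301:600] <- 200  # 2x gain over 300 contiguous genes
  prof <- cbind(ref = base, tumor = gained)
  rownames(prof) <- genes$gene
  cnv <- estimate_cnv_windowed(prof, genes, reference = "ref", window = 101,
                               pseudocount = 0)
  # interior of the plateau: the whole window sits inside the gain, and the
  # matrix maximum equals the plateau, so scaled values are exactly 1
  interior <- 351:550
  expect_equal(unname(cnv$values[interior, "tumor"]), rep(1, 200))
  # far outside the gain the ratio is exactly 0
  expect_equal(unname(cnv$values[1:100, "tumor"]), rep(0, 100))
  # window = 1 leaves per-gene ratios unchanged (up to scaling)
  cnv1 <- estimate_cnv_windowed(prof, genes, reference = "ref", window = 1,
                                pseudocount = 0)
  expect_equal(unname(cnv1$values[, "tumor"]),
               log2(gained / base) / max(abs(log2(gained / base))))
  expect_error(estimate_cnv_windowed(prof, genes, "ref", window = 100),
               "odd")
  expect_error(estimate_cnv_windowed(prof, genes, "nope", window = 11),
               "reference")
})

test_that("cnv scores are quadratic sums with sign symmetry", {
  expect_equal(cnv_score(c(0.5, -0.5)), 0.5)
  expect_equal(cnv_score(rep(0, 10)), 0)
  set.seed(41)
  v <- runif(20, -1, 1)
  flip <- v * sample(c(-1, 1), 20, replace = TRUE)
  expect_equal(cnv_score(v), cnv_score(flip))
  m <- cbind(a = c(0.5, -0.5), b = c(1, 0))
  expect_equal(cnv_score(m), c(a = 0.5, b = 1))
  expect_error(cnv_score(c(0.5, 1.5)), "scale range")
})

test_that("expectations follow the worked example and the outlier rule", {
  e <- compute_expectations(c(a1 = 0.1, a2 = 0.2, t1 = 0.8, t2 = 1.0),
                            c("adjacent", "adjacent", "tumor", "tumor"))
  expect_equal(e$normal_expectation, 0.15)
  expect_equal(e$malignant_expectation, 0.9)
  expect_equal(nrow(e$outliers_removed), 0L)

  # an adjacent pseudobulk at/above the initial malignant expectation is
  # removed before recomputation
  e2 <- compute_expectations(
    c(a1 = 0.1, a2 = 0.2, a3 = 0.95, t1 = 0.8, t2 = 1.0),
    c("adjacent", "adjacent", "adjacent", "tumor", "tumor")
  )
  expect_equal(e2$outliers_removed$pseudobulk, "a3")
  expect_equal(e2$normal_expectation, 0.15)
  # and a tumor pseudobulk at/below the initial normal expectation likewise
  e3 <- compute_expectations(
    c(a1 = 0.1, a2 = 0.2, t0 = 0.1, t1 = 0.8, t2 = 1.0),
    c("adjacent", "adjacent", "tumor", "tumor", "tumor")
  )
  expect_equal(e3$outliers_removed$pseudobulk, "t0")
  expect_equal(e3$malignant_expectation, 0.9)

  # identical score sets cannot support the correction: every adjacent
  # pseudobulk sits at/above the initial malignant expectation, so the
  # tissue empties and the expectations are undefined
  expect_error(
    compute_expectations(c(a = 0.5, t = 0.5), c("adjacent", "tumor")),
    "emptied"
  )
  # survivors are strictly separated: normal expectation < malignant
  expect_lt(e2$normal_expectation, e2$malignant_expectation)
  expect_error(compute_expectations(c(a = 1), "adjacent"), "required")
})

test_that("well-separated scores classify in one round like thresholding", {
  # two score-homogeneous modes: clusters are pure, so the iterative rule
  # must coincide with direct thresholding of each pseudobulk's score
  n <- 40
  profiles <- rbind(
    matrix(0.05, 20, 30),
    matrix(0.60, 20, 30)
  )
  rownames(profiles) <- sprintf("pb%02d", seq_len(n))
  cnv <- as_cnv_matrix(t(profiles), tibble::tibble(region = 1:30))
  scores <- cnv_score(cnv)
  e <- structure(list(normal_expectation = unname(quantile(scores, 0.25)),
                      malignant_expectation = unname(quantile(scores, 0.75)),
                      outliers_removed = tibble::tibble(), initial = NULL),
                 class = "cnv_expectations")
  cl <- iterative_classify(cnv, scores, e, k = 4, max_recursion = 5)
  direct <- ifelse(scores <= e$normal_expectation, "normal",
                   ifelse(scores >= e$malignant_expectation, "malignant",
                          "intermediate"))
  expect_equal(cl$label, unname(direct[cl$pseudobulk]))
  expect_equal(attr(cl, "depth_used"), 1L)
})

test_that("inseparable intermediates stay intermediate at max recursion", {
  n <- 12
  profiles <- matrix(0.3, nrow = 5, ncol = n,
                     dimnames = list(NULL, sprintf("pb%02d", 1:n)))
  cnv <- as_cnv_matrix(profiles, tibble::tibble(region = 1:5))
  scores <- cnv_score(cnv)  # all equal, strictly between the expectations
  e <- structure(list(normal_expectation = min(scores) - 1,
                      malignant_expectation = max(scores) + 1,
                      outliers_removed = tibble::tibble(), initial = NULL),
                 class = "cnv_expectations")
  cl <- iterative_classify(cnv, scores, e, k = 3, max_recursion = 4)
  expect_true(all(cl$label == "intermediate"))
  expect_lte(attr(cl, "depth_used"), 4L)
})

test_that("a cluster mean exactly at the normal expectation is normal", {
  profiles <- matrix(c(0.2, 0.2), nrow = 1,
                     dimnames = list(NULL, c("pb1", "pb2")))
  cnv <- as_cnv_matrix(profiles, tibble::tibble(region = 1))
  scores <- cnv_score(cnv)
  e <- structure(list(normal_expectation = unname(scores[1]),
                      malignant_expectation = unname(scores[1]) + 1,
                      outliers_removed = tibble::tibble(), initial = NULL),
                 class = "cnv_expectations")
  cl <- iterative_classify(cnv, scores, e, k = 2)
  expect_true(all(cl$label == "normal"))  # <= is inclusive
  # invalid expectations refuse to classify
  e_bad <- structure(list(normal_expectation = 2, malignant_expectation = 1,
                          outliers_removed = tibble::tibble(), initial = NULL),
                     class = "cnv_expectations")
  expect_error(iterative_classify(cnv, scores, e_bad, k = 2), "cannot proceed")
})

test_that("cell labels inherit from pseudobulks, with orphan detection", {
  cl <- tibble::tibble(pseudobulk = c("p1", "p2"), score = c(0.1, 2),
                       label = c("normal", "malignant"),
                       depth = c(1L, 1L))
  members <- tibble::tibble(cell = sprintf("c%d", 1:5),
                            pseudobulk = c("p1", "p1", "p2", "p2", "p2"))
  lab <- propagate_to_cells(cl, members)
  expect_equal(table(lab$label),
               table(c(rep("normal", 2), rep("malignant", 3))))
  orphan <- tibble::tibble(cell = "c9", pseudobulk = "p9")
  expect_error(propagate_to_cells(cl, orphan), "unclassified")
})

test_that("the full classifier recovers planted clones on a small study", {
  study <- small_study(seed = 7)
  res <- classify_malignant(study$counts,
                            dplyr::select(study$cells, cell, group),
                            study$genes,
                            n_per_group = c(tumor = 20, adjacent = 10,
                                            normal = 10),
                            window = 31)
  m <- dplyr::inner_join(res$cell_labels, study$cells, by = "cell")
  acc <- mean((m$label == "malignant") == m$malignant)
  expect_gt(acc, 0.9)
  # determinism: rerun gives identical labels
  res2 <- classify_malignant(study$counts,
                             dplyr::select(study$cells, cell, group),
                             study$genes,
                             n_per_group = c(tumor = 20, adjacent = 10,
                                             normal = 10),
                             window = 31)
  expect_identical(tidy(res$classification), tidy(res2$classification))
})

test_that("tidiers expose labels and summary of a classification", {
  study <- small_study(seed = 8)
  res <- classify_malignant(study$counts,
                            dplyr::select(study$cells, cell, group),
                            study$genes,
                            n_per_group = c(tumor = 12, adjacent = 6,
                                            normal = 6),
                            window = 31)
  td <- tidy(res$classification)
  expect_true(all(c("pseudobulk", "score", "label", "depth") %in% names(td)))
  gl <- glance(res$classification)
  expect_equal(gl$n_pseudobulks, 24L)
  expect_equal(gl$n_normal + gl$n_malignant + gl$n_intermediate, 24L)
})
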