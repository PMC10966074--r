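# Shared fixtures and independent oracles used across test files.

# small whitelist for fast fixtures (distance >= 3 so correction stays exact)
tiny_whitelist <- function(seed = 1L) {
  make_whitelist(n_segment_entries = 8L, n_preindex = 8L, seed = seed)
}

# brute-force Jaccard over all bead pairs (double loop on sets); the oracle
# for the sparse inverted-index implementation
jaccard_brute <- function(features) {
  sets <- split(features$feature, features$bead_barcode)
  sets <- lapply(sets, unique)
  beads <- sort(names(sets))
  out <- list()
  for (i in seq_along(beads)) {
    for (j in seq_along(beads)) {
      if (i >= j) next
      a <- sets[[beads[i]]]
      b <- sets[[beads[j]]]
      shared <- length(intersect(a, b))
      if (shared >= 1L) {
        out[[length(out) + 1L]] <- tibble::tibble(
          bead_a = beads[i], bead_b = beads[j], shared = shared,
          union = length(union(a, b)),
          jaccard = shared / length(union(a, b))
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(bead_a = character(0), bead_b = character(0),
                          shared = integer(0), union = integer(0),
                          jaccard = numeric(0)))
  }
  dplyr::arrange(dplyr::bind_rows(out), bead_a, bead_b)
}

# pairwise same-group precision/recall between a predicted and a true
# partition, computed from group tallies (no pair enumeration)
pair_prf <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  n2 <- function(x) sum(choose(table(x), 2))
  tp <- n2(paste(pred, truth, sep = "\r"))
  pp <- n2(pred)
  ap <- n2(truth)
  c(precision = if (pp > 0) tp / pp else NA_real_,
    recall = if (ap > 0) tp / ap else NA_real_)
}

# Hamming distance between two equal-length strings
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# all single-base mutants of a k-mer
single_mutants <- function(x) {
  bases <- c("A", "C", "G", "T")
  ch <- strsplit(x, "")[[1]]
  out <- character(0)
  for (pos in seq_along(ch)) {
    for (b in setdiff(bases, ch[pos])) {
      y <- ch
      y[pos] <- b
      out <- c(out, paste(y, collapse = ""))
    }
  }
  out
}

# default-seed full-size whitelist, built once per test session
default_whitelist <- function() make_whitelist(seed = 1L)

# 16 entries per segment: 4096 bead combinations, for chips needing more
# beads than tiny_whitelist's 512
mid_whitelist <- function(seed = 1L) {
  make_whitelist(n_segment_entries = 16L, n_preindex = 8L, seed = seed)
}

# build a cnv_matrix for one "method": per-cytoband effect vector rendered as
# malignant-vs-normal pseudobulk values plus optional noise
render_method <- function(effects, n_bands = length(effects), n_mal = 6,
                          n_nor = 6, noise_sd = 0, genes_per_band = 1,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bands <- sprintf("band%02d", seq_len(n_bands))
  regions <- tibble::tibble(
    gene = sprintf("g%03d", seq_len(n_bands * genes_per_band)),
    chrom = "chr1",
    start = seq_len(n_bands * genes_per_band),
    cytoband = rep(bands, each = genes_per_band)
  )
  base <- rep(effects, each = genes_per_band)
  vals <- cbind(
    matrix(rep(base, n_mal), ncol = n_mal) +
      matrix(rnorm(length(base) * n_mal, 0, noise_sd), ncol = n_mal),
    matrix(0, length(base), n_nor) +
      matrix(rnorm(length(base) * n_nor, 0, noise_sd), ncol = n_nor)
  )
  colnames(vals) <- c(sprintf("mal%02d", seq_len(n_mal)),
                      sprintf("nor%02d", seq_len(n_nor)))
  rownames(vals) <- regions$gene
  vals <- vals / max(abs(vals))
  as_cnv_matrix(vals, regions)
}

method_labels <- function(n_mal = 6, n_nor = 6) {
  tibble::tibble(
    pseudobulk = c(sprintf("mal%02d", seq_len(n_mal)),
                   sprintf("nor%02d", seq_len(n_nor))),
    label = rep(c("malignant", "normal"), c(n_mal, n_nor))
  )
}

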