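#' Retain the top-ranked barcodes by unit count
#'
#' Ranks barcodes by their total units (reads-UMIs for RNA, reads-fragments
#' for ATAC) and keeps the top `n`. Ties at the boundary are broken
#' lexicographically so the result is deterministic.
#'
#' @param counts A data frame with columns `barcode` and `units`.
#' @param n Number of barcodes to keep (default 20000; tumor chips in the
#'   platform's own processing use 10000).
#' @return A tibble of the retained barcodes, highest units first.
#' @examples
#' top_barcodes(tibble::tibble(barcode = c("A", "B", "C"),
#'                             units = c(10, 3, 8)), n = 2)
#' @export
top_barcodes <- function(counts, n = 20000L) {
  stopifnot(all(c("barcode", "units") %in% names(counts)), n >= 1)
  counts <- as_tibble(counts)
  if (nrow(counts) < n) {
    message("only ", nrow(counts), " barcodes available (requested ", n, ")")
  }
  counts |>
    arrange(dplyr::desc(.data$units), .data$barcode) |>
    slice_head(n = min(n, nrow(counts)))
}

#' Build per-bead feature sets
#'
#' Collects, for every bead barcode, the set of well-identifying features:
#' the random molecule-tag sequences for RNA, and fragment insertion
#' coordinates plus spike-in random oligonucleotides for ATAC. Sharing of
#' these features across bead barcodes marks co-residence in one microwell.
#'
#' @param tags A tibble of corrected tagged reads. RNA requires `feature_tag`;
#'   ATAC requires `chrom`, `start`, `end` and/or `spikein_tag`.
#' @param assay `"rna"` or `"atac"`.
#' @param spikein_mode How ATAC spike-in tags enter the feature set:
#'   `"union"` pools coordinate features and spike-in tags into one set,
#'   `"refine"` keeps them as a secondary confirmation set (a candidate bead
#'   pair must also share at least one spike-in), `"none"` ignores them.
#' @return An object of class `bead_features`: a tibble with columns
#'   `bead_barcode`, `feature`, `kind`, deduplicated; per-bead totals are
#'   attached as attribute `units` (a tibble of `barcode`, `units` counting
#'   raw reads).
#' @export
build_feature_sets <- function(tags, assay = c("rna", "atac"),
                               spikein_mode = c("union", "refine", "none")) {
  assay <- match.arg(assay)
  spikein_mode <- match.arg(spikein_mode)
  tags <- as_tibble(tags)
  if (assay == "rna") {
    if (!"feature_tag" %in% names(tags) || all(tags$feature_tag == "")) {
      stop("rna feature sets need a populated `feature_tag` column",
           call. = FALSE)
    }
    feats <- tags |>
      filter(.data$feature_tag != "") |>
      mutate(feature = .data$feature_tag, kind = "tag") |>
      select("bead_barcode", "feature", "kind")
  } else {
    have_frag <- all(c("chrom", "start", "end") %in% names(tags))
    have_spike <- "spikein_tag" %in% names(tags)
    if (!have_frag && !have_spike) {
      stop("atac feature sets need fragment coordinates and/or `spikein_tag`",
           call. = FALSE)
    }
    parts <- list()
    if (have_frag) {
      parts$frag <- tags |>
        filter(!is.na(.data$chrom)) |>
        mutate(feature = paste(.data$chrom, .data$start, .data$end, sep = ":"),
               kind = "fragment") |>
        select("bead_barcode", "feature", "kind")
    }
    if (have_spike && spikein_mode != "none") {
      parts$spike <- tags |>
        filter(!is.na(.data$spikein_tag) & .data$spikein_tag != "") |>
        mutate(feature = .data$spikein_tag, kind = "spikein") |>
        select("bead_barcode", "feature", "kind")
    }
    feats <- bind_rows(parts)
  }
  units <- tags |> count(barcode = .data$bead_barcode, name = "units")
  out <- distinct(feats)
  empty <- setdiff(unique(tags$bead_barcode), unique(out$bead_barcode))
  if (length(empty) > 0L) {
    message(length(empty), " bead(s) had no usable features and are excluded")
  }
  structure(out, units = units, assay = assay, spikein_mode = spikein_mode,
            class = c("bead_features", class(out)))
}

#' Pairwise Jaccard indices between bead feature sets
#'
#' Computes, for every unordered pair of beads sharing at least `min_shared`
#' features, the Jaccard index of their feature sets. The computation goes
#' through an inverted index (feature -> beads), so pairs sharing nothing are
#' never materialised and the cost is near linear in total feature
#' occurrences rather than quadratic in beads.
#'
#' @param features A [build_feature_sets()] result (or any tibble with
#'   `bead_barcode` and `feature` columns, deduplicated).
#' @param min_shared Minimum number of shared features for a pair to be
#'   reported. Default 1.
#' @return A tibble with columns `bead_a`, `bead_b` (`bead_a < bead_b`),
#'   `shared`, `union`, `jaccard`. Under `spikein_mode = "refine"` the
#'   Jaccard is computed on fragment features and pairs lacking a shared
#'   spike-in are dropped.
#' @examples
#' fs <- tibble::tibble(bead_barcode = c("X", "X", "X", "Y", "Y", "Y"),
#'                      feature = c("f1", "f2", "f3", "f2", "f3", "f4"))
#' jaccard_pairs(fs)
#' @export
jaccard_pairs <- function(features, min_shared = 1L) {
  stopifnot(all(c("bead_barcode", "feature") %in% names(features)))
  refine <- identical(attr(features, "spikein_mode"), "refine") &&
    "kind" %in% names(features) && any(features$kind == "spikein")
  primary <- if (refine) {
    features |> filter(.data$kind != "spikein")
  } else {
    features
  }
  primary <- distinct(as_tibble(primary)[c("bead_barcode", "feature")])
  if (length(unique(primary$bead_barcode)) < 2L) {
    stop("need feature sets for at least 2 beads", call. = FALSE)
  }
  sizes <- primary |> count(.data$bead_barcode, name = "size")
  pairs <- pair_counts(primary)
  pairs <- pairs |>
    filter(.data$shared >= min_shared) |>
    left_join(sizes, by = c(bead_a = "bead_barcode")) |>
    rename(size_a = "size") |>
    left_join(sizes, by = c(bead_b = "bead_barcode")) |>
    rename(size_b = "size") |>
    mutate(union = .data$size_a + .data$size_b - .data$shared,
           jaccard = .data$shared / .data$union) |>
    select("bead_a", "bead_b", "shared", "union", "jaccard") |>
    arrange(.data$bead_a, .data$bead_b)
  if (refine) {
    spikes <- features |>
      filter(.data$kind == "spikein") |>
      distinct(.data$bead_barcode, .data$feature)
    confirmed <- pair_counts(spikes)
    pairs <- pairs |>
      dplyr::semi_join(confirmed, by = c("bead_a", "bead_b"))
  }
  pairs
}

# inverted-index co-occurrence counts: for each feature, emit all bead pairs
# carrying it, then tally per unordered pair
pair_counts <- function(bead_feature) {
  df <- bead_feature |> arrange(.data$feature, .data$bead_barcode)
  joined <- inner_join(df, df, by = "feature", relationship = "many-to-many",
                       suffix = c("_a", "_b"))
  joined |>
    filter(.data$bead_barcode_a < .data$bead_barcode_b) |>
    count(bead_a = .data$bead_barcode_a, bead_b = .data$bead_barcode_b,
          name = "shared")
}

#' Knee-point threshold on a score distribution
#'
#' Separates the high (same-well) mode of a Jaccard distribution from the
#' background. Scores are sorted in decreasing order and log10-transformed;
#' the knee is the point of the rank--value curve at maximum perpendicular
#' distance from the chord joining its first and last points (strategy
#' `"distance"`), or the point of maximum second difference (strategy
#' `"second_diff"`). The threshold is the score at the knee, and scores
#' strictly above it are the same-well candidates.
#'
#' If all scores are equal no knee exists: the maximum value is returned with
#' a warning, so that nothing lies strictly above the threshold.
#'
#' @param values Positive numeric scores (e.g. the `jaccard` column of
#'   [jaccard_pairs()]).
#' @param strategy Knee-detection strategy; see above.
#' @return The threshold value, with attributes `knee_rank` (rank of the knee
#'   point) and `n`.
#' @examples
#' knee_threshold(c(rep(0.4, 5), rep(0.002, 100)))
#' @export
knee_threshold <- function(values, strategy = c("distance", "second_diff")) {
  strategy <- match.arg(strategy)
  values <- values[!is.na(values)]
  if (length(values) < 2L || any(values <= 0)) {
    stop("need at least 2 positive values", call. = FALSE)
  }
  y <- sort(values, decreasing = TRUE)
  if (length(unique(y)) < 2L) {
    warning("all values equal: no knee; returning the maximum (retain nothing)")
    return(structure(y[1], knee_rank = 1L, n = length(y)))
  }
  ly <- log10(y)
  n <- length(ly)
  x <- seq_len(n)
  if (strategy == "distance") {
    # perpendicular distance from (x, ly) to the chord (1, ly1)-(n, lyn)
    dx <- n - 1
    dy <- ly[n] - ly[1]
    d <- abs(dy * (x - 1) - dx * (ly - ly[1])) / sqrt(dx^2 + dy^2)
    knee <- which.max(d)
  } else {
    if (n < 3L) {
      knee <- n
    } else {
      d2 <- diff(ly, differences = 2)
      knee <- which.max(abs(d2)) + 1L
    }
  }
  structure(y[knee], knee_rank = knee, n = n)
}

#' Merge beads into wells
#'
#' Bead pairs with Jaccard index above the threshold are treated as same-well
#' evidence; wells are the connected components of the resulting bead graph
#' (the transitive, order-independent closure of pairwise merging). Beads
#' without any above-threshold partner become singleton wells. Components
#' with more than `max_beads` members are technical confounders and are
#' dropped entirely, with the reason recorded. Each well is represented by
#' its lexicographically smallest member barcode.
#'
#' @param pairs A [jaccard_pairs()] tibble.
#' @param threshold Jaccard threshold, e.g. from [knee_threshold()]; pairs
#'   with `jaccard > threshold` are merged.
#' @param max_beads Maximum beads per retained well. Default 6.
#' @param beads Optional character vector of all bead barcodes (so that beads
#'   absent from `pairs` still appear as singleton wells).
#' @return An object of class `well_partition`: a tibble with columns
#'   `bead_barcode`, `well_id` (the representative barcode), `n_beads`,
#'   `retained`, `drop_reason`.
#' @examples
#' p <- tibble::tibble(bead_a = c("A", "B"), bead_b = c("B", "C"),
#'                     shared = 5L, union = 8L, jaccard = 0.6)
#' merge_beads(p, threshold = 0.1)
#' @export
merge_beads <- function(pairs, threshold, max_beads = 6L, beads = NULL) {
  edges <- pairs |> filter(.data$jaccard > threshold)
  all_beads <- sort(unique(c(pairs$bead_a, pairs$bead_b, beads)))
  if (length(all_beads) == 0L) stop("no beads to partition", call. = FALSE)
  if (!all(c(edges$bead_a, edges$bead_b) %in% all_beads)) {
    stop("pairs reference beads missing from `beads`", call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    edges[c("bead_a", "bead_b")], directed = FALSE,
    vertices = data.frame(name = all_beads)
  )
  comp <- igraph::components(g)
  membership <- comp$membership[all_beads]
  out <- tibble(bead_barcode = all_beads, component = as.integer(membership)) |>
    group_by(.data$component) |>
    mutate(well_id = min(.data$bead_barcode), n_beads = n()) |>
    ungroup() |>
    mutate(
      retained = .data$n_beads <= max_beads,
      drop_reason = if_else(.data$retained, NA_character_, "overloaded")
    ) |>
    select("bead_barcode", "well_id", "n_beads", "retained", "drop_reason") |>
    arrange(.data$well_id, .data$bead_barcode)
  structure(out, threshold = threshold, max_beads = as.integer(max_beads),
            class = c("well_partition", class(out)))
}

#' Assign reads to single cells and build per-cell outputs
#'
#' Relabels each read with its well's representative bead barcode and splits
#' co-resident nuclei by preindex: the final single-cell barcode is the pair
#' (preindex, representative bead barcode). Reads on beads of dropped
#' (overloaded) wells, or on beads absent from the partition, are discarded
#' and tallied. For RNA a gene x cell UMI count matrix is built (UMIs
#' deduplicated per gene and cell); for ATAC a per-cell fragment table is
#' returned (duplicate fragments per cell collapsed into a count).
#'
#' @param tags Corrected tagged reads; RNA counting uses columns `gene` and
#'   `umi` when present.
#' @param partition A [merge_beads()] partition.
#' @param assay `"rna"` or `"atac"`.
#' @return An object of class `cell_assignment`: a list with `cells` (tibble
#'   of `cell_barcode`, `preindex`, `well_id`, `n_reads`), `counts` (RNA:
#'   sparse gene x cell matrix, or `NULL`), `fragments` (ATAC: tibble, or
#'   `NULL`) and `n_dropped_reads`.
#' @export
assign_cells <- function(tags, partition, assay = c("rna", "atac")) {
  assay <- match.arg(assay)
  stopifnot(inherits(partition, "well_partition"))
  kept_map <- partition |> filter(.data$retained)
  labeled <- tags |>
    inner_join(kept_map |> select("bead_barcode", "well_id"),
               by = "bead_barcode") |>
    mutate(cell_barcode = paste(.data$preindex, .data$well_id, sep = "+"))
  n_dropped <- nrow(tags) - nrow(labeled)
  cells <- labeled |>
    group_by(.data$cell_barcode, .data$preindex, .data$well_id) |>
    summarise(n_reads = n(), .groups = "drop") |>
    arrange(.data$cell_barcode)
  counts <- NULL
  fragments <- NULL
  if (assay == "rna" && all(c("gene", "umi") %in% names(labeled))) {
    mol <- labeled |>
      distinct(.data$cell_barcode, .data$gene, .data$umi) |>
      count(.data$gene, .data$cell_barcode, name = "n")
    genes <- sort(unique(mol$gene))
    cb <- cells$cell_barcode
    counts <- Matrix::sparseMatrix(
      i = match(mol$gene, genes),
      j = match(mol$cell_barcode, cb),
      x = mol$n,
      dims = c(length(genes), length(cb)),
      dimnames = list(genes, cb)
    )
  } else if (assay == "atac" && all(c("chrom", "start", "end") %in% names(labeled))) {
    fragments <- labeled |>
      count(.data$chrom, .data$start, .data$end,
            barcode = .data$cell_barcode, name = "count") |>
      arrange(.data$chrom, .data$start, .data$end, .data$barcode)
  }
  structure(
    list(cells = cells, counts = counts, fragments = fragments,
         n_dropped_reads = n_dropped),
    class = "cell_assignment"
  )
}

#' @export
print.cell_assignment <- function(x, ...) {
  cat("<cell_assignment> ", nrow(x$cells), " cells; ",
      x$n_dropped_reads, " reads dropped (bead not in a retained well)\n",
      sep = "")
  invisible(x)
}

#' One-call well deconvolution
#'
#' Runs the full identification of cell-containing wells: per-bead feature
#' sets, top-barcode filtering, sparse Jaccard, knee-calling, bead merging
#' and the overloaded-well filter, then splits wells into single cells by
#' preindex.
#'
#' @inheritParams build_feature_sets
#' @inheritParams merge_beads
#' @param top_n Retain this many bead barcodes by unit count before pairing
#'   (default 20000).
#' @param min_shared,strategy Passed to [jaccard_pairs()] / [knee_threshold()].
#' @return A list with `features`, `pairs`, `threshold`, `partition`,
#'   `assignment` and a one-row `report` tibble of counts at each stage.
#' @export
deconvolve_wells <- function(tags, assay = c("rna", "atac"),
                             spikein_mode = c("union", "refine", "none"),
                             top_n = 20000L, min_shared = 1L,
                             strategy = "distance", max_beads = 6L) {
  assay <- match.arg(assay)
  spikein_mode <- match.arg(spikein_mode)
  features <- build_feature_sets(tags, assay, spikein_mode)
  units <- attr(features, "units")
  keep <- top_barcodes(units, n = top_n)$barcode
  features_kept <- features |> filter(.data$bead_barcode %in% keep)
  attributes(features_kept)[c("units", "assay", "spikein_mode")] <-
    attributes(features)[c("units", "assay", "spikein_mode")]
  class(features_kept) <- class(features)
  pairs <- jaccard_pairs(features_kept, min_shared = min_shared)
  threshold <- knee_threshold(pairs$jaccard, strategy = strategy)
  partition <- merge_beads(pairs, threshold = as.numeric(threshold),
                           max_beads = max_beads,
                           beads = unique(features_kept$bead_barcode))
  assignment <- assign_cells(tags, partition, assay = assay)
  report <- tibble(
    n_reads = nrow(tags),
    n_beads_observed = nrow(units),
    n_beads_kept = length(keep),
    n_pairs = nrow(pairs),
    threshold = as.numeric(threshold),
    n_wells_retained = length(unique(partition$well_id[partition$retained])),
    n_wells_dropped = length(unique(partition$well_id[!partition$retained])),
    n_cells = nrow(assignment$cells),
    n_reads_dropped = assignment$n_dropped_reads
  )
  list(features = features_kept, pairs = pairs, threshold = threshold,
       partition = partition, assignment = assignment, report = report)
}
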