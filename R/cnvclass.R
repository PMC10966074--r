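#' Build pseudobulks by within-group hierarchical clustering
#'
#' Cells are first grouped (typically sample-source x cell type); groups with
#' fewer cells than their requested number of pseudobulks are dropped and
#' recorded. Within each surviving group, cells are clustered on the
#' Euclidean distance between their count profiles (Ward linkage) and the
#' tree is cut into the requested number of clusters; each cluster's counts
#' are summed and the summed profile is scaled to `normalization_total`.
#'
#' @param counts Gene x cell matrix (dense or sparse) with dimnames.
#' @param cell_groups Data frame with columns `cell` and `group`.
#' @param n_per_group Number of pseudobulks per group: a single integer or a
#'   named vector keyed by group.
#' @param normalization_total Post-normalization column total. Default 1e7.
#' @param linkage Agglomeration method for [stats::hclust()]. Default
#'   `"ward.D2"`.
#' @param normalize_cells Scale each cell to the group's median library size
#'   before computing distances (default `TRUE`). Clustering raw counts lets
#'   total library size dominate the Euclidean metric, which skews how many
#'   clusters each expression state receives; size-normalised clustering
#'   allocates clusters by composition. Set `FALSE` to cluster raw counts.
#' @return An object of class `pseudobulk_set`: a list with `profiles`
#'   (normalized gene x pseudobulk matrix), `raw` (pre-normalization sums),
#'   `members` (tibble `cell`, `pseudobulk`, `group`), `dropped` (tibble of
#'   dropped groups) and `normalization_total`.
#' @export
build_pseudobulks <- function(counts, cell_groups, n_per_group,
                              normalization_total = 1e7,
                              linkage = "ward.D2",
                              normalize_cells = TRUE) {
  if (length(counts) == 0L || nrow(counts) == 0L || ncol(counts) == 0L) {
    stop("`counts` is empty", call. = FALSE)
  }
  stopifnot(all(c("cell", "group") %in% names(cell_groups)))
  cell_groups <- as_tibble(cell_groups)
  if (!all(cell_groups$cell %in% colnames(counts))) {
    stop("some cells in `cell_groups` are absent from `counts`", call. = FALSE)
  }
  grps <- unique(cell_groups$group)
  n_req <- if (length(n_per_group) == 1L && is.null(names(n_per_group))) {
    setNames(rep(as.integer(n_per_group), length(grps)), grps)
  } else {
    setNames(as.integer(n_per_group[grps]), grps)
  }
  if (anyNA(n_req) || any(n_req < 1L)) {
    stop("`n_per_group` must give an integer >= 1 for every group",
         call. = FALSE)
  }
  members <- list()
  dropped <- list()
  for (g in grps) {
    cells_g <- cell_groups$cell[cell_groups$group == g]
    ng <- n_req[[g]]
    if (length(cells_g) < ng) {
      dropped[[g]] <- tibble(group = g, n_cells = length(cells_g),
                             n_requested = ng)
      next
    }
    cl <- if (ng == 1L) {
      rep(1L, length(cells_g))
    } else {
      sub <- as.matrix(counts[, cells_g, drop = FALSE])
      if (normalize_cells) {
        tot <- colSums(sub)
        sub <- sweep(sub, 2, tot / stats::median(tot), "/")
      }
      cutree(hclust(dist(t(sub)), method = linkage), k = ng)
    }
    members[[g]] <- tibble(
      cell = cells_g, group = g,
      pseudobulk = sprintf("%s.pb%03d", g, cl)
    )
  }
  members <- bind_rows(members)
  if (nrow(members) == 0L) stop("all groups were dropped", call. = FALSE)
  pbs <- sort(unique(members$pseudobulk))
  agg <- Matrix::sparseMatrix(
    i = match(members$pseudobulk, pbs), j = seq_len(nrow(members)), x = 1,
    dims = c(length(pbs), nrow(members))
  )
  raw <- as.matrix(Matrix::tcrossprod(
    methods::as(Matrix::Matrix(counts[, members$cell, drop = FALSE],
                               sparse = TRUE), "generalMatrix"), agg))
  dimnames(raw) <- list(rownames(counts), pbs)
  profiles <- sweep(raw, 2, colSums(raw), "/") * normalization_total
  structure(
    list(profiles = profiles, raw = raw,
         members = members |> arrange(.data$pseudobulk, .data$cell),
         dropped = bind_rows(dropped),
         normalization_total = normalization_total),
    class = "pseudobulk_set"
  )
}

#' @export
print.pseudobulk_set <- function(x, ...) {
  cat("<pseudobulk_set> ", ncol(x$profiles), " pseudobulks over ",
      nrow(x$members), " cells (", nrow(x$dropped), " group(s) dropped); ",
      "normalized to ", format(x$normalization_total, scientific = TRUE),
      "\n", sep = "")
  invisible(x)
}

#' Windowed relative-expression CNV estimate
#'
#' A deliberately simple region-level CNV estimator for pseudobulk profiles:
#' per pseudobulk, the log2 ratio of its normalized expression to the mean of
#' the reference pseudobulks is smoothed along each chromosome with a
#' centered moving average (partial windows at chromosome ends), then the
#' whole matrix is scaled into \[-1, 1\] by dividing by its maximum absolute
#' value (zero stays neutral). Any externally produced region x pseudobulk
#' CNV matrix can be substituted via [as_cnv_matrix()], so the downstream
#' classifier is estimator-agnostic.
#'
#' @param pseudobulks A [build_pseudobulks()] result, or a normalized
#'   gene x pseudobulk matrix.
#' @param genes Gene map with columns `gene`, `chrom`, `start` (and
#'   optionally `cytoband`), covering the matrix rows.
#' @param reference Character vector of reference pseudobulk column names
#'   (e.g. the tumor-adjacent pseudobulks).
#' @param window Odd moving-average window in genes. Default 101.
#' @param pseudocount Added to numerator and denominator of the ratio.
#'   Default 1; use 0 for exact ratios on strictly positive profiles.
#' @param scale_mode `"matrix"` divides by the matrix-wide maximum absolute
#'   value; `"gene"` scales each gene row independently.
#' @return An object of class `cnv_matrix`: a list with `values` (region x
#'   pseudobulk matrix in \[-1, 1\]), `regions` (tibble), `scale_range`,
#'   `window`.
#' @export
estimate_cnv_windowed <- function(pseudobulks, genes, reference,
                                  window = 101L, pseudocount = 1,
                                  scale_mode = c("matrix", "gene")) {
  scale_mode <- match.arg(scale_mode)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("`window` must be a positive odd integer", call. = FALSE)
  }
  prof <- if (inherits(pseudobulks, "pseudobulk_set")) {
    pseudobulks$profiles
  } else {
    as.matrix(pseudobulks)
  }
  if (length(reference) == 0L || !all(reference %in% colnames(prof))) {
    stop("`reference` must name columns of the profile matrix", call. = FALSE)
  }
  genes <- as_tibble(genes)
  stopifnot(all(c("gene", "chrom", "start") %in% names(genes)))
  genes <- genes |> arrange(.data$chrom, .data$start)
  if (!all(rownames(prof) %in% genes$gene)) {
    stop("profile rows missing from the gene map", call. = FALSE)
  }
  genes <- genes |> filter(.data$gene %in% rownames(prof))
  prof <- prof[genes$gene, , drop = FALSE]
  ref_mean <- rowMeans(prof[, reference, drop = FALSE])
  lr <- log2(sweep(prof + pseudocount, 1, ref_mean + pseudocount, "/"))
  smoothed <- lr
  half <- (window - 1L) %/% 2L
  for (ch in unique(genes$chrom)) {
    rows <- which(genes$chrom == ch)
    if (length(rows) > 1L && half > 0L) {
      smoothed[rows, ] <- centered_ma(lr[rows, , drop = FALSE], half)
    }
  }
  m <- max(abs(smoothed))
  values <- if (scale_mode == "matrix") {
    if (m > 0) smoothed / m else smoothed
  } else {
    rm <- apply(abs(smoothed), 1, max)
    sweep(smoothed, 1, ifelse(rm > 0, rm, 1), "/")
  }
  structure(
    list(values = values, regions = genes, scale_range = c(-1, 1),
         window = window),
    class = "cnv_matrix"
  )
}

# centered moving average with partial windows at the edges, per column,
# via cumulative sums (exact, O(n) per column)
centered_ma <- function(x, half) {
  n <- nrow(x)
  cs <- rbind(0, apply(x, 2, cumsum))
  hi <- pmin(seq_len(n) + half, n)
  lo <- pmax(seq_len(n) - half, 1L)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
}

#' Wrap an externally produced CNV matrix
#'
#' @param values Region x pseudobulk matrix of scaled CNV values.
#' @param regions Region metadata tibble (at least `gene` or a region id
#'   matching rownames, plus `chrom`, `start`; `cytoband` if available).
#' @param scale_range Stated value range. Default c(-1, 1).
#' @return A `cnv_matrix` object.
#' @export
as_cnv_matrix <- function(values, regions, scale_range = c(-1, 1)) {
  values <- as.matrix(values)
  if (any(values < scale_range[1] - 1e-9 | values > scale_range[2] + 1e-9)) {
    stop("values fall outside `scale_range`", call. = FALSE)
  }
  structure(list(values = values, regions = as_tibble(regions),
                 scale_range = scale_range, window = NA_integer_),
            class = "cnv_matrix")
}

#' CNV score of scaled profiles
#'
#' The CNV score of a pseudobulk is the quadratic sum (sum of squares) of its
#' scaled CNV-region values; it is invariant to the sign of any region.
#'
#' @param x A `cnv_matrix`, or a matrix / numeric vector of values scaled to
#'   \[-1, 1\].
#' @return Named numeric vector of per-pseudobulk scores.
#' @examples
#' cnv_score(c(0.5, -0.5))
#' @export
cnv_score <- function(x) {
  values <- if (inherits(x, "cnv_matrix")) x$values else x
  rng <- if (inherits(x, "cnv_matrix")) x$scale_range else c(-1, 1)
  if (any(values < rng[1] - 1e-9 | values > rng[2] + 1e-9)) {
    stop("values fall outside the scale range [", rng[1], ", ", rng[2], "]",
         call. = FALSE)
  }
  if (is.null(dim(values))) sum(values^2) else colSums(values^2)
}

#' Tissue-level score expectations with outlier correction
#'
#' The normal expectation is the mean CNV score of tumor-adjacent
#' pseudobulks and the malignant expectation the mean over tumor
#' pseudobulks. Initial means are corrected by removing outlier pseudobulks
#' — adjacent pseudobulks scoring at or above the initial malignant
#' expectation, and tumor pseudobulks scoring at or below the initial normal
#' expectation (these plausibly are malignant cells in adjacent tissue and
#' normal cells in tumor, respectively) — and the means are recomputed once
#' on the survivors.
#'
#' @param scores Named numeric vector of pseudobulk CNV scores.
#' @param tissue Character vector (same order/names) with values `"tumor"`
#'   or `"adjacent"`; other values are ignored.
#' @return An object of class `cnv_expectations`: list with
#'   `normal_expectation`, `malignant_expectation`, `outliers_removed`
#'   (tibble), `initial` (the uncorrected means).
#' @examples
#' compute_expectations(c(a1 = 0.1, a2 = 0.2, t1 = 0.8, t2 = 1.0),
#'                      c("adjacent", "adjacent", "tumor", "tumor"))
#' @export
compute_expectations <- function(scores, tissue) {
  stopifnot(length(scores) == length(tissue))
  adj <- scores[tissue == "adjacent"]
  tum <- scores[tissue == "tumor"]
  if (length(adj) == 0L || length(tum) == 0L) {
    stop("both tumor and adjacent pseudobulks are required", call. = FALSE)
  }
  normal0 <- mean(adj)
  malignant0 <- mean(tum)
  out_adj <- adj[adj >= malignant0]
  out_tum <- tum[tum <= normal0]
  adj2 <- adj[adj < malignant0]
  tum2 <- tum[tum > normal0]
  if (length(adj2) == 0L || length(tum2) == 0L) {
    stop("outlier removal emptied a tissue; expectations undefined",
         call. = FALSE)
  }
  normal_expectation <- mean(adj2)
  malignant_expectation <- mean(tum2)
  outliers <- bind_rows(
    tibble(pseudobulk = names(out_adj) %||% character(0),
           score = unname(out_adj), tissue = rep("adjacent", length(out_adj))),
    tibble(pseudobulk = names(out_tum) %||% character(0),
           score = unname(out_tum), tissue = rep("tumor", length(out_tum)))
  )
  if (normal_expectation == malignant_expectation) {
    warning("normal and malignant expectations coincide; ",
            "classification is degenerate")
  }
  structure(
    list(normal_expectation = normal_expectation,
         malignant_expectation = malignant_expectation,
         outliers_removed = outliers,
         initial = c(normal = normal0, malignant = malignant0)),
    class = "cnv_expectations"
  )
}

#' @export
print.cnv_expectations <- function(x, ...) {
  cat("<cnv_expectations> normal = ", signif(x$normal_expectation, 5),
      ", malignant = ", signif(x$malignant_expectation, 5), " (",
      nrow(x$outliers_removed), " outlier(s) removed)\n", sep = "")
  invisible(x)
}

#' Iterative hierarchical normal/malignant classification
#'
#' Pseudobulk CNV profiles are Ward-clustered into `min(k, n)` clusters; a
#' cluster whose mean CNV score is at or below the normal expectation is
#' labelled normal (inclusive), at or above the malignant expectation
#' malignant, and anything between is intermediate. Intermediate pseudobulks
#' are re-clustered with the same `k` and the rule re-applied, until a round
#' assigns nothing new or `max_recursion` rounds have run; survivors stay
#' intermediate.
#'
#' @param cnv A `cnv_matrix` (profiles used for clustering).
#' @param scores Named pseudobulk CNV scores, e.g. [cnv_score()] output.
#' @param expectations A [compute_expectations()] object.
#' @param k Clusters per round. Default 50.
#' @param max_recursion Maximum rounds. Default 5.
#' @param linkage [stats::hclust()] method. Default `"ward.D2"`.
#' @return An object of class `cnv_classification`: tibble with columns
#'   `pseudobulk`, `score`, `label` (`normal`/`malignant`/`intermediate`),
#'   `depth` (round of assignment; `NA` for terminal intermediates), plus
#'   attributes `expectations` and `depth_used`.
#' @export
iterative_classify <- function(cnv, scores, expectations, k = 50L,
                               max_recursion = 5L, linkage = "ward.D2") {
  stopifnot(inherits(expectations, "cnv_expectations"))
  ne <- expectations$normal_expectation
  me <- expectations$malignant_expectation
  if (ne > me) {
    stop("normal expectation exceeds malignant expectation; ",
         "classification cannot proceed", call. = FALSE)
  }
  profiles <- t(if (inherits(cnv, "cnv_matrix")) cnv$values else as.matrix(cnv))
  pbs <- rownames(profiles)
  stopifnot(!is.null(pbs), all(pbs %in% names(scores)))
  scores <- scores[pbs]
  label <- setNames(rep(NA_character_, length(pbs)), pbs)
  depth <- setNames(rep(NA_integer_, length(pbs)), pbs)
  active <- pbs
  round_i <- 0L
  while (length(active) > 0L && round_i < max_recursion) {
    round_i <- round_i + 1L
    kk <- min(k, length(active))
    cl <- if (length(active) == 1L) {
      setNames(1L, active)
    } else {
      cutree(hclust(dist(profiles[active, , drop = FALSE]), method = linkage),
             k = kk)
    }
    assigned_any <- FALSE
    for (g in unique(cl)) {
      mem <- active[cl == g]
      ms <- mean(scores[mem])
      lab <- if (ms <= ne) "normal" else if (ms >= me) "malignant" else NA
      if (!is.na(lab)) {
        label[mem] <- lab
        depth[mem] <- round_i
        assigned_any <- TRUE
      }
    }
    active <- names(label)[is.na(label)]
    if (!assigned_any) break
  }
  label[is.na(label)] <- "intermediate"
  out <- tibble(pseudobulk = pbs, score = unname(scores),
                label = unname(label), depth = unname(depth))
  structure(out, expectations = expectations, depth_used = round_i,
            k = as.integer(k), max_recursion = as.integer(max_recursion),
            class = c("cnv_classification", class(out)))
}

#' Propagate pseudobulk labels to member cells
#'
#' Each cell inherits the label of its pseudobulk; a cell whose pseudobulk is
#' absent from the classification is an error.
#'
#' @param classification A [iterative_classify()] result.
#' @param members Tibble with columns `cell` and `pseudobulk` (e.g. from
#'   [build_pseudobulks()]).
#' @return Tibble with `cell`, `pseudobulk`, `label`.
#' @export
propagate_to_cells <- function(classification, members) {
  stopifnot(all(c("cell", "pseudobulk") %in% names(members)))
  orphans <- setdiff(members$pseudobulk, classification$pseudobulk)
  if (length(orphans) > 0L) {
    stop("cells belong to unclassified pseudobulk(s): ",
         paste(head(orphans, 3), collapse = ", "), call. = FALSE)
  }
  as_tibble(members)[c("cell", "pseudobulk")] |>
    inner_join(as_tibble(classification)[c("pseudobulk", "label")],
               by = "pseudobulk") |>
    arrange(.data$cell)
}

#' Full malignant-cell calling pipeline
#'
#' Convenience wrapper: pseudobulks per (group x) tissue, windowed CNV
#' against the adjacent-tissue reference, scoring, expectations with outlier
#' correction, iterative classification, and propagation back to cells.
#'
#' @param counts Gene x cell count matrix.
#' @param cells Tibble with `cell` and `group`; group names must be
#'   `"tumor"`, `"adjacent"`, `"normal"` (normal is optional and is used
#'   neither for reference nor expectations, only classified).
#' @param genes Gene map (`gene`, `chrom`, `start`, optionally `cytoband`).
#' @param n_per_group Pseudobulks per group (single integer or named).
#' @param window,k,max_recursion,normalization_total,pseudocount See the
#'   stage functions.
#' @return A list with `pseudobulks`, `cnv`, `scores`, `expectations`,
#'   `classification`, `cell_labels`.
#' @export
classify_malignant <- function(counts, cells, genes,
                               n_per_group = c(tumor = 100L, adjacent = 50L,
                                               normal = 50L),
                               window = 101L, k = 50L, max_recursion = 5L,
                               normalization_total = 1e7, pseudocount = 1) {
  pb <- build_pseudobulks(counts, cells |> rename(group = "group"),
                          n_per_group,
                          normalization_total = normalization_total)
  tissue_of <- function(pbs) sub("\\.pb[0-9]+$", "", pbs)
  reference <- colnames(pb$profiles)[tissue_of(colnames(pb$profiles)) == "adjacent"]
  cnv <- estimate_cnv_windowed(pb, genes, reference, window = window,
                               pseudocount = pseudocount)
  scores <- cnv_score(cnv)
  tissue <- tissue_of(names(scores))
  expectations <- compute_expectations(scores, tissue)
  classification <- iterative_classify(cnv, scores, expectations, k = k,
                                       max_recursion = max_recursion)
  cell_labels <- propagate_to_cells(classification, pb$members)
  list(pseudobulks = pb, cnv = cnv, scores = scores,
       expectations = expectations, classification = classification,
       cell_labels = cell_labels)
}
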