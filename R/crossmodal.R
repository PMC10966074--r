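#' Cytoband-level CNV effects per method
#'
#' Reduces each method's region x pseudobulk CNV matrix to a per-cytoband
#' duplication/deletion effect: values are scaled into \[-2, 2\] (division by
#' the matrix maximum absolute value, times 2, so zero stays neutral),
#' averaged over the genes/bins of each cytoband, and the effect is the mean
#' over malignant pseudobulks minus the mean over normal pseudobulks.
#' Positive effects indicate duplication, negative deletion. Only cytobands
#' present in every method are kept.
#'
#' @param methods Named list of `cnv_matrix` objects (their `regions` must
#'   carry a `cytoband` column) or of plain region x pseudobulk matrices
#'   accompanied by a `cytoband` attribute-free `regions` tibble inside a
#'   `cnv_matrix` (use [as_cnv_matrix()]).
#' @param labels Data frame with columns `pseudobulk` and `label`
#'   (`"malignant"` / `"normal"`; other labels are ignored).
#' @return An object of class `effect_table`: a tibble with `cytoband` and
#'   one effect column per method.
#' @export
cytoband_effects <- function(methods, labels) {
  stopifnot(is.list(methods), !is.null(names(methods)))
  stopifnot(all(c("pseudobulk", "label") %in% names(labels)))
  labels <- as_tibble(labels)
  mal <- labels$pseudobulk[labels$label == "malignant"]
  nor <- labels$pseudobulk[labels$label == "normal"]
  if (length(mal) == 0L || length(nor) == 0L) {
    stop("`labels` must contain both malignant and normal pseudobulks",
         call. = FALSE)
  }
  per_method <- purrr::imap(methods, function(m, name) {
    stopifnot(inherits(m, "cnv_matrix"))
    if (!"cytoband" %in% names(m$regions)) {
      stop("method '", name, "' has no cytoband annotation", call. = FALSE)
    }
    v <- m$values
    mx <- max(abs(v))
    if (mx > 0) v <- v / mx * 2  # rescale to [-2, 2], zero preserved
    mal_m <- intersect(mal, colnames(v))
    nor_m <- intersect(nor, colnames(v))
    if (length(mal_m) == 0L || length(nor_m) == 0L) {
      stop("method '", name, "' lacks malignant or normal pseudobulks",
           call. = FALSE)
    }
    tibble(
      cytoband = m$regions$cytoband,
      delta = rowMeans(v[, mal_m, drop = FALSE]) -
        rowMeans(v[, nor_m, drop = FALSE])
    ) |>
      group_by(.data$cytoband) |>
      summarise(!!name := mean(.data$delta), .groups = "drop")
  })
  out <- purrr::reduce(per_method, inner_join, by = "cytoband")
  if (nrow(out) == 0L) stop("no overlapping cytobands across methods",
                            call. = FALSE)
  structure(arrange(out, .data$cytoband),
            class = c("effect_table", class(out)))
}

#' Cross-method concordance of cytoband effects
#'
#' Labels each cytoband `dup_effect` when every method's effect is strictly
#' positive, `del_effect` when every effect is strictly negative, and
#' `not_correlated` otherwise (a zero effect counts as disagreement), and
#' computes the Spearman correlation of effects for every method pair over
#' the shared cytobands.
#'
#' @param effects An [cytoband_effects()] table (>= 3 cytobands for rho).
#' @return An object of class `cnv_concordance`: list with `table` (the
#'   effect table plus a `label` column) and `rho` (tibble `method_a`,
#'   `method_b`, `rho`, `n`; `rho` is `NA` when an effect vector is
#'   constant, i.e. rank correlation is undefined).
#' @export
concordance <- function(effects) {
  stopifnot(inherits(effects, "effect_table"))
  method_cols <- setdiff(names(effects), "cytoband")
  if (nrow(effects) < 3L) {
    stop("need >= 3 overlapping cytobands for rank correlation",
         call. = FALSE)
  }
  em <- as.matrix(as_tibble(effects)[method_cols])
  all_pos <- rowSums(em > 0) == ncol(em)
  all_neg <- rowSums(em < 0) == ncol(em)
  table <- as_tibble(effects) |>
    mutate(label = dplyr::case_when(
      all_pos ~ "dup_effect",
      all_neg ~ "del_effect",
      TRUE ~ "not_correlated"
    ))
  pairs <- utils::combn(method_cols, 2, simplify = FALSE)
  rho <- purrr::map_dfr(pairs, function(p) {
    a <- em[, p[1]]
    b <- em[, p[2]]
    r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      message("constant effect vector for pair ", p[1], "/", p[2],
              ": rho undefined")
      NA_real_
    } else {
      cor(a, b, method = "spearman")
    }
    tibble(method_a = p[1], method_b = p[2], rho = r, n = nrow(em))
  })
  structure(list(table = table, rho = rho), class = "cnv_concordance")
}

#' @export
print.cnv_concordance <- function(x, ...) {
  cat("<cnv_concordance> ", nrow(x$table), " cytobands: ",
      sum(x$table$label == "dup_effect"), " dup, ",
      sum(x$table$label == "del_effect"), " del, ",
      sum(x$table$label == "not_correlated"), " not correlated\n", sep = "")
  print(x$rho)
  invisible(x)
}

#' K-nearest-neighbour value transfer between modalities
#'
#' For each query point in a shared embedding (e.g. a common CCA space), the
#' transferred value is the unweighted mean of the values attached to its
#' `k` nearest reference points by Euclidean distance. Distance ties are
#' broken by reference index, so the result is deterministic.
#'
#' @param query Numeric matrix/data frame of query coordinates.
#' @param reference Numeric matrix/data frame of reference coordinates
#'   (same dimensionality).
#' @param values Numeric vector of reference values (e.g. pseudotime), one
#'   per reference row.
#' @param k Number of neighbours. Default 50; must not exceed the reference
#'   size.
#' @return Numeric vector of transferred values, one per query row.
#' @examples
#' ref <- cbind(x = c(0, 1, 2), y = c(0, 0, 0))
#' knn_value_transfer(rbind(c(0.1, 0)), ref, values = c(10, 20, 30), k = 1)
#' @export
knn_value_transfer <- function(query, reference, values, k = 50L) {
  query <- as.matrix(query)
  reference <- as.matrix(reference)
  if (ncol(query) != ncol(reference)) {
    stop("query and reference must share dimensionality", call. = FALSE)
  }
  if (length(values) != nrow(reference)) {
    stop("`values` must have one entry per reference point", call. = FALSE)
  }
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  if (k > nrow(reference)) {
    stop("`k` exceeds the reference size (", nrow(reference), ")",
         call. = FALSE)
  }
  # exact squared Euclidean cross-distances
  d2 <- outer(rowSums(query^2), rowSums(reference^2), "+") -
    2 * tcrossprod(query, reference)
  apply(d2, 1, function(d) {
    idx <- order(d, seq_along(d))[seq_len(k)]  # ties broken by index
    mean(values[idx])
  })
}
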