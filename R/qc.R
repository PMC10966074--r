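#' Assay- and sample-specific QC thresholds
#'
#' Bundles the per-assay, per-sample-class filtering rules. Defaults follow
#' the platform's processing: RNA cells below 500 transcripts are discarded
#' (tumor-derived RNA cells below 300 detected genes); ATAC species-mixing
#' cells below 3000 reads are low quality; wild-type tissue ATAC cells are
#' removed when TSS enrichment < 7 *or* unique fragments < 1000, while tumor
#' ATAC cells are removed only when fragments < 800 *and* TSS enrichment
#' < 4. Species purity is strict: a cell is species-specific only when more
#' than `purity` (default 0.80) of its units map to one genome.
#'
#' @param assay `"rna"` or `"atac"`.
#' @param sample_class `"cell_line"`, `"wildtype_tissue"` or `"tumor"`.
#' @param min_transcripts,min_genes_tumor,min_reads_atac,min_fragments,min_tss,purity
#'   Override individual thresholds; `min_fragments`/`min_tss` default to
#'   1000/7 for wild-type tissue and 800/4 for tumor.
#' @return An object of class `qc_thresholds`.
#' @examples
#' qc_thresholds("atac", "tumor")
#' @export
qc_thresholds <- function(assay = c("rna", "atac"),
                          sample_class = c("cell_line", "wildtype_tissue",
                                           "tumor"),
                          min_transcripts = 500,
                          min_genes_tumor = 300,
                          min_reads_atac = 3000,
                          min_fragments = NULL,
                          min_tss = NULL,
                          purity = 0.80) {
  assay <- match.arg(assay)
  sample_class <- match.arg(sample_class)
  if (is.null(min_fragments)) {
    min_fragments <- if (sample_class == "tumor") 800 else 1000
  }
  if (is.null(min_tss)) {
    min_tss <- if (sample_class == "tumor") 4 else 7
  }
  vals <- c(min_transcripts, min_genes_tumor, min_reads_atac, min_fragments,
            min_tss)
  if (any(vals < 0)) stop("thresholds must be >= 0", call. = FALSE)
  if (purity <= 0.5 || purity > 1) {
    stop("`purity` must lie in (0.5, 1]", call. = FALSE)
  }
  structure(
    list(assay = assay, sample_class = sample_class,
         min_transcripts = min_transcripts,
         min_genes_tumor = min_genes_tumor,
         min_reads_atac = min_reads_atac,
         min_fragments = min_fragments,
         min_tss = min_tss,
         purity = purity),
    class = "qc_thresholds"
  )
}

#' @export
print.qc_thresholds <- function(x, ...) {
  cat("<qc_thresholds> ", x$assay, " / ", x$sample_class, "\n", sep = "")
  str <- unlist(x[-(1:2)])
  cat(paste0("  ", names(str), " = ", str, collapse = "\n"), "\n")
  invisible(x)
}

# which metadata columns a threshold set needs, and the removal rule
qc_rules <- function(thresholds) {
  with(thresholds, {
    if (assay == "rna") {
      if (sample_class == "tumor") {
        list(need = "genes_detected",
             rules = list(low_genes = function(m) m$genes_detected < min_genes_tumor))
      } else {
        list(need = "total_counts",
             rules = list(low_transcripts = function(m) m$total_counts < min_transcripts))
      }
    } else {
      if (sample_class == "cell_line") {
        list(need = "total_counts",
             rules = list(low_reads = function(m) m$total_counts < min_reads_atac))
      } else if (sample_class == "wildtype_tissue") {
        # OR rule: either failure removes the cell
        list(need = c("fragments", "tss_score"),
             rules = list(
               low_fragments = function(m) m$fragments < min_fragments,
               low_tss = function(m) m$tss_score < min_tss
             ))
      } else {
        # tumor: removed only when both fragments and TSS fail
        list(need = c("fragments", "tss_score"),
             rules = list(
               low_fragments_and_tss = function(m)
                 m$fragments < min_fragments & m$tss_score < min_tss
             ))
      }
    }
  })
}

#' Filter cells by QC thresholds
#'
#' Applies the active thresholds for the assay and sample class; a cell is
#' retained iff it fails none of the removal rules. The returned tibble
#' carries a per-rule removal report as attribute `report` (a cell failing
#' several rules is counted under each).
#'
#' @param metadata Per-cell metadata: a data frame with a `cell_barcode`
#'   column plus whichever of `total_counts`, `genes_detected`, `fragments`,
#'   `tss_score` the active thresholds need.
#' @param thresholds A [qc_thresholds()] object.
#' @return The retained rows of `metadata`, with attribute `report`.
#' @examples
#' meta <- tibble::tibble(cell_barcode = c("a", "b"),
#'                        total_counts = c(499, 1200))
#' filter_cells(meta, qc_thresholds("rna", "cell_line"))
#' @export
filter_cells <- function(metadata, thresholds) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  metadata <- as_tibble(metadata)
  spec <- qc_rules(thresholds)
  missing_cols <- setdiff(spec$need, names(metadata))
  if (length(missing_cols) > 0L) {
    stop("metadata is missing required field(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  fails <- lapply(spec$rules, function(f) f(metadata))
  removed <- Reduce(`|`, fails)
  report <- tibble(
    rule = names(spec$rules),
    n_removed = unname(vapply(fails, sum, integer(1)))
  )
  out <- metadata[!removed, , drop = FALSE]
  attr(out, "report") <- report
  out
}

#' Classify cells by species in a barnyard experiment
#'
#' Cells below the assay's quality floor (500 transcripts for RNA, 3000 reads
#' for ATAC) are labelled `low_quality` before any species call. A remaining
#' cell is species-specific when strictly more than `purity` (default 0.80)
#' of its unique units map to one genome; otherwise it is a `collision`.
#'
#' @param species_counts A data frame with columns `cell_barcode` and two
#'   per-species unit-count columns (any names, e.g. `human`, `mouse`).
#' @param thresholds A [qc_thresholds()] object (its `assay` selects the
#'   quality floor).
#' @return A tibble with the input columns plus `total`, `share_max` and
#'   `label` (one of the two species column names, `"collision"` or
#'   `"low_quality"`).
#' @examples
#' x <- tibble::tibble(cell_barcode = c("a", "b"),
#'                     human = c(900, 300), mouse = c(100, 300))
#' classify_species(x, qc_thresholds("rna", "cell_line"))
#' @export
classify_species <- function(species_counts, thresholds) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  x <- as_tibble(species_counts)
  sp_cols <- setdiff(names(x), "cell_barcode")
  if (length(sp_cols) != 2L) {
    stop("`species_counts` must have exactly two species columns",
         call. = FALSE)
  }
  a <- x[[sp_cols[1]]]
  b <- x[[sp_cols[2]]]
  if (any(a < 0) || any(b < 0)) stop("counts must be >= 0", call. = FALSE)
  total <- a + b
  floor_units <- if (thresholds$assay == "rna") {
    thresholds$min_transcripts
  } else {
    thresholds$min_reads_atac
  }
  share_a <- ifelse(total > 0, a / total, NA_real_)
  label <- dplyr::case_when(
    total < floor_units ~ "low_quality",
    share_a > thresholds$purity ~ sp_cols[1],
    (1 - share_a) > thresholds$purity ~ sp_cols[2],
    TRUE ~ "collision"
  )
  x |>
    mutate(total = total,
           share_max = pmax(share_a, 1 - share_a),
           label = label)
}

#' Collision (multiplet) rate from species calls
#'
#' The fraction of classified cells labelled `collision`; low-quality cells
#' are excluded from the denominator, since they are discarded before
#' classification.
#'
#' @param calls A [classify_species()] result.
#' @return The collision rate as a fraction, with attribute `counts`
#'   (named vector: collisions, species-specific, low-quality).
#' @examples
#' calls <- tibble::tibble(label = c(rep("human", 150), rep("mouse", 48),
#'                                   rep("collision", 2)))
#' collision_rate(calls)
#' @export
collision_rate <- function(calls) {
  lab <- calls$label
  n_low <- sum(lab == "low_quality")
  n_coll <- sum(lab == "collision")
  n_specific <- sum(lab != "low_quality" & lab != "collision")
  n_classified <- n_coll + n_specific
  if (n_classified == 0L) {
    stop("no classified (non-low-quality) cells", call. = FALSE)
  }
  structure(n_coll / n_classified,
            counts = c(collision = n_coll, species_specific = n_specific,
                       low_quality = n_low))
}
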