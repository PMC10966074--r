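#' Tidy and summarise a well partition
#'
#' @param x A [merge_beads()] result.
#' @param ... Unused.
#' @return `tidy()` returns the bead-to-well tibble; `glance()` a one-row
#'   summary (beads, retained/dropped wells, threshold, max beads).
#' @export
tidy.well_partition <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.well_partition
#' @export
glance.well_partition <- function(x, ...) {
  tibble(
    n_beads = nrow(x),
    n_beads_retained = sum(x$retained),
    n_wells_retained = length(unique(x$well_id[x$retained])),
    n_wells_dropped = length(unique(x$well_id[!x$retained])),
    max_beads = attr(x, "max_beads"),
    threshold = as.numeric(attr(x, "threshold"))
  )
}

#' Tidy and summarise a CNV classification
#'
#' @param x An [iterative_classify()] result.
#' @param ... Unused.
#' @return `tidy()` returns the per-pseudobulk label tibble; `glance()` a
#'   one-row summary with the expectations, label counts and recursion depth
#'   used.
#' @export
tidy.cnv_classification <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.cnv_classification
#' @export
glance.cnv_classification <- function(x, ...) {
  e <- attr(x, "expectations")
  tibble(
    n_pseudobulks = nrow(x),
    n_normal = sum(x$label == "normal"),
    n_malignant = sum(x$label == "malignant"),
    n_intermediate = sum(x$label == "intermediate"),
    normal_expectation = e$normal_expectation,
    malignant_expectation = e$malignant_expectation,
    depth_used = attr(x, "depth_used"),
    k = attr(x, "k")
  )
}

#' Tidy and summarise a cross-method concordance
#'
#' @param x A [concordance()] result.
#' @param ... Unused.
#' @return `tidy()` returns the labelled cytoband effect table in long form
#'   (`cytoband`, `method`, `effect`, `label`); `glance()` a one-row summary
#'   with cytoband counts and the median pairwise rho.
#' @export
tidy.cnv_concordance <- function(x, ...) {
  x$table |>
    tidyr::pivot_longer(-c("cytoband", "label"),
                        names_to = "method", values_to = "effect") |>
    select("cytoband", "method", "effect", "label")
}

#' @rdname tidy.cnv_concordance
#' @export
glance.cnv_concordance <- function(x, ...) {
  tibble(
    n_cytobands = nrow(x$table),
    n_dup = sum(x$table$label == "dup_effect"),
    n_del = sum(x$table$label == "del_effect"),
    n_not_correlated = sum(x$table$label == "not_correlated"),
    median_rho = stats::median(x$rho$rho, na.rm = TRUE)
  )
}
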