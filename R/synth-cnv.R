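#' Parameters for the CNV-study simulator
#'
#' Describes a three-group (tumor / tumor-adjacent / normal) expression study
#' with planted copy-number clones. The genome is a panel of genes laid out
#' along chromosomes and grouped into cytobands; each clone names a set of
#' cytobands, a log2 amplitude, and its prevalence in each group.
#'
#' @param n_genes Number of genes. Default 1200.
#' @param n_chroms Chromosomes the panel spans. Default 6.
#' @param bands_per_chrom Cytobands per chromosome. Default 7 (42 total).
#' @param cells Named integer vector of cells per group. Default
#'   c(tumor = 600, adjacent = 300, normal = 300).
#' @param amplitude Log2 amplitude of the default clone (ignored when
#'   `clones` is supplied). Default 0.3.
#' @param clones A list of clones, each a list with `cytobands` (character),
#'   `amplitude` (log2 fold change; clone cells multiply affected genes by
#'   `2^amplitude`) and `prevalence` (named fractions per group). The default
#'   single clone amplifies 10% of the genome at amplitude 0.3 with
#'   prevalence 0.7 in tumor (typical tumor purity), 0 in adjacent and
#'   normal tissue.
#' @param noise_sd Standard deviation of multiplicative log-normal noise
#'   applied per matrix entry. Default 0.1.
#' @param baseline_shape,baseline_scale Gamma parameters of per-gene baseline
#'   mean expression. Defaults 3 and 25 (mean 75 counts per gene), emulating
#'   deeply sampled profiles over a reduced gene panel so that Euclidean
#'   clustering of cell count profiles is informative.
#' @param seed Integer seed.
#' @return An object of class `cnv_study_params`.
#' @export
cnv_study_params <- function(n_genes = 1200L, n_chroms = 6L,
                             bands_per_chrom = 7L,
                             cells = c(tumor = 600L, adjacent = 300L,
                                       normal = 300L),
                             amplitude = 0.3,
                             clones = NULL,
                             noise_sd = 0.1,
                             baseline_shape = 3, baseline_scale = 25,
                             seed = 1L) {
  n_genes <- as.integer(n_genes)
  genes <- cnv_gene_map(n_genes, n_chroms, bands_per_chrom)
  if (is.null(clones)) {
    n_bands <- n_chroms * bands_per_chrom
    target <- ceiling(0.1 * n_bands)
    clones <- list(list(
      cytobands = unique(genes$cytoband)[seq_len(target)],
      amplitude = amplitude,
      prevalence = c(tumor = 0.7, adjacent = 0, normal = 0)
    ))
  }
  for (cl in clones) {
    missing_bands <- setdiff(cl$cytobands, genes$cytoband)
    if (length(missing_bands) > 0L) {
      stop("clone cytoband(s) absent from map: ",
           paste(missing_bands, collapse = ", "), call. = FALSE)
    }
    if (any(cl$prevalence < 0 | cl$prevalence > 1)) {
      stop("clone prevalences must lie in [0, 1]", call. = FALSE)
    }
    if (!is.finite(cl$amplitude)) stop("clone amplitude must be finite",
                                       call. = FALSE)
  }
  structure(
    list(n_genes = n_genes, genes = genes, cells = cells, clones = clones,
         noise_sd = noise_sd, baseline_shape = baseline_shape,
         baseline_scale = baseline_scale, seed = as.integer(seed)),
    class = "cnv_study_params"
  )
}

# evenly spaced gene panel with chromosome and cytoband assignments
cnv_gene_map <- function(n_genes, n_chroms, bands_per_chrom) {
  chrom <- paste0("chr", rep(seq_len(n_chroms), length.out = n_genes,
                             each = ceiling(n_genes / n_chroms)))[seq_len(n_genes)]
  pos <- unlist(lapply(table(factor(chrom, unique(chrom))), seq_len),
                use.names = FALSE)
  per_band <- ceiling(ceiling(n_genes / n_chroms) / bands_per_chrom)
  band_idx <- (pos - 1L) %/% per_band + 1L
  tibble(
    gene = paste0("g", seq_len(n_genes)),
    chrom = chrom,
    start = pos * 100000L,
    end = pos * 100000L + 1000L,
    cytoband = paste0(sub("^chr", "", chrom), "q", band_idx)
  )
}

#' Simulate an expression matrix with planted CNV clones
#'
#' Draws a baseline count matrix (per-gene Gamma means, Poisson counts),
#' multiplies genes in clone-affected cytobands by `2^amplitude` in the cells
#' carrying the clone, then applies multiplicative log-normal noise. Clone
#' membership per cell is Bernoulli at the clone's prevalence for the cell's
#' group. With `noise_sd = 0` and a single clone of amplitude 1, affected
#' genes in clone cells are exactly doubled relative to the same-seed
#' baseline.
#'
#' @param params A [cnv_study_params()] object.
#' @return An object of class `cnv_study`: a list with `counts` (gene x cell
#'   matrix), `genes` (the gene map), `cells` (tibble with `cell`, `group`,
#'   `clone`, `malignant`) and `params`.
#' @examples
#' study <- simulate_cnv_study(cnv_study_params(
#'   n_genes = 60, cells = c(tumor = 20, adjacent = 10, normal = 10)))
#' dim(study$counts)
#' @export
simulate_cnv_study <- function(params) {
  stopifnot(inherits(params, "cnv_study_params"))
  set.seed(params$seed)
  genes <- params$genes
  groups <- rep(names(params$cells), params$cells)
  n_cells <- length(groups)
  cells <- tibble(
    cell = sprintf("c%05d", seq_len(n_cells)),
    group = groups,
    clone = NA_character_
  )
  base_mean <- stats::rgamma(params$n_genes, shape = params$baseline_shape,
                             scale = params$baseline_scale)
  counts <- matrix(rpois(params$n_genes * n_cells, base_mean),
                   nrow = params$n_genes, ncol = n_cells,
                   dimnames = list(genes$gene, cells$cell))
  counts <- counts * 1.0  # numeric from here on: CNV scaling is multiplicative
  for (ci in seq_along(params$clones)) {
    cl <- params$clones[[ci]]
    prev <- cl$prevalence[cells$group]
    prev[is.na(prev)] <- 0
    carrier <- runif(n_cells) < prev
    affected <- genes$cytoband %in% cl$cytobands
    counts[affected, carrier] <- counts[affected, carrier] * 2^cl$amplitude
    cells$clone[carrier] <- paste0("clone", ci)
  }
  if (params$noise_sd > 0) {
    counts <- counts * exp(matrix(rnorm(length(counts), 0, params$noise_sd),
                                  nrow = nrow(counts)))
  }
  cells$malignant <- !is.na(cells$clone)
  structure(
    list(counts = counts, genes = genes, cells = cells, params = params),
    class = "cnv_study"
  )
}

#' @export
print.cnv_study <- function(x, ...) {
  cat("<cnv_study> ", nrow(x$counts), " genes x ", ncol(x$counts), " cells; ",
      sum(x$cells$malignant), " malignant\n", sep = "")
  invisible(x)
}
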