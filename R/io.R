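#' Read and write fragment files
#'
#' Fragments use the conventional five-column TSV layout (`chrom`, `start`,
#' `end`, `barcode`, `count`) with 0-based half-open coordinates and no
#' header. `read_fragments()` validates every line and reports the first
#' malformed line by number.
#'
#' @param x A data frame with columns `chrom`, `start`, `end`, `barcode`,
#'   `count`.
#' @param path File path (plain or gzipped TSV).
#' @return `read_fragments()` returns a tibble; `write_fragments()` returns
#'   `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' frags <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L,
#'                         barcode = "AAAC", count = 1L)
#' write_fragments(frags, f)
#' read_fragments(f)
#' @export
write_fragments <- function(x, path) {
  need <- c("chrom", "start", "end", "barcode", "count")
  if (!all(need %in% names(x))) {
    stop("fragments need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  readr::write_tsv(x[need], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_fragments
#' @export
read_fragments <- function(path) {
  x <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "barcode", "count"),
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_character(),
      end = readr::col_character(), barcode = readr::col_character(),
      count = readr::col_character()
    ),
    progress = FALSE
  )
  for (col in c("start", "end", "count")) {
    v <- suppressWarnings(as.integer(x[[col]]))
    bad <- which(is.na(v) & !is.na(x[[col]]))
    if (length(bad) > 0L || anyNA(x[[col]])) {
      line <- if (length(bad) > 0L) bad[1] else which(is.na(x[[col]]))[1]
      stop("malformed fragments line ", line, " in ", path, call. = FALSE)
    }
    x[[col]] <- v
  }
  if (any(x$end < x$start)) {
    stop("malformed fragments line ", which(x$end < x$start)[1], " in ", path,
         ": end < start", call. = FALSE)
  }
  x
}

#' Read and write count matrices (MatrixMarket triplet)
#'
#' A count matrix directory holds `matrix.mtx` (genes/bins x cells),
#' `features.tsv` and `barcodes.tsv`.
#'
#' @param counts A `dgCMatrix` (or coercible matrix) with rownames (features)
#'   and colnames (cell barcodes).
#' @param dir Directory path.
#' @return `read_count_matrix()` returns a `dgCMatrix` with dimnames;
#'   `write_count_matrix()` returns `dir` invisibly.
#' @export
write_count_matrix <- function(counts, dir) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must carry feature rownames and cell colnames",
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(counts, file.path(dir, "matrix.mtx"))
  readr::write_lines(rownames(counts), file.path(dir, "features.tsv"))
  readr::write_lines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  feats <- readr::read_lines(file.path(dir, "features.tsv"), progress = FALSE)
  cells <- readr::read_lines(file.path(dir, "barcodes.tsv"), progress = FALSE)
  if (nrow(m) != length(feats) || ncol(m) != length(cells)) {
    stop("matrix dimensions do not match label files", call. = FALSE)
  }
  if (any(m@x < 0)) stop("counts must be non-negative", call. = FALSE)
  dimnames(m) <- list(feats, cells)
  methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
}

#' Read and write cytoband annotations (BED4)
#'
#' Four tab-separated columns: `chrom`, `start`, `end`, `cytoband`, 0-based
#' half-open.
#'
#' @param x Data frame with columns `chrom`, `start`, `end`, `cytoband`.
#' @param path File path.
#' @return `read_cytobands()` returns a tibble with an additional `width`
#'   column (`end - start`).
#' @export
write_cytobands <- function(x, path) {
  need <- c("chrom", "start", "end", "cytoband")
  if (!all(need %in% names(x))) {
    stop("cytobands need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  readr::write_tsv(x[need], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_cytobands
#' @export
read_cytobands <- function(path) {
  x <- readr::read_tsv(
    path, col_names = c("chrom", "start", "end", "cytoband"),
    col_types = "ciic", progress = FALSE
  )
  bad <- which(!complete.cases(x) | x$end < x$start)
  if (length(bad) > 0L) {
    stop("malformed cytoband line ", bad[1], " in ", path, call. = FALSE)
  }
  x$width <- x$end - x$start
  x
}

#' Read and write JSON reports and simulation truth
#'
#' Thin wrappers around jsonlite with deterministic formatting, used for
#' partition/report/truth files.
#'
#' @param x A list (or coercible object).
#' @param path File path.
#' @return `read_json_report()` returns the parsed list.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_json_report
#' @export
read_json_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read and write FASTQ
#'
#' FASTQ support (via Biostrings) for emitting simulated read pairs and
#' reading them back; round-trips names, sequences and qualities.
#'
#' @param x A tibble with columns `id`, `seq` and optionally `qual` (defaults
#'   to maximum quality).
#' @param path FASTQ path (`.gz` allowed).
#' @return `read_fastq()` returns a tibble with `id`, `seq`, `qual`.
#' @export
write_fastq <- function(x, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("FASTQ support requires the Biostrings package", call. = FALSE)
  }
  qual <- x$qual %||% strrep("I", nchar(x$seq))
  s <- Biostrings::DNAStringSet(x$seq)
  names(s) <- x$id
  Biostrings::writeXStringSet(
    s, path, format = "fastq",
    qualities = Biostrings::BStringSet(qual)
  )
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("FASTQ support requires the Biostrings package", call. = FALSE)
  }
  s <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(
    id = names(s),
    seq = unname(as.character(s)),
    qual = unname(as.character(S4Vectors::mcols(s)$qualities))
  )
}
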