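#' Describe the read structure of an assay
#'
#' A read layout records where each barcode and tag lives on the paired-end
#' read. For the RNA assay, read 1 starts with a molecule-tag region (a random
#' oligonucleotide stretch whose first `umi_len` bases serve as the UMI and
#' whose first `feature_tag_len` bases serve as the well-matching feature tag),
#' followed by the bead barcode; read 2 starts with the preindex. For the ATAC
#' assay, read 1 carries the bead barcode followed directly by the preindex,
#' and the molecule itself is an aligned fragment supplied as coordinates.
#'
#' @param assay `"rna"` or `"atac"`.
#' @param umi_len UMI length in bases (RNA only). Default 6.
#' @param feature_tag_len Length of the molecule-tag region used as the
#'   well-matching feature (RNA only). Default 17; must be >= `umi_len`.
#' @param bead_barcode_len Total bead-barcode length. Default 18.
#' @param bead_segments Number of split-pool segments composing the bead
#'   barcode. Default 3 (segments of 6).
#' @param preindex_len Preindex (plate barcode) length. Default 10.
#'
#' @return An object of class `read_layout`.
#' @examples
#' read_layout("rna")
#' read_layout("atac")
#' @export
read_layout <- function(assay = c("rna", "atac"),
                        umi_len = 6L,
                        feature_tag_len = 17L,
                        bead_barcode_len = 18L,
                        bead_segments = 3L,
                        preindex_len = 10L) {
  assay <- match.arg(assay)
  umi_len <- as.integer(umi_len)
  feature_tag_len <- as.integer(feature_tag_len)
  bead_barcode_len <- as.integer(bead_barcode_len)
  bead_segments <- as.integer(bead_segments)
  preindex_len <- as.integer(preindex_len)
  if (bead_barcode_len <= 0L || preindex_len <= 0L) {
    stop("barcode lengths must be positive", call. = FALSE)
  }
  if (bead_barcode_len %% bead_segments != 0L) {
    stop("`bead_barcode_len` must be divisible by `bead_segments`", call. = FALSE)
  }
  if (assay == "rna") {
    if (umi_len <= 0L || feature_tag_len <= 0L) {
      stop("`umi_len` and `feature_tag_len` must be positive", call. = FALSE)
    }
    if (feature_tag_len < umi_len) {
      stop("`feature_tag_len` must be >= `umi_len` (the UMI is its prefix)",
           call. = FALSE)
    }
  }
  structure(
    list(
      assay = assay,
      umi_len = if (assay == "rna") umi_len else 0L,
      feature_tag_len = if (assay == "rna") feature_tag_len else 0L,
      bead_barcode_len = bead_barcode_len,
      bead_segments = bead_segments,
      segment_len = bead_barcode_len %/% bead_segments,
      preindex_len = preindex_len
    ),
    class = "read_layout"
  )
}

#' @export
print.read_layout <- function(x, ...) {
  cat("<read_layout> assay =", x$assay, "\n")
  if (x$assay == "rna") {
    cat("  read1: [tag region ", x$feature_tag_len, " (UMI ", x$umi_len,
        ")][bead barcode ", x$bead_barcode_len, "] ; read2: [preindex ",
        x$preindex_len, "]\n", sep = "")
  } else {
    cat("  read1: [bead barcode ", x$bead_barcode_len, "][preindex ",
        x$preindex_len, "] ; fragment coordinates supplied separately\n",
        sep = "")
  }
  invisible(x)
}

# minimum read1 span required by a layout
layout_min_read1 <- function(layout) {
  if (layout$assay == "rna") {
    layout$feature_tag_len + layout$bead_barcode_len
  } else {
    layout$bead_barcode_len + layout$preindex_len
  }
}

random_kmers <- function(n, width) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
              nrow = n)
  do.call(paste0, asplit(m, 2))
}

kmer_matrix <- function(x) {
  do.call(rbind, strsplit(x, "", fixed = TRUE))
}

# Greedy packing of k-mers at pairwise Hamming distance >= min_dist.
# Deterministic given `seed`; restarts with derived seeds until `n` entries
# are found (the greedy outcome depends on candidate order, and for dense
# targets such as 96 six-mers at distance 3 only some orders reach n).
greedy_kmer_code <- function(n, width, min_dist, seed, max_restarts = 50L) {
  for (r in seq_len(max_restarts)) {
    set.seed(seed + (r - 1L) * 7919L)
    if (width <= 7L) {
      cand <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), width),
                                          stringsAsFactors = FALSE))
      cand <- sample(cand)
    } else {
      cand <- unique(random_kmers(max(50L * n, 5000L), width))
    }
    M <- kmer_matrix(cand)
    keep <- integer(0)
    for (i in seq_len(nrow(M))) {
      if (length(keep) == 0L) {
        keep <- i
      } else {
        d <- rowSums(M[keep, , drop = FALSE] !=
                       matrix(M[i, ], length(keep), width, byrow = TRUE))
        if (all(d >= min_dist)) keep <- c(keep, i)
      }
      if (length(keep) >= n) break
    }
    if (length(keep) >= n) return(sort(cand[keep[seq_len(n)]]))
  }
  stop("could not construct ", n, " ", width, "-mers at Hamming distance >= ",
       min_dist, " after ", max_restarts, " restarts", call. = FALSE)
}

#' Construct barcode whitelists
#'
#' Builds the per-segment bead-barcode whitelists (by default three segments of
#' 96 six-mers, mirroring three-round split-pool bead synthesis) and the
#' preindex whitelist (default 384 ten-mers). Entries are packed at a minimum
#' pairwise Hamming distance so that single-error correction is unambiguous:
#' with `min_dist >= 2 * max_hamming + 1`, every singly-mutated entry is
#' recovered exactly.
#'
#' @param n_segment_entries Entries per bead segment. Default 96.
#' @param segment_width Bases per bead segment. Default 6.
#' @param n_segments Number of bead segments. Default 3.
#' @param n_preindex Preindex entries. Default 384.
#' @param preindex_width Preindex length in bases. Default 10.
#' @param min_dist Minimum pairwise Hamming distance within each list.
#'   Default 3.
#' @param max_hamming Maximum correction distance. Default 1.
#' @param seed Integer seed; the construction is deterministic given the seed.
#'
#' @return An object of class `whitelist`: a list with `segments` (list of
#'   character vectors), `preindex` (character vector) and `max_hamming`.
#' @examples
#' wl <- make_whitelist(n_segment_entries = 8, n_preindex = 8, seed = 1)
#' lengths(wl$segments)
#' @export
make_whitelist <- function(n_segment_entries = 96L,
                           segment_width = 6L,
                           n_segments = 3L,
                           n_preindex = 384L,
                           preindex_width = 10L,
                           min_dist = 3L,
                           max_hamming = 1L,
                           seed = 1L) {
  key <- paste(n_segment_entries, segment_width, n_segments, n_preindex,
               preindex_width, min_dist, max_hamming, seed, sep = "|")
  if (!is.null(.whitelist_cache[[key]])) return(.whitelist_cache[[key]])
  segments <- lapply(seq_len(n_segments), function(s) {
    greedy_kmer_code(n_segment_entries, segment_width, min_dist,
                     seed = seed + 1000L * s)
  })
  preindex <- greedy_kmer_code(n_preindex, preindex_width, min_dist,
                               seed = seed + 999983L)
  out <- structure(
    list(segments = segments, preindex = preindex,
         segment_width = as.integer(segment_width),
         max_hamming = as.integer(max_hamming)),
    class = "whitelist"
  )
  .whitelist_cache[[key]] <- out
  out
}

# construction is deterministic per parameter set, so memoise within a session
.whitelist_cache <- new.env(parent = emptyenv())

#' @export
print.whitelist <- function(x, ...) {
  cat("<whitelist> ", length(x$segments), " bead segments x ",
      length(x$segments[[1]]), " entries (", x$segment_width, " nt), ",
      length(x$preindex), " preindex entries (", nchar(x$preindex[1]),
      " nt), max_hamming = ", x$max_hamming, "\n", sep = "")
  invisible(x)
}

#' Correct observed barcodes against a whitelist segment
#'
#' Returns, for each observed k-mer, the unique whitelist entry within
#' `max_hamming` mismatches, or `NA` when no entry or two equidistant entries
#' qualify (ambiguous observations are dropped downstream rather than guessed
#' at, which prevents barcode cross-talk). Exact matches are returned
#' unchanged, so correction is idempotent.
#'
#' @param observed Character vector of observed k-mers, all the same width as
#'   the whitelist entries.
#' @param whitelist_segment Character vector of allowed k-mers.
#' @param max_hamming Maximum number of mismatches to correct. Default 1.
#'
#' @return Character vector the length of `observed`, with `NA` for
#'   uncorrectable entries.
#' @examples
#' correct_barcode(c("ACGTAT", "ACGTAC"), c("ACGTAC", "TTTTTT"))
#' @export
correct_barcode <- function(observed, whitelist_segment, max_hamming = 1L) {
  if (length(observed) == 0L) return(character(0))
  w <- nchar(whitelist_segment[1])
  if (any(nchar(whitelist_segment) != w)) {
    stop("whitelist entries must all have the same width", call. = FALSE)
  }
  if (anyDuplicated(whitelist_segment)) {
    stop("whitelist entries must be unique", call. = FALSE)
  }
  bad_width <- !is.na(observed) & nchar(observed) != w
  if (any(bad_width)) {
    stop("observed barcodes must match the whitelist width (", w, ")",
         call. = FALSE)
  }
  uo <- unique(observed[!is.na(observed)])
  corrected <- setNames(rep(NA_character_, length(uo)), uo)
  exact <- uo %in% whitelist_segment
  corrected[exact] <- uo[exact]
  todo <- uo[!exact]
  if (length(todo) > 0L && max_hamming > 0L) {
    WM <- kmer_matrix(whitelist_segment)
    OM <- kmer_matrix(todo)
    for (i in seq_along(todo)) {
      d <- rowSums(WM != matrix(OM[i, ], nrow(WM), w, byrow = TRUE))
      dmin <- min(d)
      if (dmin <= max_hamming && sum(d == dmin) == 1L) {
        corrected[todo[i]] <- whitelist_segment[which.min(d)]
      }
    }
  }
  unname(corrected[observed])
}

# Segment-wise correction of composite bead barcodes: each segment is
# corrected against its own whitelist; any uncorrectable segment voids the
# whole barcode.
correct_bead_barcode <- function(observed, whitelist) {
  sw <- whitelist$segment_width
  parts <- lapply(seq_along(whitelist$segments), function(s) {
    seg <- substr(observed, (s - 1L) * sw + 1L, s * sw)
    correct_barcode(seg, whitelist$segments[[s]], whitelist$max_hamming)
  })
  out <- do.call(paste0, parts)
  out[Reduce(`|`, lapply(parts, is.na))] <- NA_character_
  out
}

#' Extract barcodes and tags from paired-end reads
#'
#' Slices the UMI, bead barcode, preindex and (RNA) feature tag out of raw
#' read pairs according to a [read_layout()]. Reads shorter than the span the
#' layout requires are flagged invalid, counted and skipped.
#'
#' @param reads A data frame with columns `read1` and `read2` (raw sequences);
#'   ATAC layouts may also carry `chrom`, `start`, `end` fragment columns,
#'   which are passed through.
#' @param layout A [read_layout()].
#'
#' @return A tibble of tagged reads (uncorrected) with columns `bead_barcode`,
#'   `preindex`, `umi`, `feature_tag` plus any fragment columns; the number of
#'   invalid reads is attached as attribute `n_invalid`.
#' @examples
#' lay <- read_layout("rna", feature_tag_len = 6)
#' reads <- tibble::tibble(
#'   read1 = paste0("ACGTAC", strrep("A", 18), "GGGG"),
#'   read2 = paste0(strrep("T", 10), "CCCC")
#' )
#' extract_tags(reads, lay)
#' @export
extract_tags <- function(reads, layout) {
  stopifnot(inherits(layout, "read_layout"))
  if (!all(c("read1", "read2") %in% names(reads))) {
    stop("`reads` must have columns `read1` and `read2`", call. = FALSE)
  }
  reads <- as_tibble(reads)
  if (nrow(reads) == 0L) stop("`reads` is empty", call. = FALSE)
  min1 <- layout_min_read1(layout)
  min2 <- if (layout$assay == "rna") layout$preindex_len else 0L
  ok <- !is.na(reads$read1) & !is.na(reads$read2) &
    nchar(reads$read1) >= min1 & nchar(reads$read2) >= min2
  kept <- reads[ok, , drop = FALSE]
  if (layout$assay == "rna") {
    tag_region <- substr(kept$read1, 1L, layout$feature_tag_len)
    out <- tibble(
      bead_barcode = substr(kept$read1, layout$feature_tag_len + 1L,
                            layout$feature_tag_len + layout$bead_barcode_len),
      preindex = substr(kept$read2, 1L, layout$preindex_len),
      umi = substr(tag_region, 1L, layout$umi_len),
      feature_tag = tag_region
    )
  } else {
    out <- tibble(
      bead_barcode = substr(kept$read1, 1L, layout$bead_barcode_len),
      preindex = substr(kept$read1, layout$bead_barcode_len + 1L,
                        layout$bead_barcode_len + layout$preindex_len),
      umi = "",
      feature_tag = ""
    )
    for (col in c("chrom", "start", "end", "spikein_tag")) {
      if (col %in% names(kept)) out[[col]] <- kept[[col]]
    }
  }
  n_invalid <- sum(!ok)
  if (n_invalid > 0L) {
    message(n_invalid, " read(s) shorter than the layout span were skipped")
  }
  attr(out, "n_invalid") <- n_invalid
  out
}

#' Correct tagged reads against whitelists
#'
#' Applies segment-wise bead-barcode correction and preindex correction to a
#' table of tagged reads; reads whose barcodes cannot be corrected
#' unambiguously are dropped and counted.
#'
#' @param tags A tibble as returned by [extract_tags()] (or the simulator).
#' @param whitelist A [make_whitelist()] object.
#'
#' @return The corrected tibble, with attribute `n_dropped`.
#' @export
correct_tags <- function(tags, whitelist) {
  stopifnot(inherits(whitelist, "whitelist"))
  bead <- correct_bead_barcode(tags$bead_barcode, whitelist)
  pre <- correct_barcode(tags$preindex, whitelist$preindex,
                         whitelist$max_hamming)
  keep <- !is.na(bead) & !is.na(pre)
  out <- tags[keep, , drop = FALSE]
  out$bead_barcode <- bead[keep]
  out$preindex <- pre[keep]
  attr(out, "n_dropped") <- sum(!keep)
  out
}
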