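#' Parameters for the chip simulator
#'
#' Describes a microwell chip run: how many partitions, how beads and nuclei
#' distribute over wells, how deeply each nucleus is sampled, and the barcode
#' space. Defaults emulate the platform's chip (10,000 partitions, 384
#' preindexes, three 96-entry bead-barcode segments) with beads uniform over
#' 1..8 per well and 0..2 nuclei per well at 300 molecules per nucleus.
#'
#' Capture physics: the chip amplifies each nucleus's molecules inside the
#' well, and every bead in the well samples that shared pool. Under the
#' default `capture_model = "bernoulli"`, each molecule is captured
#' independently by each bead of its well with probability `capture_rate`;
#' `"single"` assigns each molecule to exactly one uniformly chosen bead
#' (no sharing — useful as a negative control, since well deconvolution then
#' has no signal).
#'
#' @param n_wells Number of microwell partitions. Default 10000.
#' @param bead_probs Named numeric vector: probability of 0..8 beads per
#'   well (names are bead counts). Default uniform over 1..8. Mass on counts
#'   above 8 is an error.
#' @param nuclei_probs Named numeric vector over nuclei counts. Default
#'   uniform over 0..2.
#' @param molecules_per_nucleus Molecules sampled per nucleus. Default 300.
#' @param capture_rate Per-bead capture probability of each molecule
#'   (`"bernoulli"` model). Default 0.5.
#' @param capture_model `"bernoulli"` or `"single"`.
#' @param assay `"rna"` or `"atac"`.
#' @param n_genes Size of the simulated gene panel (RNA annotation labels).
#' @param spikeins_per_well Spike-in oligos per well (ATAC): each spike-in is
#'   a random 14-mer shared by, and observed on, every bead of its well.
#' @param species_mix Optional named fractions (two species) assigned to
#'   nuclei.
#' @param per_base_error_rate Per-base substitution rate applied to emitted
#'   barcode/tag sequences. Default 0.
#' @param whitelist A [make_whitelist()] object; built from `seed` when
#'   omitted.
#' @param seed Integer seed; identical seeds give identical simulations.
#' @return An object of class `chip_params`.
#' @export
chip_params <- function(n_wells = 10000L,
                        bead_probs = setNames(rep(1 / 8, 8), 1:8),
                        nuclei_probs = setNames(rep(1 / 3, 3), 0:2),
                        molecules_per_nucleus = 300L,
                        capture_rate = 0.5,
                        capture_model = c("bernoulli", "single"),
                        assay = c("rna", "atac"),
                        n_genes = 100L,
                        spikeins_per_well = 5L,
                        species_mix = NULL,
                        per_base_error_rate = 0,
                        whitelist = NULL,
                        seed = 1L) {
  capture_model <- match.arg(capture_model)
  assay <- match.arg(assay)
  chk_probs <- function(p, what, max_support = Inf) {
    if (is.null(names(p))) stop(what, " must be a named vector", call. = FALSE)
    k <- as.integer(names(p))
    if (anyNA(k) || any(k < 0)) stop(what, " has invalid counts", call. = FALSE)
    if (any(k > max_support & p > 0)) {
      stop(what, " puts mass on counts > ", max_support, call. = FALSE)
    }
    if (abs(sum(p) - 1) > 1e-8) stop(what, " must sum to 1", call. = FALSE)
  }
  chk_probs(bead_probs, "`bead_probs`", max_support = 8L)
  chk_probs(nuclei_probs, "`nuclei_probs`")
  if (capture_rate < 0 || capture_rate > 1 ||
      per_base_error_rate < 0 || per_base_error_rate > 1) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(species_mix)) {
    if (length(species_mix) != 2L || is.null(names(species_mix)) ||
        abs(sum(species_mix) - 1) > 1e-8) {
      stop("`species_mix` must be two named fractions summing to 1",
           call. = FALSE)
    }
  }
  structure(
    list(n_wells = as.integer(n_wells), bead_probs = bead_probs,
         nuclei_probs = nuclei_probs,
         molecules_per_nucleus = as.integer(molecules_per_nucleus),
         capture_rate = capture_rate, capture_model = capture_model,
         assay = assay, n_genes = as.integer(n_genes),
         spikeins_per_well = as.integer(spikeins_per_well),
         species_mix = species_mix,
         per_base_error_rate = per_base_error_rate,
         whitelist = whitelist, seed = as.integer(seed)),
    class = "chip_params"
  )
}

# substitute bases at a fixed per-base rate; x is a vector of equal-width
# strings
mutate_bases <- function(x, rate) {
  if (rate <= 0 || length(x) == 0L) return(x)
  w <- nchar(x[1])
  M <- kmer_matrix(x)
  hit <- which(runif(length(M)) < rate)
  if (length(hit) > 0L) {
    bases <- c("A", "C", "G", "T")
    cur <- M[hit]
    M[hit] <- vapply(cur, function(b) sample(setdiff(bases, b), 1L),
                     character(1))
  }
  do.call(paste0, asplit(M, 2))
}

#' Simulate a microwell chip with full ground truth
#'
#' Draws bead and nucleus occupancies per well, assigns bead barcodes from
#' the whitelist and preindexes to nuclei, samples each nucleus's molecules,
#' and emits one tagged read per capture event (see [chip_params()] for the
#' capture physics). RNA molecules carry a random 17-mer molecule tag (whose
#' prefix is the UMI) and a gene label; ATAC molecules carry unique fragment
#' coordinates, and each well's spike-in 14-mers are observed on every bead
#' of the well. Sequencing errors are applied at `per_base_error_rate`.
#' Identical seeds give identical output.
#'
#' @param params A [chip_params()] object.
#' @return An object of class `chip_sim`: a list with `tags` (tibble of
#'   tagged reads, including truth columns `well`, `nucleus`, `molecule`),
#'   `truth` (list of `wells`, `beads`, `nuclei` tibbles and `n_molecules`),
#'   `whitelist` and `params`.
#' @examples
#' sim <- simulate_chip(chip_params(n_wells = 20, seed = 1,
#'   whitelist = make_whitelist(n_segment_entries = 8, n_preindex = 8)))
#' nrow(sim$tags)
#' @export
simulate_chip <- function(params) {
  stopifnot(inherits(params, "chip_params"))
  wl <- params$whitelist %||% make_whitelist(seed = params$seed)
  set.seed(params$seed)

  # --- wells: bead and nucleus occupancy (drawn in fixed well order) ---
  draw_counts <- function(p, n) {
    support <- as.integer(names(p))
    support[sample.int(length(p), n, replace = TRUE, prob = p)]
  }
  n_beads_w <- draw_counts(params$bead_probs, params$n_wells)
  n_nuc_w <- draw_counts(params$nuclei_probs, params$n_wells)
  wells <- tibble(well = seq_len(params$n_wells),
                  n_beads = n_beads_w, n_nuclei = n_nuc_w)

  # --- beads: distinct barcodes sampled from the 96^3 combinatorial space ---
  n_beads <- sum(n_beads_w)
  n_seg <- lengths(wl$segments)
  if (n_beads > prod(n_seg)) {
    stop("chip needs ", n_beads, " distinct bead barcodes but the whitelist ",
         "spans only ", prod(n_seg), " combinations", call. = FALSE)
  }
  idx <- sample(prod(n_seg), n_beads) - 1L
  seg_idx <- cbind(idx %% n_seg[1],
                   (idx %/% n_seg[1]) %% n_seg[2],
                   idx %/% (n_seg[1] * n_seg[2]))
  bead_bc <- paste0(wl$segments[[1]][seg_idx[, 1] + 1L],
                    wl$segments[[2]][seg_idx[, 2] + 1L],
                    wl$segments[[3]][seg_idx[, 3] + 1L])
  beads <- tibble(bead_barcode = bead_bc,
                  well = rep(wells$well, wells$n_beads))

  # --- nuclei: preindex and optional species ---
  n_nuclei <- sum(n_nuc_w)
  nuclei <- tibble(
    nucleus = seq_len(n_nuclei),
    well = rep(wells$well, wells$n_nuclei),
    preindex = sample(wl$preindex, n_nuclei, replace = TRUE)
  )
  if (!is.null(params$species_mix)) {
    nuclei$species <- sample(names(params$species_mix), n_nuclei,
                             replace = TRUE, prob = params$species_mix)
  }

  # --- molecules: fixed depth per nucleus ---
  mpn <- params$molecules_per_nucleus
  n_mol <- n_nuclei * mpn
  molecules <- tibble(
    molecule = seq_len(n_mol),
    nucleus = rep(nuclei$nucleus, each = mpn),
    well = rep(nuclei$well, each = mpn)
  )
  if (params$assay == "rna") {
    molecules$gene <- paste0("g", sample.int(params$n_genes, n_mol,
                                             replace = TRUE))
    molecules$feature_tag <- random_kmers(n_mol, 17L)
  } else {
    molecules$chrom <- paste0("chr", sample.int(19L, n_mol, replace = TRUE))
    molecules$start <- sample.int(100000000L, n_mol, replace = TRUE)
    molecules$end <- molecules$start + 50L +
      sample.int(450L, n_mol, replace = TRUE)
  }

  # --- capture: molecules x beads of their well ---
  cap <- inner_join(molecules, beads, by = "well",
                    relationship = "many-to-many")
  if (params$capture_model == "bernoulli") {
    cap <- cap[runif(nrow(cap)) < params$capture_rate, , drop = FALSE]
  } else {
    cap <- cap |>
      group_by(.data$molecule) |>
      dplyr::slice_sample(n = 1) |>
      ungroup()
  }
  tags <- cap |>
    inner_join(nuclei, by = c("nucleus", "well")) |>
    arrange(.data$molecule, .data$bead_barcode)

  # --- ATAC spike-ins: one random 14-mer per (well, spike-in), observed on
  #     every bead of the well ---
  if (params$assay == "atac" && params$spikeins_per_well > 0L) {
    spike_wells <- wells |> filter(.data$n_beads > 0L)
    n_spk <- nrow(spike_wells) * params$spikeins_per_well
    spikes <- tibble(
      well = rep(spike_wells$well, each = params$spikeins_per_well),
      spikein_tag = random_kmers(n_spk, 14L)
    )
    spike_reads <- inner_join(spikes, beads, by = "well",
                              relationship = "many-to-many") |>
      mutate(molecule = NA_integer_, nucleus = NA_integer_,
             preindex = NA_character_)
    tags <- bind_rows(tags, spike_reads)
  }

  # --- sequencing error on emitted sequences ---
  err <- params$per_base_error_rate
  if (err > 0) {
    tags$bead_barcode <- mutate_bases(tags$bead_barcode, err)
    has_pre <- !is.na(tags$preindex)
    tags$preindex[has_pre] <- mutate_bases(tags$preindex[has_pre], err)
    if (params$assay == "rna") {
      tags$feature_tag <- mutate_bases(tags$feature_tag, err)
    }
  }
  if (params$assay == "rna") {
    tags$umi <- substr(tags$feature_tag, 1L, 6L)
  }
  tags <- tags |> mutate(read = dplyr::row_number()) |>
    select(dplyr::any_of(c("read", "bead_barcode", "preindex", "umi",
                           "feature_tag", "gene", "chrom", "start", "end",
                           "spikein_tag", "well", "nucleus", "molecule")))
  structure(
    list(tags = tags,
         truth = list(wells = wells, beads = beads, nuclei = nuclei,
                      n_molecules = n_mol),
         whitelist = wl, params = params),
    class = "chip_sim"
  )
}

#' @export
print.chip_sim <- function(x, ...) {
  cat("<chip_sim> ", x$params$assay, ": ", nrow(x$truth$wells), " wells, ",
      nrow(x$truth$beads), " beads, ", nrow(x$truth$nuclei), " nuclei, ",
      nrow(x$tags), " reads\n", sep = "")
  invisible(x)
}

#' Render simulated tagged reads as raw read pairs
#'
#' Reconstructs the raw paired-end sequences implied by a chip simulation
#' under the default read layout, for exercising [extract_tags()] and FASTQ
#' output. RNA: read 1 is the 17-base molecule-tag region followed by the
#' bead barcode and a poly-A stuffer; read 2 is the preindex plus stuffer.
#' ATAC: read 1 is the bead barcode followed by the preindex.
#'
#' @param sim A [simulate_chip()] result.
#' @return A tibble with columns `read1`, `read2` (plus fragment columns for
#'   ATAC), one row per simulated read.
#' @export
sim_read_pairs <- function(sim) {
  stopifnot(inherits(sim, "chip_sim"))
  tags <- sim$tags
  if (sim$params$assay == "rna") {
    tibble(
      read1 = paste0(tags$feature_tag, tags$bead_barcode, "AAAAAA"),
      read2 = paste0(tags$preindex, "AAAAAA")
    )
  } else {
    out <- tibble(
      read1 = paste0(tags$bead_barcode,
                     ifelse(is.na(tags$preindex),
                            strrep("N", nchar(sim$whitelist$preindex[1])),
                            tags$preindex)),
      read2 = strrep("A", 30L)
    )
    for (col in c("chrom", "start", "end", "spikein_tag")) {
      if (col %in% names(tags)) out[[col]] <- tags[[col]]
    }
    out
  }
}

#' Simulate a species-mixing (barnyard) experiment
#'
#' Plants an exact number of collision cells (`round(n_cells *
#' collision_fraction)`) among species-specific cells. Species-specific cells
#' draw a small cross-species contamination fraction; collision cells mix the
#' two species at a fraction drawn uniformly from `mix_range`.
#'
#' @param n_cells Number of cells. Default 5000.
#' @param collision_fraction Planted collision fraction. Default 0.02.
#' @param units_per_cell Sequenced units (UMIs/fragments) per cell.
#'   Default 1000.
#' @param contamination Cross-species contamination fraction in
#'   species-specific cells. Default 0.01.
#' @param mix_range Range of the minor-species fraction in collision cells.
#'   Default c(0.35, 0.65).
#' @param species Names of the two species columns.
#' @param seed Integer seed.
#' @return A tibble with `cell_barcode`, the two species unit counts, and
#'   the planted `truth` label.
#' @export
simulate_barnyard <- function(n_cells = 5000L, collision_fraction = 0.02,
                              units_per_cell = 1000L, contamination = 0.01,
                              mix_range = c(0.35, 0.65),
                              species = c("human", "mouse"), seed = 1L) {
  set.seed(seed)
  n_coll <- round(n_cells * collision_fraction)
  truth <- sample(c(rep("collision", n_coll),
                    sample(species, n_cells - n_coll, replace = TRUE)))
  own_frac <- ifelse(truth == "collision",
                     runif(n_cells, mix_range[1], mix_range[2]),
                     1 - contamination)
  own <- rbinom(n_cells, units_per_cell, own_frac)
  first_is_own <- truth != species[2]
  a <- ifelse(first_is_own, own, units_per_cell - own)
  out <- tibble(
    cell_barcode = sprintf("cell%05d", seq_len(n_cells)),
    !!species[1] := a,
    !!species[2] := units_per_cell - a,
    truth = truth
  )
  out
}
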