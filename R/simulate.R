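#' Default dentate-gyrus identity panel
#'
#' Marker-gene sets for the major dentate-gyrus cell populations
#' recoverable from a plate-based experiment: astrocytes/radial glia-like
#' cells, neural intermediate progenitors/neuroblasts, immature and
#' mature (granule) neurons, microglia, oligodendrocytes, OPCs and
#' endothelial cells. Used both by [assign_identities()] and as the
#' marker structure of the plate simulator, so label recovery can be
#' checked end to end.
#'
#' @return named list: identity -> character vector of marker symbols.
#' @export
default_identity_panel <- function() {
  list(
    astrocyte_rgl = c("S100b", "Sox2", "Sox9", "Aldoc", "Hopx", "Id4"),
    nipc_neuroblast = c("Eomes", "Dcx", "Ccnd2", "Sox11", "Calb2"),
    immature_neuron = c("Dsp", "Gda", "Rbm24", "Rasgrf2", "Rbfox3", "Ncam1"),
    mature_neuron = c("Rasgrp1", "Smad3", "Kcnip3", "Mfsd4", "Tanc1"),
    microglia = c("Csf1r", "Cx3cr1"),
    oligodendrocyte = c("Mbp", "Plp1"),
    opc = c("Olig1", "Sox10", "Cspg4"),
    endothelial = c("Prom1", "Esam")
  )
}

#' Parameters of the fixation-artifact plate simulator
#'
#' Defines a paired fresh/fixed SORT-seq-like experiment: 384-well plates
#' (8 no-template wells), ~8 dentate-gyrus-like populations with a
#' dominant granule-neuron type, ERCC spike-ins per well, UMI counts
#' saturating in a 4,096-barcode space, and condition-specific artifacts.
#'
#' Artifact knobs (all null when 0 / 1):
#' * `leakage` (delta): fraction of each fixed cell's molecules diverted
#'   to the shared ambient pool (fixation-permeabilized membranes).
#' * `contamination` (rho): fraction of each cell's captured molecules
#'   drawn from the ambient profile instead of its own.
#' * `length_decay` (lambda): in the fixed condition each gene's profile
#'   weight is multiplied by the per-molecule retention
#'   `exp(-lambda * L / 1e4)` (longer transcripts recover worse).
#' * `stress_induction` (s >= 1): multiplier on stress-panel weights in
#'   the fresh condition (sorting-induced stress; fixation arrests it).
#' * `damaged_frac`: fraction of fresh wells rendered low quality
#'   (endogenous content x `damaged_lib_factor`, mitochondrial share
#'   raised to `damaged_mito_share`); damage probability is tilted
#'   towards fragile neuronal types via `damage_weights`.
#'
#' @param n_types number of cell populations.
#' @param type_names,type_props population names and proportions
#'   (defaults: 8 DG-like types with granule neurons at 50%).
#' @param n_genes total endogenous genes (includes 13 mitochondrial and
#'   the 17-gene stress panel).
#' @param marker_boost fold-boost of a type's marker genes in its profile.
#' @param off_frac fraction of background genes switched fully off
#'   (weight 0) in each type's profile; other types' markers are always
#'   off. Real cell types express a subset of the genome, and these
#'   ambient-only genes are what makes contamination identifiable.
#' @param lib_meanlog,lib_sdlog log-normal molecules/cell.
#' @param leakage,contamination,length_decay,stress_induction,damaged_frac
#'   artifact knobs, see above.
#' @param damage_weights named per-type relative damage susceptibility.
#' @param damaged_lib_factor,damaged_mito_share damage transformation.
#' @param mito_share baseline mitochondrial fraction of a healthy profile.
#' @param ercc_per_well mean spike-in molecules per well.
#' @param n_ercc number of distinct spike-in species.
#' @param empty_ambient_rate endogenous background in empty wells, as a
#'   fraction of the mean library size.
#' @param K UMI space size.
#' @param structure_seed seed for the shared structure (gene lengths,
#'   expression profiles), so paired plates share profiles.
#' @return validated list of class `FixationSimParams`.
#' @export
fixation_sim_params <- function(n_types = 8,
                                type_names = names(default_identity_panel()),
                                type_props = c(mature_neuron = 0.50,
                                               immature_neuron = 0.12,
                                               astrocyte_rgl = 0.12,
                                               nipc_neuroblast = 0.08,
                                               oligodendrocyte = 0.06,
                                               opc = 0.05,
                                               microglia = 0.04,
                                               endothelial = 0.03),
                                n_genes = 2000,
                                marker_boost = 20,
                                off_frac = 0.3,
                                lib_meanlog = log(8000), lib_sdlog = 0.5,
                                leakage = 0.2,
                                contamination = 0.05,
                                length_decay = 0.2,
                                stress_induction = 2,
                                damaged_frac = 0.3,
                                damage_weights = c(mature_neuron = 2,
                                                   immature_neuron = 1.5),
                                damaged_lib_factor = 0.05,
                                damaged_mito_share = 0.40,
                                mito_share = 0.08,
                                ercc_per_well = 1500,
                                n_ercc = 20,
                                empty_ambient_rate = 0.005,
                                K = 4096,
                                structure_seed = 1) {
  if (n_types < 1) stop("n_types must be >= 1")
  if (length(type_names) != n_types) type_names <- type_names[seq_len(n_types)]
  if (anyNA(type_names)) stop("type_names must cover n_types")
  type_props <- type_props[type_names]
  if (anyNA(type_props)) stop("type_props must name every type")
  type_props <- type_props / sum(type_props)
  for (p in c(leakage, contamination, damaged_frac, damaged_lib_factor,
              damaged_mito_share, mito_share, empty_ambient_rate, off_frac))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  if (length_decay < 0) stop("length_decay must be >= 0")
  if (stress_induction < 1) stop("stress_induction must be >= 1")
  if (n_genes < 100) stop("n_genes must be >= 100")
  if (K < 1 || ercc_per_well < 0) stop("invalid K or ercc_per_well")
  dw <- stats::setNames(rep(1, n_types), type_names)
  dw[names(damage_weights)[names(damage_weights) %in% type_names]] <-
    damage_weights[names(damage_weights) %in% type_names]
  structure(list(n_types = n_types, type_names = type_names,
                 type_props = type_props, n_genes = n_genes,
                 marker_boost = marker_boost, off_frac = off_frac,
                 lib_meanlog = lib_meanlog, lib_sdlog = lib_sdlog,
                 leakage = leakage, contamination = contamination,
                 length_decay = length_decay,
                 stress_induction = stress_induction,
                 damaged_frac = damaged_frac, damage_weights = dw,
                 damaged_lib_factor = damaged_lib_factor,
                 damaged_mito_share = damaged_mito_share,
                 mito_share = mito_share,
                 ercc_per_well = ercc_per_well, n_ercc = n_ercc,
                 empty_ambient_rate = empty_ambient_rate,
                 K = K, structure_seed = structure_seed),
            class = "FixationSimParams")
}

# Shared structure of a simulated experiment: gene identities, lengths,
# per-type profiles, spike-in composition. Deterministic given
# params$structure_seed, so fresh and fixed plates share it.
.sim_structure <- function(params) {
  p <- params
  set.seed(p$structure_seed)
  panel <- default_identity_panel()[p$type_names]
  markers <- unlist(panel, use.names = FALSE)
  special <- c(mito_genes_mouse(), stress_panel(), markers)
  n_fill <- p$n_genes - length(special)
  if (n_fill < 0) stop("n_genes too small for the named gene sets")
  gene_names <- c(special, sprintf("Gene%04d", seq_len(n_fill)))
  lengths_bp <- round(10^stats::runif(p$n_genes, log10(500), log10(1e5)))
  is_mito <- startsWith(tolower(gene_names), "mt-")
  base <- stats::rlnorm(p$n_genes, 0, 1)
  # genes every type must express: mitochondrial, stress panel, own markers
  always_on <- gene_names %in% c(mito_genes_mouse(), stress_panel())
  W <- matrix(0, p$n_genes, p$n_types,
              dimnames = list(gene_names, p$type_names))
  for (t in seq_len(p$n_types)) {
    w <- base * exp(stats::rnorm(p$n_genes, 0, 0.4))
    own <- match(panel[[t]], gene_names)
    w[own] <- w[own] * p$marker_boost
    # type-specific silent genes: other types' markers plus a random
    # fraction of the background genes (ambient-only support)
    off <- gene_names %in% setdiff(markers, panel[[t]])
    candidates <- which(!always_on & !off & !(seq_along(w) %in% own))
    off[sample(candidates, round(p$off_frac * length(candidates)))] <- TRUE
    w[off] <- 0
    # pin the mitochondrial share of a healthy profile
    s_m <- sum(w[is_mito]) / sum(w)
    w[is_mito] <- w[is_mito] * p$mito_share / s_m
    w[!is_mito] <- w[!is_mito] * (1 - p$mito_share) / (1 - s_m)
    W[, t] <- w / sum(w)
  }
  ercc_names <- sprintf("ERCC-%05d", seq_len(p$n_ercc))
  ercc_w <- stats::rlnorm(p$n_ercc, 0, 0.7)
  ercc_w <- ercc_w / sum(ercc_w)
  list(gene_names = gene_names, lengths_bp = lengths_bp,
       is_mito = is_mito, W = W, panel = panel,
       ercc_names = ercc_names, ercc_w = ercc_w)
}

# Exact UMI saturation: every molecule draws a bin among K, per gene;
# the observed count is the number of distinct (gene, bin) pairs.
.umi_saturate <- function(mvec, K) {
  tot <- sum(mvec)
  if (tot == 0) return(numeric(length(mvec)))
  ids <- rep.int(seq_along(mvec), mvec)
  bins <- sample.int(K, tot, replace = TRUE)
  keys <- unique((ids - 1) * K + bins)
  tabulate(((keys - 1) %/% K) + 1, nbins = length(mvec))
}

# Condition-specific profile matrix and per-type retention factor.
.condition_profiles <- function(S, params, condition) {
  W <- S$W
  if (condition == "fresh") {
    idx <- match(tolower(stress_panel()), tolower(rownames(W)))
    idx <- idx[!is.na(idx)]
    W[idx, ] <- W[idx, ] * params$stress_induction
    W <- sweep(W, 2, colSums(W), "/")
    ret <- rep(1, ncol(W))
  } else {
    retention <- exp(-params$length_decay * S$lengths_bp / 1e4)
    W <- W * retention
    ret <- colSums(W)
    W <- sweep(W, 2, ret, "/")
  }
  list(W = W, retention = stats::setNames(ret, colnames(W)))
}

#' Simulate one SORT-seq-like plate
#'
#' Generates a raw 384-barcode count matrix (endogenous genes plus ERCC
#' spike-in rows) for one condition, together with full per-well ground
#' truth. Template wells hold one cell each: molecules are drawn
#' multinomially from `(1 - rho) * type profile + rho * ambient profile`,
#' with the condition transforms of [fixation_sim_params()] applied, and
#' every gene's molecules are pushed through exact UMI-bin sampling in a
#' `K`-barcode space. Empty (no-template) wells receive only spike-ins
#' plus a small Poisson ambient background. Bit-reproducible given
#' `(params, seed)`.
#'
#' @param params a [fixation_sim_params()] object.
#' @param condition `"fresh"` or `"fixed"`.
#' @param seed integer seed for the plate's sampling (the shared
#'   structure is governed by `params$structure_seed`).
#' @return list with `matrix` (raw `CountMatrix`, 384 barcodes, meta
#'   columns `well`, `condition`, `is_empty`), `truth` (data.frame per
#'   template well: `barcode`, `well`, `true_type`, `true_rho`,
#'   `damaged`, `lib_size`, `true_molecules`), and `annotation`
#'   (gene_symbol / exon_length_bp for the simulated genes).
#' @export
simulate_plate <- function(params, condition = c("fresh", "fixed"),
                           seed = 1) {
  condition <- match.arg(condition)
  stopifnot(inherits(params, "FixationSimParams"))
  S <- .sim_structure(params)
  prof <- .condition_profiles(S, params, condition)
  ambient <- as.vector(prof$W %*% params$type_props)
  ambient <- ambient / sum(ambient)
  layout <- read_plate_layout(NULL)
  wells <- layout$wells
  is_empty <- wells %in% layout$empty_wells
  n_wells <- length(wells)
  cell_wells <- which(!is_empty)
  n_cells <- length(cell_wells)

  set.seed(seed)
  types <- sample(params$type_names, n_cells, replace = TRUE,
                  prob = params$type_props)
  dmg_p <- params$damaged_frac * params$damage_weights[types] /
    sum(params$type_props * params$damage_weights)
  dmg_flag <- stats::rbinom(n_cells, 1, pmin(dmg_p, 1)) == 1
  damaged <- dmg_flag & condition == "fresh"
  lib <- stats::rlnorm(n_cells, params$lib_meanlog, params$lib_sdlog)

  n_genes <- params$n_genes
  counts <- matrix(0, n_genes + params$n_ercc, n_wells)
  rownames(counts) <- c(S$gene_names, S$ercc_names)
  colnames(counts) <- paste0(condition, "_", wells)
  truth_mol <- numeric(n_cells)
  mean_lib <- exp(params$lib_meanlog + params$lib_sdlog^2 / 2)

  for (i in seq_len(n_cells)) {
    t <- types[i]
    phi <- prof$W[, t]
    lib_i <- lib[i]
    if (damaged[i]) {
      s_m <- sum(phi[S$is_mito])
      phi[S$is_mito] <- phi[S$is_mito] * params$damaged_mito_share / s_m
      phi[!S$is_mito] <- phi[!S$is_mito] *
        (1 - params$damaged_mito_share) / (1 - s_m)
      lib_i <- lib_i * params$damaged_lib_factor
    }
    m <- if (condition == "fixed")
      round(lib_i * (1 - params$leakage) * prof$retention[t])
    else round(lib_i)
    truth_mol[i] <- m
    p_mix <- (1 - params$contamination) * phi +
      params$contamination * ambient
    mol <- stats::rmultinom(1, m, p_mix)[, 1]
    ercc_mol <- stats::rmultinom(1, stats::rpois(1, params$ercc_per_well),
                                 S$ercc_w)[, 1]
    counts[, cell_wells[i]] <- .umi_saturate(c(mol, ercc_mol), params$K)
  }
  for (j in which(is_empty)) {
    bg <- stats::rpois(1, params$empty_ambient_rate * mean_lib)
    mol <- stats::rmultinom(1, bg, ambient)[, 1]
    ercc_mol <- stats::rmultinom(1, stats::rpois(1, params$ercc_per_well),
                                 S$ercc_w)[, 1]
    counts[, j] <- .umi_saturate(c(mol, ercc_mol), params$K)
  }

  meta <- data.frame(well = wells, condition = condition,
                     is_empty = is_empty)
  truth <- data.frame(barcode = colnames(counts)[cell_wells],
                      well = wells[cell_wells],
                      true_type = types,
                      true_rho = params$contamination,
                      damaged = damaged,
                      lib_size = lib,
                      true_molecules = truth_mol,
                      row.names = NULL)
  annotation <- data.frame(gene_symbol = S$gene_names,
                           exon_length_bp = S$lengths_bp)
  list(matrix = count_matrix(counts, meta), truth = truth,
       annotation = annotation)
}

#' Simulate contaminated cells for EM parameter recovery
#'
#' A lighter companion to [simulate_plate()] for calibrating
#' [estimate_contamination()]: draws `n_cells` cells from the shared type
#' profiles with a known ambient-contamination fraction `rho` (no plate
#' geometry, no UMI saturation), returning the counts, the true type
#' labels and the true ambient profile.
#'
#' @param params a [fixation_sim_params()] object (profiles and library
#'   sizes are taken from it).
#' @param n_cells number of cells.
#' @param rho true contamination fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return list with `counts` (genes x cells), `types`, `ambient`, `rho`.
#' @export
simulate_mixture_cells <- function(params, n_cells, rho, seed = 1) {
  stopifnot(inherits(params, "FixationSimParams"), rho >= 0, rho <= 1)
  S <- .sim_structure(params)
  ambient <- as.vector(S$W %*% params$type_props)
  ambient <- ambient / sum(ambient)
  set.seed(seed)
  types <- sample(params$type_names, n_cells, replace = TRUE,
                  prob = params$type_props)
  lib <- round(stats::rlnorm(n_cells, params$lib_meanlog, params$lib_sdlog))
  counts <- vapply(seq_len(n_cells), function(i) {
    p_mix <- (1 - rho) * S$W[, types[i]] + rho * ambient
    stats::rmultinom(1, lib[i], p_mix)[, 1]
  }, numeric(params$n_genes))
  dimnames(counts) <- list(S$gene_names, sprintf("cell_%03d", seq_len(n_cells)))
  list(counts = counts, types = types,
       ambient = stats::setNames(ambient, S$gene_names), rho = rho)
}

#' Simulate a paired fresh/fixed experiment
#'
#' Both plates share expression profiles and gene lengths (the same
#' tissue sorted on the same day onto two plates); only the
#' condition-specific artifacts differ. The fresh plate is sampled with
#' `seed`, the fixed plate with `seed + 1`.
#'
#' @param params a [fixation_sim_params()] object.
#' @param seed integer seed.
#' @return list with elements `fresh` and `fixed` (each as
#'   [simulate_plate()]) and `annotation`.
#' @export
simulate_pair <- function(params, seed = 1) {
  fresh <- simulate_plate(params, "fresh", seed)
  fixed <- simulate_plate(params, "fixed", seed + 1)
  list(fresh = fresh, fixed = fixed, annotation = fresh$annotation)
}
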