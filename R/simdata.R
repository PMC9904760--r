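#' Configuration for the synthetic HSPC dataset generator
#'
#' Bundles and validates all parameters of the negative-binomial single-cell
#' count simulator. The defaults emulate a CD34+ hematopoietic
#' stem/progenitor landscape: 14 cell types spanning stem, progenitor and
#' committed states, type-specific marker genes, a mitochondrial gene block,
#' log-normal library sizes, donor batch effects, doublets, and a latent
#' pseudotime with branch structure.
#'
#' @param n_types Number of cell types (default 14).
#' @param type_names Optional character vector of type names (length
#'   `n_types`). Defaults to an HSPC-flavoured palette for 14 types or
#'   `Type01..` otherwise.
#' @param n_genes Number of non-mitochondrial genes.
#' @param markers_per_type Marker genes assigned to each type.
#' @param n_dynamic_genes Genes whose expression follows a non-constant
#'   trend along pseudotime.
#' @param n_cells_per_donor Cells simulated per donor.
#' @param donors_per_condition Named integer vector, condition -> number of
#'   donors. The first condition is the reference.
#' @param type_proportions Named list, condition -> probability vector over
#'   types (each summing to 1). Defaults to a shared HSPC-like composition.
#' @param marker_fold Fold-change (> 1) of a marker gene's mean in its own
#'   type relative to other types.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param library_size_lognormal Length-2 vector `(meanlog, sdlog)` of the
#'   log-normal library size distribution.
#' @param mito_fraction Length-2 vector `(mean, sd)` of the per-cell
#'   mitochondrial count fraction.
#' @param n_mito_genes Number of mitochondrial genes (named `MT-*`).
#' @param doublet_rate Fraction of cells replaced by two-parent doublets.
#' @param batch_shift_sd SD of per-donor log-scale gene shifts (0 = no batch
#'   effect).
#' @param n_branches Number of terminal differentiation branches.
#' @param n_regulons Number of regulons simulated for AUC matrices.
#' @param trend_amplitude Natural-log amplitude of dynamic gene trends.
#' @param seed Master seed; all generator randomness derives from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_types = 14L,
                       type_names = NULL,
                       n_genes = 1000L,
                       markers_per_type = 10L,
                       n_dynamic_genes = 30L,
                       n_cells_per_donor = 500L,
                       donors_per_condition = c(young = 5L, elderly = 3L),
                       type_proportions = NULL,
                       marker_fold = 5,
                       nb_dispersion = 0.4,
                       library_size_lognormal = c(meanlog = log(5000), sdlog = 0.3),
                       mito_fraction = c(mean = 0.03, sd = 0.01),
                       n_mito_genes = 13L,
                       doublet_rate = 0.02,
                       batch_shift_sd = 0,
                       n_branches = 3L,
                       n_regulons = 20L,
                       trend_amplitude = 1,
                       seed = 1L) {
  n_types <- as.integer(n_types)
  if (n_types < 1L) stop("n_types must be a positive integer")
  if (is.null(type_names)) {
    type_names <- if (n_types == 14L) {
      c("HSC", "MEP", "LMPP", "CLP", "GMP", "Monocyte_prog", "DC_prog",
        "ProB", "Erythroid_early", "Erythroid_late", "Megakaryocyte_prog",
        "Basophil_prog", "T_NK_prog", "Cycling_prog")
    } else {
      sprintf("Type%02d", seq_len(n_types))
    }
  }
  if (length(type_names) != n_types) stop("type_names must have length n_types")
  if (anyDuplicated(type_names)) stop("type_names must be unique")

  if (is.null(type_proportions)) {
    w <- 1 / (seq_len(n_types) + 2)
    base <- w / sum(w)
    type_proportions <- lapply(names(donors_per_condition), function(cond) base)
    names(type_proportions) <- names(donors_per_condition)
  }
  if (is.null(names(donors_per_condition)) ||
      any(!nzchar(names(donors_per_condition))))
    stop("donors_per_condition must be a named vector")
  if (any(donors_per_condition < 1)) stop("each condition needs >= 1 donor")
  for (cond in names(type_proportions)) {
    p <- type_proportions[[cond]]
    if (length(p) != n_types)
      stop(sprintf("type_proportions[['%s']] must have length n_types", cond))
    if (any(p < 0) || any(p > 1))
      stop(sprintf("type_proportions[['%s']] must lie in [0, 1]", cond))
    if (abs(sum(p) - 1) > 1e-9)
      stop(sprintf("type_proportions[['%s']] must sum to 1 (got %.12f)",
                   cond, sum(p)))
    names(type_proportions[[cond]]) <- type_names
  }
  if (marker_fold <= 1) stop("marker_fold must exceed 1")
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  stopifnot(n_genes >= 1, markers_per_type >= 1, n_cells_per_donor >= 1,
            n_mito_genes >= 1, n_branches >= 1, n_regulons >= 1)
  if (markers_per_type * n_types + n_dynamic_genes > n_genes)
    stop("n_genes too small for the requested markers and dynamic genes")
  .stop_if_not_prob(doublet_rate, "doublet_rate")
  .stop_if_not_prob(mito_fraction[["mean"]], "mito_fraction mean")
  if (batch_shift_sd < 0) stop("batch_shift_sd must be non-negative")
  if (library_size_lognormal[["sdlog"]] < 0) stop("library sdlog must be >= 0")

  structure(list(
    n_types = n_types, type_names = type_names, n_genes = as.integer(n_genes),
    markers_per_type = as.integer(markers_per_type),
    n_dynamic_genes = as.integer(n_dynamic_genes),
    n_cells_per_donor = as.integer(n_cells_per_donor),
    donors_per_condition = donors_per_condition,
    type_proportions = type_proportions,
    marker_fold = marker_fold, nb_dispersion = nb_dispersion,
    library_size_lognormal = library_size_lognormal,
    mito_fraction = mito_fraction, n_mito_genes = as.integer(n_mito_genes),
    doublet_rate = doublet_rate, batch_shift_sd = batch_shift_sd,
    n_branches = as.integer(n_branches), n_regulons = as.integer(n_regulons),
    trend_amplitude = trend_amplitude, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Evaluate a ground-truth trend function
#'
#' Trend functions are parametric curves on pseudotime `[0, 1]` used by the
#' simulator to modulate dynamic gene expression (natural-log scale).
#'
#' @param trend A trend descriptor (list with a `type` field: one of
#'   `"constant"`, `"linear"`, `"sigmoid"`, `"transient"`).
#' @param t Pseudotime values in `[0, 1]`.
#' @return Numeric vector of trend values.
#' @export
trend_value <- function(trend, t) {
  switch(trend$type,
    constant = rep(trend$value %||% 0, length(t)),
    linear = trend$intercept + trend$slope * t,
    sigmoid = trend$amplitude / (1 + exp(-(t - trend$midpoint) / trend$scale)),
    transient = trend$amplitude *
      exp(-(t - trend$midpoint)^2 / (2 * trend$width^2)),
    stop(sprintf("unknown trend type '%s'", trend$type))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gene-level generative model shared between reference and query: baseline
# relative expression, marker assignment, mitochondrial block, trend
# functions, branch geometry and regulon definitions.
.build_gene_model <- function(config) {
  ng <- config$n_genes
  genes <- sprintf("GENE%05d", seq_len(ng))
  mito <- sprintf("MT-G%02d", seq_len(config$n_mito_genes))

  baseline <- rgamma(ng, shape = 0.5, rate = 1) + 0.02

  marker_map <- vector("list", config$n_types)
  names(marker_map) <- config$type_names
  pool <- sample.int(ng)
  used <- 0L
  for (k in seq_len(config$n_types)) {
    idx <- pool[(used + 1L):(used + config$markers_per_type)]
    marker_map[[k]] <- genes[idx]
    # markers are moderately expressed so the fold-change is detectable
    baseline[idx] <- pmax(baseline[idx], 0.5)
    used <- used + config$markers_per_type
  }
  dyn_idx <- pool[(used + 1L):(used + config$n_dynamic_genes)]
  dynamic_genes <- genes[dyn_idx]
  baseline[dyn_idx] <- pmax(baseline[dyn_idx], 0.8)

  trend_functions <- lapply(genes, function(g) list(type = "constant", value = 0))
  names(trend_functions) <- genes
  kinds <- c("linear", "sigmoid", "transient")
  for (g in dynamic_genes) {
    kind <- sample(kinds, 1L)
    amp <- config$trend_amplitude * sample(c(-1, 1), 1L)
    trend_functions[[g]] <- switch(kind,
      linear = list(type = "linear", intercept = 0, slope = amp),
      sigmoid = list(type = "sigmoid", amplitude = amp,
                     midpoint = runif(1, 0.25, 0.75), scale = 0.08),
      transient = list(type = "transient", amplitude = amp,
                       midpoint = runif(1, 0.3, 0.7), width = 0.12))
  }

  # pseudotime centre per type: stem types early, committed types late
  type_center <- seq(0.08, 0.92, length.out = config$n_types)
  # branch membership: root type feeds all branches equally
  branch_names <- if (config$n_branches == 3L) {
    c("erythroid", "myeloid", "lymphoid")
  } else sprintf("branch%02d", seq_len(config$n_branches))
  branch_of_type <- ((seq_len(config$n_types) - 1L) %% config$n_branches) + 1L
  branch_of_type[1L] <- NA_integer_  # the root has no committed branch

  # regulons: one specific to each type, two ubiquitous (active in every
  # cell, tracked separately from the cluster-specific map), rest silent
  regulon_names <- sprintf("TF%03d(+)", seq_len(config$n_regulons))
  active_map <- lapply(config$type_names, function(tt) character(0))
  names(active_map) <- config$type_names
  n_specific <- min(config$n_regulons, config$n_types)
  for (r in seq_len(n_specific)) {
    tt <- config$type_names[r]
    active_map[[tt]] <- c(active_map[[tt]], regulon_names[r])
  }
  ubiquitous <- character(0)
  if (config$n_regulons >= n_specific + 2L)
    ubiquitous <- regulon_names[(n_specific + 1L):(n_specific + 2L)]

  regulon_targets <- lapply(regulon_names, function(r) {
    n_t <- sample(8:20, 1L)
    data.frame(tf = r, target = sample(genes, n_t),
               importance = rgamma(n_t, shape = 2, rate = 0.5) + 0.1,
               stringsAsFactors = FALSE)
  })
  names(regulon_targets) <- regulon_names

  list(genes = genes, mito_genes = mito, baseline = baseline,
       marker_map = marker_map, dynamic_genes = dynamic_genes,
       trend_functions = trend_functions, type_center = type_center,
       branch_names = branch_names, branch_of_type = branch_of_type,
       active_regulon_map = active_map, ubiquitous_regulons = ubiquitous,
       regulon_names = regulon_names, regulon_targets = regulon_targets)
}

# Draw one condition's cells from the gene model.
.generate_condition <- function(config, model, condition, proportions, seed) {
  withr::with_seed(seed, {
    n_donors <- config$donors_per_condition[[condition]]
    donors <- sprintf("%s_d%d", condition, seq_len(n_donors))
    n_cells <- n_donors * config$n_cells_per_donor
    donor <- rep(donors, each = config$n_cells_per_donor)

    label_idx <- sample.int(config$n_types, n_cells, replace = TRUE,
                            prob = proportions)
    labels <- config$type_names[label_idx]

    pt <- rnorm(n_cells, mean = model$type_center[label_idx], sd = 0.07)
    pt <- pmin(pmax(pt, 0), 1)

    # branch probabilities: softmax of pseudotime-scaled branch affinity
    nb <- config$n_branches
    aff <- matrix(0, n_cells, nb)
    own <- model$branch_of_type[label_idx]
    on_branch <- !is.na(own)
    aff[cbind(which(on_branch), own[on_branch])] <- 3
    bp <- .softmax_rows(aff * pt)
    colnames(bp) <- model$branch_names

    ng <- config$n_genes
    type_mult <- matrix(1, ng, config$n_types)
    for (k in seq_len(config$n_types)) {
      mk <- match(model$marker_map[[k]], model$genes)
      type_mult[mk, k] <- config$marker_fold
    }
    mu <- (model$baseline * type_mult)[, label_idx, drop = FALSE]
    for (g in model$dynamic_genes) {
      gi <- match(g, model$genes)
      mu[gi, ] <- mu[gi, ] * exp(trend_value(model$trend_functions[[g]], pt))
    }
    if (config$batch_shift_sd > 0) {
      bshift <- matrix(exp(rnorm(ng * n_donors, 0, config$batch_shift_sd)),
                       ng, n_donors)
      mu <- mu * bshift[, match(donor, donors), drop = FALSE]
    }
    mu <- sweep(mu, 2L, colSums(mu), "/")

    lib <- rlnorm(n_cells, config$library_size_lognormal[["meanlog"]],
                  config$library_size_lognormal[["sdlog"]])
    fm <- pmin(pmax(rnorm(n_cells, config$mito_fraction[["mean"]],
                          config$mito_fraction[["sd"]]), 0), 0.5)
    mu <- sweep(mu, 2L, lib * (1 - fm), "*")
    mito_mu <- matrix(rep(lib * fm / config$n_mito_genes,
                          each = config$n_mito_genes),
                      config$n_mito_genes, n_cells)

    size <- 1 / config$nb_dispersion
    counts <- matrix(rnbinom(length(mu), mu = mu, size = size), ng, n_cells)
    mito_counts <- matrix(rnbinom(length(mito_mu), mu = mito_mu, size = size),
                          config$n_mito_genes, n_cells)
    counts <- rbind(counts, mito_counts)
    rownames(counts) <- c(model$genes, model$mito_genes)
    cell_ids <- sprintf("%s_c%05d", condition, seq_len(n_cells))
    colnames(counts) <- cell_ids

    doublet <- rep(FALSE, n_cells)
    n_doub <- round(config$doublet_rate * n_cells)
    if (n_doub > 0) {
      targets <- sample.int(n_cells, n_doub)
      doublet[targets] <- TRUE
      for (i in targets) {
        parents <- sample(setdiff(which(donor == donor[i] & !doublet), i), 2L)
        counts[, i] <- counts[, parents[1L]] + counts[, parents[2L]]
        labels[i] <- labels[parents[1L]]
        pt[i] <- pt[parents[1L]]
      }
    }

    truth <- list(
      cell_ids = cell_ids, cell_labels = setNames(labels, cell_ids),
      doublet_flags = setNames(doublet, cell_ids),
      pseudotime = setNames(pt, cell_ids),
      branch_probabilities = `rownames<-`(bp, cell_ids),
      trend_functions = model$trend_functions,
      dynamic_genes = model$dynamic_genes,
      active_regulon_map = model$active_regulon_map,
      donors = setNames(donor, cell_ids), condition = condition,
      proportions = setNames(as.numeric(proportions), config$type_names),
      model = model
    )
    metadata <- data.frame(cell_id = cell_ids, donor = donor,
                           condition = condition, label = labels,
                           stringsAsFactors = FALSE)
    structure(list(counts = .as_sparse(counts), metadata = metadata,
                   truth = truth),
              class = "hspc_sim")
  })
}

#' Generate a synthetic reference dataset with ground truth
#'
#' Draws a labeled reference dataset (the first condition in
#' `donors_per_condition`) from the negative-binomial generative model:
#' type-specific marker genes with a `marker_fold` mean increase,
#' per-cell log-normal library sizes, a mitochondrial gene block whose
#' summed share follows the configured fraction, two-parent doublets, donor
#' batch effects, and latent pseudotime with branch probabilities.
#' Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `hspc_sim` with elements `counts` (genes x cells
#'   sparse dgCMatrix), `metadata` (cell_id, donor, condition, label) and
#'   `truth` (labels, doublet flags, pseudotime, branch probabilities, trend
#'   functions, active regulon map, and the internal gene model).
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  model_seed <- .derive_seed(config$seed, "gene-model")
  model <- withr::with_seed(model_seed, .build_gene_model(config))
  cond <- names(config$donors_per_condition)[1L]
  .generate_condition(config, model, cond, config$type_proportions[[cond]],
                      seed = .derive_seed(config$seed, "condition", cond))
}

#' Generate a perturbed query dataset sharing the reference gene model
#'
#' Draws a second condition from the same gene universe and marker/trend
#' structure as a reference, optionally applying condition effects:
#' cell-type proportion shifts and gene trend perturbations. Effects are
#' recorded in the returned ground truth.
#'
#' @param config The [sim_config()] used for the reference.
#' @param reference_truth `truth` element of a [generate_reference()] result.
#' @param effects Optional list with elements:
#'   * `prop_delta`: named numeric vector of per-type proportion deltas;
#'     shifted types change by exactly the delta, the remaining types are
#'     rescaled to keep the vector on the simplex.
#'   * `trend_perturb`: named list gene -> list of parameter deltas
#'     (`midpoint_delta`, `amplitude_delta`, `slope_delta`).
#' @param condition Condition to generate (default: second condition of
#'   `donors_per_condition`).
#' @return An `hspc_sim` list; `truth$effects` records the applied effects.
#' @export
generate_query <- function(config, reference_truth, effects = list(),
                           condition = NULL) {
  stopifnot(inherits(config, "sim_config"))
  model <- reference_truth$model
  if (is.null(model)) stop("reference_truth must come from generate_reference()")
  if (is.null(condition)) {
    conds <- names(config$donors_per_condition)
    if (length(conds) < 2L) stop("config defines no second condition")
    condition <- conds[2L]
  }
  props <- config$type_proportions[[condition]]
  if (is.null(props)) props <- reference_truth$proportions
  props <- setNames(as.numeric(props), config$type_names)

  if (!is.null(effects$prop_delta)) {
    delta <- effects$prop_delta
    unknown <- setdiff(names(delta), config$type_names)
    if (length(unknown))
      stop(sprintf("prop_delta names not in type set: %s",
                   paste(unknown, collapse = ", ")))
    shifted <- names(delta)
    rest <- setdiff(config$type_names, shifted)
    new_shifted <- props[shifted] + delta
    if (any(new_shifted < 0) || any(new_shifted > 1) || sum(new_shifted) > 1)
      stop("perturbed proportions leave the simplex")
    rest_mass <- sum(props[rest])
    props[shifted] <- new_shifted
    props[rest] <- props[rest] * (1 - sum(new_shifted)) / rest_mass
    if (abs(sum(props) - 1) > 1e-9) stop("perturbed proportions do not sum to 1")
  }

  if (!is.null(effects$trend_perturb)) {
    unknown <- setdiff(names(effects$trend_perturb), model$genes)
    if (length(unknown))
      stop(sprintf("trend_perturb names not in gene set: %s",
                   paste(unknown, collapse = ", ")))
    for (g in names(effects$trend_perturb)) {
      pert <- effects$trend_perturb[[g]]
      tr <- model$trend_functions[[g]]
      if (!is.null(pert$midpoint_delta)) {
        if (is.null(tr$midpoint)) stop(sprintf("gene %s trend has no midpoint", g))
        tr$midpoint <- tr$midpoint + pert$midpoint_delta
      }
      if (!is.null(pert$amplitude_delta) && !is.null(tr$amplitude))
        tr$amplitude <- tr$amplitude + pert$amplitude_delta
      if (!is.null(pert$slope_delta) && !is.null(tr$slope))
        tr$slope <- tr$slope + pert$slope_delta
      model$trend_functions[[g]] <- tr
    }
  }

  sim <- .generate_condition(config, model, condition, props,
                             seed = .derive_seed(config$seed, "condition",
                                                 condition))
  sim$truth$effects <- effects
  sim
}

#' Simulate a regulon-by-cell AUC activity matrix
#'
#' Emulates the per-cell regulon activity scores produced by AUC-based
#' enrichment: cells belonging to clusters where a regulon is truly active
#' draw from a high mode, all other cells from a low mode, with optional
#' additive per-donor batch offsets; values are clipped to `[0, 1]`.
#'
#' @param config The [sim_config()] used for the dataset.
#' @param truth Ground truth with `cell_labels`, `donors` and
#'   `active_regulon_map`.
#' @param modes Length-2 vector `(low, high)` of the inactive/active modes.
#' @param mode_sd Gaussian SD around each mode.
#' @return A list of class `auc_matrix` with `values` (regulons x cells),
#'   `clusters`, `batches` and the generating parameters.
#' @export
generate_auc_matrix <- function(config, truth, modes = c(low = 0.1, high = 0.8),
                                mode_sd = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth$cell_labels) || is.null(truth$active_regulon_map))
    stop("truth must carry cell_labels and active_regulon_map")
  withr::with_seed(.derive_seed(config$seed, "auc", truth$condition %||% "x"), {
    regs <- truth$model$regulon_names
    cells <- truth$cell_ids
    labels <- truth$cell_labels
    active <- matrix(FALSE, length(regs), length(cells),
                     dimnames = list(regs, cells))
    for (tt in names(truth$active_regulon_map)) {
      in_type <- labels == tt
      for (r in truth$active_regulon_map[[tt]]) active[r, in_type] <- TRUE
    }
    for (r in truth$model$ubiquitous_regulons) active[r, ] <- TRUE
    mu <- ifelse(active, modes[["high"]], modes[["low"]])
    vals <- matrix(rnorm(length(mu), mean = mu, sd = mode_sd),
                   nrow(mu), ncol(mu), dimnames = dimnames(mu))
    if (config$batch_shift_sd > 0) {
      donors <- unique(truth$donors)
      off <- matrix(rnorm(length(regs) * length(donors), 0,
                          config$batch_shift_sd),
                    length(regs), length(donors),
                    dimnames = list(regs, donors))
      vals <- vals + off[, truth$donors[cells], drop = FALSE]
    }
    vals <- pmin(pmax(vals, 0), 1)
    structure(list(values = vals, clusters = labels,
                   batches = truth$donors, modes = modes, mode_sd = mode_sd,
                   active = active),
              class = "auc_matrix")
  })
}

#' Synthesize ambiguous 50/50 two-type mixture profiles
#'
#' Builds synthetic cells whose log-normalized expression is the average of
#' two randomly paired cells from different types — an ambiguous
#' intermediate transcriptional state used to probe the classifier's
#' "not assigned" behavior. (Physical doublets, by contrast, are sums of
#' raw counts at doubled depth and are the target of the QC UMI ceiling.)
#'
#' @param normalized A `normalized_matrix`.
#' @param labels Named character vector of cell labels covering its cells.
#' @param n Number of mixture cells to build (default 200).
#' @param seed Integer seed.
#' @return A `normalized_matrix` of `n` mixture profiles; the
#'   `parent_types` attribute records each mixture's two source types.
#' @export
mixture_profiles <- function(normalized, labels, n = 200L, seed = 1L) {
  stopifnot(inherits(normalized, "normalized_matrix"))
  cells <- colnames(normalized$values)
  if (is.null(names(labels)) || !all(cells %in% names(labels)))
    stop("labels must be named and cover all cells")
  labels <- labels[cells]
  if (length(unique(labels)) < 2L) stop("need at least two types to mix")
  withr::with_seed(seed, {
    pairs <- replicate(n, {
      a <- sample(length(cells), 1L)
      b <- sample(which(labels != labels[a]), 1L)
      c(a, b)
    })
  })
  vals <- (normalized$values[, pairs[1L, ], drop = FALSE] +
           normalized$values[, pairs[2L, ], drop = FALSE]) / 2
  ids <- sprintf("mix%04d", seq_len(n))
  colnames(vals) <- ids
  out <- structure(list(values = vals,
                        library_sizes = setNames(rep(NA_real_, n), ids),
                        scale_factor = normalized$scale_factor),
                   class = "normalized_matrix")
  attr(out, "parent_types") <- data.frame(
    cell_id = ids, type_a = unname(labels[pairs[1L, ]]),
    type_b = unname(labels[pairs[2L, ]]), stringsAsFactors = FALSE)
  out
}

#' Simulated regulon edge list
#'
#' Extracts the TF -> target edge list (with importance scores) defined by
#' the simulator's gene model, in the shape consumed by [trim_network()].
#'
#' @param truth Ground truth from [generate_reference()].
#' @return data.frame with columns `tf`, `target`, `importance`.
#' @export
regulon_edges <- function(truth) {
  if (is.null(truth$model)) stop("truth must come from generate_reference()")
  do.call(rbind, c(truth$model$regulon_targets, list(make.row.names = FALSE)))
}
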