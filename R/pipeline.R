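#' Run the full annotation and perturbation-analysis pipeline
#'
#' Executes the stages in order — `simulate`, `qc`, `train`, `predict`,
#' `composition`, `trends`, `regulons` — on a simulated reference/query
#' pair, writing every stage's outputs under `outdir` and a JSON manifest
#' recording the package version, master seed, per-stage outputs with MD5
#' checksums, and per-stage summaries. All randomness derives from the
#' single master seed, so a rerun with the same configuration reproduces
#' identical output files.
#'
#' @param config A named list (or path to a JSON file) with elements:
#'   * `outdir` (required): output directory.
#'   * `seed`: master seed (default 1).
#'   * `stages`: character subset of the seven stages (default: all, in
#'     order).
#'   * `sim`: arguments for [sim_config()] (minus `seed`).
#'   * `effects`: condition effects passed to [generate_query()].
#'   * `qc`: arguments for [qc_thresholds()].
#'   * `hvg_n`: number of highly variable genes (default 2000).
#'   * `classify`: arguments for [elastic_net_spec()].
#'   * `trends`: list with optional `genes`, `branch`, `grid_size`, `k`,
#'     `trajectory_file` (external trajectory TSV; must exist if given).
#'   * `regulons`: list with optional `top_k`.
#' @return The manifest, invisibly (also written to
#'   `outdir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  all_stages <- c("simulate", "qc", "train", "predict", "composition",
                  "trends", "regulons")
  stages <- config$stages %||% all_stages
  unknown <- setdiff(stages, all_stages)
  if (length(unknown))
    stop(sprintf("unknown stage(s): %s", paste(unknown, collapse = ", ")))
  stages <- all_stages[all_stages %in% stages]
  if (is.null(config$outdir)) stop("config$outdir is required")

  # pre-flight: every externally referenced path must exist before any
  # stage runs
  if ("trends" %in% stages && !is.null(config$trends$trajectory_file) &&
      !file.exists(config$trends$trajectory_file))
    stop(sprintf("trajectory file not found: %s",
                 config$trends$trajectory_file))

  seed <- config$seed %||% 1L
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  manifest <- list(package = "hspcflow",
                   version = as.character(utils::packageVersion("hspcflow")),
                   seed = seed, stages = list())
  note <- function(stage, files, summary) {
    files <- files[file.exists(files)]
    manifest$stages[[stage]] <<- list(
      outputs = as.list(setNames(unname(tools::md5sum(files)), files)),
      summary = summary)
  }
  fail <- function(stage, e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)

  env <- new.env(parent = emptyenv())
  for (stage in stages) {
    tryCatch(switch(stage,
      simulate = {
        env$cfg <- do.call(sim_config,
                           c(config$sim %||% list(), list(seed = seed)))
        env$ref <- generate_reference(env$cfg)
        env$qry <- generate_query(env$cfg, env$ref$truth,
                                  effects = config$effects %||% list())
        env$auc <- generate_auc_matrix(env$cfg, env$qry$truth)
        rdir <- file.path(outdir, "reference")
        qdir <- file.path(outdir, "query")
        write_sim(env$ref, rdir, env$cfg)
        write_sim(env$qry, qdir)
        auc_df <- data.frame(regulon = rownames(env$auc$values),
                             env$auc$values, check.names = FALSE)
        write_tsv(auc_df, file.path(outdir, "auc_matrix.tsv"))
        note("simulate",
             c(file.path(rdir, c("matrix.mtx", "metadata.tsv", "truth.tsv")),
               file.path(qdir, c("matrix.mtx", "metadata.tsv", "truth.tsv")),
               file.path(outdir, "auc_matrix.tsv")),
             list(reference_cells = ncol(env$ref$counts),
                  query_cells = ncol(env$qry$counts),
                  genes = nrow(env$ref$counts)))
      },
      qc = {
        thr <- do.call(qc_thresholds, config$qc %||% list())
        env$ref_qc <- filter_cells(env$ref$counts, thr)
        env$qry_qc <- filter_cells(env$qry$counts, thr)
        env$ref_norm <- log_normalize(env$ref_qc$counts)
        env$qry_norm <- log_normalize(env$qry_qc$counts)
        write_tsv(env$ref_qc$report, file.path(outdir, "qc_reference.tsv"))
        write_tsv(env$qry_qc$report, file.path(outdir, "qc_query.tsv"))
        note("qc", file.path(outdir, c("qc_reference.tsv", "qc_query.tsv")),
             list(reference_retained = ncol(env$ref_qc$counts),
                  query_retained = ncol(env$qry_qc$counts)))
      },
      train = {
        hvg_n <- config$hvg_n %||% 2000L
        hvg_ref <- select_hvg(env$ref_qc$counts, hvg_n)
        hvg_qry <- select_hvg(env$qry_qc$counts, hvg_n)
        env$features <- intersect_features(hvg_ref, hvg_qry)
        spec <- do.call(elastic_net_spec, config$classify %||% list())
        labels <- env$ref$truth$cell_labels[colnames(env$ref_qc$counts)]
        env$ensemble <- train_ensemble(env$ref_norm, labels, env$features,
                                       spec, seed = seed)
        write_ensemble(env$ensemble, file.path(outdir, "model.json"))
        note("train", file.path(outdir, "model.json"),
             list(n_types = length(env$ensemble$types),
                  n_models = length(env$ensemble$types) * spec$n_repetitions,
                  n_features = length(env$features)))
      },
      predict = {
        env$annotations <- predict(env$ensemble, env$qry_norm)
        write_tsv(env$annotations, file.path(outdir, "annotations.tsv"))
        note("predict", file.path(outdir, "annotations.tsv"),
             list(n_cells = nrow(env$annotations),
                  not_assigned = sum(env$annotations$label == "not assigned")))
      },
      composition = {
        ref_ann <- data.frame(
          cell_id = colnames(env$ref_qc$counts),
          label = unname(env$ref$truth$cell_labels[colnames(env$ref_qc$counts)]),
          stringsAsFactors = FALSE)
        comp_ref <- compute_composition(ref_ann, env$ref$metadata, "donor")
        qry_meta <- env$qry$metadata
        comp_qry <- compute_composition(
          env$annotations[, c("cell_id", "label")], qry_meta, "donor")
        env$shift <- test_composition_shift(comp_ref, comp_qry)
        write_tsv(rbind(cbind(dataset = "reference", comp_ref),
                        cbind(dataset = "query", comp_qry)),
                  file.path(outdir, "composition.tsv"))
        write_tsv(env$shift, file.path(outdir, "composition_tests.tsv"))
        note("composition",
             file.path(outdir, c("composition.tsv", "composition_tests.tsv")),
             list(n_types_tested = nrow(env$shift),
                  n_significant = sum(env$shift$significant)))
      },
      trends = {
        tc <- config$trends %||% list()
        genes <- tc$genes %||% env$ref$truth$dynamic_genes
        branch <- tc$branch %||% colnames(env$ref$truth$branch_probabilities)[1L]
        gs <- tc$grid_size %||% 500L
        tr_ref <- fit_trend_set(
          env$ref_norm, genes, env$ref$truth$pseudotime,
          weights = env$ref$truth$branch_probabilities[, branch],
          branch = branch, condition = env$ref$truth$condition,
          grid_size = gs)
        tr_qry <- fit_trend_set(
          env$qry_norm, genes, env$qry$truth$pseudotime,
          weights = env$qry$truth$branch_probabilities[, branch],
          branch = branch, condition = env$qry$truth$condition,
          grid_size = gs)
        env$trend_cmp <- compare_trend_set(tr_ref, tr_qry)
        cl <- cluster_trends(tr_ref, k = tc$k %||% 4L)
        wide <- data.frame(gene = names(tr_ref),
                           cluster = unname(cl[names(tr_ref)]),
                           do.call(rbind, lapply(tr_ref, function(t) t$values)),
                           check.names = FALSE)
        write_tsv(wide, file.path(outdir, "trends_reference.tsv"))
        write_tsv(env$trend_cmp, file.path(outdir, "trend_tests.tsv"))
        note("trends",
             file.path(outdir, c("trends_reference.tsv", "trend_tests.tsv")),
             list(branch = branch, n_genes = length(genes),
                  n_significant = sum(env$trend_cmp$tier != "NS")))
      },
      regulons = {
        rk <- config$regulons %||% list()
        corrected <- batch_center(env$auc)
        bin <- binarize_auc(corrected)
        clusters <- env$qry$truth$cell_labels[colnames(corrected$values)]
        pct <- percent_active(bin$binary, clusters)
        rss <- regulon_rss(pmax(corrected$values, 0), clusters)
        env$top <- top_regulons(rss, k = rk$top_k %||% 5L)
        trimmed <- trim_network(regulon_edges(env$ref$truth))
        write_tsv(data.frame(regulon = rownames(pct), pct,
                             check.names = FALSE),
                  file.path(outdir, "regulon_percent_active.tsv"))
        write_tsv(data.frame(regulon = rownames(rss), rss,
                             check.names = FALSE),
                  file.path(outdir, "regulon_rss.tsv"))
        write_tsv(trimmed, file.path(outdir, "regulon_network_trimmed.tsv"))
        note("regulons",
             file.path(outdir, c("regulon_percent_active.tsv",
                                 "regulon_rss.tsv",
                                 "regulon_network_trimmed.tsv")),
             list(n_regulons = nrow(pct),
                  n_edges_trimmed = nrow(trimmed)))
      }
    ), error = function(e) fail(stage, e))
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
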