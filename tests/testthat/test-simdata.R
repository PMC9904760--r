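test_that("generators are deterministic given the config seed", {
  cfg <- tiny_config(seed = 7)
  a <- generate_reference(cfg)
  b <- generate_reference(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth$cell_labels, b$truth$cell_labels)
  expect_identical(a$truth$pseudotime, b$truth$pseudotime)
  qa <- generate_query(cfg, a$truth)
  qb <- generate_query(cfg, b$truth)
  expect_identical(qa$counts, qb$counts)
  aa <- generate_auc_matrix(cfg, qa$truth)
  ab <- generate_auc_matrix(cfg, qb$truth)
  expect_identical(aa$values, ab$values)
})

test_that("marker genes have elevated mean expression in their own type", {
  cfg <- tiny_config(seed = 3, marker_fold = 5, doublet_rate = 0)
  sim <- generate_reference(cfg)
  labels <- sim$truth$cell_labels[colnames(sim$counts)]
  norm <- log_normalize(sim$counts)
  for (tt in cfg$type_names) {
    mk <- sim$truth$model$marker_map[[tt]]
    own <- Matrix::rowMeans(norm$values[mk, labels == tt, drop = FALSE])
    other <- Matrix::rowMeans(norm$values[mk, labels != tt, drop = FALSE])
    expect_gt(mean(own), mean(other))
  }
})

test_that("generated type frequencies match configured proportions", {
  props <- c(0.30, 0.45, 0.25)
  cfg <- sim_config(n_types = 3, n_genes = 60, markers_per_type = 3,
                    n_dynamic_genes = 3, n_cells_per_donor = 10000,
                    donors_per_condition = c(young = 1, elderly = 1),
                    type_proportions = list(young = props, elderly = props),
                    doublet_rate = 0, seed = 9)
  sim <- generate_reference(cfg)
  frac <- mean(sim$truth$cell_labels == cfg$type_names[1])
  se <- sqrt(0.30 * 0.70 / 10000)
  expect_lt(abs(frac - 0.30), 3 * se)
})

test_that("proportion effects shift query label fractions by the stated delta", {
  cfg <- tiny_config(seed = 5, n_cells_per_donor = 2500, doublet_rate = 0)
  ref <- generate_reference(cfg)
  qry <- generate_query(cfg, ref$truth,
                        effects = list(prop_delta = c(HSC = 0.10)))
  n <- length(qry$truth$cell_labels)
  target <- cfg$type_proportions$elderly[["HSC"]] + 0.10
  se <- sqrt(target * (1 - target) / n)
  expect_lt(abs(mean(qry$truth$cell_labels == "HSC") - target), 3 * se)
  expect_equal(qry$truth$proportions[["HSC"]], target)
  expect_equal(sum(qry$truth$proportions), 1, tolerance = 1e-9)
})

test_that("off-simplex proportion effects are rejected", {
  cfg <- tiny_config()
  ref <- generate_reference(cfg)
  expect_error(generate_query(cfg, ref$truth,
                              effects = list(prop_delta = c(HSC = 0.95))),
               "simplex")
  expect_error(generate_query(cfg, ref$truth,
                              effects = list(prop_delta = c(Nope = 0.1))),
               "type set")
  expect_error(sim_config(type_proportions = list(young = rep(0.5, 14),
                                                  elderly = rep(1 / 14, 14))),
               "sum to 1")
})

test_that("sigmoid midpoint perturbations move the trend where expected", {
  cfg <- tiny_config(seed = 13)
  ref <- generate_reference(cfg)
  sig_genes <- names(Filter(function(tr) tr$type == "sigmoid",
                            ref$truth$trend_functions))
  g <- sig_genes[1]
  qry <- generate_query(cfg, ref$truth,
    effects = list(trend_perturb = setNames(list(list(midpoint_delta = 0.2)), g)))
  t_grid <- seq(0, 1, length.out = 501)
  d <- abs(trend_value(ref$truth$trend_functions[[g]], t_grid) -
           trend_value(qry$truth$trend_functions[[g]], t_grid))
  expect_gt(max(d), 0)
  m0 <- ref$truth$trend_functions[[g]]$midpoint
  peak <- t_grid[which.max(d)]
  expect_gte(peak, m0 - 0.01)
  expect_lte(peak, m0 + 0.21)
})

test_that("doublets are parent sums with roughly doubled library size", {
  cfg <- tiny_config(seed = 21, doublet_rate = 0.05)
  sim <- generate_reference(cfg)
  lib <- Matrix::colSums(sim$counts)
  doub <- sim$truth$doublet_flags
  expect_gt(sum(doub), 0)
  expect_gt(mean(lib[doub]), 1.5 * mean(lib[!doub]))
})

test_that("mitochondrial counts follow the configured fraction", {
  cfg <- tiny_config(seed = 2, doublet_rate = 0,
                     mito_fraction = c(mean = 0.04, sd = 0.005))
  sim <- generate_reference(cfg)
  mito <- grep("^MT-", rownames(sim$counts), value = TRUE)
  frac <- Matrix::colSums(sim$counts[mito, ]) / Matrix::colSums(sim$counts)
  expect_lt(abs(mean(frac) - 0.04), 0.01)
})

test_that("AUC matrix separates active and inactive modes", {
  cfg <- tiny_config(seed = 17, batch_shift_sd = 0)
  ref <- generate_reference(cfg)
  auc <- generate_auc_matrix(cfg, ref$truth)
  expect_true(all(auc$values >= 0 & auc$values <= 1))

  # regulons active in no cluster stay in the low mode
  silent <- setdiff(rownames(auc$values),
                    c(unique(unlist(ref$truth$active_regulon_map)),
                      ref$truth$model$ubiquitous_regulons))
  expect_gt(length(silent), 0)
  midpoint <- mean(auc$modes)
  for (r in silent) expect_lt(mean(auc$values[r, ]), midpoint)

  # with no batch shift, per-donor means of one regulon agree within
  # sampling error of the mode SD
  r1 <- rownames(auc$values)[1]
  donors <- split(seq_len(ncol(auc$values)), auc$batches)
  means <- vapply(donors, function(i) mean(auc$values[r1, i]), 0)
  expect_lt(diff(range(means)), 6 * auc$mode_sd / sqrt(min(lengths(donors))))

  # the two modes are essentially non-overlapping: the Gaussian tail mass
  # beyond the midpoint is < 1e-4, so no simulated value should cross it
  active <- auc$active
  expect_lt(pnorm(midpoint, 0.8, 0.05) + pnorm(midpoint, 0.1, 0.05,
                                               lower.tail = FALSE), 1e-4)
  expect_gt(min(auc$values[active]), midpoint)
  expect_lt(max(auc$values[!active]), midpoint)
})

test_that("mixture profiles average two parents from different types", {
  cfg <- tiny_config(seed = 43, doublet_rate = 0)
  sim <- generate_reference(cfg)
  norm <- log_normalize(sim$counts)
  mix <- mixture_profiles(norm, sim$truth$cell_labels, n = 50, seed = 9)
  expect_identical(ncol(mix$values), 50L)
  parents <- attr(mix, "parent_types")
  expect_true(all(parents$type_a != parents$type_b))
  mix2 <- mixture_profiles(norm, sim$truth$cell_labels, n = 50, seed = 9)
  expect_identical(mix$values, mix2$values)
  one_type <- setNames(rep("HSC", ncol(norm$values)), colnames(norm$values))
  expect_error(mixture_profiles(norm, one_type), "two types")
})

test_that("branch probabilities are valid and pseudotime lies in [0,1]", {
  cfg <- tiny_config(seed = 31)
  sim <- generate_reference(cfg)
  bp <- sim$truth$branch_probabilities
  expect_true(all(bp >= 0 & bp <= 1))
  expect_equal(unname(rowSums(bp)), rep(1, nrow(bp)), tolerance = 1e-9)
  expect_true(all(sim$truth$pseudotime >= 0 & sim$truth$pseudotime <= 1))
  expect_false(any(is.na(sim$truth$cell_labels)))
})
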