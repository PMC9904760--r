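make_labels <- function(n_pos, n_total, target = "HSC", other = "rest") {
  labs <- c(rep(target, n_pos), rep(other, n_total - n_pos))
  setNames(labs, sprintf("c%04d", seq_len(n_total)))
}

test_that("training sets are balanced, split 75/25, and deterministic", {
  labels <- make_labels(100, 1000)
  s <- build_training_set(labels, "HSC", seed = 3)
  expect_length(s$train_cells, 150)
  expect_length(s$val_cells, 50)
  expect_identical(sum(s$train_labels), 75L)
  expect_identical(sum(s$val_labels), 25L)
  expect_length(intersect(s$train_cells, s$val_cells), 0)
  s2 <- build_training_set(labels, "HSC", seed = 3)
  expect_identical(s, s2)
  s3 <- build_training_set(labels, "HSC", seed = 4)
  expect_false(identical(sort(s$train_cells), sort(s3$train_cells)))
})

test_that("negative sampling saturates with a warning when positives dominate", {
  labels <- make_labels(600, 1000)
  expect_warning(s <- build_training_set(labels, "HSC", seed = 1),
                 "non-target")
  expect_identical(length(s$train_cells) + length(s$val_cells), 1000L)
  expect_error(build_training_set(labels, "absent"), "absent")
  expect_error(build_training_set(make_labels(5, 100), "HSC"), ">= 8")
})

test_that("feature intersection preserves reference order and errors when empty", {
  expect_identical(intersect_features(c("A", "B", "C"), c("C", "B", "D")),
                   c("B", "C"))
  expect_identical(intersect_features(c("X", "Y"), c("X", "Y")), c("X", "Y"))
  expect_error(intersect_features(c("A"), c("B")), "intersect")
  expect_error(intersect_features(character(0), "A"), "non-empty")
})

sep_data <- function(n = 200, p_noise = 20, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(0:1, each = n / 2)
    x <- cbind(y * 2 + rnorm(n, sd = 0.1),
               matrix(rnorm(n * p_noise), n))
    colnames(x) <- sprintf("g%03d", seq_len(ncol(x)))
    list(x = x, y = y)
  })
}

test_that("a perfectly separating feature yields validation AUC 1", {
  d <- sep_data()
  idx <- seq(1, 200, by = 2)
  m <- fit_binary_model(d$x[idx, ], d$y[idx], d$x[-idx, ], d$y[-idx],
                        alpha = 0.5, spec = elastic_net_spec(), seed = 2)
  expect_equal(m$metrics$auc, 1)
  expect_true("g001" %in% names(m$coefficients))
  expect_identical(m$n_nonzero, length(m$coefficients))
})

test_that("at lambda >= lambda_max the lasso fits the null model", {
  d <- sep_data()
  lam_max <- max(glmnet::glmnet(d$x, d$y, family = "binomial",
                                alpha = 1)$lambda)
  m <- fit_binary_model(d$x, d$y, d$x, d$y, alpha = 1,
                        spec = elastic_net_spec(), lambda = lam_max * 1.01)
  expect_identical(m$n_nonzero, 0L)
  expect_error(fit_binary_model(d$x, rep(1, 200), d$x, rep(1, 200),
                                alpha = 1, spec = elastic_net_spec()),
               "single-class")
})

test_that("permuted labels give chance-level validation AUC", {
  d <- sep_data(n = 120, p_noise = 30)
  aucs <- vapply(1:8, function(i) {
    y_perm <- withr::with_seed(100 + i, sample(d$y))
    idx <- seq(1, 120, by = 2)
    m <- fit_binary_model(d$x[idx, ], y_perm[idx], d$x[-idx, ], y_perm[-idx],
                          alpha = 1, spec = elastic_net_spec(n_cv_folds = 5),
                          seed = i)
    m$metrics$auc
  }, 0)
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), max(3 * se, 0.15))
})

test_that("model selection applies the eligibility window and tie cascade", {
  spec <- elastic_net_spec()
  # only the 50-variable model falls in [20, 150]
  cands <- list(stub_model(1, 10, 0.99), stub_model(0.75, 50, 0.80),
                stub_model(0.5, 200, 0.99))
  expect_identical(select_model(cands, spec)$n_nonzero, 50L)
  # higher AUC wins among eligible
  cands <- list(stub_model(1, 30, 0.90), stub_model(0.5, 40, 0.95))
  expect_identical(select_model(cands, spec)$metrics$auc, 0.95)
  # AUC tie -> lower FPR wins
  cands <- list(stub_model(1, 30, 0.9, fpr = 0.20),
                stub_model(0.5, 30, 0.9, fpr = 0.10))
  expect_identical(select_model(cands, spec)$metrics$fpr, 0.10)
  # AUC+FPR tie -> lower FNR wins
  cands <- list(stub_model(1, 30, 0.9, fpr = 0.1, fnr = 0.3),
                stub_model(0.5, 30, 0.9, fpr = 0.1, fnr = 0.2))
  expect_identical(select_model(cands, spec)$metrics$fnr, 0.2)
  # full tie -> more variables wins
  cands <- list(stub_model(1, 30, 0.9), stub_model(0.5, 60, 0.9))
  expect_identical(select_model(cands, spec)$n_nonzero, 60L)
  # identical metrics -> smallest alpha-grid index (alpha = 1 first)
  cands <- list(stub_model(0.5, 30, 0.9), stub_model(1, 30, 0.9))
  expect_identical(select_model(cands, spec)$alpha, 1)
  # no eligible candidate -> window dropped
  cands <- list(stub_model(1, 5, 0.7), stub_model(0.5, 300, 0.9))
  expect_identical(select_model(cands, spec)$n_nonzero, 300L)
  expect_error(select_model(list(), spec), "empty")
})

test_that("ensemble training stores n_types x n_repetitions models and is reproducible", {
  cfg <- tiny_config(seed = 29, n_types = 3,
                     type_names = c("HSC", "MEP", "GMP"), doublet_rate = 0)
  sim <- generate_reference(cfg)
  norm <- log_normalize(sim$counts)
  feats <- select_hvg(sim$counts, 60)
  spec <- elastic_net_spec(alpha_grid = c(1, 0.25), n_repetitions = 2,
                           n_cv_folds = 5)
  labels <- sim$truth$cell_labels
  e1 <- train_ensemble(norm, labels, feats, spec, seed = 6)
  expect_identical(length(e1$models), 3L)
  expect_true(all(lengths(e1$models) == 2L))
  e2 <- train_ensemble(norm, labels, feats, spec, seed = 6)
  expect_identical(lapply(e1$models, function(r) lapply(r, `[[`, "coefficients")),
                   lapply(e2$models, function(r) lapply(r, `[[`, "coefficients")))

  ann <- predict(e1, norm)
  expect_true(all(ann$label %in% c(e1$types, "not assigned")))
  probs <- as.matrix(ann[, paste0("prob_", e1$types)])
  expect_true(all(probs >= 0 & probs <= 1))

  # averaged probabilities equal a brute-force re-evaluation of the stored
  # coefficients
  x <- Matrix::t(norm$values[e1$features, , drop = FALSE])
  for (tt in e1$types) {
    manual <- rowMeans(vapply(e1$models[[tt]], function(m) {
      beta <- setNames(numeric(length(e1$features)), e1$features)
      beta[names(m$coefficients)] <- m$coefficients
      plogis(m$intercept + as.numeric(x %*% beta))
    }, numeric(nrow(x))))
    expect_equal(unname(manual), ann[[paste0("prob_", tt)]], tolerance = 1e-12)
  }
})

fake_ensemble <- function(type_probs, features = c("f1", "f2")) {
  types <- names(type_probs)
  models <- lapply(type_probs, function(p) {
    list(structure(list(coefficients = setNames(numeric(0), character(0)),
                        intercept = qlogis(p), alpha = 1, lambda = 0.1,
                        n_nonzero = 0L,
                        metrics = list(auc = 1, fpr = 0, fnr = 0,
                                       n_validation = 10)),
                   class = "binary_model"))
  })
  structure(list(models = models, features = features,
                 spec = elastic_net_spec(n_repetitions = 1),
                 types = types, seed = 1L),
            class = "ensemble_classifier")
}

fake_query <- function(features, n_cells = 4) {
  v <- toy_counts(matrix(1, length(features), n_cells), genes = features)
  log_normalize(v, scale_factor = length(features))
}

test_that("assignment takes the argmax only above the probability threshold", {
  ens <- fake_ensemble(c(HSC = 0.9, MEP = 0.2))
  ann <- predict(ens, fake_query(ens$features))
  expect_true(all(ann$label == "HSC"))
  expect_equal(ann$prob_HSC, rep(0.9, 4), tolerance = 1e-12)

  low <- fake_ensemble(c(HSC = 0.45, MEP = 0.30))
  ann_low <- predict(low, fake_query(low$features))
  expect_true(all(ann_low$label == "not assigned"))

  # probability exactly at the threshold is not assigned
  at <- fake_ensemble(c(HSC = 0.5, MEP = 0.1))
  expect_true(all(predict(at, fake_query(at$features))$label == "not assigned"))
})

test_that("missing query features are zero-imputed with a warning", {
  ens <- fake_ensemble(c(HSC = 0.9, MEP = 0.2), features = c("f1", "f2", "f3"))
  q <- fake_query(c("f1", "f2"))
  expect_warning(ann <- predict(ens, q), "imputed")
  expect_identical(nrow(ann), 4L)
})

test_that("confusion proportions are row-normalized with not-assigned column", {
  truth <- setNames(c("A", "A", "B", "B"), sprintf("c%d", 1:4))
  pred <- data.frame(cell_id = sprintf("c%d", 1:4),
                     label = c("A", "A", "B", "B"))
  cp <- confusion_proportions(pred, truth)
  expect_identical(unname(cp[, "not assigned"]), c(0, 0))
  expect_equal(unname(diag(cp[, c("A", "B")])), c(1, 1))

  pred_na <- data.frame(cell_id = sprintf("c%d", 1:4),
                        label = rep("not assigned", 4))
  cp_na <- confusion_proportions(pred_na, truth)
  expect_equal(unname(cp_na[, "not assigned"]), c(1, 1))
  expect_equal(unname(rowSums(cp)), c(1, 1), tolerance = 1e-12)
  expect_error(confusion_proportions(pred, truth[1:3]), "different cell sets")
})

test_that("ensembles round-trip through JSON serialization", {
  ens <- fake_ensemble(c(HSC = 0.8, MEP = 0.3))
  ens$models$HSC[[1]]$coefficients <- c(f1 = 0.5, f2 = -1.2)
  ens$models$HSC[[1]]$n_nonzero <- 2L
  path <- tempfile(fileext = ".json")
  write_ensemble(ens, path)
  back <- read_ensemble(path)
  q <- fake_query(ens$features)
  expect_equal(predict(back, q), predict(ens, q), tolerance = 1e-12)
})
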