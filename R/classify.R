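#' Specification for the elastic-net cell-type classifier ensemble
#'
#' Hyper-parameters of the one-vs-rest elastic-net logistic regression
#' classifier: the alpha (L1/L2 mixing) grid searched per binary model, the
#' cross-validation used to pick lambda, the variable-count eligibility
#' window, the train/validation split, the number of repetitions averaged,
#' and the assignment probability threshold.
#'
#' @param alpha_grid Mixing parameters searched, each in (0, 1].
#' @param n_cv_folds Folds for the lambda cross-validation (default 10).
#' @param min_vars,max_vars Eligibility window on the number of nonzero
#'   coefficients (default 20–150); dropped when no candidate satisfies it.
#' @param train_fraction Fraction of the pooled set used for training
#'   (default 0.75; the rest validates).
#' @param n_repetitions Independent resampling repetitions per type whose
#'   probabilities are averaged (default 10).
#' @param assign_threshold Averaged probability a type must strictly exceed
#'   for assignment (default 0.5).
#' @param lambda_rule `"min"` (minimize CV deviance, default) or `"1se"`.
#' @return A validated list of class `elastic_net_spec`.
#' @export
elastic_net_spec <- function(alpha_grid = c(1, 0.75, 0.5, 0.25, 0.1),
                             n_cv_folds = 10L,
                             min_vars = 20L, max_vars = 150L,
                             train_fraction = 0.75,
                             n_repetitions = 10L,
                             assign_threshold = 0.5,
                             lambda_rule = c("min", "1se")) {
  if (any(alpha_grid <= 0) || any(alpha_grid > 1))
    stop("every alpha must lie in (0, 1]")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  if (min_vars > max_vars) stop("min_vars must not exceed max_vars")
  stopifnot(n_cv_folds >= 3, n_repetitions >= 1)
  .stop_if_not_prob(assign_threshold, "assign_threshold")
  structure(list(alpha_grid = alpha_grid, n_cv_folds = as.integer(n_cv_folds),
                 min_vars = as.integer(min_vars),
                 max_vars = as.integer(max_vars),
                 train_fraction = train_fraction,
                 n_repetitions = as.integer(n_repetitions),
                 assign_threshold = assign_threshold,
                 lambda_rule = match.arg(lambda_rule)),
            class = "elastic_net_spec")
}

#' Build a balanced train/validation split for one binary model
#'
#' Positives are all cells of the target type; negatives are a uniform
#' random sample without replacement from the remaining cells, of equal size
#' (capped at the number available, with a warning). The pooled set is split
#' into train/validation stratified by class. Deterministic given `seed`.
#'
#' @param labels Named character vector of cell labels (names = cell ids).
#' @param target_type Cell type to model.
#' @param train_fraction Training fraction (default 0.75).
#' @param seed Integer seed.
#' @return List with `train_cells`, `train_labels` (0/1 integer),
#'   `val_cells`, `val_labels`.
#' @export
build_training_set <- function(labels, target_type, train_fraction = 0.75,
                               seed = 1L) {
  if (is.null(names(labels))) stop("labels must be named by cell id")
  pos <- names(labels)[labels == target_type]
  if (length(pos) == 0L) stop(sprintf("target type '%s' absent", target_type))
  if (length(pos) < 8L)
    stop(sprintf("target type '%s' has %d cells; need >= 8", target_type,
                 length(pos)))
  rest <- names(labels)[labels != target_type]
  withr::with_seed(seed, {
    n_neg <- min(length(pos), length(rest))
    if (n_neg < length(pos))
      warning(sprintf("only %d non-target cells available for %d positives",
                      length(rest), length(pos)))
    neg <- sample(rest, n_neg)
    split1 <- function(cells) {
      n_train <- round(train_fraction * length(cells))
      tr <- sample(cells, n_train)
      list(train = tr, val = setdiff(cells, tr))
    }
    sp <- split1(pos)
    sn <- split1(neg)
    list(train_cells = c(sp$train, sn$train),
         train_labels = c(rep(1L, length(sp$train)), rep(0L, length(sn$train))),
         val_cells = c(sp$val, sn$val),
         val_labels = c(rep(1L, length(sp$val)), rep(0L, length(sn$val))))
  })
}

#' Intersect reference and query highly variable genes
#'
#' The classifier's feature space is the set of highly variable genes
#' present in both the reference (training/validation) data and the data to
#' be classified, in reference order.
#'
#' @param reference_hvg,query_hvg Non-empty character vectors.
#' @return Character vector: the intersection in reference order.
#' @export
intersect_features <- function(reference_hvg, query_hvg) {
  if (!length(reference_hvg) || !length(query_hvg))
    stop("both gene lists must be non-empty")
  out <- reference_hvg[reference_hvg %in% query_hvg]
  if (!length(out)) stop("reference and query gene lists do not intersect")
  out
}

# Stratified fold ids for cv.glmnet: shuffle within each class, then deal
# round-robin so every fold holds both classes.
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Fit one binary elastic-net logistic model
#'
#' Penalized logistic regression at a fixed alpha; lambda is chosen by
#' stratified k-fold cross-validation minimizing binomial deviance (or the
#' 1-SE variant). Validation metrics (AUC, FPR, FNR at probability cutoff
#' 0.5) are computed on the held-out validation set.
#'
#' @param x_train,x_val Cells x features matrices (sparse accepted).
#' @param y_train,y_val Binary 0/1 labels.
#' @param alpha Elastic-net mixing parameter in (0, 1].
#' @param spec An [elastic_net_spec()].
#' @param seed Integer seed (controls CV fold assignment).
#' @param lambda Optional fixed lambda; bypasses cross-validation.
#' @return Object of class `binary_model`: target-free coefficient map
#'   (sparse named numeric), intercept, alpha, lambda, `n_nonzero`, and
#'   `metrics` (auc, fpr, fnr, n_validation).
#' @export
fit_binary_model <- function(x_train, y_train, x_val, y_val, alpha, spec,
                             seed = 1L, lambda = NULL) {
  if (length(unique(y_train)) < 2L) stop("training labels are single-class")
  withr::with_seed(seed, {
    if (is.null(lambda)) {
      foldid <- .stratified_folds(y_train, spec$n_cv_folds)
      cv <- glmnet::cv.glmnet(x_train, y_train, family = "binomial",
                              alpha = alpha, foldid = foldid,
                              type.measure = "deviance", nlambda = 60,
                              standardize = TRUE)
      lambda <- if (spec$lambda_rule == "1se") cv$lambda.1se else cv$lambda.min
      fit <- cv$glmnet.fit
    } else {
      fit <- glmnet::glmnet(x_train, y_train, family = "binomial",
                            alpha = alpha, standardize = TRUE)
    }
  })
  cf <- as.matrix(stats::coef(fit, s = lambda, exact = FALSE))[, 1L]
  intercept <- cf[1L]
  beta <- cf[-1L]
  nz <- beta[beta != 0]

  prob_val <- plogis(intercept + as.numeric(x_val %*% beta))
  pred <- as.integer(prob_val > 0.5)
  fp <- sum(pred == 1L & y_val == 0L)
  fn <- sum(pred == 0L & y_val == 1L)
  metrics <- list(auc = .rank_auc(prob_val, y_val),
                  fpr = fp / max(sum(y_val == 0L), 1L),
                  fnr = fn / max(sum(y_val == 1L), 1L),
                  n_validation = length(y_val))
  structure(list(coefficients = nz, intercept = unname(intercept),
                 alpha = alpha, lambda = lambda, n_nonzero = length(nz),
                 metrics = metrics, features = colnames(x_train)),
            class = "binary_model")
}

#' Select the best binary model among per-alpha candidates
#'
#' Applies the variable-count eligibility window (`[min_vars, max_vars]`);
#' if no candidate is eligible the window is dropped. Among eligible models
#' the winner has maximum validation AUC, with ties broken successively by
#' minimum false-positive rate, minimum false-negative rate, maximum number
#' of variables, and finally smallest alpha-grid index (deterministic).
#'
#' @param candidates Non-empty list of `binary_model`s.
#' @param spec An [elastic_net_spec()].
#' @return The selected `binary_model`.
#' @export
select_model <- function(candidates, spec) {
  if (!length(candidates)) stop("empty candidate list")
  nz <- vapply(candidates, function(m) as.numeric(m$n_nonzero), 0)
  eligible <- which(nz >= spec$min_vars & nz <= spec$max_vars)
  if (!length(eligible)) eligible <- seq_along(candidates)
  pick <- candidates[eligible]
  auc <- vapply(pick, function(m) m$metrics$auc, 0)
  fpr <- vapply(pick, function(m) m$metrics$fpr, 0)
  fnr <- vapply(pick, function(m) m$metrics$fnr, 0)
  nzv <- nz[eligible]
  alpha_idx <- vapply(pick, function(m) {
    i <- match(m$alpha, spec$alpha_grid)
    if (is.na(i)) length(spec$alpha_grid) + 1 else as.numeric(i)
  }, 0)
  ord <- order(-auc, fpr, fnr, -nzv, alpha_idx)
  pick[[ord[1L]]]
}

#' Train the one-vs-rest elastic-net ensemble
#'
#' For every cell type, repeats `n_repetitions` times: draw a balanced
#' train/validation split, fit one model per alpha on the shared feature
#' set, and keep the [select_model()] winner. All sub-seeds derive
#' deterministically from the master seed, so training is fully
#' reproducible.
#'
#' @param reference A `normalized_matrix` (genes x cells) of the reference.
#' @param labels Named character vector of reference cell labels.
#' @param features Character vector of feature genes (typically
#'   [intersect_features()] of reference and query HVGs).
#' @param spec An [elastic_net_spec()].
#' @param seed Master seed.
#' @return Object of class `ensemble_classifier`: per-type lists of selected
#'   `binary_model`s plus `features`, `spec`, `types`, `seed`.
#' @export
train_ensemble <- function(reference, labels, features,
                           spec = elastic_net_spec(), seed = 1L) {
  stopifnot(inherits(reference, "normalized_matrix"),
            inherits(spec, "elastic_net_spec"))
  if (is.null(names(labels))) stop("labels must be named by cell id")
  missing_feat <- setdiff(features, rownames(reference$values))
  if (length(missing_feat))
    stop(sprintf("features absent from reference: %s",
                 paste(head(missing_feat, 5), collapse = ", ")))
  x_all <- Matrix::t(reference$values[features, names(labels), drop = FALSE])
  types <- sort(unique(unname(labels)))
  models <- vector("list", length(types))
  names(models) <- types
  for (tt in types) {
    reps <- vector("list", spec$n_repetitions)
    for (r in seq_len(spec$n_repetitions)) {
      rs <- .derive_seed(seed, "split", tt, r)
      sets <- tryCatch(
        build_training_set(labels, tt, spec$train_fraction, seed = rs),
        error = function(e) stop(sprintf("[%s] %s", tt, conditionMessage(e)),
                                 call. = FALSE))
      x_tr <- x_all[sets$train_cells, , drop = FALSE]
      x_va <- x_all[sets$val_cells, , drop = FALSE]
      cands <- lapply(seq_along(spec$alpha_grid), function(ai) {
        fit_binary_model(x_tr, sets$train_labels, x_va, sets$val_labels,
                         alpha = spec$alpha_grid[ai], spec = spec,
                         seed = .derive_seed(seed, "fit", tt, r, ai))
      })
      reps[[r]] <- select_model(cands, spec)
      reps[[r]]$target_type <- tt
    }
    models[[tt]] <- reps
  }
  structure(list(models = models, features = features, spec = spec,
                 types = types, seed = as.integer(seed)),
            class = "ensemble_classifier")
}

#' Predict cell-type annotations with a trained ensemble
#'
#' For every cell and type, the assigned probability is the mean of the
#' logistic responses over the type's repetition models. A cell is labeled
#' with the argmax type if its averaged probability strictly exceeds the
#' assignment threshold, otherwise `"not assigned"`. Feature genes missing
#' from the query are imputed as zero with a warning.
#'
#' @param object A trained `ensemble_classifier`.
#' @param query A `normalized_matrix` (genes x cells) to annotate.
#' @param ... Unused.
#' @return A `cell_annotation` data.frame: `cell_id`, `label`, and one
#'   `prob_<type>` column per type.
#' @export
predict.ensemble_classifier <- function(object, query, ...) {
  stopifnot(inherits(query, "normalized_matrix"))
  feats <- object$features
  missing_feat <- setdiff(feats, rownames(query$values))
  v <- query$values
  if (length(missing_feat)) {
    warning(sprintf("%d feature gene(s) missing from query; imputed as 0",
                    length(missing_feat)))
    pad <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                dims = c(length(missing_feat), ncol(v)),
                                dimnames = list(missing_feat, colnames(v)))
    v <- rbind(v, pad)
  }
  x <- Matrix::t(v[feats, , drop = FALSE])
  n <- nrow(x)
  probs <- matrix(0, n, length(object$types),
                  dimnames = list(rownames(x), object$types))
  for (tt in object$types) {
    acc <- numeric(n)
    for (m in object$models[[tt]]) {
      beta <- numeric(length(feats))
      names(beta) <- feats
      beta[names(m$coefficients)] <- m$coefficients
      acc <- acc + plogis(m$intercept + as.numeric(x %*% beta))
    }
    probs[, tt] <- acc / length(object$models[[tt]])
  }
  best <- max.col(probs, ties.method = "first")
  best_p <- probs[cbind(seq_len(n), best)]
  label <- ifelse(best_p > object$spec$assign_threshold,
                  object$types[best], "not assigned")
  out <- data.frame(cell_id = rownames(x), label = label,
                    stringsAsFactors = FALSE)
  pm <- as.data.frame(probs, row.names = NULL)
  names(pm) <- paste0("prob_", object$types)
  out <- cbind(out, pm)
  class(out) <- c("cell_annotation", "data.frame")
  out
}

#' Confusion table of predicted vs true cell types, row-normalized
#'
#' @param predicted A `cell_annotation` (or data.frame with `cell_id`,
#'   `label`).
#' @param truth Named character vector of true labels over the same cells.
#' @return Matrix; rows = true types, columns = predicted types plus
#'   `"not assigned"`, each row summing to 1.
#' @export
confusion_proportions <- function(predicted, truth) {
  if (is.null(names(truth))) stop("truth must be named by cell id")
  if (!setequal(predicted$cell_id, names(truth)))
    stop("predicted and truth cover different cell sets")
  truth <- truth[predicted$cell_id]
  true_types <- sort(unique(unname(truth)))
  pred_types <- c(sort(setdiff(unique(predicted$label), "not assigned")),
                  "not assigned")
  tab <- matrix(0, length(true_types), length(pred_types),
                dimnames = list(true_types, pred_types))
  cross <- table(truth, predicted$label)
  tab[rownames(cross), colnames(cross)] <- cross
  sweep(tab, 1L, rowSums(tab), "/")
}

#' Serialize an ensemble classifier to JSON
#' @param ensemble An `ensemble_classifier`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "ensemble_classifier"))
  ser <- list(
    features = ensemble$features, types = ensemble$types,
    seed = ensemble$seed, spec = unclass(ensemble$spec),
    models = lapply(ensemble$models, function(reps) {
      lapply(reps, function(m) {
        list(target_type = m$target_type,
             coefficients = as.list(m$coefficients),
             intercept = m$intercept, alpha = m$alpha, lambda = m$lambda,
             n_nonzero = m$n_nonzero, metrics = m$metrics)
      })
    }))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ensemble classifier written by [write_ensemble()]
#' @param path JSON path.
#' @return An `ensemble_classifier`.
#' @export
read_ensemble <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  spec <- do.call(elastic_net_spec, ser$spec)
  models <- lapply(ser$models, function(reps) {
    lapply(reps, function(m) {
      cf <- unlist(m$coefficients)
      if (is.null(cf)) cf <- setNames(numeric(0), character(0))
      structure(list(
        coefficients = cf, intercept = m$intercept, alpha = m$alpha,
        lambda = m$lambda, n_nonzero = m$n_nonzero,
        metrics = m$metrics, target_type = m$target_type),
        class = "binary_model")
    })
  })
  structure(list(models = models, features = ser$features, spec = spec,
                 types = ser$types, seed = as.integer(ser$seed)),
            class = "ensemble_classifier")
}
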