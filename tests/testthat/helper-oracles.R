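# Independent oracles and small fixture factories used across the suite.

# Literal step-down Holm definition: sort ascending, multiply p_(i) by
# (m - i + 1), running maximum, cap at 1, restore input order.
holm_oracle <- function(p) {
  m <- length(p)
  if (!m) return(numeric(0))
  o <- order(p)
  adj <- numeric(m)
  run <- 0
  for (i in seq_len(m)) {
    run <- max(run, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, run)
  }
  adj
}

# Brute-force two-sided rank-sum p-value: enumerate every assignment of the
# pooled midranks to group a and compare rank sums.
wilcoxon_oracle <- function(a, b) {
  n <- length(a)
  m <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n)])
  idx <- utils::combn(n + m, n)
  W <- colSums(matrix(r[idx], nrow = n))
  min(1, 2 * min(mean(W <= w_obs + 1e-9), mean(W >= w_obs - 1e-9)))
}

# Adjusted Rand index between two partitions.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Small simulation config shared by several tests.
tiny_config <- function(seed = 42, ...) {
  args <- list(
    n_types = 4, type_names = c("HSC", "MEP", "GMP", "CLP"),
    n_genes = 150, markers_per_type = 6, n_dynamic_genes = 8,
    n_cells_per_donor = 120, donors_per_condition = c(young = 2, elderly = 2),
    n_regulons = 8, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# Dense toy count matrix with named genes/cells.
toy_counts <- function(mat, genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(mat)))
  if (is.null(cells)) cells <- sprintf("c%02d", seq_len(ncol(mat)))
  dimnames(mat) <- list(genes, cells)
  Matrix::Matrix(mat, sparse = TRUE)
}

# Hand-built binary_model stub for selection-cascade tests.
stub_model <- function(alpha, n_nonzero, auc, fpr = 0, fnr = 0) {
  structure(list(coefficients = setNames(rep(1, n_nonzero),
                                         sprintf("g%03d", seq_len(n_nonzero))),
                 intercept = 0, alpha = alpha, lambda = 0.1,
                 n_nonzero = as.integer(n_nonzero),
                 metrics = list(auc = auc, fpr = fpr, fnr = fnr,
                                n_validation = 50)),
            class = "binary_model")
}
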