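# Internal helpers shared across modules.

# Deterministic 31-bit sub-seed derived from a master seed and a stream label.
# Keeps all randomness traceable to one integer while giving each stage and
# repetition its own stream.
.derive_seed <- function(master, ...) {
  key <- paste(c(as.character(master), vapply(list(...), as.character, "")),
               collapse = "/")
  codes <- utf8ToInt(key)
  s <- 0
  for (v in codes) s <- (s * 31 + v) %% 2147483629
  as.integer(s)
}

# Mann-Whitney AUC of `scores` for binary `labels` (1 = positive).
.rank_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

# Column sums / per-column nonzero counts for dgCMatrix without densifying.
.assert_counts <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix must carry gene rownames and cell colnames")
  if (any(counts@x < 0)) stop("count matrix must be non-negative")
  invisible(counts)
}

.as_sparse <- function(m) {
  if (is(m, "CsparseMatrix") && is(m, "dMatrix") && is(m, "generalMatrix"))
    return(m)
  if (is.matrix(m)) m <- Matrix::Matrix(m, sparse = TRUE)
  methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
              "CsparseMatrix")
}

.stop_if_not_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("%s must lie in [0, 1]", name))
  invisible(x)
}
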