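#' Cell-type composition per donor or condition
#'
#' Counts annotated cells per group and cell type and computes within-group
#' proportions. `"not assigned"` is kept as its own category.
#'
#' @param annotations Data.frame with `cell_id` and `label` (e.g. a
#'   `cell_annotation`).
#' @param metadata Data.frame with `cell_id` and the grouping column.
#' @param group_by Metadata column defining groups (default `"donor"`).
#' @return A `composition_table` data.frame: `group`, `cell_type`, `count`,
#'   `proportion` (proportions sum to 1 within each group).
#' @export
compute_composition <- function(annotations, metadata, group_by = "donor") {
  if (!all(c("cell_id", "label") %in% names(annotations)))
    stop("annotations must have cell_id and label columns")
  if (!group_by %in% names(metadata))
    stop(sprintf("metadata has no '%s' column", group_by))
  m <- merge(annotations[, c("cell_id", "label")],
             metadata[, c("cell_id", group_by)], by = "cell_id")
  if (nrow(m) < nrow(annotations))
    stop("metadata missing for some annotated cells")
  tab <- as.data.frame(table(group = m[[group_by]], cell_type = m$label),
                       stringsAsFactors = FALSE)
  names(tab)[3L] <- "count"
  totals <- tapply(tab$count, tab$group, sum)
  if (any(totals == 0)) stop("group with zero cells")
  tab$proportion <- tab$count / as.numeric(totals[tab$group])
  tab <- tab[order(tab$group, tab$cell_type), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("composition_table", "data.frame")
  tab
}

#' Two-sided test for a difference between two proportions
#'
#' Pooled-variance z-test with Yates continuity correction (the chi-square
#' equivalent), or Fisher's exact test.
#'
#' @param a,b Length-2 vectors `(successes, total)`.
#' @param method `"z"` (default) or `"fisher"`.
#' @param correct Apply continuity correction for the z-test.
#' @return Two-sided p-value in (0, 1].
#' @export
two_proportion_test <- function(a, b, method = c("z", "fisher"),
                                correct = TRUE) {
  method <- match.arg(method)
  for (v in list(a, b)) {
    if (length(v) != 2L || any(v < 0)) stop("each group must be (successes, total)")
    if (v[1L] > v[2L]) stop("successes exceed total")
    if (v[2L] == 0) stop("totals must be positive")
  }
  p <- if (method == "z") {
    if (a[1L] / a[2L] == b[1L] / b[2L]) 1 else
      suppressWarnings(stats::prop.test(c(a[1L], b[1L]), c(a[2L], b[2L]),
                                        correct = correct)$p.value)
  } else {
    tab <- matrix(c(a[1L], a[2L] - a[1L], b[1L], b[2L] - b[1L]), 2L)
    stats::fisher.test(tab)$p.value
  }
  min(max(p, .Machine$double.xmin), 1)
}

#' Holm (Bonferroni-Holm) step-down multiple-testing adjustment
#'
#' Sorts p-values ascending, multiplies the i-th by `m - i + 1`, enforces
#' monotonicity by a running maximum, caps at 1 and restores input order.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values in input order (empty in, empty out).
#' @export
holm_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "holm")
}

#' Test for cell-type proportion shifts between two compositions
#'
#' Pools counts per cell type within each composition table, runs one
#' [two_proportion_test()] per shared type, Holm-adjusts across types, and
#' flags significance at adjusted p < 0.05.
#'
#' @param a,b `composition_table`s (e.g. one per condition).
#' @param method Passed to [two_proportion_test()].
#' @param alpha Significance level on the adjusted p-values (default 0.05).
#' @return Data.frame with one row per shared type: pooled
#'   `successes_a/total_a/successes_b/total_b`, `proportion_a/b`, `p_raw`,
#'   `p_adjusted`, `significant`.
#' @export
test_composition_shift <- function(a, b, method = "z", alpha = 0.05) {
  pool <- function(tab) {
    cnt <- tapply(tab$count, tab$cell_type, sum)
    list(counts = cnt, total = sum(cnt))
  }
  pa <- pool(a)
  pb <- pool(b)
  shared <- intersect(names(pa$counts), names(pb$counts))
  if (!length(shared)) stop("no shared cell types between the two tables")
  shared <- sort(shared)
  p_raw <- vapply(shared, function(tt) {
    two_proportion_test(c(pa$counts[[tt]], pa$total),
                        c(pb$counts[[tt]], pb$total), method = method)
  }, 0)
  p_adj <- holm_adjust(p_raw)
  data.frame(cell_type = shared,
             successes_a = as.integer(pa$counts[shared]), total_a = pa$total,
             successes_b = as.integer(pb$counts[shared]), total_b = pb$total,
             proportion_a = as.numeric(pa$counts[shared]) / pa$total,
             proportion_b = as.numeric(pb$counts[shared]) / pb$total,
             p_raw = unname(p_raw), p_adjusted = unname(p_adj),
             significant = unname(p_adj) < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pairwise proportion tests between donors
#'
#' For one cell type, tests every pair of donors within a composition table
#' (the within-condition comparison mode).
#'
#' @param composition A `composition_table` grouped by donor.
#' @param cell_type Cell type to test.
#' @param method Passed to [two_proportion_test()].
#' @return Data.frame of donor pairs with raw and Holm-adjusted p-values.
#' @export
pairwise_donor_tests <- function(composition, cell_type, method = "z") {
  sub <- composition[composition$cell_type == cell_type, , drop = FALSE]
  if (nrow(sub) < 2L) stop("need at least two donors")
  totals <- tapply(composition$count, composition$group, sum)
  prs <- utils::combn(as.character(sub$group), 2L)
  p_raw <- apply(prs, 2L, function(pr) {
    two_proportion_test(
      c(sub$count[sub$group == pr[1L]], totals[[pr[1L]]]),
      c(sub$count[sub$group == pr[2L]], totals[[pr[2L]]]), method = method)
  })
  data.frame(donor_a = prs[1L, ], donor_b = prs[2L, ],
             p_raw = p_raw, p_adjusted = holm_adjust(p_raw),
             stringsAsFactors = FALSE)
}
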