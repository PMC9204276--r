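#' Percentile expression cutoff for one tissue
#'
#' Computes the nearest-rank percentile cutoff used for class labeling: for
#' the top p% the value at rank `ceiling(p/100 * N)` from the largest present
#' value in that tissue, for the bottom p% the symmetric rank from the
#' smallest. No interpolation is used, so the cutoff is always a value
#' attained by some gene, and labeling with the `>=` (top) / `<=` (bottom)
#' rule reproduces the intended positive count in the absence of ties.
#'
#' @param expr long expression tibble (`gene`, `tissue`, `value`).
#' @param tissue tissue name to threshold.
#' @param direction `"top"` (high expression is the positive class) or
#'   `"bottom"` (low expression is the positive class).
#' @param percent percentile in (0, 50]; the study design uses
#'   5, 10, 15, 20, 25, 30.
#' @return One-row tibble: `tissue`, `direction`, `percent`, `value`,
#'   `n_present`, `rank`.
#' @export
compute_cutoff <- function(expr, tissue, direction = c("top", "bottom"), percent) {
  direction <- match.arg(direction)
  percent <- as.numeric(percent)
  if (is.na(percent) || percent <= 0 || percent > 50) {
    abort("`percent` must be in (0, 50]")
  }
  vals <- expr$value[expr$tissue == tissue & !is.na(expr$value)]
  if (length(vals) == 0) abort(paste0("no present values for tissue '", tissue, "'"))
  r <- ceiling(percent / 100 * length(vals))
  r <- max(r, 1L)
  value <- if (direction == "top") {
    sort(vals, decreasing = TRUE)[r]
  } else {
    sort(vals)[r]
  }
  tibble(tissue = tissue, direction = direction, percent = percent,
         value = value, n_present = length(vals), rank = r)
}

#' Label genes in one tissue against a cutoff
#'
#' Applies the class-labeling rule: under a top cutoff a gene is expressed
#' (class `c1`) iff its value is greater than or equal to the cutoff value;
#' under a bottom cutoff iff less than or equal. Everything else is the
#' unexpressed class `c0`. Genes without a measured value in the tissue are
#' excluded. Ties at the cutoff are all labeled positive, which can push the
#' positive fraction above `percent`.
#'
#' @param expr long expression tibble.
#' @param cutoff one-row tibble from [compute_cutoff()] (or with columns
#'   `tissue`, `direction`, `value`).
#' @return Tibble `gene`, `tissue`, `value`, `class` (`"c0"`/`"c1"`), unbalanced.
#' @export
label_genes <- function(expr, cutoff) {
  if (nrow(cutoff) != 1) abort("`cutoff` must be a single cutoff row")
  if (!cutoff$tissue %in% expr$tissue) {
    abort(paste0("cutoff tissue '", cutoff$tissue, "' not in expression table"))
  }
  sub <- expr[expr$tissue == cutoff$tissue & !is.na(expr$value), , drop = FALSE]
  pos <- if (cutoff$direction == "top") sub$value >= cutoff$value else sub$value <= cutoff$value
  out <- tibble(gene = sub$gene, tissue = sub$tissue, value = sub$value,
                class = ifelse(pos, "c1", "c0"))
  attr(out, "cutoff") <- as_tibble(cutoff)
  out
}

#' Balance a labeled set by subsampling negatives
#'
#' Keeps every positive (`c1`) gene and draws, uniformly without replacement
#' with the given seed, an equal number of negatives, yielding the balanced
#' dataset used for training and cross-validation. The positive set is never
#' altered; the draw is deterministic given `seed`, which is recorded on the
#' result for provenance.
#'
#' @param labels tibble from [label_genes()] (columns `gene`, `class`).
#' @param seed integer RNG seed for the negative draw.
#' @return Balanced tibble of the same columns, with attributes `seed` and
#'   (when present on the input) `cutoff`.
#' @export
balance_labels <- function(labels, seed) {
  n_pos <- sum(labels$class == "c1")
  n_neg <- sum(labels$class == "c0")
  if (n_pos == 0) {
    warn("no positive examples; returning empty balanced set")
    out <- labels[0, , drop = FALSE]
  } else if (n_pos > n_neg) {
    abort("more positives than negatives; balancing by negative subsampling impossible")
  } else {
    keep_neg <- withr::with_seed(seed, sample(which(labels$class == "c0"), n_pos))
    out <- labels[sort(c(which(labels$class == "c1"), keep_neg)), , drop = FALSE]
  }
  attr(out, "seed") <- as.integer(seed)
  attr(out, "cutoff") <- attr(labels, "cutoff")
  out
}

#' Labeled, balanced dataset for one tissue in one step
#'
#' Convenience pipeline: cutoff, label, balance.
#'
#' @inheritParams compute_cutoff
#' @inheritParams balance_labels
#' @return Balanced label tibble (see [balance_labels()]).
#' @export
labeled_set <- function(expr, tissue, direction = c("top", "bottom"), percent, seed) {
  direction <- match.arg(direction)
  cutoff <- compute_cutoff(expr, tissue, direction, percent)
  balance_labels(label_genes(expr, cutoff), seed)
}

#' @rdname label_genes
#' @param path output path; labels are written as tab-delimited
#'   `gene  tissue  direction  percent  class`.
#' @export
write_labels <- function(labels, path) {
  cutoff <- attr(labels, "cutoff")
  out <- tibble(
    gene = labels$gene, tissue = labels$tissue,
    direction = if (is.null(cutoff)) NA_character_ else cutoff$direction,
    percent = if (is.null(cutoff)) NA_real_ else cutoff$percent,
    class = labels$class
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
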