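#' Median-of-ratios size factors
#'
#' Per-sample normalization constants correcting for sequencing depth: each
#' sample's factor is the median, over sites with all-positive counts, of the
#' ratio of its count to the geometric mean of that site's counts across
#' samples. A matrix whose columns are identical gets factors of exactly 1.
#'
#' @param se A \code{RangedSummarizedExperiment} with assay \code{counts}, or
#'   a plain counts matrix (sites x samples).
#' @return A named numeric vector of positive factors, one per sample.
#' @export
size_factors <- function(se) {
  counts <- screen_counts(se)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    stop("no site has positive counts in every sample; size factors are ",
         "undefined (add a pseudocount or provide more data)", call. = FALSE)
  }
  m <- counts[all_pos, , drop = FALSE]
  ref <- exp(rowMeans(log(m)))
  factors <- apply(m, 2L, function(col) stats::median(col / ref))
  stats::setNames(factors, colnames(counts))
}

screen_counts <- function(se) {
  if (methods::is(se, "SummarizedExperiment")) {
    SummarizedExperiment::assay(se, "counts")
  } else {
    as.matrix(se)
  }
}

screen_condition <- function(se, condition = NULL) {
  if (is.null(condition) && methods::is(se, "SummarizedExperiment")) {
    condition <- stats::setNames(
      as.character(SummarizedExperiment::colData(se)$condition),
      colnames(se))
  }
  if (is.null(condition)) {
    stop("condition labels are required", call. = FALSE)
  }
  condition
}

# Mean normalized count per condition for each site; conditions ordered so
# log2fc is log2(condA / condB) with condA the first label alphabetically
# unless a reference ordering is supplied.
group_means <- function(counts, factors, condition) {
  norm <- sweep(counts, 2L, factors, "/")
  labels <- unique(condition)
  if (length(labels) != 2L) {
    stop("the screen requires exactly 2 condition labels, got ",
         length(labels), call. = FALSE)
  }
  cols_of <- function(lab) {
    cols <- which(condition == lab)
    if (!length(cols)) stop("condition '", lab, "' has 0 samples",
                            call. = FALSE)
    rowMeans(norm[, cols, drop = FALSE])
  }
  out <- do.call(cbind, lapply(labels, cols_of))
  colnames(out) <- labels
  out
}

#' Log2 fold-change screen between two conditions
#'
#' Normalizes counts by median-of-ratios size factors, computes per-site
#' \code{log2fc = log2((meanA + pseudocount) / (meanB + pseudocount))} over
#' the condition means, and flags sites with \code{|log2fc|} strictly above
#' the cutoff. Condition A is \code{numerator} (default: the first label in
#' column order), so \code{log2fc} reads as log2(A/B) — e.g. log2FC(M1/M2).
#'
#' @param se A \code{RangedSummarizedExperiment} with assay \code{counts} and
#'   a \code{condition} column, or a counts matrix plus \code{condition}.
#' @param condition Optional named character vector of sample conditions
#'   (required when \code{se} is a plain matrix).
#' @param numerator Condition label used as the fold-change numerator.
#' @param lfc_cutoff Absolute log2 fold-change cutoff, strict (default 1.0).
#' @param pseudocount Added to each condition mean before the log ratio
#'   (default 1.0).
#' @return A data.frame with one row per site: \code{site}, \code{mean_A},
#'   \code{mean_B}, \code{log2fc}, \code{flagged}.
#' @export
log2fc_screen <- function(se, condition = NULL, numerator = NULL,
                          lfc_cutoff = 1.0, pseudocount = 1.0) {
  stopifnot(lfc_cutoff > 0, pseudocount > 0)
  counts <- screen_counts(se)
  condition <- screen_condition(se, condition)[colnames(counts)]
  factors <- size_factors(counts)
  if (is.null(numerator)) numerator <- condition[1L]
  labels <- c(numerator, setdiff(unique(condition), numerator))
  if (!numerator %in% condition) {
    stop("numerator condition '", numerator, "' has 0 samples",
         call. = FALSE)
  }
  means <- group_means(counts, factors, condition)[, labels, drop = FALSE]
  log2fc <- log2((means[, 1L] + pseudocount) / (means[, 2L] + pseudocount))
  data.frame(site = rownames(counts),
             mean_A = unname(means[, 1L]),
             mean_B = unname(means[, 2L]),
             log2fc = unname(log2fc),
             flagged = unname(abs(log2fc) > lfc_cutoff),
             row.names = NULL, stringsAsFactors = FALSE)
}

# All distinct assignments of nA samples to condition A among n samples,
# as a matrix of column-index subsets (one column per split).
label_splits <- function(n, nA) {
  utils::combn(n, nA)
}

#' Permutation test on the absolute log2 fold change
#'
#' A self-contained significance measure for the screen: the statistic is
#' \code{|log2fc|} on size-factor-normalized counts, and its null
#' distribution comes from reassigning condition labels to samples. All
#' distinct label splits are enumerated when there are at most
#' \code{n_permutations} of them; otherwise \code{n_permutations} random
#' splits are drawn (reproducibly from \code{seed}). The p-value uses +1
#' smoothing: \code{p = (1 + #(null >= observed)) / (1 + #null)}.
#'
#' @inheritParams log2fc_screen
#' @param n_permutations Maximum number of label splits (default 10000).
#' @param seed Integer seed for the random-split branch.
#' @return Numeric vector of per-site permutation p-values.
#' @export
permutation_test <- function(se, condition = NULL, numerator = NULL,
                             pseudocount = 1.0, n_permutations = 10000L,
                             seed = 1L) {
  counts <- screen_counts(se)
  condition <- screen_condition(se, condition)[colnames(counts)]
  labels <- unique(condition)
  if (length(labels) != 2L) {
    stop("permutation test requires exactly 2 conditions", call. = FALSE)
  }
  if (is.null(numerator)) numerator <- condition[1L]
  nA <- sum(condition == numerator)
  n <- length(condition)
  if (nA < 2L || n - nA < 2L) {
    stop("permutation test requires >= 2 samples per condition",
         call. = FALSE)
  }
  n_splits <- choose(n, nA)
  if (n_splits < 2L) {
    stop("fewer than 2 distinct label permutations", call. = FALSE)
  }
  factors <- size_factors(counts)
  norm <- sweep(counts, 2L, factors, "/")
  abs_lfc <- function(idx_a) {
    ma <- rowMeans(norm[, idx_a, drop = FALSE])
    mb <- rowMeans(norm[, -idx_a, drop = FALSE])
    abs(log2((ma + pseudocount) / (mb + pseudocount)))
  }
  observed <- abs_lfc(which(condition == numerator))
  if (n_splits <= n_permutations) {
    splits <- label_splits(n, nA)
  } else {
    set.seed(seed)
    splits <- replicate(n_permutations, sort(sample.int(n, nA)))
  }
  n_null <- ncol(splits)
  exceed <- rep(0L, nrow(norm))
  for (k in seq_len(n_null)) {
    exceed <- exceed + (abs_lfc(splits[, k]) >= observed - 1e-12)
  }
  unname((1 + exceed) / (1 + n_null))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' adjusted values are >= raw and order-preserving.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Filter a statistics table on adjusted p-value and fold change
#'
#' Keeps rows with \code{padj < padj_cutoff} AND
#' \code{|log2fc| > lfc_cutoff}, both strict, preserving row order. This is
#' the generic selection rule applied to any table carrying those two
#' columns, e.g. output of an external differential tool.
#'
#' @param stats_table A data.frame with columns \code{padj} and
#'   \code{log2fc}.
#' @param padj_cutoff Strict upper bound on adjusted p (default 0.05).
#' @param lfc_cutoff Strict lower bound on |log2fc| (default 1.0).
#' @return The filtered subset of \code{stats_table}.
#' @export
apply_de_filter <- function(stats_table, padj_cutoff = 0.05,
                            lfc_cutoff = 1.0) {
  for (col in c("padj", "log2fc")) {
    if (!col %in% names(stats_table)) {
      stop("missing required column '", col, "'", call. = FALSE)
    }
  }
  keep <- stats_table$padj < padj_cutoff &
    abs(stats_table$log2fc) > lfc_cutoff
  stats_table[keep, , drop = FALSE]
}

#' Full differential-enrichment screen
#'
#' Runs \code{\link{log2fc_screen}}, optionally adds permutation p-values and
#' their BH adjustment, and sets the final flag. With p-values the flag is
#' \code{padj < padj_cutoff AND |log2fc| > lfc_cutoff}; without, it is the
#' fold-change criterion alone. This screen is a deliberately lightweight
#' built-in; the canonical route for a full analysis is exporting the count
#' matrix (\code{\link{write_count_matrix}}) to a dedicated differential
#' tool.
#'
#' @inheritParams log2fc_screen
#' @inheritParams permutation_test
#' @param padj_cutoff Strict adjusted-p cutoff when permutations are used
#'   (default 0.05).
#' @param with_permutations Compute permutation p-values (default TRUE).
#' @return A data.frame: \code{site}, \code{mean_A}, \code{mean_B},
#'   \code{log2fc}, and when permuting \code{perm_p}, \code{padj}, plus
#'   \code{flagged}.
#' @export
screen_sites <- function(se, condition = NULL, numerator = NULL,
                         lfc_cutoff = 1.0, padj_cutoff = 0.05,
                         pseudocount = 1.0, with_permutations = TRUE,
                         n_permutations = 10000L, seed = 1L) {
  res <- log2fc_screen(se, condition = condition, numerator = numerator,
                       lfc_cutoff = lfc_cutoff, pseudocount = pseudocount)
  if (with_permutations) {
    res$perm_p <- permutation_test(se, condition = condition,
                                   numerator = numerator,
                                   pseudocount = pseudocount,
                                   n_permutations = n_permutations,
                                   seed = seed)
    res$padj <- bh_adjust(res$perm_p)
    res$flagged <- res$padj < padj_cutoff & abs(res$log2fc) > lfc_cutoff
    res <- res[, c("site", "mean_A", "mean_B", "log2fc", "perm_p", "padj",
                   "flagged")]
  }
  res
}

#' Write / read the screen result table
#'
#' @param result Screen result data.frame.
#' @param path TSV path.
#' @return Invisibly the path (write) or the data.frame (read).
#' @export
write_screen_tsv <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
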