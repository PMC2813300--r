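#' Fold changes relative to reference tumors
#'
#' Converts a linear-scale expression table (e.g. RT-qPCR quantities)
#' into per-gene fold changes over the average of designated reference
#' tumors. The reference average is geometric by default -- fold
#' changes are log-scale quantities -- with an arithmetic option.
#'
#' @param expr Genes-by-tumors numeric matrix, strictly positive,
#'   linear scale.
#' @param reference_ids Column names of the reference tumors.
#' @param average `"geometric"` (default) or `"arithmetic"`.
#' @return Matrix of fold changes (all columns of `expr`, including
#'   the references), with attributes `reference_ids` and `average`.
#' @examples
#' expr <- matrix(c(20, 2, 8), 1, dimnames = list("SOX2", c("T1", "R1", "R2")))
#' relative_fold_changes(expr, c("R1", "R2"))["SOX2", "T1"] # 5
#' @export
relative_fold_changes <- function(expr, reference_ids,
                                  average = c("geometric", "arithmetic")) {
  average <- match.arg(average)
  expr <- as.matrix(expr)
  if (any(!is.na(expr) & expr <= 0)) {
    stopf("expression values must be strictly positive (linear scale)")
  }
  unknown <- setdiff(reference_ids, colnames(expr))
  if (length(unknown)) {
    stopf("unknown reference tumor id(s): %s", paste(unknown, collapse = ", "))
  }
  if (length(reference_ids) < 1L) stopf("at least one reference tumor required")
  ref <- expr[, reference_ids, drop = FALSE]
  ref_avg <- if (average == "geometric") {
    2^rowMeans(log2(ref))
  } else {
    rowMeans(ref)
  }
  fc <- expr / ref_avg
  attr(fc, "reference_ids") <- reference_ids
  attr(fc, "average") <- average
  fc
}

#' Classify driver candidates by recurrence of over-expression
#'
#' Applies two independent recurrence rules over a tumor subset of
#' size `n`: a gene is *recurrently over-expressed* when its fold
#' change exceeds `thr_recurrent` in at least `k` of the `n` tumors,
#' and *strongly over-expressed* when it exceeds `thr_strong` in at
#' least `k` of `n`. The defaults (k = 4, n = 5, thresholds 2 and 5)
#' separate driver candidates from bystanders within an amplicon.
#'
#' @param fc Fold-change matrix from [relative_fold_changes()].
#' @param tumor_subset The tumors to evaluate (exactly `n` of them).
#' @param k Minimum number of passing tumors (default 4).
#' @param n Required subset size (default 5).
#' @param thr_recurrent,thr_strong Fold-change cutoffs (2 and 5).
#' @return data.frame with gene, n_passing_over2, n_passing_over5,
#'   recurrent_over2, strong_over5.
#' @export
classify_driver_candidates <- function(fc, tumor_subset, k = 4L, n = 5L,
                                       thr_recurrent = 2, thr_strong = 5) {
  if (length(tumor_subset) != n) {
    stopf("tumor_subset has %d tumors, expected n = %d",
          length(tumor_subset), n)
  }
  unknown <- setdiff(tumor_subset, colnames(fc))
  if (length(unknown)) stopf("unknown tumor id(s): %s",
                             paste(unknown, collapse = ", "))
  sub <- fc[, tumor_subset, drop = FALSE]
  n2 <- rowSums(sub > thr_recurrent, na.rm = TRUE)
  n5 <- rowSums(sub > thr_strong, na.rm = TRUE)
  data.frame(
    gene = rownames(fc),
    n_passing_over2 = n2, n_passing_over5 = n5,
    recurrent_over2 = n2 >= k, strong_over5 = n5 >= k,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Directed differential-expression signature container
#'
#' @param up,down Disjoint character vectors of gene symbols.
#' @param table Optional per-gene statistics data.frame.
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(up, down, table = NULL) {
  up <- unique(toupper(up)); down <- unique(toupper(down))
  if (length(intersect(up, down))) {
    stopf("up and down lists must be disjoint")
  }
  structure(list(up = up, down = down, table = table),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature: %d up, %d down\n",
              length(x$up), length(x$down)))
  invisible(x)
}

#' Members of a signature
#' @param x A `gene_signature`.
#' @return Character vector `c(up, down)`.
#' @export
signature_members <- function(x) c(x$up, x$down)

# vectorized per-gene Welch two-sample t statistics
welch_rows <- function(mat, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(mat[, idx1, drop = FALSE])
  m2 <- rowMeans(mat[, idx2, drop = FALSE])
  v1 <- rowSums((mat[, idx1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((mat[, idx2, drop = FALSE] - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  p <- 2 * pt(-abs(stat), df)
  zerovar <- se2 == 0
  stat[zerovar] <- 0; p[zerovar] <- 1
  list(statistic = stat, p = p, lfc = m1 - m2, df = df)
}

resolve_case <- function(labels, case) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2L) stopf("labels must define exactly two groups")
  if (is.null(case)) case <- if ("tumor" %in% lev) "tumor" else lev[1L]
  if (!case %in% lev) stopf("case level '%s' not present in labels", case)
  list(labels = labels, case = case, other = setdiff(lev, case))
}

#' Define a differential-expression signature
#'
#' Per-gene Welch two-sample t test between the case and control
#' groups, Benjamini-Hochberg adjustment across genes, and membership
#' when the adjusted p-value is below `alpha` and the absolute log2
#' fold change is at least `min_abs_lfc`. Direction follows the sign
#' of the case-minus-control mean difference.
#'
#' @param mat Genes-by-samples log2 expression matrix.
#' @param labels Group label per column (two groups).
#' @param case Label of the case group (default `"tumor"` if present,
#'   else the first label).
#' @param alpha BH-adjusted significance cutoff (default 0.05).
#' @param min_abs_lfc Minimum |log2 fold change| (default 1).
#' @return A [gene_signature()] whose `table` holds gene, statistic,
#'   p, padj, lfc and direction for every gene.
#' @export
define_signature <- function(mat, labels, case = NULL, alpha = 0.05,
                             min_abs_lfc = 1) {
  rc <- resolve_case(labels, case)
  idx1 <- which(rc$labels == rc$case)
  idx2 <- which(rc$labels == rc$other)
  if (length(idx1) < 2L || length(idx2) < 2L) {
    stopf("each group needs at least 2 samples")
  }
  w <- welch_rows(mat, idx1, idx2)
  padj <- p.adjust(w$p, method = "BH")
  member <- padj < alpha & abs(w$lfc) >= min_abs_lfc
  direction <- ifelse(w$lfc > 0, "up", "down")
  tab <- data.frame(
    gene = rownames(mat), statistic = w$statistic, p = w$p, padj = padj,
    lfc = w$lfc, direction = direction, member = member,
    stringsAsFactors = FALSE, row.names = NULL
  )
  gene_signature(up = tab$gene[member & direction == "up"],
                 down = tab$gene[member & direction == "down"],
                 table = tab)
}

#' Top deregulated marker genes
#'
#' Genes ranked by the absolute Welch statistic of the case-vs-control
#' comparison, ties broken lexicographically by gene id (stable), the
#' first `n` returned.
#'
#' @inheritParams define_signature
#' @param n Number of markers (default 100); if larger than the gene
#'   count, all genes are returned with a warning.
#' @return data.frame of gene, statistic, lfc in rank order.
#' @export
top_markers <- function(mat, labels, n = 100L, case = NULL) {
  rc <- resolve_case(labels, case)
  idx1 <- which(rc$labels == rc$case)
  idx2 <- which(rc$labels == rc$other)
  if (length(idx1) < 2L || length(idx2) < 2L) {
    stopf("each group needs at least 2 samples")
  }
  w <- welch_rows(mat, idx1, idx2)
  ord <- order(-abs(w$statistic), rownames(mat))
  if (n > nrow(mat)) {
    warning(sprintf("n = %d exceeds the %d genes; returning all", n, nrow(mat)))
    n <- nrow(mat)
  }
  sel <- ord[seq_len(n)]
  data.frame(gene = rownames(mat)[sel], statistic = w$statistic[sel],
             lfc = w$lfc[sel], stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-gene detection fraction
#'
#' Diagnostic reported alongside signatures: the fraction of case
#' samples in which a gene exceeds `fold` times the mean control
#' expression (both on linear scale after undoing the log2).
#'
#' @inheritParams define_signature
#' @param genes Genes to report (default all).
#' @param fold Per-sample fold-change cutoff (default 2).
#' @return Named numeric vector of fractions in `[0, 1]`.
#' @export
detection_fraction <- function(mat, labels, genes = rownames(mat),
                               case = NULL, fold = 2) {
  rc <- resolve_case(labels, case)
  idx1 <- which(rc$labels == rc$case)
  idx2 <- which(rc$labels == rc$other)
  lin <- 2^mat[genes, , drop = FALSE]
  ref <- rowMeans(lin[, idx2, drop = FALSE])
  rowMeans(lin[, idx1, drop = FALSE] > fold * ref)
}
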