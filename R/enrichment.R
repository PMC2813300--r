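#' Exact hypergeometric overlap test for two gene lists
#'
#' Upper-tail probability of observing at least the seen intersection
#' of two lists drawn from an explicit finite universe:
#' `P(X >= |A intersect B|)` with X hypergeometric (population
#' `|universe|`, successes `|A|`, draws `|B|`). Computed exactly via
#' the hypergeometric distribution function, never a normal
#' approximation. The universe must be passed explicitly.
#'
#' @param A,B Character vectors of gene symbols (case-insensitive).
#' @param universe Character vector containing both lists.
#' @return List of class `overlap_result`: n_universe, n_A, n_B,
#'   n_overlap, p_value, fraction_of_A (= overlap / |A|) and
#'   fraction_of_B.
#' @export
hypergeometric_overlap <- function(A, B, universe) {
  A <- unique(toupper(A)); B <- unique(toupper(B))
  universe <- unique(toupper(universe))
  bad <- c(setdiff(A, universe), setdiff(B, universe))
  if (length(bad)) {
    stopf("symbol(s) outside the universe: %s",
          paste(head(unique(bad), 5), collapse = ", "))
  }
  k <- length(intersect(A, B))
  p <- phyper(k - 1, length(A), length(universe) - length(A), length(B),
              lower.tail = FALSE)
  structure(list(
    n_universe = length(universe), n_A = length(A), n_B = length(B),
    n_overlap = k, p_value = p,
    fraction_of_A = if (length(A)) k / length(A) else NA_real_,
    fraction_of_B = if (length(B)) k / length(B) else NA_real_
  ), class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap %d of |A|=%d, |B|=%d in universe %d; p = %.3g\n",
              x$n_overlap, x$n_A, x$n_B, x$n_universe, x$p_value))
  invisible(x)
}

#' Partitioned (activated/repressed) target-list container
#'
#' @param activated,repressed Disjoint character vectors of symbols.
#' @return An object of class `target_list`.
#' @export
target_list <- function(activated, repressed) {
  activated <- unique(toupper(activated))
  repressed <- unique(toupper(repressed))
  if (length(intersect(activated, repressed))) {
    stopf("activated and repressed sets must be disjoint")
  }
  structure(list(activated = activated, repressed = repressed),
            class = "target_list")
}

#' @export
print.target_list <- function(x, ...) {
  cat(sprintf("target_list: %d activated, %d repressed (%d total)\n",
              length(x$activated), length(x$repressed),
              length(x$activated) + length(x$repressed)))
  invisible(x)
}

#' Total size of a target list
#' @param x A `target_list`.
#' @export
target_list_size <- function(x) length(x$activated) + length(x$repressed)

#' Build a curated direct-target list by list intersection
#'
#' Intersects a set of genes with transcription-factor-bound promoters
#' with a directed differential gene list: targets the factor
#' activates are the bound genes among the up-regulated, repressed
#' targets the bound genes among the down-regulated.
#'
#' @param bound_promoters Character vector of bound genes.
#' @param differential data.frame with columns `gene` and `direction`
#'   (`"up"`/`"down"`), or a [gene_signature()].
#' @return A [target_list()].
#' @export
build_target_list <- function(bound_promoters, differential) {
  if (inherits(differential, "gene_signature")) {
    differential <- data.frame(
      gene = c(differential$up, differential$down),
      direction = rep(c("up", "down"),
                      c(length(differential$up), length(differential$down))),
      stringsAsFactors = FALSE)
  }
  gene <- toupper(differential$gene)
  dir <- differential$direction
  both <- intersect(unique(gene[dir == "up"]), unique(gene[dir == "down"]))
  if (length(both)) {
    stopf("gene(s) listed in both directions: %s",
          paste(head(both, 5), collapse = ", "))
  }
  bound <- unique(toupper(bound_promoters))
  target_list(activated = intersect(bound, gene[dir == "up"]),
              repressed = intersect(bound, gene[dir == "down"]))
}

#' Rank all genes against a phenotype
#'
#' For a two-class phenotype the per-gene score is the
#' signal-to-noise ratio (case mean minus control mean over the sum
#' of group standard deviations); for a continuous phenotype profile
#' (e.g. the expression of one gene) it is the Pearson correlation of
#' each gene with that profile. Genes are returned in descending
#' score order with ties broken by gene id; zero-variance genes get
#' score 0 and are flagged.
#'
#' @param mat Genes-by-samples expression matrix.
#' @param phenotype Factor/character of length `ncol(mat)` (two
#'   classes) or a numeric profile of the same length.
#' @param case Case label for the two-class mode.
#' @return data.frame with gene and score, ordered; flagged
#'   zero-variance genes in attribute `"flagged"`.
#' @export
rank_genes_by_phenotype <- function(mat, phenotype, case = NULL) {
  if (length(phenotype) != ncol(mat)) {
    stopf("phenotype length must equal the sample count")
  }
  if (is.numeric(phenotype)) {
    if (stats::var(phenotype) == 0) stopf("continuous phenotype has zero variance")
    score <- gene_pearson(mat, phenotype)
  } else {
    rc <- resolve_case(phenotype, case)
    idx1 <- which(rc$labels == rc$case)
    idx2 <- which(rc$labels == rc$other)
    m1 <- rowMeans(mat[, idx1, drop = FALSE])
    m2 <- rowMeans(mat[, idx2, drop = FALSE])
    s1 <- sqrt(rowSums((mat[, idx1, drop = FALSE] - m1)^2) /
                 max(1, length(idx1) - 1))
    s2 <- sqrt(rowSums((mat[, idx2, drop = FALSE] - m2)^2) /
                 max(1, length(idx2) - 1))
    denom <- s1 + s2
    score <- ifelse(denom > 0, (m1 - m2) / denom, 0)
  }
  flagged <- rownames(mat)[is.na(score) | (score == 0 & rowVars0(mat))]
  score[is.na(score)] <- 0
  ord <- order(-score, rownames(mat))
  out <- data.frame(gene = rownames(mat)[ord], score = score[ord],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "flagged") <- flagged
  out
}

rowVars0 <- function(mat) {
  rowSums((mat - rowMeans(mat))^2) == 0
}

# vectorized Pearson correlation of every row with a profile
gene_pearson <- function(mat, profile) {
  pc <- profile - mean(profile)
  mc <- mat - rowMeans(mat)
  num <- as.numeric(mc %*% pc)
  den <- sqrt(rowSums(mc^2) * sum(pc^2))
  ifelse(den > 0, num / den, NA_real_)
}

#' Recover targets correlated with a driver gene's expression
#'
#' Partitions a curated target list by its behavior in the tumors:
#' activated targets whose expression correlates positively with the
#' driver gene (Pearson, BH-adjusted p < `alpha` across all tested
#' targets) and repressed targets that anti-correlate. The driver
#' gene itself is excluded from testing.
#'
#' @param mat Genes-by-samples expression matrix.
#' @param sox2_gene Row name of the driver gene profile.
#' @param targets A [target_list()] of known direct targets.
#' @param alpha BH-adjusted cutoff (default 0.05).
#' @return A [target_list()] of the correlated partition, with the
#'   per-gene statistics in attribute `"stats"`.
#' @export
correlated_target_lists <- function(mat, sox2_gene, targets, alpha = 0.05) {
  if (!sox2_gene %in% rownames(mat)) {
    stopf("driver gene '%s' absent from the matrix", sox2_gene)
  }
  tested <- setdiff(intersect(c(targets$activated, targets$repressed),
                              rownames(mat)), sox2_gene)
  if (!length(tested)) {
    out <- target_list(character(0), character(0))
    attr(out, "stats") <- data.frame(gene = character(), r = numeric(),
                                     p = numeric(), padj = numeric())
    return(out)
  }
  profile <- mat[sox2_gene, ]
  r <- gene_pearson(mat[tested, , drop = FALSE], profile)
  n <- ncol(mat)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), n - 2)
  p[is.na(r)] <- 1
  padj <- p.adjust(p, method = "BH")
  stats_df <- data.frame(gene = tested, r = r, p = p, padj = padj,
                         stringsAsFactors = FALSE, row.names = NULL)
  act <- tested[tested %in% targets$activated & !is.na(r) & r > 0 &
                  padj < alpha]
  rep_ <- tested[tested %in% targets$repressed & !is.na(r) & r < 0 &
                   padj < alpha]
  out <- target_list(act, rep_)
  attr(out, "stats") <- stats_df
  out
}

#' Consolidate a driver-response signature with disease signatures
#'
#' Returns the genes present in the driver-response signature (up or
#' down) and in at least one of the disease signatures, recording
#' direction concordance per gene. The result is always a subset of
#' the driver-response signature.
#'
#' @param sox2_squamous A [gene_signature()] from the in-vitro driver
#'   over-expression model.
#' @param lung_sigs List of one or more [gene_signature()]s.
#' @return data.frame with gene, direction_sox2, direction_lung and
#'   concordant columns.
#' @export
consolidate_signatures <- function(sox2_squamous, lung_sigs) {
  if (inherits(lung_sigs, "gene_signature")) lung_sigs <- list(lung_sigs)
  if (!length(lung_sigs)) stopf("at least one disease signature required")
  sox_genes <- signature_members(sox2_squamous)
  sox_dir <- rep(c("up", "down"),
                 c(length(sox2_squamous$up), length(sox2_squamous$down)))
  lung_up <- unique(unlist(lapply(lung_sigs, `[[`, "up")))
  lung_down <- unique(unlist(lapply(lung_sigs, `[[`, "down")))
  lung_all <- union(lung_up, lung_down)
  keep <- sox_genes %in% lung_all
  gene <- sox_genes[keep]
  dir_sox <- sox_dir[keep]
  dir_lung <- ifelse(gene %in% lung_up & gene %in% lung_down, "both",
              ifelse(gene %in% lung_up, "up", "down"))
  data.frame(gene = gene, direction_sox2 = dir_sox,
             direction_lung = dir_lung,
             concordant = dir_lung == "both" | dir_lung == dir_sox,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Literature-curated cancer gene panel
#'
#' A static 16-entry list of cancer-relevant genes selected from the
#' consolidated driver-response list on the basis of published
#' functional evidence. It is shipped as packaged data, is not
#' computed, and is excluded from all statistics.
#'
#' @return data.frame with symbol and comment columns (16 rows).
#' @export
cancer_gene_panel <- function() {
  path <- system.file("extdata", "cancer_gene_panel.tsv",
                      package = "ampliconmap", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
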