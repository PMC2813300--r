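#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked gene list accumulating a running sum that
#' increments by `|score|^weight / sum(|score in S|^weight)` at gene-set
#' hits and decrements by `1 / (N - |S|)` at misses; the enrichment
#' score (ES) is the signed maximum-magnitude deviation from zero.
#' `weight = 1` is the standard weighted statistic; `weight = 0` gives
#' the classic (unweighted) Kolmogorov-Smirnov variant.
#'
#' @param ranked A data.frame with `gene` and `score` columns ordered
#'   by decreasing score (as from [rank_genes_by_phenotype()]), or a
#'   named numeric vector in that order.
#' @param S Character vector of gene-set symbols.
#' @param weight Exponent on the score weights (default 1).
#' @return List of class `gsea_es`: `es`, `running` (length-N running
#'   sum), `hits` (positions of set members), `extremum` (position of
#'   the ES).
#' @export
gsea_es <- function(ranked, S, weight = 1) {
  rs <- as_ranked(ranked)
  S <- unique(toupper(S))
  hit <- names(rs) %in% S
  if (!any(hit)) stopf("gene set has no member in the ranked list")
  N <- length(rs)
  nh <- sum(hit)
  w <- abs(rs)^weight
  nr <- sum(w[hit])
  inc <- if (nr > 0) w / nr else rep(1 / nh, N)
  step <- ifelse(hit, inc, 0)
  if (N > nh) step[!hit] <- -1 / (N - nh)
  running <- cumsum(step)
  # earliest position within numerical tolerance of the max deviation,
  # so exact-rational ties (weight 0) resolve deterministically
  extremum <- which(abs(running) >= max(abs(running)) - 1e-12)[1L]
  structure(list(es = running[extremum], running = running,
                 hits = which(hit), extremum = extremum,
                 weight = weight),
            class = "gsea_es")
}

as_ranked <- function(ranked) {
  if (is.data.frame(ranked)) {
    rs <- ranked$score
    names(rs) <- toupper(ranked$gene)
  } else {
    rs <- ranked
    names(rs) <- toupper(names(rs))
  }
  rs
}

# O(|S|) enrichment score from sorted hit positions; agrees with
# gsea_es() and avoids materializing the running sum (used in
# permutation loops).
es_from_hits <- function(pos, absw, N) {
  k <- length(pos)
  w <- absw[pos]
  nr <- sum(w)
  p_cum <- if (nr > 0) cumsum(w) / nr else seq_len(k) / k
  miss_pen <- if (N > k) (pos - seq_len(k)) / (N - k) else numeric(k)
  tops <- p_cum - miss_pen
  bottoms <- c(0, p_cum[-k]) - miss_pen
  cand <- as.vector(rbind(bottoms, tops)) # positional order per hit
  cand[which(abs(cand) >= max(abs(cand)) - 1e-12)[1L]]
}

#' Leading-edge subset
#'
#' The members of a gene set at or before the running-sum extremum
#' (at or after it, for negative ES): the genes that drive the
#' enrichment signal.
#'
#' @inheritParams gsea_es
#' @param es Optional precomputed [gsea_es()] result for this ranked
#'   list and set.
#' @return Character vector of leading-edge genes (a subset of `S`),
#'   in rank order.
#' @export
leading_edge <- function(ranked, S, weight = 1, es = NULL) {
  rs <- as_ranked(ranked)
  if (is.null(es)) es <- gsea_es(rs, S, weight)
  pos <- es$hits
  keep <- if (es$es >= 0) pos[pos <= es$extremum] else pos[pos >= es$extremum]
  names(rs)[keep]
}

#' Gene-set enrichment analysis with permutation FDR
#'
#' Ranks all genes against the phenotype, computes the weighted KS
#' enrichment score of each gene set, and calibrates it by
#' permutation: the normalized enrichment score (NES) divides the ES
#' by the mean magnitude of same-sign permuted scores, the nominal
#' p-value is the same-sign permutation tail, and the FDR q-value
#' compares each observed NES with the pooled permuted NES
#' distribution (the standard multi-set procedure). With
#' `scheme = "auto"`, phenotype permutation is used when the
#' phenotype is two-class with at least 7 samples per class,
#' otherwise gene-set (random set) permutation; the scheme used is
#' recorded in the output.
#'
#' @param mat Genes-by-samples expression matrix.
#' @param phenotype Two-class labels or a continuous profile
#'   (see [rank_genes_by_phenotype()]).
#' @param sets Named list of gene sets (a single character vector is
#'   accepted and named `"set1"`).
#' @param n_perm Number of permutations (default 1000; fewer than 100
#'   draws a warning).
#' @param scheme `"auto"`, `"phenotype"` or `"geneset"`.
#' @param weight Score exponent (default 1).
#' @param seed Integer seed; results are reproducible bit-for-bit.
#' @param case Case label for two-class phenotypes.
#' @return data.frame of class `enrichment_result` with one row per
#'   set: set, size, es, nes, p, fdr, n_perm, scheme; leading-edge
#'   gene lists in attribute `"leading_edge"`.
#' @export
gsea <- function(mat, phenotype, sets, n_perm = 1000L,
                 scheme = c("auto", "phenotype", "geneset"),
                 weight = 1, seed = NULL, case = NULL) {
  scheme <- match.arg(scheme)
  if (!is.list(sets)) sets <- list(set1 = sets)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  if (n_perm < 100) warning("fewer than 100 permutations: unstable p and FDR")
  two_class <- !is.numeric(phenotype)
  if (scheme == "auto") {
    scheme <- if (two_class && min(table(phenotype)) >= 7) "phenotype"
              else "geneset"
  }
  if (scheme == "phenotype" && two_class && min(table(phenotype)) < 2) {
    stopf("phenotype permutation requires at least 2 samples per class")
  }
  ranked <- rank_genes_by_phenotype(mat, phenotype, case = case)
  rs <- as_ranked(ranked)
  N <- length(rs)
  sets <- lapply(sets, function(s) unique(toupper(s)))
  obs <- lapply(sets, function(s) gsea_es(rs, s, weight))
  es_obs <- vapply(obs, `[[`, 0, "es")
  sizes <- vapply(sets, function(s) sum(names(rs) %in% s), 0L)

  perm_es <- with_seed(seed, {
    if (scheme == "phenotype") {
      vapply(seq_len(n_perm), function(i) {
        ph <- sample(phenotype)
        prs <- as_ranked(rank_genes_by_phenotype(mat, ph, case = case))
        absw <- abs(prs)^weight
        vapply(names(sets), function(nm) {
          pos <- which(names(prs) %in% sets[[nm]])
          es_from_hits(pos, absw, N)
        }, 0)
      }, numeric(length(sets)))
    } else {
      absw <- abs(rs)^weight
      vapply(seq_len(n_perm), function(i) {
        vapply(sizes, function(k) {
          es_from_hits(sort(sample.int(N, k)), absw, N)
        }, 0)
      }, numeric(length(sets)))
    }
  })
  perm_es <- matrix(perm_es, nrow = length(sets),
                    dimnames = list(names(sets), NULL))

  nes <- p <- numeric(length(sets))
  nes_perm <- matrix(NA_real_, nrow = length(sets), ncol = n_perm)
  for (i in seq_along(sets)) {
    pe <- perm_es[i, ]
    pos_mean <- mean(pe[pe >= 0])
    neg_mean <- mean(abs(pe[pe < 0]))
    nes_perm[i, pe >= 0] <- pe[pe >= 0] / pos_mean
    nes_perm[i, pe < 0] <- pe[pe < 0] / neg_mean
    same <- if (es_obs[i] >= 0) pe[pe >= 0] else pe[pe < 0]
    if (length(same) == 0L) {
      p[i] <- 1 / (n_perm + 1)
      nes[i] <- es_obs[i] / mean(abs(pe))
    } else {
      p[i] <- sum(abs(same) >= abs(es_obs[i])) / length(same)
      nes[i] <- es_obs[i] / mean(abs(same))
    }
  }
  pool <- nes_perm[is.finite(nes_perm)]
  fdr <- vapply(seq_along(sets), function(i) {
    if (is.na(nes[i])) return(NA_real_)
    if (nes[i] >= 0) {
      num <- sum(pool >= nes[i]) / max(1, sum(pool >= 0))
      den <- sum(nes >= nes[i]) / max(1, sum(nes >= 0))
    } else {
      num <- sum(pool <= nes[i]) / max(1, sum(pool < 0))
      den <- sum(nes <= nes[i]) / max(1, sum(nes < 0))
    }
    min(1, num / max(den, .Machine$double.eps))
  }, 0)

  res <- data.frame(
    set = names(sets), size = as.integer(sizes), es = es_obs, nes = nes,
    p = p, fdr = fdr, n_perm = as.integer(n_perm), scheme = scheme,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(res, "leading_edge") <- lapply(seq_along(sets), function(i) {
    leading_edge(rs, sets[[i]], weight, es = obs[[i]])
  })
  names(attr(res, "leading_edge")) <- names(sets)
  class(res) <- c("enrichment_result", "data.frame")
  res
}
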