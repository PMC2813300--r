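#' Design of a synthetic tumor-vs-normal expression dataset
#'
#' Fixes the ground truth embedded by [make_expression_dataset()]:
#' directed differentially expressed genes (log2 effect +/-2), an
#' ESC-like co-activation module (+1.5 in tumors), a designated SOX2
#' gene (over-expressed in tumors), and a block of SOX2 target genes
#' generated as `coefficient x SOX2 expression + noise`, the
#' coefficient sign encoding activated (+) vs repressed (-) targets.
#' All blocks are disjoint by construction; supplying explicit lists
#' that assign one gene contradictory roles is an error.
#'
#' @param n_genes Size of the gene universe (default 2000).
#' @param n_tumors,n_normals Group sizes (default 20 and 10).
#' @param n_up,n_down Counts of embedded up/down DE genes (100 each).
#' @param de_effect Absolute DE effect in log2 units (default 2).
#' @param n_module Module size (default 50) and `module_effect` its
#'   tumor-activation effect (+1.5 log2).
#' @param module_effect See above.
#' @param sox2_effect Tumor effect on the SOX2 gene itself (log2).
#' @param n_act,n_rep Activated/repressed target-block sizes (60/30).
#' @param target_coef Absolute regression coefficient of targets on
#'   SOX2 (default 0.8); `target_noise_sd` the residual s.d. (0.5).
#' @param target_noise_sd See above.
#' @param baseline_mean,baseline_sd Baseline log2 expression (8, 1).
#' @return A list of class `expression_design` carrying explicit gene
#'   lists (`de_up`, `de_down`, `module_genes`, `sox2_gene`,
#'   `targets_activated`, `targets_repressed`).
#' @export
expression_design <- function(n_genes = 2000L, n_tumors = 20L, n_normals = 10L,
                              n_up = 100L, n_down = 100L, de_effect = 2,
                              n_module = 50L, module_effect = 1.5,
                              sox2_effect = 2,
                              n_act = 60L, n_rep = 30L, target_coef = 0.8,
                              target_noise_sd = 0.5,
                              baseline_mean = 8, baseline_sd = 1) {
  need <- n_up + n_down + n_module + 1L + n_act + n_rep
  if (n_genes < need) {
    stopf("gene universe (%d) smaller than the %d truth genes", n_genes, need)
  }
  genes <- sprintf("G%04d", seq_len(n_genes))
  de_up <- genes[seq_len(n_up)]
  de_down <- genes[n_up + seq_len(n_down)]
  module_genes <- genes[n_up + n_down + seq_len(n_module)]
  sox2_gene <- "SOX2"
  genes[n_up + n_down + n_module + 1L] <- sox2_gene
  targets_activated <- genes[n_up + n_down + n_module + 1L + seq_len(n_act)]
  targets_repressed <-
    genes[n_up + n_down + n_module + 1L + n_act + seq_len(n_rep)]
  blocks <- list(de_up, de_down, module_genes, sox2_gene,
                 targets_activated, targets_repressed)
  if (anyDuplicated(unlist(blocks))) {
    stopf("overlapping gene-role assignments with contradictory signs")
  }
  structure(list(
    genes = genes, n_tumors = as.integer(n_tumors),
    n_normals = as.integer(n_normals),
    de_up = de_up, de_down = de_down, de_effect = de_effect,
    module_genes = module_genes, module_effect = module_effect,
    sox2_gene = sox2_gene, sox2_effect = sox2_effect,
    targets_activated = targets_activated,
    targets_repressed = targets_repressed,
    target_coef = target_coef, target_noise_sd = target_noise_sd,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd
  ), class = "expression_design")
}

#' Simulate a tumor-vs-normal expression matrix with known truth
#'
#' Baseline log2 expression is Gaussian; embedded DE genes, the
#' co-activated module and SOX2 receive additive tumor effects;
#' target-block genes are linear responses to the SOX2 profile with
#' the designed coefficient sign, so they correlate with SOX2 with
#' that sign.
#'
#' @param design An [expression_design()].
#' @param seed Integer seed.
#' @return List with `matrix` (genes x samples, log2), `labels`
#'   (character, "tumor"/"normal") and `truth` (the design + seed).
#' @export
make_expression_dataset <- function(design = expression_design(), seed = 17L) {
  stopifnot(inherits(design, "expression_design"))
  d <- design
  n_s <- d$n_tumors + d$n_normals
  labels <- c(rep("tumor", d$n_tumors), rep("normal", d$n_normals))
  samples <- sprintf("%s%02d", ifelse(labels == "tumor", "T", "N"),
                     c(seq_len(d$n_tumors), seq_len(d$n_normals)))
  with_seed(seed, {
    m <- matrix(rnorm(length(d$genes) * n_s, d$baseline_mean, d$baseline_sd),
                nrow = length(d$genes),
                dimnames = list(d$genes, samples))
    tum <- labels == "tumor"
    m[d$de_up, tum] <- m[d$de_up, tum] + d$de_effect
    m[d$de_down, tum] <- m[d$de_down, tum] - d$de_effect
    m[d$module_genes, tum] <- m[d$module_genes, tum] + d$module_effect
    m[d$sox2_gene, tum] <- m[d$sox2_gene, tum] + d$sox2_effect
    sox2 <- m[d$sox2_gene, ]
    centered <- sox2 - mean(sox2)
    for (g in d$targets_activated) {
      m[g, ] <- d$baseline_mean + d$target_coef * centered +
        rnorm(n_s, sd = d$target_noise_sd)
    }
    for (g in d$targets_repressed) {
      m[g, ] <- d$baseline_mean - d$target_coef * centered +
        rnorm(n_s, sd = d$target_noise_sd)
    }
    list(matrix = m, labels = labels,
         truth = c(unclass(d), list(seed = seed)))
  })
}

#' Simulate an RT-qPCR fold-change input table
#'
#' Emulates a nine-gene panel (the genes of the 3q26.33 consensus
#' interval, in genomic order) measured across five tumors with
#' high-level 3q26.33 amplification, two tumors with low-level gains,
#' and two reference tumors without copy-number change. Designed fold
#' changes place SOX2 and SOX2OT above 5-fold in at least 4/5
#' amplified tumors, six further genes above 2-fold in at least 4/5,
#' and LAMP3 below 1; measurement noise is multiplicative
#' (log-normal, sd `noise_sd` log2 units).
#'
#' @param seed Integer seed.
#' @param noise_sd Log2-scale measurement noise s.d. (default 0.04).
#' @return List with `expr` (linear-scale genes x tumors matrix
#'   including the reference tumors), `reference_ids`, `amplified_ids`,
#'   `gained_ids` and `truth` (per-gene label: strong / recurrent /
#'   none).
#' @export
make_qpcr_fixture <- function(seed = 17L, noise_sd = 0.04) {
  genes <- c("FXR1", "DNAJC19", "B3GNT5", "MCCC1", "LAMP3",
             "SOX2OT", "SOX2", "ATP11B", "DCUN1D1")
  amplified <- c("T15", "T35", "T04", "T10", "T22")
  gained <- c("T07", "T41")
  refs <- c("R01", "R02")
  fold <- rbind(
    FXR1    = c(2.6, 3.1, 1.4, 2.8, 3.9, 1.5, 1.6),
    DNAJC19 = c(2.5, 2.9, 3.4, 1.3, 2.7, 1.4, 1.3),
    B3GNT5  = c(3.0, 2.6, 2.8, 3.3, 1.2, 1.6, 1.2),
    MCCC1   = c(1.4, 2.7, 3.2, 2.5, 3.8, 1.3, 1.5),
    LAMP3   = c(0.6, 0.8, 0.5, 0.9, 0.7, 0.8, 0.9),
    SOX2OT  = c(18, 45, 2.8, 7.2, 95, 4.0, 5.5),
    SOX2    = c(22, 60, 3.2, 9.1, 140, 4.5, 6.0),
    ATP11B  = c(2.9, 3.5, 2.6, 1.5, 4.2, 1.4, 1.7),
    DCUN1D1 = c(3.8, 2.7, 3.1, 2.9, 1.4, 1.5, 1.3)
  )
  colnames(fold) <- c(amplified, gained)
  with_seed(seed, {
    ref_expr <- matrix(2^rnorm(length(genes) * 2, mean = 5, sd = 0.2),
                       nrow = length(genes),
                       dimnames = list(genes, refs))
    geo <- 2^rowMeans(log2(ref_expr))
    tum_expr <- fold[genes, ] * geo *
      2^matrix(rnorm(length(fold), sd = noise_sd), nrow = nrow(fold))
    expr <- cbind(tum_expr, ref_expr)
    truth <- setNames(rep("recurrent", length(genes)), genes)
    truth[c("SOX2", "SOX2OT")] <- "strong"
    truth["LAMP3"] <- "none"
    list(expr = expr, reference_ids = refs, amplified_ids = amplified,
         gained_ids = gained, truth = truth, seed = seed)
  })
}

#' Simulate a 51-case immunohistochemistry score table
#'
#' Emulates a lung SCC cohort scored for SOX2 staining: by default 34
#' cases exceed the normal bronchial nuclear reference (H-score 90 =
#' intensity 3 in 30% of cells), 5 cases show strong exclusively
#' cytoplasmic staining, and the remaining 12 are normal-like. Case
#' order and the individual scores are drawn from the seed; the
#' category counts are fixed by the arguments.
#'
#' @param n_activated,n_cytoplasmic,n_other Category counts
#'   (defaults 34 / 5 / 12).
#' @param seed Integer seed.
#' @return List with `records` (a data.frame accepted by
#'   [score_case()]) and `truth` (per-case category label).
#' @export
make_ihc_fixture <- function(n_activated = 34L, n_cytoplasmic = 5L,
                             n_other = 12L, seed = 17L) {
  n <- n_activated + n_cytoplasmic + n_other
  with_seed(seed, {
    act <- data.frame(
      nuclear_intensity = sample(2:3, n_activated, replace = TRUE),
      cytoplasmic_intensity = sample(0:2, n_activated, replace = TRUE),
      pct_positive_nuclei = sample(seq(50, 95, by = 5), n_activated,
                                   replace = TRUE)
    )
    cyt <- data.frame(
      nuclear_intensity = 0L,
      cytoplasmic_intensity = 3L,
      pct_positive_nuclei = 0
    )[rep(1L, n_cytoplasmic), ]
    pool <- data.frame(
      nuclear_intensity = c(3L, 2L, 1L, 2L, 1L, 3L, 0L),
      pct_positive_nuclei = c(30, 40, 60, 25, 80, 20, 0)
    )
    oth_idx <- sample(nrow(pool), n_other, replace = TRUE)
    oth <- data.frame(
      nuclear_intensity = pool$nuclear_intensity[oth_idx],
      cytoplasmic_intensity = sample(0:2, n_other, replace = TRUE),
      pct_positive_nuclei = pool$pct_positive_nuclei[oth_idx]
    )
    records <- rbind(act, cyt[names(act)], oth[names(act)])
    label <- rep(c("activated", "cytoplasmic_only", "other"),
                 c(n_activated, n_cytoplasmic, n_other))
    ord <- sample(n)
    records <- records[ord, ]
    label <- label[ord]
    records <- cbind(case_id = sprintf("LSCC%02d", seq_len(n)), records)
    rownames(records) <- NULL
    list(records = records, truth = setNames(label, records$case_id),
         seed = seed)
  })
}

#' Component fixtures for curated target-list construction
#'
#' Deterministic gene lists whose intersection structure mirrors the
#' published curated SOX2 target list: 242 promoter-bound genes among
#' the up-regulated and 103 among the down-regulated, so that
#' [build_target_list()] returns a 345-gene list.
#'
#' @param n_up,n_down Differential list sizes (600/400).
#' @param n_bound_up,n_bound_down Bound genes inside each direction
#'   (242/103); `n_bound_only` bound genes outside the differential
#'   lists (300).
#' @param n_bound_only See above.
#' @param seed Integer seed (controls which symbols are drawn).
#' @return List with `bound` (character) and `differential`
#'   (data.frame gene/direction).
#' @export
make_target_components <- function(n_up = 600L, n_down = 400L,
                                   n_bound_up = 242L, n_bound_down = 103L,
                                   n_bound_only = 300L, seed = 17L) {
  genes <- sprintf("TG%04d", seq_len(n_up + n_down + n_bound_only))
  up <- genes[seq_len(n_up)]
  down <- genes[n_up + seq_len(n_down)]
  outside <- genes[n_up + n_down + seq_len(n_bound_only)]
  with_seed(seed, {
    bound <- c(sample(up, n_bound_up), sample(down, n_bound_down), outside)
    list(bound = sort(bound),
         differential = data.frame(
           gene = c(up, down),
           direction = rep(c("up", "down"), c(n_up, n_down)),
           stringsAsFactors = FALSE))
  })
}

#' Fixture for correlation-based target recovery
#'
#' Builds an expression matrix and a curated target list so that
#' exactly `n_corr_act` activated targets correlate positively with
#' the SOX2 profile and `n_corr_rep` repressed targets correlate
#' negatively (defaults 71 and 26, a 97-gene recovered list). The
#' non-correlated targets are residualized against the SOX2 profile,
#' making their sample correlation exactly zero.
#'
#' @param n_act,n_rep Target-list partition sizes (242/103).
#' @param n_corr_act,n_corr_rep Truly correlated counts (71/26).
#' @param n_samples Sample count (default 40).
#' @param seed Integer seed.
#' @return List with `matrix`, `targets` (a [target_list()]),
#'   `sox2_gene` and `truth` (the correlated gene names).
#' @export
make_correlated_targets_fixture <- function(n_act = 242L, n_rep = 103L,
                                            n_corr_act = 71L, n_corr_rep = 26L,
                                            n_samples = 40L, seed = 17L) {
  act_genes <- sprintf("AT%03d", seq_len(n_act))
  rep_genes <- sprintf("RT%03d", seq_len(n_rep))
  with_seed(seed, {
    z <- rnorm(n_samples)
    zc <- z - mean(z)
    orthogonal_noise <- function() {
      e <- rnorm(n_samples)
      ec <- e - mean(e)
      resid <- ec - sum(ec * zc) / sum(zc * zc) * zc
      resid
    }
    gene_row <- function(sign_coef, correlated) {
      if (correlated) {
        8 + sign_coef * (0.9 * zc + rnorm(n_samples, sd = 0.3))
      } else {
        8 + orthogonal_noise()
      }
    }
    m <- rbind(
      SOX2 = 8 + z,
      do.call(rbind, lapply(seq_len(n_act), function(i) {
        gene_row(+1, i <= n_corr_act)
      })),
      do.call(rbind, lapply(seq_len(n_rep), function(i) {
        gene_row(-1, i <= n_corr_rep)
      }))
    )
    rownames(m) <- c("SOX2", act_genes, rep_genes)
    colnames(m) <- sprintf("S%02d", seq_len(n_samples))
    list(matrix = m,
         targets = target_list(act_genes, rep_genes),
         sox2_gene = "SOX2",
         truth = list(correlated_activated = act_genes[seq_len(n_corr_act)],
                      anticorrelated_repressed = rep_genes[seq_len(n_corr_rep)]),
         seed = seed)
  })
}

#' Fixture for signature consolidation
#'
#' Deterministic signatures whose overlap structure yields a
#' consolidated list of exactly `n_overlap` genes (default 142): the
#' in-vitro SOX2-responsive signature shares 100 genes with the first
#' lung SCC signature and 62 with the second, 20 of them common to
#' both.
#'
#' @param n_overlap Consolidated list size (default 142).
#' @param seed Unused; kept for the uniform generator interface.
#' @return List with `sox2_squamous` (a [gene_signature()]) and
#'   `lung_sigs` (list of two [gene_signature()]s).
#' @export
make_consolidation_fixture <- function(n_overlap = 142L, seed = 17L) {
  genes <- sprintf("CG%04d", seq_len(2000L))
  sox2_members <- genes[seq_len(400L)]
  sox2 <- gene_signature(up = sox2_members[seq_len(250L)],
                         down = sox2_members[251:400])
  lung1_members <- c(sox2_members[seq_len(100L)], genes[1001:1300])
  lung2_members <- c(sox2_members[81:n_overlap], genes[1501:1700])
  lung1 <- gene_signature(up = lung1_members[seq_len(200L)],
                          down = lung1_members[201:length(lung1_members)])
  lung2 <- gene_signature(up = lung2_members[seq_len(130L)],
                          down = lung2_members[131:length(lung2_members)])
  list(sox2_squamous = sox2, lung_sigs = list(lung1, lung2))
}
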