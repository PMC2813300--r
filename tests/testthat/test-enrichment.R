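test_that("hypergeometric overlap matches exhaustive enumeration", {
  # fixed worked example: |U|=10, |A|=4, |B|=5, overlap 3 -> 66/252
  U <- paste0("g", 1:10)
  A <- U[1:4]
  B <- c(U[1:3], U[9:10])
  res <- hypergeometric_overlap(A, B, U)
  expect_equal(res$n_overlap, 3L)
  expect_equal(res$p_value, 66 / 252, tolerance = 1e-12)
  expect_equal(res$p_value, enum_overlap_p(toupper(U), toupper(A), 3, 5))

  # random instances over small universes
  for (i in 1:15) {
    set.seed(400 + i)
    u_size <- sample(6:12, 1)
    U <- paste0("x", seq_len(u_size))
    A <- sample(U, sample(1:u_size, 1))
    B <- sample(U, sample(1:u_size, 1))
    res <- hypergeometric_overlap(A, B, U)
    expect_equal(res$p_value,
                 enum_overlap_p(toupper(U), toupper(A), res$n_overlap,
                                length(B)),
                 tolerance = 1e-12)
  }
})

test_that("hypergeometric boundary cases and universe validation", {
  U <- paste0("g", 1:8)
  # B = universe: overlap is |A| and p = 1
  res <- hypergeometric_overlap(U[1:3], U, U)
  expect_equal(res$n_overlap, 3L)
  expect_equal(res$p_value, 1)
  # zero overlap: upper tail at 0 is 1
  res0 <- hypergeometric_overlap(U[1:3], U[4:6], U)
  expect_equal(res0$p_value, 1)
  expect_error(hypergeometric_overlap(c(U[1], "ZZZ"), U[1:2], U), "ZZZ")
})

test_that("target lists intersect bound promoters with directed genes", {
  tc <- make_target_components(seed = 17)
  tl <- build_target_list(tc$bound, tc$differential)
  expect_equal(length(tl$activated), 242L)
  expect_equal(length(tl$repressed), 103L)
  expect_equal(target_list_size(tl), 345L)
  expect_length(intersect(tl$activated, tl$repressed), 0L)

  # no overlap at all
  empty <- build_target_list(c("ZZ1", "ZZ2"), tc$differential)
  expect_equal(target_list_size(empty), 0L)

  # contradictory direction is an error
  bad <- data.frame(gene = c("A", "A"), direction = c("up", "down"))
  expect_error(build_target_list("A", bad), "both directions")
})

test_that("phenotype ranking: correlation mode, antisymmetry, flags", {
  set.seed(9)
  mat <- matrix(rnorm(8 * 12), 8, 12,
                dimnames = list(paste0("g", 1:8), NULL))
  profile <- mat[3, ]
  ranked <- rank_genes_by_phenotype(mat, profile)
  expect_identical(ranked$gene[1], "g3")
  expect_equal(ranked$score[1], 1)
  flipped <- rank_genes_by_phenotype(mat, -profile)
  expect_identical(flipped$gene, rev(ranked$gene))
  expect_equal(flipped$score, -rev(ranked$score))

  mat2 <- rbind(mat, flat = rep(5, 12))
  r2 <- rank_genes_by_phenotype(mat2, profile)
  expect_true("flat" %in% attr(r2, "flagged"))
  expect_equal(r2$score[r2$gene == "flat"], 0)
  expect_error(rank_genes_by_phenotype(mat, rep(1, 12)), "zero variance")
})

test_that("two-class ranking is the signal-to-noise ratio", {
  mat <- rbind(g1 = c(4, 5, 6, 1, 2, 3), g2 = c(1, 1, 2, 4, 4, 6))
  labels <- rep(c("tumor", "normal"), each = 3)
  ranked <- rank_genes_by_phenotype(mat, labels)
  s2n <- function(v) {
    (mean(v[1:3]) - mean(v[4:6])) / (sd(v[1:3]) + sd(v[4:6]))
  }
  expect_equal(ranked$score[ranked$gene == "g1"], s2n(mat["g1", ]))
  expect_equal(ranked$score[ranked$gene == "g2"], s2n(mat["g2", ]))
  expect_identical(ranked$gene, c("g1", "g2"))
})

test_that("enrichment score matches hand-computed extremes", {
  rs <- setNames(c(3, 2, 1, 0.5), paste0("g", 1:4))
  # single hit at the top, unweighted: running +1 then -1/3 steps
  top <- gsea_es(rs, "g1", weight = 0)
  expect_equal(top$es, 1)
  expect_equal(top$running, c(1, 2 / 3, 1 / 3, 0))
  bottom <- gsea_es(rs, "g4", weight = 0)
  expect_equal(bottom$es, -1)
  # the whole list as the set: all increments
  whole <- gsea_es(rs, paste0("g", 1:4))
  expect_equal(whole$es, 1)
  expect_error(gsea_es(rs, "absent"), "no member")
})

test_that("enrichment score equals brute force on 1000 random instances", {
  worst <- 0
  for (i in 1:1000) {
    set.seed(i)
    N <- sample(5:50, 1)
    scores <- sort(rnorm(N, sd = 2), decreasing = TRUE)
    names(scores) <- paste0("g", seq_len(N))
    k <- sample(1:(N - 1), 1)
    S <- sample(names(scores), k)
    w <- sample(c(0, 1), 1)
    es <- gsea_es(scores, S, weight = w)
    ref <- brute_es(scores, toupper(names(scores)) %in% toupper(S), w)
    worst <- max(worst, abs(abs(es$es) - abs(ref)))
    # the sign is determined unless the extreme deviations tie exactly
    if (abs(max(es$running) - max(-es$running)) > 1e-9) {
      expect_equal(es$es, ref, tolerance = 1e-12)
    }
    expect_true(abs(es$es) <= 1 + 1e-12)
    # fast permutation path agrees with the running-sum definition
    fast <- ampliconmap:::es_from_hits(sort(es$hits), abs(scores)^w, N)
    expect_equal(fast, es$es, tolerance = 1e-12)
  }
  expect_lt(worst, 1e-12)
})

test_that("reversing the ranked list negates the unweighted ES", {
  for (i in 1:20) {
    set.seed(600 + i)
    N <- 30
    scores <- sort(rnorm(N), decreasing = TRUE)
    names(scores) <- paste0("g", 1:N)
    S <- sample(names(scores), 6)
    fwd <- gsea_es(scores, S, weight = 0)
    es_rev <- gsea_es(rev(scores), S, weight = 0)$es
    expect_equal(abs(es_rev), abs(fwd$es), tolerance = 1e-12)
    if (abs(max(fwd$running) - max(-fwd$running)) > 1e-9) {
      expect_equal(es_rev, -fwd$es, tolerance = 1e-12)
    }
  }
})

test_that("leading edge is the set prefix up to the extremum", {
  rs <- setNames(c(3, 2, 1, 0.5), paste0("g", 1:4))
  expect_identical(leading_edge(rs, "g1"), "G1")
  for (i in 1:10) {
    set.seed(700 + i)
    scores <- sort(rnorm(25), decreasing = TRUE)
    names(scores) <- paste0("g", 1:25)
    S <- sample(names(scores), 7)
    le <- leading_edge(scores, S)
    expect_true(all(le %in% toupper(S)))
  }
})

test_that("gsea flags the embedded module and is seed-reproducible", {
  ex <- make_expression_dataset(seed = 17)
  sets <- list(esc_module = ex$truth$module_genes,
               random = sample(rownames(ex$matrix), 50))
  r1 <- gsea(ex$matrix, ex$labels, sets, n_perm = 500, seed = 99)
  r2 <- gsea(ex$matrix, ex$labels, sets, n_perm = 500, seed = 99)
  expect_identical(r1, r2)
  mod <- r1[r1$set == "esc_module", ]
  expect_gt(mod$nes, 0)
  expect_lt(mod$fdr, 0.05)
  expect_identical(mod$scheme, "phenotype") # 20 and 10 per class
  # leading edge of the module captures most embedded members
  le <- attr(r1, "leading_edge")$esc_module
  expect_gte(mean(ex$truth$module_genes %in% le), 0.8)
})

test_that("gsea warns on tiny permutation counts and validates classes", {
  ex <- make_expression_dataset(
    design = expression_design(n_genes = 300, n_tumors = 5, n_normals = 5,
                               n_up = 20, n_down = 20, n_module = 20,
                               n_act = 10, n_rep = 5), seed = 1)
  expect_warning(
    gsea(ex$matrix, ex$labels, list(s = ex$truth$module_genes),
         n_perm = 50, seed = 1),
    "100 permutations")
  # small classes fall back to gene-set permutation under auto
  res <- gsea(ex$matrix, ex$labels, list(s = ex$truth$module_genes),
              n_perm = 200, seed = 1)
  expect_identical(res$scheme, "geneset")
})

test_that("correlated target recovery matches the embedded partition", {
  fx <- make_correlated_targets_fixture(seed = 17)
  ct <- correlated_target_lists(fx$matrix, fx$sox2_gene, fx$targets)
  expect_setequal(ct$activated, fx$truth$correlated_activated)
  expect_setequal(ct$repressed, fx$truth$anticorrelated_repressed)
  expect_equal(target_list_size(ct), 97L)

  expect_equal(target_list_size(
    correlated_target_lists(fx$matrix, fx$sox2_gene,
                            target_list(character(0), character(0)))), 0L)
  expect_error(correlated_target_lists(fx$matrix, "NOPE", fx$targets),
               "absent")
})

test_that("target block genes from the synthetic dataset are recovered", {
  ex <- make_expression_dataset(seed = 17)
  targets <- target_list(ex$truth$targets_activated,
                         ex$truth$targets_repressed)
  ct <- correlated_target_lists(ex$matrix, ex$truth$sox2_gene, targets)
  expect_gte(mean(ex$truth$targets_activated %in% ct$activated), 0.9)
  expect_gte(mean(ex$truth$targets_repressed %in% ct$repressed), 0.9)
  # ranking by the SOX2 profile concentrates activated targets on top
  ranked <- rank_genes_by_phenotype(ex$matrix, ex$matrix["SOX2", ])
  top150 <- ranked$gene[2:151] # skip SOX2 itself at rank 1
  expect_gte(mean(ex$truth$targets_activated %in% top150), 0.8)
})

test_that("signature consolidation returns the shared genes only", {
  fx <- make_consolidation_fixture()
  cons <- consolidate_signatures(fx$sox2_squamous, fx$lung_sigs)
  expect_equal(nrow(cons), 142L)
  expect_true(all(cons$gene %in% signature_members(fx$sox2_squamous)))

  empty <- consolidate_signatures(gene_signature(character(0), character(0)),
                                  fx$lung_sigs)
  expect_equal(nrow(empty), 0L)
  expect_error(consolidate_signatures(fx$sox2_squamous, list()),
               "at least one")
})

test_that("enrichment statistic agrees with an established implementation", {
  skip_if_not_installed("fgsea")
  for (i in 1:25) {
    set.seed(800 + i)
    N <- 40
    scores <- sort(rnorm(N, sd = 1.5), decreasing = TRUE)
    names(scores) <- paste0("g", 1:N)
    S <- sample(names(scores), 8)
    mine <- gsea_es(scores, S, weight = 1)$es
    ref <- fgsea::calcGseaStat(scores, selectedStats = which(names(scores) %in% S),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("the curated cancer gene panel is static with 16 entries", {
  panel <- cancer_gene_panel()
  expect_equal(nrow(panel), 16L)
  expect_true(all(c("RIT1", "CASP1", "TNFSF10") %in% panel$symbol))
})
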