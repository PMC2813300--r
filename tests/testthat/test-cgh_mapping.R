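test_that("clone states follow the threshold contract", {
  thr <- call_thresholds(amp_min = 1.0)
  vals <- c(a = 1.2, b = 0.0, c = -0.3, d = 0.5, e = NA, f = 1.0)
  st <- call_clone_states(vals, thr)
  expect_identical(unname(st),
                   c("amp", "neutral", "loss", "gain", "missing", "gain"))
  # the whole-genome preset reclassifies a 1.2 ratio as gain
  st2 <- call_clone_states(1.2, call_thresholds(amp_min = 1.5))
  expect_identical(unname(st2), "gain")
  expect_error(call_thresholds(loss_max = 0.1), "loss_max")
})

test_that("aberration frequency matches a brute-force enumeration", {
  thr <- call_thresholds()
  for (i in 1:8) {
    set.seed(100 + i)
    n_cl <- sample(5:20, 1)
    n_tum <- sample(2:5, 1)
    vals <- matrix(rnorm(n_cl * n_tum, sd = 0.6), n_cl, n_tum)
    vals[sample(length(vals), floor(length(vals) / 10))] <- NA
    cohort <- toy_cohort(vals)
    got <- aberration_frequency(cohort, bin_size = 3e5, thresholds = thr)
    want <- brute_bin_freq(cohort, 3e5, thr)
    expect_equal(got$loss_freq, want$loss_freq)
    expect_equal(got$gain_freq, want$gain_freq)
    expect_equal(got$n_informative, want$n_informative)
  }
})

test_that("frequency semantics: tumor-level counts, missing bins, bounds", {
  cm <- toy_clone_map(2)
  vals <- matrix(c(-0.5, NA, 0.1, NA), nrow = 2,
                 dimnames = list(names(cm), c("T1", "T2")))
  cohort <- cgh_cohort(cm, vals)
  fm <- aberration_frequency(cohort, bin_size = 1e5)
  # first bin holds clone 1: one lost tumor of two informative
  expect_equal(fm$loss_freq[1], 0.5)
  # second clone sits at 2e5; the bin at [1e5, 2e5) has no clone
  expect_true(is.na(fm$loss_freq[2]))
  # clone 2 missing in both tumors -> reported missing, not zero
  bin3 <- which(fm$start == 2e5)
  expect_equal(fm$n_informative[bin3], 0L)
  expect_true(is.na(fm$loss_freq[bin3]))
  expect_error(aberration_frequency(cohort, bin_size = 0), "bin_size")
})

test_that("frequencies never exceed [0,1] and fall as thresholds rise", {
  for (i in 1:10) {
    set.seed(i)
    vals <- matrix(rnorm(60, sd = 1), 12, 5)
    cohort <- toy_cohort(vals, toy_clone_map(12))
    f1 <- amplification_frequency(cohort, call_thresholds(amp_min = 0.8))
    f2 <- amplification_frequency(cohort, call_thresholds(amp_min = 1.3))
    expect_true(all(f1$freq >= 0 & f1$freq <= 1, na.rm = TRUE))
    expect_true(all(f2$freq <= f1$freq, na.rm = TRUE))
    fm1 <- aberration_frequency(cohort, 4e5, call_thresholds(loss_max = -0.25))
    fm2 <- aberration_frequency(cohort, 4e5, call_thresholds(loss_max = -0.6))
    expect_true(all(fm2$loss_freq <= fm1$loss_freq, na.rm = TRUE))
  }
})

test_that("synthetic cohort loss frequency at 8-10 Mb matches the truth", {
  out <- make_cgh_cohort(seed = 17)
  fm <- aberration_frequency(out$cohort, bin_size = 2e6)
  bin <- which(fm$start == 8e6)
  expect_equal(fm$n_loss[bin], length(out$truth$loss_tumors))
  expect_equal(fm$loss_freq[bin], 16 / 26, tolerance = 0.08)
})

test_that("single amplified tumor yields frequency 1 at that clone only", {
  cm <- toy_clone_map(4)
  vals <- matrix(c(0, 2, 0, 0), 4, 1, dimnames = list(names(cm), "T1"))
  f <- amplification_frequency(cgh_cohort(cm, vals))
  expect_equal(f$freq, c(0, 1, 0, 0))
})

test_that("amplicons are maximal runs with optional gap merging", {
  cm <- GenomicRanges::GRanges("chr3",
                               IRanges::IRanges(c(1, 1001, 2001, 3001),
                                                c(1000, 2000, 3000, 4000)))
  names(cm) <- paste0("K", 1:4)
  vals <- matrix(c(0.1, 1.4, 1.6, 0.2), 4, 1,
                 dimnames = list(names(cm), "T1"))
  segs <- extract_amplicons(cgh_cohort(cm, vals))
  expect_length(segs, 1L)
  expect_equal(GenomicRanges::start(segs), 1001)
  expect_equal(GenomicRanges::end(segs), 3000)
  expect_equal(S4Vectors::mcols(segs)$n_clones, 2L)
  expect_equal(S4Vectors::mcols(segs)$peak_log2, 1.6)

  # interrupted run: split at gap 0, merged at gap 1
  vals2 <- matrix(c(1.4, 0.2, 1.6, 0.1), 4, 1,
                  dimnames = list(names(cm), "T1"))
  co2 <- cgh_cohort(cm, vals2)
  expect_length(extract_amplicons(co2), 2L)
  merged <- extract_amplicons(co2, max_gap_clones = 1)
  expect_length(merged, 1L)
  expect_equal(GenomicRanges::end(merged), 3000)

  # nothing above threshold -> empty
  vals3 <- matrix(rep(0.3, 4), 4, 1, dimnames = list(names(cm), "T1"))
  expect_length(extract_amplicons(cgh_cohort(cm, vals3)), 0L)
})

test_that("boundary recovery stays within one clone spacing (100 replicates)", {
  spacing <- 100e3
  worst <- 0
  for (i in 1:100) {
    set.seed(2000 + i)
    b0 <- 177e6 + runif(1, 0.5e6, 4e6)
    b1 <- b0 + runif(1, 1.5e6, 4e6)
    out <- make_tiling_cohort(boundaries_by_tumor = list(T1 = c(b0, b1)),
                              clone_spacing = spacing, noise_sd = 0.2,
                              amp_log2 = 2.2, seed = 2000 + i)
    segs <- extract_amplicons(out$cohort)
    expect_gte(length(segs), 1L)
    main <- segs[which.max(GenomicRanges::width(segs))]
    err <- max(abs(GenomicRanges::start(main) - 1 - b0),
               abs(GenomicRanges::end(main) - b1))
    worst <- max(worst, err)
  }
  expect_lte(worst, spacing)
})

test_that("consensus region is the strict interval intersection", {
  segs <- GenomicRanges::GRanges(
    "chr3",
    IRanges::IRanges(c(181.0e6, 181.9e6, 180.5e6) + 1,
                     c(185.0e6, 184.6e6, 186.0e6)),
    tumor_id = c("A", "B", "C"))
  cr <- consensus_region(segs)
  expect_equal(cr$start - 1, 181.9e6)
  expect_equal(cr$end, 184.6e6)
  expect_equal(cr$support, 3L)
  expect_setequal(cr$supporting_tumor_ids, c("A", "B", "C"))

  # single tumor: consensus is its own segment
  one <- segs[1]
  cr1 <- consensus_region(one)
  expect_equal(cr1$start, GenomicRanges::start(one))
  expect_equal(cr1$end, GenomicRanges::end(one))

  expect_error(consensus_region(list()), "no amplicons")
})

test_that("disjoint amplicons fall back to the maximal-support region", {
  segs <- GenomicRanges::GRanges(
    "chr3", IRanges::IRanges(c(1e6, 1.5e6, 10e6) + 1, c(2e6, 2.5e6, 11e6)),
    tumor_id = c("A", "B", "C"))
  cr <- consensus_region(segs)
  expect_equal(cr$support, 2L)
  expect_equal(cr$start - 1, 1.5e6)
  expect_equal(cr$end, 2e6)
  expect_setequal(cr$supporting_tumor_ids, c("A", "B"))
})

test_that("consensus is contained in every supporting segment", {
  for (i in 1:25) {
    set.seed(300 + i)
    n_tum <- sample(2:5, 1)
    segs <- do.call(c, lapply(seq_len(n_tum), function(t) {
      s <- sort(runif(2, 0, 9e6))
      GenomicRanges::GRanges("chr3", IRanges::IRanges(s[1] + 1, s[2] + 1e5),
                             tumor_id = paste0("T", t))
    }))
    cr <- consensus_region(segs)
    widths <- numeric(0)
    for (tid in cr$supporting_tumor_ids) {
      gr <- segs[S4Vectors::mcols(segs)$tumor_id == tid]
      contained <- any(GenomicRanges::start(gr) <= cr$start &
                         GenomicRanges::end(gr) >= cr$end)
      expect_true(contained)
      widths <- c(widths, GenomicRanges::width(gr))
    }
    expect_lte(cr$width_bp, min(widths))
  }
})

test_that("gene queries respect half-open boundaries and flanks", {
  anno <- read_gene_annotation(
    system.file("extdata", "genes_3q26_synthetic.bed",
                package = "ampliconmap"))
  inside <- genes_in_region(c(181.9e6, 184.6e6), anno)
  expect_equal(nrow(inside), 9L)
  expect_true(all(c("SOX2", "SOX2OT", "DCUN1D1", "LAMP3", "ATP11B",
                    "DNAJC19", "B3GNT5", "FXR1") %in% inside$gene))
  # stable positional order
  expect_identical(inside$gene, inside$gene[order(inside$start)])

  # empty annotation
  expect_equal(nrow(genes_in_region(c(0, 1e6), GenomicRanges::GRanges())), 0L)

  # gene abutting the region end is excluded (half-open)
  gr <- GenomicRanges::GRanges("chr3", IRanges::IRanges(1001, 2000))
  names(gr) <- "EDGE"
  expect_equal(nrow(genes_in_region(c(0, 1000), gr)), 0L)
  expect_equal(nrow(genes_in_region(c(0, 1001), gr)), 1L)

  # flank widens the query
  expect_equal(nrow(genes_in_region(c(0, 1000), gr, flank = 1)), 1L)
})
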