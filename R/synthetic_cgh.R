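#' Default chromosome-3 clone map
#'
#' A synthetic 214-clone chromosome-3 array layout: clones of 150 kb
#' evenly tiled along a 199.4 Mb chromosome, emulating a dedicated
#' BAC array. The clone covering position 183.0 Mb (between SOX2 and
#' DCUN1D1 at 3q26.33) is named `RP11-259I19` so the peak of the
#' amplification frequency map carries the conventional probe name.
#'
#' @param n_clones Number of clones (default 214).
#' @param chrom_length Chromosome length in bp (default 199.4e6).
#' @param clone_width Clone insert size in bp (default 150e3).
#' @return A `GRanges` clone map.
#' @export
chr3_clone_map <- function(n_clones = 214L, chrom_length = 199.4e6,
                           clone_width = 150e3) {
  starts0 <- floor(seq(0, chrom_length - clone_width, length.out = n_clones))
  gr <- GRanges("chr3", IRanges(starts0 + 1, starts0 + clone_width))
  names(gr) <- sprintf("CL%03d", seq_len(n_clones))
  peak <- which(starts0 <= 183.0e6 & starts0 + clone_width > 183.0e6)[1L]
  if (!is.na(peak)) names(gr)[peak] <- "RP11-259I19"
  gr
}

#' Design of a synthetic aCGH cohort
#'
#' Encodes the ground-truth copy-number architecture embedded by
#' [make_cgh_cohort()]: a focal 3q26.33 amplicon (mean log2 ratio >= 2
#' so calls at the log2 > 1 amplification threshold are unambiguous),
#' a broad 3q26-qter single-copy gain, and a 3p loss around 8-10 Mb.
#' Carrier *counts* are fixed by the design (5 focal amplicons and 11
#' broad gains among 26 tumors; loss in ~60% of tumors); which tumors
#' carry which lesion is drawn from the generator seed.
#'
#' @param amp,gain,loss Lists with chrom, start, end (bp), mean_log2
#'   and n_carriers describing each embedded lesion.
#' @param noise_sd Gaussian clone-level noise s.d. in log2 units.
#' @return A list of class `cgh_design`.
#' @export
cgh_design <- function(
    amp = list(chrom = "chr3", start = 181.5e6, end = 184.8e6,
               mean_log2 = 2.2, n_carriers = 5L),
    gain = list(chrom = "chr3", start = 176e6, end = 199.4e6,
                mean_log2 = 0.45, n_carriers = 11L),
    loss = list(chrom = "chr3", start = 7.5e6, end = 10.5e6,
                mean_log2 = -0.8, n_carriers = 16L),
    noise_sd = 0.1) {
  if (!is_number(noise_sd) || noise_sd <= 0) stopf("noise_sd must be > 0")
  if (amp$mean_log2 < 2) stopf("amp segments must have mean log2 >= 2")
  if (gain$mean_log2 <= 0.3 || gain$mean_log2 >= 0.6) {
    stopf("gain segment mean log2 must lie in (0.3, 0.6)")
  }
  if (loss$mean_log2 > -0.4) stopf("loss segment mean log2 must be <= -0.4")
  structure(list(amp = amp, gain = gain, loss = loss, noise_sd = noise_sd),
            class = "cgh_design")
}

#' Simulate an array-CGH tumor cohort with known truth
#'
#' Generates per-tumor log2-ratio profiles over `clone_map`: each
#' clone's value is the sum of the mean log2 ratios of the embedded
#' segments overlapping it, plus Gaussian noise. The default design
#' emulates a 26-tumor advanced lung squamous cell carcinoma cohort:
#' 5 tumors carry a focal 3q26.33 amplicon containing the
#' 181.9-184.6 Mb interval, 11 further tumors carry a broad 3q26-qter
#' gain, and 16 of 26 (~60%) carry a 3p loss at 8-10 Mb.
#'
#' @param n_tumors Cohort size (default 26).
#' @param clone_map A `GRanges` clone map (default [chr3_clone_map()]).
#' @param design A [cgh_design()].
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A list with elements `cohort` (a [cgh_cohort()]) and
#'   `truth` (segments per tumor, carrier ids, noise_sd, seed).
#' @export
make_cgh_cohort <- function(n_tumors = 26L, clone_map = chr3_clone_map(),
                            design = cgh_design(), seed = 17L) {
  stopifnot(is_count(n_tumors), n_tumors >= 1, length(clone_map) > 0)
  span_chroms <- unique(as.character(GenomicRanges::seqnames(clone_map)))
  for (seg in design[c("amp", "gain", "loss")]) {
    if (!seg$chrom %in% span_chroms ||
        seg$end > max(GenomicRanges::end(clone_map)) + 1 ||
        seg$start < 0) {
      stopf("design segment %s:%g-%g lies outside the clone map span",
            seg$chrom, seg$start, seg$end)
    }
  }
  n_amp <- min(design$amp$n_carriers, n_tumors)
  n_gain <- min(design$gain$n_carriers, max(0L, n_tumors - n_amp))
  n_loss <- min(design$loss$n_carriers, n_tumors)
  tumor_ids <- sprintf("T%02d", seq_len(n_tumors))
  with_seed(seed, {
    ord <- sample(n_tumors)
    amp_t <- sort(tumor_ids[ord[seq_len(n_amp)]])
    gain_t <- sort(tumor_ids[ord[n_amp + seq_len(n_gain)]])
    loss_t <- sort(tumor_ids[sample(n_tumors, n_loss)])
    m <- matrix(rnorm(length(clone_map) * n_tumors, sd = design$noise_sd),
                nrow = length(clone_map), ncol = n_tumors,
                dimnames = list(names(clone_map), tumor_ids))
    seg_rows <- list()
    add_seg <- function(tumors, seg, state) {
      if (!length(tumors)) return()
      gr <- GRanges(seg$chrom, IRanges(seg$start + 1, seg$end))
      hit <- unique(subjectHits(findOverlaps(gr, clone_map)))
      m[hit, tumors] <<- m[hit, tumors] + seg$mean_log2
      seg_rows[[state]] <<- data.frame(
        tumor_id = tumors, chrom = seg$chrom, start = seg$start,
        end = seg$end, state = state, mean_log2 = seg$mean_log2,
        stringsAsFactors = FALSE)
    }
    add_seg(amp_t, design$amp, "amp")
    add_seg(gain_t, design$gain, "gain")
    add_seg(loss_t, design$loss, "loss")
    truth <- list(
      segments = do.call(rbind, c(unname(seg_rows),
                                  list(make.row.names = FALSE))),
      amp_tumors = amp_t, gain_tumors = gain_t, loss_tumors = loss_t,
      noise_sd = design$noise_sd, seed = seed
    )
    list(cohort = cgh_cohort(clone_map, m), truth = truth)
  })
}

#' Default amplicon boundaries of the five-tumor tiling fixture
#'
#' Five per-tumor amplified intervals on 3q26.3-3q27, each containing
#' the 181.9-184.6 Mb interval with differing outer limits; their
#' intersection is exactly that 2.7 Mb consensus.
#'
#' @return Named list of `c(start, end)` pairs in bp.
#' @export
tiling_default_boundaries <- function() {
  list(
    T15 = c(181.9e6, 185.5e6),
    T35 = c(180.2e6, 184.6e6),
    T04 = c(181.0e6, 185.0e6),
    T10 = c(181.5e6, 186.0e6),
    T22 = c(180.5e6, 184.8e6)
  )
}

#' Simulate tiling-array profiles with known amplicon boundaries
#'
#' Emulates a high-resolution tiling array spanning 177-186 Mb of
#' chromosome 3: abutting clones of `clone_spacing` bp, with every
#' clone whose midpoint falls inside a tumor's amplicon interval
#' raised to `amp_log2`, plus Gaussian noise. With the default
#' boundaries (multiples of the clone spacing) amplicon boundary
#' recovery by [extract_amplicons()] is exact.
#'
#' @param boundaries_by_tumor Named list of `c(start, end)` bp pairs
#'   (default [tiling_default_boundaries()]).
#' @param clone_spacing Clone size/spacing in bp (default 50e3).
#' @param span `c(start, end)` of the tiled region in bp.
#' @param amp_log2 Mean log2 ratio inside amplicons (default 2.2).
#' @param noise_sd Gaussian noise s.d. (default 0.1).
#' @param seed Integer seed.
#' @return A list with `cohort` (a [cgh_cohort()]) and `truth`
#'   (boundaries, spacing, amp_log2, noise_sd, seed).
#' @export
make_tiling_cohort <- function(boundaries_by_tumor = tiling_default_boundaries(),
                               clone_spacing = 50e3,
                               span = c(177e6, 186e6),
                               amp_log2 = 2.2, noise_sd = 0.1, seed = 17L) {
  if (!is_number(clone_spacing) || clone_spacing <= 0) {
    stopf("clone_spacing must be > 0")
  }
  for (nm in names(boundaries_by_tumor)) {
    b <- boundaries_by_tumor[[nm]]
    if (b[1L] >= b[2L] || b[1L] < span[1L] || b[2L] > span[2L]) {
      stopf("interval for %s lies outside the %g-%g Mb tiling span",
            nm, span[1L] / 1e6, span[2L] / 1e6)
    }
  }
  starts0 <- seq(span[1L], span[2L] - clone_spacing, by = clone_spacing)
  clones <- GRanges("chr3", IRanges(starts0 + 1, starts0 + clone_spacing))
  names(clones) <- sprintf("TIL%04d", seq_along(clones))
  mid <- starts0 + clone_spacing / 2
  tumor_ids <- names(boundaries_by_tumor)
  with_seed(seed, {
    m <- matrix(rnorm(length(clones) * length(tumor_ids), sd = noise_sd),
                nrow = length(clones),
                dimnames = list(names(clones), tumor_ids))
    for (nm in tumor_ids) {
      b <- boundaries_by_tumor[[nm]]
      inside <- mid >= b[1L] & mid < b[2L]
      m[inside, nm] <- m[inside, nm] + amp_log2
    }
    truth <- list(boundaries = boundaries_by_tumor,
                  clone_spacing = clone_spacing, span = span,
                  amp_log2 = amp_log2, noise_sd = noise_sd, seed = seed)
    list(cohort = cgh_cohort(clones, m), truth = truth)
  })
}
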