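# Independent oracles used to validate the analytical implementations.

# Exhaustive hypergeometric upper tail: enumerate every |B|-subset of
# the universe and count those overlapping A in at least k genes.
enum_overlap_p <- function(universe, A, k, b_size) {
  draws <- utils::combn(universe, b_size, simplify = FALSE)
  hits <- vapply(draws, function(d) length(intersect(d, A)) >= k, TRUE)
  mean(hits)
}

# Brute-force weighted KS running sum, written as an explicit walk.
brute_es <- function(scores, is_hit, weight) {
  N <- length(scores)
  nh <- sum(is_hit)
  nr <- sum(abs(scores[is_hit])^weight)
  running <- numeric(N)
  acc <- 0
  for (i in seq_len(N)) {
    if (is_hit[i]) {
      acc <- acc + if (nr > 0) abs(scores[i])^weight / nr else 1 / nh
    } else {
      acc <- acc - 1 / (N - nh)
    }
    running[i] <- acc
  }
  running[which.max(abs(running))]
}

# Brute-force per-bin aberration frequency: nested loops over bins,
# tumors and clones, 0-based half-open bins.
brute_bin_freq <- function(cohort, bin_size, thresholds) {
  clones <- cohort$clones
  chrom <- as.character(GenomicRanges::seqnames(clones))
  cl_start0 <- GenomicRanges::start(clones) - 1
  cl_end <- GenomicRanges::end(clones)
  states <- call_clone_states(cohort$log2, thresholds)
  rows <- list()
  for (ch in unique(chrom)) {
    span_end <- max(cl_end[chrom == ch])
    bin_starts <- seq(0, span_end - 1, by = bin_size)
    for (bs in bin_starts) {
      be <- min(bs + bin_size, span_end)
      in_bin <- which(chrom == ch & cl_start0 < be & cl_end > bs)
      n_inf <- n_loss <- n_gain <- 0
      for (t in seq_len(ncol(states))) {
        st <- states[in_bin, t]
        if (any(st != "missing")) {
          n_inf <- n_inf + 1
          if (any(st == "loss")) n_loss <- n_loss + 1
          if (any(st %in% c("gain", "amp"))) n_gain <- n_gain + 1
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, start = bs, end = be,
        n_informative = n_inf, n_loss = n_loss, n_gain = n_gain,
        loss_freq = if (n_inf > 0) n_loss / n_inf else NA_real_,
        gain_freq = if (n_inf > 0) n_gain / n_inf else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# A small clone map for hand-constructed cohorts.
toy_clone_map <- function(n = 10, chrom = "chr3", width = 1e5, gap = 1e5) {
  starts0 <- (seq_len(n) - 1) * (width + gap)
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(starts0 + 1, starts0 + width))
  names(gr) <- sprintf("C%02d", seq_len(n))
  gr
}

toy_cohort <- function(values, clone_map = toy_clone_map(nrow(values))) {
  if (is.null(rownames(values))) rownames(values) <- names(clone_map)
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("T%02d", seq_len(ncol(values)))
  }
  cgh_cohort(clone_map, values)
}
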