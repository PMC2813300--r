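#' Read a clone/probe map from a BED-like file
#'
#' Clone maps describe the genomic probes (e.g. BAC clones) of an
#' array-CGH platform. The on-disk format is 4+ column tab-delimited
#' BED (chrom, start, end, name) with 0-based half-open coordinates;
#' in memory the map is a [GenomicRanges::GRanges] (1-based closed,
#' the Bioconductor convention) whose names are the clone identifiers.
#' Entries are returned sorted by (chrom, start).
#'
#' @param path Path to a BED-like text file.
#' @return A `GRanges` with clone identifiers as names.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr3\t181900000\t184600000\tRP11-259I19", bed)
#' cm <- read_clone_map(bed)
#' GenomicRanges::width(cm) # 2.7 Mb
#' @export
read_clone_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(GRanges())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 4L)
  if (length(bad)) {
    stopf("malformed BED line %d in '%s': fewer than 4 tab-separated fields",
          bad[1L], path)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  name <- vapply(fields, `[[`, "", 4L)
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad)) {
    stopf("malformed BED line %d in '%s': non-numeric coordinates", bad[1L], path)
  }
  bad <- which(start0 >= end0)
  if (length(bad)) {
    stopf("invalid interval on line %d in '%s': start >= end", bad[1L], path)
  }
  dup <- name[duplicated(name)]
  if (length(dup)) {
    stopf("duplicate clone id(s) in '%s': %s", path,
          paste(unique(dup), collapse = ", "))
  }
  gr <- GRanges(chrom, IRanges(start0 + 1, end0))
  names(gr) <- name
  gr[order(as.character(GenomicRanges::seqnames(gr)), GenomicRanges::start(gr))]
}

#' Write a clone map (or any named GRanges) as BED
#'
#' Coordinates are converted back to the 0-based half-open BED
#' convention.
#'
#' @param x A `GRanges`; names (or an `mcols` column `name`) become the
#'   BED name field.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clone_map <- function(x, path) {
  nm <- names(x)
  if (is.null(nm) && "name" %in% names(mcols(x))) nm <- mcols(x)$name
  if (is.null(nm)) nm <- paste0("feature_", seq_along(x))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(x)),
    start = format(GenomicRanges::start(x) - 1, scientific = FALSE, trim = TRUE),
    end = format(GenomicRanges::end(x), scientific = FALSE, trim = TRUE),
    name = nm,
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation from a BED-like file
#'
#' Identical format to [read_clone_map()] (the name field holds the
#' gene symbol, upper-cased), except duplicate names are permitted on
#' input and collapsed to one record per symbol (first occurrence).
#'
#' @inheritParams read_clone_map
#' @return A `GRanges` named by gene symbol, sorted by position.
#' @export
read_gene_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 4L)
  if (length(bad)) {
    stopf("malformed BED line %d in '%s': fewer than 4 fields", bad[1L], path)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- as.numeric(vapply(fields, `[[`, "", 2L))
  end0 <- as.numeric(vapply(fields, `[[`, "", 3L))
  name <- toupper(vapply(fields, `[[`, "", 4L))
  if (any(is.na(start0) | is.na(end0) | start0 >= end0)) {
    stopf("invalid coordinates in '%s'", path)
  }
  keep <- !duplicated(name)
  gr <- GRanges(chrom[keep], IRanges(start0[keep] + 1, end0[keep]))
  names(gr) <- name[keep]
  gr[order(as.character(GenomicRanges::seqnames(gr)), GenomicRanges::start(gr))]
}

#' Array-CGH cohort container
#'
#' Bundles a clone map with a clones-by-tumors matrix of log2 ratios.
#' Missing measurements are `NA` and carried as such through the
#' calling functions.
#'
#' @param clones A `GRanges` clone map (named by clone id).
#' @param log2ratio Numeric matrix, rows aligned to `clones` (rownames
#'   must equal clone ids), one column per tumor.
#' @return An object of class `cgh_cohort`.
#' @export
cgh_cohort <- function(clones, log2ratio) {
  log2ratio <- as.matrix(log2ratio)
  if (is.null(rownames(log2ratio)) || is.null(names(clones))) {
    stopf("clone map and ratio matrix must both carry clone ids")
  }
  if (!identical(rownames(log2ratio), names(clones))) {
    if (!setequal(rownames(log2ratio), names(clones))) {
      stopf("ratio matrix rows do not match the clone map")
    }
    log2ratio <- log2ratio[names(clones), , drop = FALSE]
  }
  structure(list(clones = clones, log2 = log2ratio), class = "cgh_cohort")
}

#' @export
print.cgh_cohort <- function(x, ...) {
  cat(sprintf("cgh_cohort: %d clones x %d tumors (%d missing values)\n",
              nrow(x$log2), ncol(x$log2), sum(is.na(x$log2))))
  invisible(x)
}

#' @export
dim.cgh_cohort <- function(x) dim(x$log2)

#' Read per-tumor log2-ratio profiles
#'
#' Expects a TSV with a `clone_id` column and one numeric column per
#' tumor. Every clone id must exist in `clone_map`, every clone of
#' `clone_map` must be present, and `NA` cells are permitted (they are
#' flagged as missing in downstream state calls).
#'
#' @param path Path to the TSV file.
#' @param clone_map A `GRanges` clone map from [read_clone_map()].
#' @return A [cgh_cohort()].
#' @export
read_profile_table <- function(path, clone_map) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"clone_id" %in% names(df)) stopf("'%s' lacks a clone_id column", path)
  unknown <- setdiff(df$clone_id, names(clone_map))
  if (length(unknown)) {
    stopf("clone id(s) absent from clone map: %s",
          paste(head(unknown, 5), collapse = ", "))
  }
  absent <- setdiff(names(clone_map), df$clone_id)
  if (length(absent)) {
    stopf("profile table does not cover clone(s): %s",
          paste(head(absent, 5), collapse = ", "))
  }
  m <- as.matrix(df[setdiff(names(df), "clone_id")])
  storage.mode(m) <- "double"
  rownames(m) <- df$clone_id
  cgh_cohort(clone_map, m)
}

#' Write per-tumor profiles as TSV
#'
#' @param cohort A [cgh_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(cohort, path) {
  df <- data.frame(clone_id = rownames(cohort$log2), cohort$log2,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, `name TAB description TAB
#' gene TAB gene ...`. Symbols are upper-cased and de-duplicated within
#' each set.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors; set descriptions are kept
#'   in the `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    out <- list()
    attr(out, "descriptions") <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad)) {
    stopf("malformed GMT line %d in '%s': fewer than 3 fields", bad[1L], path)
  }
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  attr(sets, "descriptions") <-
    setNames(vapply(fields, `[[`, "", 2L), names(sets))
  sets
}

#' Write gene sets as GMT
#'
#' @param sets Named list of character vectors (optionally with a
#'   `"descriptions"` attribute as produced by [read_gmt()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an RT-qPCR fold-change table
#'
#' TSV with a `gene` column and one numeric linear-scale column per
#' tumor. Values must be strictly positive.
#'
#' @param path Path to the TSV file.
#' @return A genes-by-tumors numeric matrix.
#' @export
read_qpcr_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene" %in% names(df)) stopf("'%s' lacks a gene column", path)
  m <- as.matrix(df[setdiff(names(df), "gene")])
  storage.mode(m) <- "double"
  rownames(m) <- toupper(df$gene)
  if (any(!is.na(m) & m <= 0)) stopf("non-positive expression value in '%s'", path)
  m
}

#' @rdname read_qpcr_table
#' @param x Matrix as returned by `read_qpcr_table`.
#' @export
write_qpcr_table <- function(x, path) {
  df <- data.frame(gene = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-case immunohistochemistry score table
#'
#' TSV with columns `case_id`, `nuclear_intensity` (0-3),
#' `cytoplasmic_intensity` (0-3) and `pct_positive_nuclei` (0-100).
#'
#' @param path Path to the TSV file.
#' @return A data.frame of validated records.
#' @export
read_ihc_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("case_id", "nuclear_intensity", "cytoplasmic_intensity",
            "pct_positive_nuclei")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("'%s' lacks column(s): %s", path,
                          paste(miss, collapse = ", "))
  validate_ihc(df)
  df
}

#' @rdname read_ihc_table
#' @param x Data frame of IHC records.
#' @export
write_ihc_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_ihc <- function(df) {
  ok_int <- function(v) all(v %in% 0:3)
  if (!ok_int(df$nuclear_intensity) || !ok_int(df$cytoplasmic_intensity)) {
    stopf("staining intensities must be integers in 0..3")
  }
  if (any(df$pct_positive_nuclei < 0 | df$pct_positive_nuclei > 100)) {
    stopf("pct_positive_nuclei must lie in [0, 100]")
  }
  invisible(df)
}

#' Assemble a run configuration
#'
#' Plumbing for [run_pipeline()] and the command-line wrapper. The
#' 2 Mb default bin size matches the convention of reporting
#' aberration frequencies per 2 Mb genomic interval.
#'
#' @param thresholds A [call_thresholds()] object.
#' @param bin_size Frequency-map bin width in bp (default 2e6).
#' @param seed Integer RNG seed for simulated inputs.
#' @param output_dir Where reports are written (`NULL` = don't write).
#' @param log_level One of "INFO", "WARN", "QUIET".
#' @param n_perm Permutations used by the enrichment stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(thresholds = call_thresholds(), bin_size = 2e6,
                       seed = 17L, output_dir = NULL, log_level = "INFO",
                       n_perm = 1000L) {
  if (!is_number(bin_size) || bin_size <= 0) stopf("bin_size must be > 0")
  stopifnot(inherits(thresholds, "call_thresholds"))
  structure(list(thresholds = thresholds, bin_size = bin_size,
                 seed = as.integer(seed), output_dir = output_dir,
                 log_level = log_level, n_perm = as.integer(n_perm)),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file of flat key-value configuration overrides.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  thr <- call_thresholds(
    loss_max = raw$loss_max %||% -0.25,
    gain_min = raw$gain_min %||% 0.25,
    amp_min = raw$amp_min %||% 1.0
  )
  run_config(thresholds = thr,
             bin_size = raw$bin_size %||% 2e6,
             seed = raw$seed %||% 17L,
             output_dir = raw$output_dir,
             log_level = raw$log_level %||% "INFO",
             n_perm = raw$n_perm %||% 1000L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
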