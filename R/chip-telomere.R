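#' Best in-frame repeat coverage of reads
#'
#' For each read, considers the 6 phase offsets of the repeat unit on the
#' forward strand and the 6 on the reverse complement (equivalently, matches
#' of the reverse-complemented unit on the read), and returns the largest
#' fraction of the read length covered by whole, in-frame repeat units
#' matching with at most `max_mismatches_per_unit` mismatches.
#'
#' @param reads Character vector of read sequences.
#' @param repeat_unit Repeat unit (default the telomeric hexamer `TTAGGG`).
#' @param max_mismatches_per_unit Mismatches tolerated per unit (default 0).
#' @return Numeric vector of coverage fractions in `[0, 1]`.
#' @export
telomeric_coverage <- function(reads, repeat_unit = "TTAGGG",
                               max_mismatches_per_unit = 0) {
  u <- toupper(repeat_unit)
  k <- nchar(u)
  reads <- toupper(reads)
  len <- nchar(reads)
  if (max_mismatches_per_unit == 0) {
    best_units <- function(unit) {
      hits <- stringr::str_locate_all(reads, stringr::fixed(unit))
      vapply(hits, function(m) {
        if (nrow(m) == 0) return(0L)
        max(tabulate((m[, 1] - 1L) %% k + 1L, k))
      }, integer(1))
    }
    n_best <- pmax(best_units(u), best_units(revcomp(u)))
    return(ifelse(len >= k, n_best * k / len, 0))
  }
  # mismatch-tolerant path: per-read, per-phase unit comparison
  units_match <- function(read, unit) {
    n <- nchar(read)
    if (n < k) return(0L)
    uc <- utf8ToInt(unit)
    best <- 0L
    rc <- utf8ToInt(read)
    for (off in 0:(k - 1)) {
      n_units <- (n - off) %/% k
      if (n_units == 0) next
      starts <- off + (seq_len(n_units) - 1L) * k
      mism <- integer(n_units)
      for (j in seq_len(k)) {
        mism <- mism + (rc[starts + j] != uc[j])
      }
      best <- max(best, sum(mism <= max_mismatches_per_unit))
    }
    best
  }
  ur <- revcomp(u)
  n_best <- vapply(reads, function(r) {
    max(units_match(r, u), units_match(r, ur))
  }, integer(1), USE.NAMES = FALSE)
  ifelse(len >= k, n_best * k / len, 0)
}

#' Classify reads as telomeric
#'
#' A read is telomeric when its best in-frame repeat coverage (see
#' [telomeric_coverage()]) reaches `min_coverage_fraction`. The rule is
#' reverse-complement invariant, so reads of pure `(TTAGGG)n` and pure
#' `(CCCTAA)n` are both telomeric at any phase offset.
#'
#' @inheritParams telomeric_coverage
#' @param min_coverage_fraction Minimum covered fraction of the read length
#'   (default 0.7).
#' @return Logical vector.
#' @export
is_telomeric_read <- function(reads, repeat_unit = "TTAGGG",
                              min_coverage_fraction = 0.7,
                              max_mismatches_per_unit = 0) {
  if (nchar(repeat_unit) < 1) stop("repeat unit must be non-empty", call. = FALSE)
  if (min_coverage_fraction <= 0 || min_coverage_fraction > 1) {
    stop("min_coverage_fraction must be in (0, 1]", call. = FALSE)
  }
  telomeric_coverage(reads, repeat_unit, max_mismatches_per_unit) >=
    min_coverage_fraction
}

#' Telomeric read rate of a sample
#'
#' Counts telomeric reads and normalises to the total number of reads in the
#' sample (reads per million), the study's H3K9me3 telomere-abundance
#' measure.
#'
#' @inheritParams is_telomeric_read
#' @return Tibble with `telomeric_count`, `total_count`, `per_million`.
#' @export
telomeric_read_rate <- function(reads, repeat_unit = "TTAGGG",
                                min_coverage_fraction = 0.7,
                                max_mismatches_per_unit = 0) {
  if (length(reads) == 0) stop("no reads supplied", call. = FALSE)
  telo <- is_telomeric_read(reads, repeat_unit, min_coverage_fraction,
                            max_mismatches_per_unit)
  tibble::tibble(telomeric_count = sum(telo), total_count = length(reads),
                 per_million = sum(telo) / length(reads) * 1e6)
}

#' Classify H3K9me3 peaks by TE overlap and subtelomere membership
#'
#' A peak is "on a retrotransposon" when it overlaps at least 1 bp of any TE
#' instance, and "subtelomeric" when its start lies within
#' `subtelomere_threshold` of a chromosome end; the two labels are
#' independent and their conjunction is the subtelomeric-retrotransposon
#' class.
#'
#' @param peaks Peak tibble with `chrom`, `start`, `end` (0-based half-open)
#'   and optionally `direction`.
#' @param te_annotation TE instance tibble with `chrom`, `start`, `end`.
#' @param genome Assembly tibble.
#' @param subtelomere_threshold Subtelomere distance threshold in bp.
#' @return `peaks` with logical columns `on_retrotransposon` and
#'   `subtelomeric` added; summarise with [peak_class_counts()].
#' @export
classify_peaks <- function(peaks, te_annotation, genome, subtelomere_threshold) {
  peaks <- tibble::as_tibble(peaks)
  on_te <- rep(FALSE, nrow(peaks))
  if (!is.null(te_annotation) && nrow(te_annotation) > 0 && nrow(peaks) > 0) {
    for (chr in unique(peaks$chrom)) {
      pi <- which(peaks$chrom == chr)
      ti <- which(te_annotation$chrom == chr)
      if (length(ti) == 0) next
      q <- IRanges::IRanges(start = peaks$start[pi] + 1, end = peaks$end[pi])
      s <- IRanges::IRanges(start = te_annotation$start[ti] + 1,
                            end = te_annotation$end[ti])
      on_te[pi] <- IRanges::overlapsAny(q, s)
    }
  }
  peaks$on_retrotransposon <- on_te
  peaks$subtelomeric <- if (nrow(peaks)) {
    is_subtelomeric(peaks, genome, subtelomere_threshold)
  } else {
    logical()
  }
  peaks
}

#' Tally classified peaks
#'
#' @param classified Output of [classify_peaks()].
#' @return One-row tibble: total peaks, the three named classes
#'   (on_retrotransposon, subtelomeric, subtelomeric_retrotransposon), the
#'   `other` class (neither label), and the subtelomeric percentage. The four
#'   2x2 cells (`both`, TE-only, subtelomere-only, `other`) sum to `n_peaks`.
#' @export
peak_class_counts <- function(classified) {
  stopifnot(all(c("on_retrotransposon", "subtelomeric") %in% names(classified)))
  te <- classified$on_retrotransposon
  st <- classified$subtelomeric
  tibble::tibble(
    n_peaks = length(te),
    on_retrotransposon = sum(te),
    subtelomeric = sum(st),
    subtelomeric_retrotransposon = sum(te & st),
    other = sum(!te & !st),
    subtelomeric_percent = if (length(te)) 100 * sum(st) / length(te) else NA_real_
  )
}

#' Median expression fold change of genes flanking peaks
#'
#' For each peak direction (`decreased` / `increased` H3K9me3), genomic side
#' of the peak (5' = left, 3' = right of the peak interval, irrespective of
#' gene strand) and window size, collects the genes whose TSS lies within
#' `(0, w]` bp of the corresponding peak boundary across all peaks of that
#' direction, and reports the median log2 fold change and gene count. A gene
#' flanking several peaks contributes once per peak.
#'
#' @param peaks Peak tibble with `chrom`, `start`, `end`, `direction`.
#' @param genes_fc Gene tibble with `chrom`, `start`, `end`, `strand`,
#'   `log2fc` (gene-level expression fold change).
#' @param windows Ascending vector of window sizes in bp.
#' @return Tibble with columns `direction`, `side`, `window`,
#'   `median_log2fc`, `n_genes` (cells with no genes have `n_genes = 0` and
#'   `NA` median).
#' @export
metagene_flanking_fc <- function(peaks, genes_fc, windows) {
  if (is.unsorted(windows)) stop("windows must be ascending", call. = FALSE)
  peaks <- tibble::as_tibble(peaks)
  grid <- tidyr::expand_grid(direction = unique(peaks$direction),
                             side = c("5prime", "3prime"),
                             window = windows)
  if (nrow(peaks) == 0 || nrow(genes_fc) == 0) {
    grid <- grid[0, ]
    grid$median_log2fc <- numeric()
    grid$n_genes <- integer()
    return(grid)
  }
  genes_fc <- tss_of(genes_fc)
  pairs <- dplyr::inner_join(
    dplyr::select(peaks, "chrom", peak_start = "start", peak_end = "end",
                  "direction"),
    dplyr::select(genes_fc, "chrom", "tss", "log2fc"),
    by = "chrom", relationship = "many-to-many"
  )
  pairs <- dplyr::mutate(pairs,
                         d5 = .data$peak_start - .data$tss,
                         d3 = .data$tss - .data$peak_end + 1)
  dplyr::bind_rows(purrr::pmap(grid, function(direction, side, window) {
    d <- if (side == "5prime") pairs$d5 else pairs$d3
    sel <- pairs$direction == direction & d > 0 & d <= window
    fc <- pairs$log2fc[sel]
    tibble::tibble(direction = direction, side = side, window = window,
                   median_log2fc = if (length(fc)) stats::median(fc) else NA_real_,
                   n_genes = length(fc))
  }))
}

#' Plot a flanking-gene metagene table
#'
#' @param metagene Output of [metagene_flanking_fc()].
#' @return A ggplot object: median log2FC against window size, one line per
#'   peak direction, faceted by peak side.
#' @export
plot_metagene <- function(metagene) {
  ggplot2::ggplot(metagene,
                  ggplot2::aes(x = .data$window, y = .data$median_log2fc,
                               colour = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$side)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "window (bp)", y = "median log2 fold change",
                  colour = "H3K9me3") +
    ggplot2::theme_minimal()
}
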