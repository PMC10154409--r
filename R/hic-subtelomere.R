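#' Parse a Hi-C valid-pairs file (allValidPairs dialect)
#'
#' Whitespace-separated records with at least 7 fields:
#' `readID chrom1 pos1 strand1 chrom2 pos2 strand2 ...` (positions 1-based).
#' Malformed lines (too few fields or non-numeric positions) are skipped and
#' tallied; pairs referencing chromosomes absent from `genome` are likewise
#' skipped and tallied. More than 10% malformed lines aborts the parse.
#' Gzip-compressed files are read transparently.
#'
#' @param path Path to the valid-pairs file.
#' @param genome Optional assembly tibble to screen unknown chromosomes.
#' @return Tibble with columns `read_id`, `chrom1`, `pos1`, `strand1`,
#'   `chrom2`, `pos2`, `strand2`; attributes `n_malformed` and
#'   `n_unknown_chrom` carry the skip tallies.
#' @export
read_valid_pairs <- function(path, genome = NULL) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty valid-pairs file: ", path, call. = FALSE)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  ok <- nf >= 7
  pos1 <- suppressWarnings(as.numeric(vapply(fields, function(f) f[3][1], "")))
  pos2 <- suppressWarnings(as.numeric(vapply(fields, function(f) f[6][1], "")))
  ok <- ok & !is.na(pos1) & !is.na(pos2)
  n_malformed <- sum(!ok)
  if (n_malformed > 0) {
    if (n_malformed / length(lines) > 0.10) {
      stop(n_malformed, " of ", length(lines),
           " lines malformed (> 10%); refusing to parse ", path, call. = FALSE)
    }
    warning(n_malformed, " malformed line(s) skipped in ", path)
  }
  fields <- fields[ok]
  out <- tibble::tibble(
    read_id = vapply(fields, `[`, "", 1),
    chrom1 = vapply(fields, `[`, "", 2),
    pos1 = pos1[ok],
    strand1 = vapply(fields, `[`, "", 4),
    chrom2 = vapply(fields, `[`, "", 5),
    pos2 = pos2[ok],
    strand2 = vapply(fields, `[`, "", 7)
  )
  n_unknown <- 0L
  if (!is.null(genome)) {
    known <- out$chrom1 %in% genome$chrom & out$chrom2 %in% genome$chrom
    n_unknown <- sum(!known)
    if (n_unknown > 0) {
      warning(n_unknown, " pair(s) on unknown chromosomes skipped")
      out <- out[known, ]
    }
  }
  attr(out, "n_malformed") <- n_malformed
  attr(out, "n_unknown_chrom") <- n_unknown
  out
}

#' @keywords internal
#' @noRd
pair_ends <- function(pairs, cis_only) {
  if (cis_only) pairs <- pairs[pairs$chrom1 == pairs$chrom2, ]
  tibble::tibble(
    pair = rep(seq_len(nrow(pairs)), 2),
    chrom = c(pairs$chrom1, pairs$chrom2),
    pos0 = c(pairs$pos1, pairs$pos2) - 1
  )
}

#' @keywords internal
#' @noRd
effective_windows <- function(windows, len) {
  ifelse(windows > len, len / 2, windows)
}

#' @keywords internal
#' @noRd
warn_truncated_windows <- function(windows, genome) {
  if (any(outer(windows, genome$length, ">"))) {
    warning("window(s) exceeding chromosome length truncated to length/2")
  }
}

#' Arm-resolved subtelomeric interaction counts
#'
#' For each chromosome, arm (left/right) and window size `w`, counts the
#' valid pairs having at least one end whose distance from that chromosome
#' end lies in `[exclusion, w)` -- interactions within the terminal region
#' and interactions of the region with anywhere else (including other
#' chromosomes, unless `cis_only`) both qualify. A pair with both ends in
#' the same arm-window cell is counted once in that cell; ends falling in
#' two different cells credit each once. The terminal `exclusion` zone
#' (100 kb in the study, scaled for miniature genomes) contributes nothing.
#'
#' @param pairs Valid-pair tibble from [read_valid_pairs()].
#' @param genome Assembly tibble.
#' @param windows Ascending window sizes in bp (the study ladder is 5, 10,
#'   20, 30 and 60 Mb); windows longer than a chromosome are truncated to
#'   half its length with a warning.
#' @param exclusion Terminal exclusion in bp, `< min(windows)`.
#' @param cis_only Restrict to intra-chromosomal pairs (default FALSE).
#' @return Tibble with columns `chrom`, `arm`, `window`, `count` (all
#'   chromosome x arm x window cells present, zeros kept).
#' @export
arm_window_counts <- function(pairs, genome, windows, exclusion = 0,
                              cis_only = FALSE) {
  if (is.unsorted(windows)) stop("windows must be ascending", call. = FALSE)
  if (exclusion >= min(windows)) {
    stop("exclusion must be smaller than the smallest window", call. = FALSE)
  }
  warn_truncated_windows(windows, genome)
  ends <- pair_ends(pairs, cis_only)
  grid <- tidyr::expand_grid(chrom = genome$chrom, arm = c("left", "right"),
                             window = windows)
  counts <- purrr::pmap_int(grid, function(chrom, arm, window) {
    len <- genome$length[match(chrom, genome$chrom)]
    w <- effective_windows(window, len)
    e <- ends[ends$chrom == chrom, ]
    d <- if (arm == "left") e$pos0 else len - 1 - e$pos0
    hit <- d >= exclusion & d < w
    length(unique(e$pair[hit]))
  })
  grid$count <- counts
  grid
}

#' Normalise interaction counts to percentages of the total
#'
#' @param counts Count tibble (e.g. from [arm_window_counts()]).
#' @param total_pairs Total number of valid pairs in the sample (> 0).
#' @return `counts` with a `percent_of_total` column added
#'   (`count / total_pairs * 100`).
#' @export
percent_normalize <- function(counts, total_pairs) {
  if (total_pairs <= 0) stop("total_pairs must be > 0", call. = FALSE)
  dplyr::mutate(tibble::as_tibble(counts),
                percent_of_total = .data$count / total_pairs * 100)
}

#' Chromosome-center interaction counts
#'
#' The same counting rule as [arm_window_counts()], applied to a window of
#' width `w` centered at the chromosome midpoint -- the study's baseline for
#' the center-vs-subtelomere comparison.
#'
#' @inheritParams arm_window_counts
#' @return Tibble with columns `chrom`, `window`, `count`.
#' @export
center_window_counts <- function(pairs, genome, windows, cis_only = FALSE) {
  if (is.unsorted(windows)) stop("windows must be ascending", call. = FALSE)
  warn_truncated_windows(windows, genome)
  ends <- pair_ends(pairs, cis_only)
  grid <- tidyr::expand_grid(chrom = genome$chrom, window = windows)
  counts <- purrr::pmap_int(grid, function(chrom, window) {
    len <- genome$length[match(chrom, genome$chrom)]
    w <- effective_windows(window, len)
    lo <- len / 2 - w / 2
    hi <- len / 2 + w / 2
    e <- ends[ends$chrom == chrom, ]
    hit <- e$pos0 >= lo & e$pos0 < hi
    length(unique(e$pair[hit]))
  })
  grid$count <- counts
  grid
}

#' Plot arm-resolved subtelomere interaction profiles
#'
#' @param counts Output of [arm_window_counts()], optionally through
#'   [percent_normalize()]; a `sample` column (if present) maps to colour.
#' @return A ggplot object.
#' @export
plot_arm_profile <- function(counts) {
  y <- if ("percent_of_total" %in% names(counts)) "percent_of_total" else "count"
  aes <- if ("sample" %in% names(counts)) {
    ggplot2::aes(x = .data$window, y = .data[[y]], colour = .data$sample)
  } else {
    ggplot2::aes(x = .data$window, y = .data[[y]])
  }
  ggplot2::ggplot(counts, aes) +
    ggplot2::stat_summary(fun = sum, geom = "line") +
    ggplot2::stat_summary(fun = sum, geom = "point") +
    ggplot2::facet_wrap(ggplot2::vars(.data$arm)) +
    ggplot2::labs(x = "window from chromosome end (bp)",
                  y = if (y == "count") "interactions" else "% of interactions") +
    ggplot2::theme_minimal()
}
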