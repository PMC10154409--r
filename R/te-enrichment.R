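#' Filter a differential TE-instance table
#'
#' Applies the study's instance filters: an instance is differentially
#' expressed (DE) when its fold change exceeds `fc_cutoff` in the requested
#' direction and its p-value is below `p_cutoff`; instances covered by fewer
#' than `min_reads` uniquely mapped reads are excluded from the analysis
#' altogether (they are dropped from the background universe as well, see
#' [enrichment_scan()]).
#'
#' @param de_table Tibble with columns `instance_id`, `log2fc`, `pvalue`,
#'   `unique_reads` (plus any annotation columns, carried through).
#' @param fc_cutoff Fold-change cutoff on the linear scale (default 1.5, i.e.
#'   `|log2fc| > log2(1.5)`).
#' @param p_cutoff P-value cutoff (default 0.05, strict `<`).
#' @param min_reads Minimum unique-read coverage (default 5; instances with
#'   `unique_reads < min_reads` are excluded).
#' @param direction `"up"` or `"down"`.
#' @return Tibble of DE rows (same columns as the input).
#' @export
filter_de_instances <- function(de_table, fc_cutoff = 1.5, p_cutoff = 0.05,
                                min_reads = 5, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(de_table),
            all(c("instance_id", "log2fc", "pvalue", "unique_reads") %in% names(de_table)))
  if (fc_cutoff <= 0 || p_cutoff <= 0) stop("cutoffs must be positive", call. = FALSE)
  if (anyDuplicated(de_table$instance_id)) {
    stop("duplicate instance ids in DE table", call. = FALSE)
  }
  lfc <- if (direction == "up") de_table$log2fc else -de_table$log2fc
  dplyr::filter(de_table,
                de_table$unique_reads >= min_reads,
                lfc > log2(fc_cutoff),
                de_table$pvalue < p_cutoff)
}

#' Partition TE instances by distance to the chromosome end
#'
#' @param instances Tibble with columns `chrom`, `start` (0-based).
#' @param genome Assembly tibble.
#' @param threshold Subtelomere distance threshold in bp.
#' @return The input with a logical `subtelomeric` column added; the two
#'   groups (subtelomere adjacent / non-adjacent) partition the input.
#' @export
split_by_distance <- function(instances, genome, threshold) {
  instances <- tibble::as_tibble(instances)
  if (nrow(instances) == 0) {
    instances$subtelomeric <- logical()
    return(instances)
  }
  instances$subtelomeric <- is_subtelomeric(instances, genome, threshold)
  instances
}

#' Expected subtelomeric DE count under the genomic-density baseline
#'
#' The number of DE instances expected to fall in the subtelomeric region by
#' chance, using the genomic distribution of the superfamily as the baseline:
#' `n_de * n_background_subtelomeric / n_background_total`.
#'
#' @param n_de Number of DE instances.
#' @param n_background_subtelomeric Subtelomeric background instances.
#' @param n_background_total Total background instances (> 0).
#' @return Expected count (real).
#' @export
expected_subtelomeric_count <- function(n_de, n_background_subtelomeric,
                                        n_background_total) {
  if (n_background_total <= 0) stop("background set is empty", call. = FALSE)
  if (n_background_subtelomeric < 0 || n_background_subtelomeric > n_background_total) {
    stop("invalid background counts", call. = FALSE)
  }
  n_de * n_background_subtelomeric / n_background_total
}

#' Two-sided exact hypergeometric p for a 2x2 table
#'
#' Probability-mass method: conditioning on the table margins, the p-value is
#' the sum of probabilities of all tables whose hypergeometric probability
#' does not exceed that of the observed table (a relative tolerance of 1e-7
#' guards floating-point ties, the convention of common exact-test
#' implementations).
#'
#' @keywords internal
#' @noRd
hypergeom_two_sided <- function(a, b, c, d) {
  m <- a + b      # row 1 total (DE)
  k <- a + c      # column 1 total (subtelomeric)
  n <- c + d      # row 2 total
  lo <- max(0, k - n)
  hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Fisher's exact enrichment test on a 2x2 table
#'
#' Rows are DE vs background (non-DE) instances, columns subtelomeric vs not.
#' Returns the cross-product odds ratio (infinite on a zero denominator) and
#' the two-sided exact hypergeometric p-value (probability-mass method).
#' Background counts must exclude the DE instances.
#'
#' @param de_sub,de_nonsub DE instances inside / outside the subtelomere.
#' @param bg_sub,bg_nonsub Background (non-DE) instances inside / outside.
#' @return Tibble with columns `odds_ratio` and `p_value`.
#' @examples
#' fisher_enrichment(8, 2, 2, 8) # p = 4252/184756
#' @export
fisher_enrichment <- function(de_sub, de_nonsub, bg_sub, bg_nonsub) {
  counts <- c(de_sub, de_nonsub, bg_sub, bg_nonsub)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  or_num <- de_sub * bg_nonsub
  or_den <- de_nonsub * bg_sub
  odds_ratio <- if (or_den == 0) {
    if (or_num == 0) NaN else Inf
  } else {
    or_num / or_den
  }
  p <- min(1, hypergeom_two_sided(de_sub, de_nonsub, bg_sub, bg_nonsub))
  tibble::tibble(odds_ratio = odds_ratio, p_value = p)
}

#' Subtelomeric enrichment scan over thresholds, directions and superfamilies
#'
#' The study's headline analysis: for each TE superfamily and DE direction,
#' count DE instances inside the subtelomeric region at each distance
#' threshold, compare against the superfamily's genomic density (expected
#' count and Fisher's exact test), and adjust p-values with
#' Benjamini-Hochberg across the whole scan.
#'
#' The background universe is, by default, the "expressed" instances of the
#' superfamily -- all instances passing the `min_reads` coverage filter --
#' with the DE instances removed from the background row of the 2x2 table.
#' Set `background = "annotated"` to use every annotated instance instead.
#'
#' @param de_table Differential TE table (see [filter_de_instances()]), with
#'   `superfamily`, `chrom` and `start` columns.
#' @param genome Assembly tibble.
#' @param thresholds Ascending vector of subtelomere thresholds in bp (the
#'   study scans 1, 20 and 50 Mb on the mouse genome).
#' @param directions Character vector, subset of `c("up", "down")`.
#' @param superfamilies Superfamilies to test; default all present.
#' @param background `"expressed"` (default) or `"annotated"`.
#' @param fc_cutoff,p_cutoff,min_reads Instance filters, see
#'   [filter_de_instances()].
#' @return An object of class `subtelo_enrichment`; its `results` tibble has
#'   one row per superfamily x direction x threshold with columns `observed`,
#'   `n_de`, `expected`, `odds_ratio`, `p_value`, `adjusted_p`. Use [tidy()],
#'   [glance()] and [ggplot2::autoplot()] on it.
#' @export
enrichment_scan <- function(de_table, genome, thresholds,
                            directions = c("up", "down"),
                            superfamilies = NULL,
                            background = c("expressed", "annotated"),
                            fc_cutoff = 1.5, p_cutoff = 0.05, min_reads = 5) {
  background <- match.arg(background)
  stopifnot(all(directions %in% c("up", "down")))
  if (is.unsorted(thresholds)) stop("thresholds must be ascending", call. = FALSE)
  de_table <- tibble::as_tibble(de_table)
  if (is.null(superfamilies)) superfamilies <- sort(unique(de_table$superfamily))
  missing_sf <- setdiff(superfamilies, unique(de_table$superfamily))
  if (length(missing_sf)) {
    warning("superfamily absent from annotation, skipped: ",
            paste(missing_sf, collapse = ", "))
    superfamilies <- setdiff(superfamilies, missing_sf)
  }

  grid <- tidyr::expand_grid(superfamily = superfamilies,
                             direction = directions,
                             threshold = thresholds)
  rows <- purrr::pmap(grid, function(superfamily, direction, threshold) {
    sf_tab <- dplyr::filter(de_table, .data$superfamily == !!superfamily)
    universe <- if (background == "expressed") {
      dplyr::filter(sf_tab, .data$unique_reads >= min_reads)
    } else {
      sf_tab
    }
    de <- filter_de_instances(sf_tab, fc_cutoff, p_cutoff, min_reads, direction)
    bg <- dplyr::anti_join(universe, de, by = "instance_id")
    de <- split_by_distance(de, genome, threshold)
    bg <- split_by_distance(bg, genome, threshold)
    de_sub <- sum(de$subtelomeric)
    bg_sub <- sum(bg$subtelomeric)
    n_uni <- nrow(de) + nrow(bg)
    expected <- if (n_uni > 0) {
      expected_subtelomeric_count(nrow(de), de_sub + bg_sub, n_uni)
    } else {
      NA_real_
    }
    ft <- if (nrow(de) == 0) {
      tibble::tibble(odds_ratio = NaN, p_value = 1)
    } else {
      fisher_enrichment(de_sub, nrow(de) - de_sub, bg_sub, nrow(bg) - bg_sub)
    }
    tibble::tibble(superfamily = superfamily, direction = direction,
                   threshold = threshold, observed = de_sub, n_de = nrow(de),
                   expected = expected, odds_ratio = ft$odds_ratio,
                   p_value = ft$p_value)
  })
  results <- dplyr::bind_rows(rows)
  results$adjusted_p <- stats::p.adjust(results$p_value, method = "BH")
  structure(
    list(results = results,
         params = list(thresholds = thresholds, background = background,
                       fc_cutoff = fc_cutoff, p_cutoff = p_cutoff,
                       min_reads = min_reads)),
    class = "subtelo_enrichment"
  )
}

#' @export
print.subtelo_enrichment <- function(x, ...) {
  cat("Subtelomeric TE enrichment scan\n")
  cat("  thresholds (bp):", paste(format(x$params$thresholds, scientific = FALSE),
                                  collapse = ", "), "\n")
  cat("  background:", x$params$background, "\n")
  print(x$results, ...)
  invisible(x)
}

#' Tidy an enrichment scan
#'
#' @param x A `subtelo_enrichment` object.
#' @param ... Unused.
#' @return The per-test results tibble.
#' @export
tidy.subtelo_enrichment <- function(x, ...) x$results

#' One-row summary of an enrichment scan
#'
#' @param x A `subtelo_enrichment` object.
#' @param ... Unused.
#' @return Tibble with the number of tests and how many are significant after
#'   Benjamini-Hochberg adjustment at 0.05.
#' @export
glance.subtelo_enrichment <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x$results),
    n_signif_adj = sum(x$results$adjusted_p < 0.05, na.rm = TRUE),
    min_adjusted_p = suppressWarnings(min(x$results$adjusted_p, na.rm = TRUE))
  )
}

#' Observed-vs-expected plot of an enrichment scan
#'
#' Bar panel per threshold and direction: observed subtelomeric DE counts
#' next to the counts expected from the genomic density baseline.
#'
#' @param object A `subtelo_enrichment` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.subtelo_enrichment <- function(object, ...) {
  df <- tidyr::pivot_longer(object$results, c("observed", "expected"),
                            names_to = "kind", values_to = "count")
  df$threshold_lab <- paste0(format(df$threshold / 1e6, trim = TRUE), " Mb")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$superfamily, y = .data$count,
                                   fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(ggplot2::vars(.data$direction),
                        ggplot2::vars(.data$threshold_lab)) +
    ggplot2::labs(x = NULL, y = "subtelomeric DE instances", fill = NULL) +
    ggplot2::theme_minimal()
}
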