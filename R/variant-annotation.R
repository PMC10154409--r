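#' Subtract a wild-type baseline from variant calls
#'
#' Removes from `case` every variant with an identical match in `control`.
#' By default a match is the exact allele (`chrom`, `pos`, `ref`, `alt`);
#' `by_position = TRUE` relaxes this to (`chrom`, `pos`) for call sets where
#' indel representation may drift between samples.
#'
#' @param case,control Variant tibbles with columns `chrom`, `pos` (1-based),
#'   `ref`, `alt`.
#' @param by_position Match on position only (default FALSE, exact allele).
#' @return The case tibble with baseline variants removed.
#' @export
subtract_baseline <- function(case, control, by_position = FALSE) {
  keys <- if (by_position) c("chrom", "pos") else c("chrom", "pos", "ref", "alt")
  stopifnot(all(keys %in% names(case)))
  case <- tibble::as_tibble(case)
  if (is.null(control) || nrow(control) == 0) return(case)
  dplyr::anti_join(case, control, by = keys)
}

#' Tally variants by genomic category and variant type
#'
#' Each variant is classified at its leftmost affected reference base with
#' [classify_genomic_category()] and counted in exactly one category.
#' Variants on chromosomes absent from `genome` are skipped with a warning
#' and reported in the `n_skipped` attribute.
#'
#' @param variants Baseline-subtracted variant tibble with `chrom`, `pos`
#'   (1-based), `vtype` (`"SNV"` or `"indel"`).
#' @param genes Gene-model tibble.
#' @param genome Assembly tibble (used only to screen unknown chromosomes);
#'   `NULL` skips the screen.
#' @param ... Passed to [classify_genomic_category()].
#' @return Tibble with one row per category (all levels kept) and one count
#'   column per variant type; column sums equal the number of classified
#'   variants.
#' @export
variant_category_counts <- function(variants, genes, genome = NULL, ...) {
  variants <- tibble::as_tibble(variants)
  n_skipped <- 0L
  if (!is.null(genome) && nrow(variants) > 0) {
    known <- variants$chrom %in% genome$chrom
    n_skipped <- sum(!known)
    if (n_skipped > 0) {
      warning(n_skipped, " variant(s) on unknown chromosomes skipped")
      variants <- variants[known, ]
    }
  }
  vtypes <- c("SNV", "indel")
  if (nrow(variants) == 0) {
    out <- tibble::tibble(category = factor(genomic_categories(),
                                            levels = genomic_categories()),
                          SNV = 0L, indel = 0L)
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  cls <- classify_genomic_category(
    tibble::tibble(chrom = variants$chrom, pos = variants$pos - 1),
    genes, ...
  )
  tab <- table(category = cls$category,
               vtype = factor(variants$vtype, levels = vtypes))
  out <- tibble::as_tibble(as.data.frame.matrix(tab), rownames = "category")
  out$category <- factor(out$category, levels = genomic_categories())
  out <- dplyr::arrange(out, .data$category)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Classify a single-base substitution
#'
#' Directional class `ref>alt`, or the 6-class pyrimidine-reference
#' convention when `collapse = TRUE` (purine-reference substitutions are
#' mapped to their reverse complement, e.g. A>G becomes T>C). Vectorised.
#'
#' @param ref,alt Single nucleotides in `A`,`C`,`G`,`T`; `ref != alt`.
#' @param collapse Collapse to the pyrimidine convention.
#' @return Character vector of substitution classes.
#' @examples
#' classify_sbs("A", "G")                  # "A>G"
#' classify_sbs("A", "G", collapse = TRUE) # "T>C"
#' @export
classify_sbs <- function(ref, alt, collapse = FALSE) {
  ref <- toupper(ref); alt <- toupper(alt)
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!ok)) stop("ref/alt must be unambiguous single nucleotides", call. = FALSE)
  if (any(ref == alt)) stop("ref and alt must differ", call. = FALSE)
  if (collapse) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    purine <- ref %in% c("A", "G")
    ref[purine] <- comp[ref[purine]]
    alt[purine] <- comp[alt[purine]]
  }
  paste0(ref, ">", alt)
}

#' All directional (and collapsed) SBS class labels
#'
#' @param collapse Return the 6 pyrimidine-reference classes instead of the
#'   12 directional ones.
#' @return Character vector of class labels.
#' @export
sbs_classes <- function(collapse = FALSE) {
  nt <- c("A", "C", "G", "T")
  all12 <- as.vector(outer(nt, nt, function(r, a) paste0(r, ">", a)))
  all12 <- all12[substr(all12, 1, 1) != substr(all12, 3, 3)]
  all12 <- sort(all12)
  if (!collapse) return(all12)
  sort(unique(classify_sbs(substr(all12, 1, 1), substr(all12, 3, 3),
                           collapse = TRUE)))
}

#' SBS spectrum of a set of SNVs
#'
#' @param variants Variant tibble; rows with `vtype != "SNV"` are ignored.
#' @param collapse Use the 6-class pyrimidine convention.
#' @return Tibble with columns `sbs_class` and `count`, one row per class
#'   (zero counts kept).
#' @export
sbs_spectrum <- function(variants, collapse = FALSE) {
  lev <- sbs_classes(collapse)
  snv <- dplyr::filter(tibble::as_tibble(variants), .data$vtype == "SNV")
  cls <- if (nrow(snv)) classify_sbs(snv$ref, snv$alt, collapse) else character()
  tab <- table(factor(cls, levels = lev))
  tibble::tibble(sbs_class = lev, count = as.integer(tab))
}

#' Filter CNV segments by read depth
#'
#' Keeps segments whose mean depth strictly exceeds `min_depth` (the study
#' filters low-confidence regions with `depth > 10`). Order preserved.
#'
#' @param segments Tibble with a `depth` column.
#' @param min_depth Depth cutoff (default 10, strict `>`).
#' @return Filtered tibble.
#' @export
filter_cnv_segments <- function(segments, min_depth = 10) {
  if (min_depth < 0) stop("min_depth must be >= 0", call. = FALSE)
  stopifnot(is.data.frame(segments), "depth" %in% names(segments))
  dplyr::filter(tibble::as_tibble(segments), .data$depth > min_depth)
}

#' Bar plot of a variant category spectrum
#'
#' @param counts Output of [variant_category_counts()].
#' @return A ggplot object.
#' @export
plot_category_counts <- function(counts) {
  df <- tidyr::pivot_longer(counts, -"category",
                            names_to = "vtype", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$count,
                                   fill = .data$vtype)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "variants", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap-style tile plot of SBS spectra across samples
#'
#' @param spectra Tibble with columns `sample`, `sbs_class`, `count` (e.g.
#'   several [sbs_spectrum()] results bound with a `sample` column).
#' @return A ggplot object.
#' @export
plot_sbs_spectrum <- function(spectra) {
  ggplot2::ggplot(spectra, ggplot2::aes(x = .data$sample, y = .data$sbs_class,
                                        fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "count") +
    ggplot2::theme_minimal()
}
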