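#' Build a genome assembly table
#'
#' The assembly is the coordinate frame for every distance-to-end computation
#' in the package. It is an ordinary tibble with one row per chromosome, so it
#' pipes through dplyr verbs like any other table.
#'
#' @param chrom Character vector of chromosome names (unique, non-empty).
#' @param length Integer-like vector of chromosome lengths in bp (> 0).
#' @return A tibble with columns `chrom` and `length`.
#' @examples
#' genome_assembly(c("chr1", "chr2"), c(2e6, 1e6))
#' @export
genome_assembly <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) == 0) stop("assembly needs at least one chromosome", call. = FALSE)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique", call. = FALSE)
  if (any(is.na(chrom)) || any(!nzchar(chrom))) {
    stop("chromosome names must be non-empty", call. = FALSE)
  }
  if (any(is.na(length)) || any(length <= 0)) {
    stop("chromosome lengths must be positive", call. = FALSE)
  }
  tibble::tibble(chrom = chrom, length = length)
}

#' @keywords internal
#' @noRd
chrom_lengths <- function(genome, chroms) {
  idx <- match(chroms, genome$chrom)
  if (anyNA(idx)) {
    bad <- unique(chroms[is.na(idx)])
    stop("unknown chromosome(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  genome$length[idx]
}

#' Distance from a position to the nearest chromosome end
#'
#' Distances are measured on 0-based coordinates: the first base of a
#' chromosome and its last base both have distance 0. The function is
#' vectorised over positions and chromosomes.
#'
#' @param position 0-based position(s), `0 <= position < length`.
#' @param chrom Chromosome name(s), recycled against `position`.
#' @param genome Assembly tibble from [genome_assembly()].
#' @return Numeric vector of distances in bp.
#' @examples
#' g <- genome_assembly("chr1", 1000)
#' distance_to_nearest_end(c(0, 400, 999), "chr1", g)
#' @export
distance_to_nearest_end <- function(position, chrom, genome) {
  len <- chrom_lengths(genome, chrom)
  position <- as.numeric(position)
  if (any(is.na(position)) || any(position < 0) || any(position >= len)) {
    stop("position out of chromosome bounds", call. = FALSE)
  }
  pmin(position, len - 1 - position)
}

#' Subtelomere membership of genomic intervals
#'
#' An interval is subtelomeric when its reference point (the 5'-most genomic
#' coordinate, i.e. `start`) lies strictly within `threshold` bp of either
#' chromosome end. The strict-`<` boundary rule means an interval starting
#' exactly `threshold` bp from an end is *not* subtelomeric.
#'
#' @param x A data frame with columns `chrom` and `start` (0-based).
#' @param genome Assembly tibble.
#' @param threshold Distance threshold in bp (> 0); the study scans 1 Mb,
#'   20 Mb and 50 Mb on the mouse genome.
#' @return Logical vector, one element per row of `x`.
#' @export
is_subtelomeric <- function(x, genome, threshold) {
  stopifnot(is.data.frame(x), all(c("chrom", "start") %in% names(x)))
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    stop("threshold must be a single positive number", call. = FALSE)
  }
  distance_to_nearest_end(x$start, x$chrom, genome) < threshold
}

#' Chromosome arm of a position
#'
#' Mouse chromosomes are acrocentric, so "arm" here simply means the half of
#' the chromosome a position falls in; the exact midpoint is assigned to the
#' left arm.
#'
#' @inheritParams distance_to_nearest_end
#' @return Character vector, `"left"` or `"right"`.
#' @export
arm_of <- function(position, chrom, genome) {
  len <- chrom_lengths(genome, chrom)
  position <- as.numeric(position)
  if (any(is.na(position)) || any(position < 0) || any(position >= len)) {
    stop("position out of chromosome bounds", call. = FALSE)
  }
  ifelse(position <= len / 2, "left", "right")
}

#' Genomic-category levels
#'
#' The fixed partition used for mutation and insertion-site spectra:
#' promoter (2 kb around a TSS, both sides), exon, intron, 5' proximal
#' (2-10 kb upstream), 5' distal (10-100 kb upstream), 3' proximal
#' (0-10 kb downstream), 3' distal (10-100 kb downstream), gene desert
#' (> 100 kb from the nearest gene), and intergenic_other for intergenic
#' positions within 100 kb of a gene but outside every named flank window
#' (possible only with non-default window widths).
#'
#' @return Character vector of category levels, in display order.
#' @export
genomic_categories <- function() {
  c("promoter", "five_prime_proximal", "five_prime_distal", "exon", "intron",
    "three_prime_proximal", "three_prime_distal", "gene_desert",
    "intergenic_other")
}

#' Transcription start sites of gene models
#'
#' @param genes Gene-model tibble (see [read_bed12()]): columns `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, and list-columns `exon_starts`,
#'   `exon_ends`. The TSS is `start` for `+` genes and `end - 1` for `-`
#'   genes (0-based).
#' @return `genes` with a `tss` column added.
#' @export
tss_of <- function(genes) {
  stopifnot(is.data.frame(genes))
  strand <- genes$strand
  if (any(!strand %in% c("+", "-"))) {
    warning("unstranded gene(s) treated as '+' strand")
    strand[!strand %in% c("+", "-")] <- "+"
  }
  dplyr::mutate(genes, tss = ifelse(strand == "+", .data$start, .data$end - 1))
}

#' Classify positions into genomic categories relative to gene models
#'
#' Each position receives exactly one category with the precedence
#' promoter > exon > intron > flank-of-nearest-gene > gene desert.
#' The promoter window is symmetric (+/- `promoter_halfwidth`) around every
#' TSS regardless of strand; flank windows are strand-aware relative to the
#' nearest gene: 2-10 kb upstream is 5' proximal, 10-100 kb upstream 5'
#' distal, 0-10 kb downstream 3' proximal, 10-100 kb downstream 3' distal.
#' Positions more than `desert_min` bp from every gene are gene desert.
#' With an empty gene set everything is gene desert. Ties in the
#' nearest-gene lookup go to the smaller distance, then input order.
#'
#' @param x Data frame with columns `chrom` and `pos` (0-based).
#' @param genes Gene-model tibble; unstranded genes are treated as `+` with a
#'   warning.
#' @param promoter_halfwidth Promoter half-width around the TSS (bp).
#' @param proximal_max Outer edge of the proximal flank windows (bp).
#' @param distal_max Outer edge of the distal flank windows (bp).
#' @param desert_min Minimum distance from the nearest gene for the gene
#'   desert call (bp, strict `>`).
#' @return `x` with a `category` factor column (levels
#'   [genomic_categories()]) added.
#' @export
classify_genomic_category <- function(x, genes,
                                      promoter_halfwidth = 2000,
                                      proximal_max = 10000,
                                      distal_max = 100000,
                                      desert_min = 100000) {
  stopifnot(is.data.frame(x), all(c("chrom", "pos") %in% names(x)))
  lev <- genomic_categories()
  out <- tibble::as_tibble(x)
  n <- nrow(out)
  if (n == 0) {
    out$category <- factor(character(), levels = lev)
    return(out)
  }
  if (is.null(genes) || nrow(genes) == 0) {
    out$category <- factor(rep("gene_desert", n), levels = lev)
    return(out)
  }
  genes <- tss_of(genes)
  strand <- ifelse(genes$strand %in% c("+", "-"), genes$strand, "+")

  cat <- rep(NA_character_, n)
  for (chr in unique(out$chrom)) {
    pi <- which(out$chrom == chr)
    gi <- which(genes$chrom == chr)
    if (length(gi) == 0) {
      cat[pi] <- "gene_desert"
      next
    }
    # work in 1-based closed coordinates for IRanges
    pos1 <- out$pos[pi] + 1
    q <- IRanges::IRanges(start = pos1, end = pos1)
    g <- genes[gi, ]
    gs <- strand[gi]

    prom <- IRanges::IRanges(start = pmax(g$tss + 1 - promoter_halfwidth, 1),
                             end = g$tss + 1 + promoter_halfwidth)
    in_prom <- IRanges::overlapsAny(q, prom)

    ex_start <- unlist(g$exon_starts, use.names = FALSE)
    ex_end <- unlist(g$exon_ends, use.names = FALSE)
    if (length(ex_start)) {
      exons <- IRanges::IRanges(start = ex_start + 1, end = ex_end)
      in_exon <- IRanges::overlapsAny(q, exons)
    } else {
      in_exon <- rep(FALSE, length(pi))
    }

    body <- IRanges::IRanges(start = g$start + 1, end = g$end)
    in_body <- IRanges::overlapsAny(q, body)

    # nearest gene body for flank categories; ties go to input order
    near <- IRanges::distanceToNearest(q, body, select = "all")
    hq <- S4Vectors::queryHits(near)
    hs <- S4Vectors::subjectHits(near)
    ni <- vapply(split(hs, factor(hq, levels = seq_along(pi))), min, integer(1))
    flank <- rep(NA_character_, length(pi))
    p0 <- out$pos[pi]
    left_gap <- g$start[ni] - p0           # > 0 when the position is left of the gene
    right_gap <- p0 - g$end[ni] + 1        # > 0 when right of the gene
    gap <- pmax(left_gap, right_gap)       # one of the two is positive outside
    side_left <- left_gap > 0
    upstream <- (side_left & gs[ni] == "+") | (!side_left & gs[ni] == "-")
    flank[upstream & gap > promoter_halfwidth & gap <= proximal_max] <- "five_prime_proximal"
    flank[upstream & gap > proximal_max & gap <= distal_max] <- "five_prime_distal"
    flank[!upstream & gap >= 1 & gap <= proximal_max] <- "three_prime_proximal"
    flank[!upstream & gap > proximal_max & gap <= distal_max] <- "three_prime_distal"

    res <- dplyr::case_when(
      in_prom ~ "promoter",
      in_exon ~ "exon",
      in_body ~ "intron",
      !is.na(flank) ~ flank,
      gap > desert_min ~ "gene_desert",
      .default = "intergenic_other"
    )
    cat[pi] <- res
  }
  out$category <- factor(cat, levels = lev)
  out
}
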