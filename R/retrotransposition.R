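#' Reverse-complement nucleotide strings
#'
#' @param x Character vector of ACGTN sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @keywords internal
#' @noRd
kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  unique(substring(seq, seq_len(n - k + 1), k:n))
}

#' Subtract a baseline sample from structural-variant insertion calls
#'
#' Removes case insertions having a control insertion within `tolerance` bp
#' on the same chromosome -- long-read breakpoint positions jitter by tens of
#' bases, so exact-position matching would under-subtract.
#'
#' @param case,control Insertion tibbles with columns `chrom`, `pos`
#'   (1-based).
#' @param tolerance Matching window in bp (default 100).
#' @return Case tibble with baseline-matched calls removed.
#' @export
subtract_baseline_sv <- function(case, control, tolerance = 100) {
  if (tolerance < 0) stop("tolerance must be >= 0", call. = FALSE)
  case <- tibble::as_tibble(case)
  if (is.null(control) || nrow(control) == 0 || nrow(case) == 0) return(case)
  keep <- purrr::map_lgl(seq_len(nrow(case)), function(i) {
    ctrl <- control$pos[control$chrom == case$chrom[i]]
    !any(abs(ctrl - case$pos[i]) <= tolerance)
  })
  case[keep, ]
}

#' Build a k-mer index of a TE consensus library
#'
#' @param library Named character vector of consensus sequences (family name
#'   -> sequence) or a tibble with columns `family`, `sequence`.
#' @param k K-mer length.
#' @return Internal index object for [classify_insertion_family()].
#' @export
consensus_kmer_index <- function(library, k = 15) {
  if (is.data.frame(library)) {
    library <- stats::setNames(library$sequence, library$family)
  }
  if (anyDuplicated(names(library))) stop("family names must be unique", call. = FALSE)
  sets <- lapply(library, function(s) kmer_set(toupper(s), k))
  structure(list(sets = sets, lengths = nchar(library), k = k),
            class = "consensus_kmer_index")
}

#' Assign structural-variant insertions to TE families by k-mer identity
#'
#' For each insertion sequence, identity against a family is the fraction of
#' the insertion's bases covered by at least one k-mer present in that
#' family's consensus (seed-and-extend style coverage; an exact consensus
#' substring therefore scores 1 for any k up to its length, while isolated
#' substitutions cost at most `k` covered bases each). The better of the
#' forward sequence and its reverse complement is taken, which also fixes
#' the reported strand. The best-scoring family is reported when its
#' identity reaches `identity_threshold`, otherwise `"unclassified"`. Ties
#' are broken by the longer consensus, then lexicographic family name; equal
#' identities on both strands report `"+"`.
#'
#' @param calls Insertion tibble with a `sequence` column (plus `chrom`,
#'   `pos`, carried through).
#' @param library Consensus library (see [consensus_kmer_index()]), or a
#'   prebuilt index.
#' @param k K-mer length (default 15).
#' @param identity_threshold Minimum identity for a family call (default
#'   0.5).
#' @return `calls` with columns `family`, `identity`, `strand` added.
#' @export
classify_insertion_family <- function(calls, library, k = 15,
                                      identity_threshold = 0.5) {
  calls <- tibble::as_tibble(calls)
  idx <- if (inherits(library, "consensus_kmer_index")) library else
    consensus_kmer_index(library, k)
  fams <- names(idx$sets)
  if (length(fams) == 0) {
    warning("empty consensus library: all insertions unclassified")
    calls$family <- rep("unclassified", nrow(calls))
    calls$identity <- rep(NA_real_, nrow(calls))
    calls$strand <- rep(NA_character_, nrow(calls))
    return(calls)
  }
  # tie-break order: longer consensus first, then name
  ord <- order(-idx$lengths, fams)
  res <- purrr::map(calls$sequence, function(s) {
    s <- toupper(s)
    if (is.na(s) || nchar(s) < idx$k) {
      return(list(family = "unclassified", identity = NA_real_,
                  strand = NA_character_))
    }
    L <- nchar(s)
    fwd <- substring(s, seq_len(L - idx$k + 1), idx$k:L)
    rev <- substring(revcomp(s), seq_len(L - idx$k + 1), idx$k:L)
    kmer_cover <- function(shared) {
      if (!any(shared)) return(0)
      # fraction of bases under >= 1 shared k-mer, via a difference array
      delta <- integer(L + 1)
      i <- which(shared)
      delta[i] <- delta[i] + 1L
      delta[i + idx$k] <- delta[i + idx$k] - 1L
      mean(cumsum(delta[seq_len(L)]) > 0)
    }
    best <- list(family = "unclassified", identity = 0, strand = "+")
    for (i in ord) {
      set <- idx$sets[[i]]
      id_f <- kmer_cover(fwd %in% set)
      id_r <- kmer_cover(rev %in% set)
      id <- max(id_f, id_r)
      if (id > best$identity) {
        best <- list(family = fams[i], identity = id,
                     strand = if (id_f >= id_r) "+" else "-")
      }
    }
    if (best$identity < identity_threshold) {
      best$family <- "unclassified"
      best$strand <- NA_character_
    }
    best
  })
  calls$family <- purrr::map_chr(res, "family")
  calls$identity <- purrr::map_dbl(res, function(r) {
    if (is.null(r$identity)) NA_real_ else r$identity
  })
  calls$strand <- purrr::map_chr(res, function(r) {
    if (is.null(r$strand) || is.na(r$strand)) NA_character_ else r$strand
  })
  calls
}

#' Genomic-category spectrum of insertion sites
#'
#' @param calls Baseline-subtracted insertion tibble with `chrom`, `pos`
#'   (1-based).
#' @param genes Gene-model tibble.
#' @param ... Passed to [classify_genomic_category()].
#' @return Tibble with `category`, `count` and `proportion` columns;
#'   proportions sum to 1 over classified calls.
#' @export
insertion_site_spectrum <- function(calls, genes, ...) {
  calls <- tibble::as_tibble(calls)
  if (nrow(calls) == 0) {
    return(tibble::tibble(category = factor(character(),
                                            levels = genomic_categories()),
                          count = integer(), proportion = numeric()))
  }
  cls <- classify_genomic_category(
    tibble::tibble(chrom = calls$chrom, pos = calls$pos - 1), genes, ...
  )
  tab <- table(cls$category)
  tibble::tibble(category = factor(names(tab), levels = genomic_categories()),
                 count = as.integer(tab),
                 proportion = as.integer(tab) / sum(tab))
}

#' Exact two-sided test for an insertion-burden difference
#'
#' Conditional on the total number of insertion events, tests whether they
#' split between case and control as expected from the exposure ratio
#' (binomial with p = exposure_case / (exposure_case + exposure_control);
#' equal exposure by default). Two-sided by the probability-mass method.
#'
#' @param n_case,n_control Event counts (non-negative).
#' @param exposure_ratio Case:control exposure ratio (default 1).
#' @return Two-sided p-value.
#' @examples
#' insertion_burden_test(0, 10) # 2/2^10
#' @export
insertion_burden_test <- function(n_case, n_control, exposure_ratio = 1) {
  if (n_case < 0 || n_control < 0) stop("counts must be >= 0", call. = FALSE)
  n <- n_case + n_control
  if (n == 0) {
    warning("no events in either sample; p = 1")
    return(1)
  }
  p0 <- exposure_ratio / (1 + exposure_ratio)
  stats::binom.test(n_case, n, p = p0, alternative = "two.sided")$p.value
}
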