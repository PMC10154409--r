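# Fixture builders and independent oracles shared across the suite.

tiny_genome <- function() {
  genome_assembly(c("chrA", "chrB"), c(1e6, 2e6))
}

# one gene with explicit exon structure (0-based half-open coordinates)
make_gene <- function(id, chrom, start, end, strand = "+",
                      exon_starts = list(start), exon_ends = list(end)) {
  tibble::tibble(gene_id = id, chrom = chrom, start = start, end = end,
                 strand = strand, exon_starts = exon_starts,
                 exon_ends = exon_ends)
}

# --- independent oracles -----------------------------------------------------

# exact two-sided Fisher p by direct enumeration with binomial coefficients
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; K <- a + c
  support <- max(0, K - n):min(K, m)
  tot <- choose(m + n, K)
  probs <- choose(m, support) * choose(n, K - support) / tot
  p_obs <- choose(m, a) * choose(n, K - a) / tot
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided binomial p (prob-mass method) by direct tail enumeration
oracle_binom_p <- function(x, n, p = 0.5) {
  probs <- choose(n, 0:n) * p^(0:n) * (1 - p)^(n - (0:n))
  min(1, sum(probs[probs <= probs[x + 1] * (1 + 1e-7)]))
}

# brute-force per-position genomic-category classifier: linear scan over all
# genes, no interval index; mirrors the documented precedence rules only
oracle_category <- function(pos, chrom, genes,
                            prom = 2000, prox = 10000, dist = 100000,
                            desert = 100000) {
  if (is.null(genes) || nrow(genes) == 0) return("gene_desert")
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0) return("gene_desert")
  strand <- ifelse(g$strand %in% c("+", "-"), g$strand, "+")
  tss <- ifelse(strand == "+", g$start, g$end - 1)
  if (any(abs(pos - tss) <= prom)) return("promoter")
  in_exon <- FALSE; in_body <- FALSE
  for (i in seq_len(nrow(g))) {
    if (pos >= g$start[i] && pos < g$end[i]) {
      in_body <- TRUE
      es <- g$exon_starts[[i]]; ee <- g$exon_ends[[i]]
      if (any(pos >= es & pos < ee)) in_exon <- TRUE
    }
  }
  if (in_exon) return("exon")
  if (in_body) return("intron")
  gaps <- pmax(g$start - pos, pos - g$end + 1)
  ni <- which.min(gaps)  # first minimal gap = input order tie-break
  gap <- gaps[ni]
  upstream <- (g$start[ni] - pos > 0) == (strand[ni] == "+")
  if (upstream) {
    if (gap > prom && gap <= prox) return("five_prime_proximal")
    if (gap > prox && gap <= dist) return("five_prime_distal")
  } else {
    if (gap >= 1 && gap <= prox) return("three_prime_proximal")
    if (gap > prox && gap <= dist) return("three_prime_distal")
  }
  if (gap > desert) return("gene_desert")
  "intergenic_other"
}

# random gene set on a genome, used by partition/oracle tests
random_genes <- function(genome, n_per_chrom = 30, seed = 42) {
  set.seed(seed)
  dplyr::bind_rows(lapply(seq_len(nrow(genome)), function(i) {
    len <- genome$length[i]
    start <- sort(sample.int(len - 40000, n_per_chrom))
    glen <- sample(5000:30000, n_per_chrom, replace = TRUE)
    end <- pmin(start + glen, len)
    mid <- floor((start + end) / 2)
    make_gene(paste0("g", genome$chrom[i], "_", seq_len(n_per_chrom)),
              genome$chrom[i], start, end,
              strand = sample(c("+", "-"), n_per_chrom, replace = TRUE),
              exon_starts = purrr::map2(start, mid, ~c(.x, .y)),
              exon_ends = purrr::map2(mid, end, ~c(.x - 1000, .y)))
  }))
}

# uniform-length genome where a 500 kb zone is exactly 10% of every chromosome
calibration_genome_lengths <- function() {
  stats::setNames(rep(10e6, 5), paste0("chr", 1:5))
}

calibration_te_family <- function(n_copies = 2000L) {
  tibble::tibble(family = "L1MdTf", superfamily = "LINE",
                 n_copies = n_copies, consensus_length = 6000L)
}
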