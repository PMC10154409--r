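#' Derive a reproducible sub-seed
#'
#' Each sub-simulator draws from its own stream derived from the master seed
#' and a stream name, so adding one generator never perturbs the others.
#'
#' @keywords internal
#' @noRd
derive_seed <- function(seed, name) {
  strtoi(substr(rlang::hash(list(as.integer(seed), name)), 1, 7), base = 16L)
}

#' @keywords internal
#' @noRd
with_sub_seed <- function(seed, name, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, name))
  force(code)
}

#' Scale a genomic distance threshold to a miniature genome
#'
#' The study's distance parameters (1 Mb subtelomere threshold, 100 kb Hi-C
#' terminal exclusion, 5-60 Mb window ladder) are defined on the mouse
#' genome, whose median chromosome is roughly 130 Mb. On the miniature
#' synthetic genome they are scaled by the ratio of the assembly's median
#' chromosome length to that reference, so the proportions of the analysis
#' are preserved.
#'
#' @param bp Distance(s) on the reference genome, in bp.
#' @param genome Miniature assembly tibble.
#' @param reference_median Reference median chromosome length (default
#'   130 Mb, mouse).
#' @return Scaled distance(s) in bp.
#' @export
scale_threshold <- function(bp, genome, reference_median = 130e6) {
  bp * stats::median(genome$length) / reference_median
}

#' Default TE family table for the simulator
#'
#' @return Tibble with columns `family`, `superfamily`, `n_copies`,
#'   `consensus_length`.
#' @export
default_te_families <- function() {
  tibble::tribble(
    ~family,   ~superfamily, ~n_copies, ~consensus_length,
    "L1MdTf",  "LINE",       1200L,     6000L,
    "L1MdA",   "LINE",       1000L,     6000L,
    "L1MdGf",  "LINE",        800L,     6000L,
    "IAPEz",   "LTR",         900L,     5000L,
    "MERVL",   "LTR",         700L,     5000L,
    "ERVB4",   "LTR",         500L,     3000L,
    "B1",      "SINE",       1500L,      150L,
    "B2",      "SINE",       1200L,      190L
  )
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator with its default. The
#' defaults describe a miniature genome (5 chromosomes, 5-20 Mb) on which
#' every distance parameter of the analyses is scaled by
#' [scale_threshold()]; see the methods vignette for the reasoning behind
#' each value.
#'
#' @param seed Master seed; every sub-simulator derives its own stream from
#'   it.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param gene_density Genes per Mb.
#' @param te_families TE family table (see [default_te_families()]).
#' @param te_zone_bp Subtelomeric zone used for planting positional bias;
#'   default is the scaled 1 Mb study threshold.
#' @param te_bias Telomere-proximity placement bias rho (>= 1) of TE copies.
#' @param de_up_rate,de_down_rate Baseline per-instance probability of an
#'   up/down DE label.
#' @param de_enrichment_factor Multiplier on the up-label probability for
#'   subtelomeric instances (1 = positional null).
#' @param expressed_fraction Fraction of unlabeled instances passing the
#'   >= 5 unique-read coverage filter.
#' @param n_reads,read_length,telomeric_fraction,read_substitution_rate
#'   ChIP-read simulation: number of reads, their length, the fraction that
#'   are telomeric repeat, and the per-base substitution rate applied to
#'   telomeric reads.
#' @param n_pairs,pair_alpha,pair_beta,pair_trans_fraction,pair_zone_bp
#'   Hi-C valid-pair simulation: pair count, cis distance-decay exponent,
#'   subtelomeric anchor boost beta (>= 1), trans-contact fraction, and the
#'   boosted arm-end zone width (default the scaled 5 Mb ladder window).
#' @param n_shared_variants,n_case_variants Variant counts: baseline calls
#'   present in both samples, and case-specific calls.
#' @param variant_category_weights Named weights over
#'   [genomic_categories()] for placing case-specific variants.
#' @param n_case_insertions,n_control_insertions Insertion-call counts.
#' @param insertion_family_mix Named weights over consensus families for
#'   case/control insertions.
#' @param insertion_substitution_rate Per-base substitution rate applied to
#'   insertion sequences cut from the consensus.
#' @param insertion_length_range Insertion length range (bp).
#' @return A `sim_config` list.
#' @export
sim_config <- function(
    seed = 1,
    chrom_lengths = c(chr1 = 20e6, chr2 = 16e6, chr3 = 12e6, chr4 = 9e6,
                      chr5 = 6e6),
    gene_density = 8,
    te_families = default_te_families(),
    te_zone_bp = NULL,
    te_bias = 1,
    de_up_rate = 0.05,
    de_down_rate = 0.05,
    de_enrichment_factor = 5,
    expressed_fraction = 0.8,
    n_reads = 5e4,
    read_length = 125,
    telomeric_fraction = 0.003,
    read_substitution_rate = 0,
    n_pairs = 5e4,
    pair_alpha = 1,
    pair_beta = 2,
    pair_trans_fraction = 0.1,
    pair_zone_bp = NULL,
    n_shared_variants = 300,
    n_case_variants = 500,
    variant_category_weights = c(promoter = 0.10, five_prime_proximal = 0.08,
                                 five_prime_distal = 0.15, exon = 0.12,
                                 intron = 0.35, three_prime_proximal = 0.08,
                                 three_prime_distal = 0.10, gene_desert = 0.02),
    n_case_insertions = 60,
    n_control_insertions = 20,
    insertion_family_mix = c(L1MdTf = 0.4, L1MdA = 0.3, L1MdGf = 0.2,
                             IAPEz = 0.1),
    insertion_substitution_rate = 0.05,
    insertion_length_range = c(200, 3000)) {
  genome <- genome_assembly(names(chrom_lengths), chrom_lengths)
  if (is.null(te_zone_bp)) te_zone_bp <- scale_threshold(1e6, genome)
  if (is.null(pair_zone_bp)) pair_zone_bp <- scale_threshold(5e6, genome)
  if (te_bias < 1 || pair_beta < 1) stop("bias factors must be >= 1", call. = FALSE)
  cfg <- as.list(environment())
  cfg$genome <- genome
  structure(cfg, class = "sim_config")
}

#' @keywords internal
#' @noRd
random_dna <- function(n, length) {
  if (n == 0) return(character())
  m <- matrix(c("A", "C", "G", "T")[sample.int(4, n * length, replace = TRUE)],
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' @keywords internal
#' @noRd
mutate_sequences <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(stats::runif(n) < rate)
    if (length(hit) == 0) return(s)
    ch <- strsplit(s, "")[[1]]
    ch[hit] <- vapply(ch[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, "")
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Draw positions with a subtelomeric placement bias
#'
#' With probability `rho * f / (rho * f + 1 - f)` (f = subtelomeric fraction
#' of the chromosome) a position falls uniformly inside the two end zones,
#' otherwise uniformly in the interior; `rho = 1` reduces to the uniform
#' distribution over the chromosome.
#'
#' @keywords internal
#' @noRd
draw_biased_positions <- function(n, len, zone_bp, rho) {
  zone_bp <- min(zone_bp, len / 2)
  f <- 2 * zone_bp / len
  p_zone <- rho * f / (rho * f + (1 - f))
  in_zone <- stats::runif(n) < p_zone
  pos <- numeric(n)
  nz <- sum(in_zone)
  if (nz) {
    left <- stats::runif(nz) < 0.5
    u <- floor(stats::runif(nz) * zone_bp)
    pos[in_zone] <- ifelse(left, u, len - 1 - u)
  }
  if (n - nz) {
    pos[!in_zone] <- floor(zone_bp + stats::runif(n - nz) * (len - 2 * zone_bp))
  }
  pos
}

#' Simulate the genome: gene models and TE instance annotation
#'
#' Genes are placed uniformly and non-overlappingly with random exon
#' structure; TE copies of each family are placed with the configured
#' telomere-proximity bias (see [sim_config()]).
#'
#' @param config A [sim_config()].
#' @return List with `genome` (assembly tibble), `genes` (gene-model
#'   tibble), `te_instances` (instance tibble with `instance_id`, locus,
#'   `family`, `superfamily`), and `truth` (per-instance subtelomeric flag
#'   at the planting zone).
#' @export
simulate_genome <- function(config) {
  genome <- config$genome
  genes <- with_sub_seed(config$seed, "genes", {
    rows <- lapply(seq_len(nrow(genome)), function(i) {
      len <- genome$length[i]
      n_genes <- max(0L, round(config$gene_density * len / 1e6))
      if (n_genes == 0) return(NULL)
      glen <- round(stats::runif(n_genes, 5000, 30000))
      start <- sort(floor(stats::runif(n_genes) * (len - max(glen))))
      # greedy removal of overlaps keeps placement uniform enough
      keep <- rep(TRUE, n_genes)
      last_end <- -1
      for (j in seq_len(n_genes)) {
        if (start[j] <= last_end) keep[j] <- FALSE else last_end <- start[j] + glen[j]
      }
      start <- start[keep]; glen <- glen[keep]
      n <- length(start)
      if (n == 0) return(NULL)
      ex <- lapply(seq_len(n), function(j) {
        n_ex <- sample(2:8, 1)
        # 2*n_ex - 2 interior boundaries alternate exon/intron from the 5' end
        cuts <- sort(sample(seq_len(glen[j] - 1), 2 * n_ex - 2))
        bounds <- c(0, cuts, glen[j])
        es <- bounds[seq(1, length(bounds) - 1, by = 2)]
        ee <- bounds[seq(2, length(bounds), by = 2)]
        list(starts = start[j] + es, ends = start[j] + ee)
      })
      tibble::tibble(
        gene_id = paste0("gene_", genome$chrom[i], "_", seq_len(n)),
        chrom = genome$chrom[i], start = start, end = start + glen,
        strand = sample(c("+", "-"), n, replace = TRUE),
        exon_starts = lapply(ex, `[[`, "starts"),
        exon_ends = lapply(ex, `[[`, "ends")
      )
    })
    dplyr::bind_rows(rows)
  })
  te <- with_sub_seed(config$seed, "te", {
    fam <- config$te_families
    rows <- lapply(seq_len(nrow(fam)), function(i) {
      n <- fam$n_copies[i]
      if (n == 0) return(NULL)
      chrom <- sample(genome$chrom, n, replace = TRUE,
                      prob = genome$length / sum(genome$length))
      pos <- numeric(n)
      for (chr in unique(chrom)) {
        ci <- chrom == chr
        pos[ci] <- draw_biased_positions(sum(ci),
                                         genome$length[genome$chrom == chr],
                                         config$te_zone_bp, config$te_bias)
      }
      cl <- fam$consensus_length[i]
      width <- round(stats::runif(n, min(300, cl), min(6000, cl)))
      tibble::tibble(
        family = fam$family[i], superfamily = fam$superfamily[i],
        chrom = chrom, start = pos,
        end = pmin(pos + width,
                   genome$length[match(chrom, genome$chrom)]),
        strand = sample(c("+", "-"), n, replace = TRUE)
      )
    })
    empty <- tibble::tibble(family = character(), superfamily = character(),
                            chrom = character(), start = numeric(),
                            end = numeric(), strand = character())
    out <- dplyr::bind_rows(empty, rows)
    out$instance_id <- paste0("te_", seq_len(nrow(out)))
    dplyr::relocate(out, "instance_id")
  })
  truth_sub <- is_subtelomeric(te, genome, config$te_zone_bp)
  list(genome = genome, genes = genes, te_instances = te,
       truth = list(te_subtelomeric = stats::setNames(truth_sub, te$instance_id)))
}

#' Simulate a differential TE-instance table with planted enrichment
#'
#' Up-label probability for instances inside the planting zone is the
#' baseline rate times the enrichment factor (capped at 1, with a warning);
#' down labels carry no positional bias. Labeled instances receive log2 fold
#' changes and p-values that pass the study's filters (|FC| > 1.5,
#' p < 0.05) and are always expressed (>= 5 unique reads); unlabeled
#' instances fail the fold-change/p filters and are expressed with
#' probability `expressed_fraction`.
#'
#' @param sim Output of [simulate_genome()].
#' @param config A [sim_config()].
#' @return List with `de_table` (tibble: `instance_id`, `family`,
#'   `superfamily`, `chrom`, `start`, `end`, `log2fc`, `pvalue`,
#'   `unique_reads`) and `truth` (planted label per instance).
#' @export
simulate_de_table <- function(sim, config) {
  te <- sim$te_instances
  genome <- sim$genome
  sub <- is_subtelomeric(te, genome, config$te_zone_bp)
  with_sub_seed(config$seed, "de", {
    p_up <- config$de_up_rate * ifelse(sub, config$de_enrichment_factor, 1)
    if (any(p_up > 1)) {
      warning("up-label probability capped at 1")
      p_up <- pmin(p_up, 1)
    }
    u <- stats::runif(nrow(te))
    label <- dplyr::case_when(
      u < p_up ~ "up",
      u < p_up + config$de_down_rate ~ "down",
      .default = "none"
    )
    n <- nrow(te)
    log2fc <- stats::runif(n, -0.4, 0.4)                 # fails |FC| > 1.5
    pvalue <- stats::runif(n, 0.05, 1)
    sgn <- ifelse(label == "up", 1, -1)
    hit <- label != "none"
    log2fc[hit] <- sgn[hit] * stats::runif(sum(hit), log2(1.5) + 0.05, 3)
    pvalue[hit] <- stats::runif(sum(hit), 1e-8, 0.049)
    unique_reads <- ifelse(stats::runif(n) < config$expressed_fraction,
                           5L + stats::rpois(n, 30), sample(0:4, n, replace = TRUE))
    unique_reads[hit] <- 5L + stats::rpois(sum(hit), 30)
    de_table <- tibble::tibble(
      instance_id = te$instance_id, family = te$family,
      superfamily = te$superfamily, chrom = te$chrom, start = te$start,
      end = te$end, log2fc = log2fc, pvalue = pvalue,
      unique_reads = as.integer(unique_reads)
    )
    list(de_table = de_table,
         truth = list(de_label = stats::setNames(label, te$instance_id)))
  })
}

#' Simulate ChIP reads with a known telomeric fraction
#'
#' Telomeric reads are phase-randomised `(TTAGGG)n` (half of them reverse
#' complemented) with the configured per-base substitution rate; background
#' reads are uniform random sequence.
#'
#' @param config A [sim_config()].
#' @return List with `reads` (tibble: `read_id`, `sequence`) and `truth`
#'   (logical vector of true telomeric labels).
#' @export
simulate_reads <- function(config) {
  with_sub_seed(config$seed, "reads", {
    n <- config$n_reads
    L <- config$read_length
    telo <- stats::runif(n) < config$telomeric_fraction
    seqs <- character(n)
    nt <- sum(telo)
    if (nt) {
      unit <- "TTAGGG"
      tract <- strrep(unit, ceiling((L + nchar(unit)) / nchar(unit)))
      off <- sample.int(nchar(unit), nt, replace = TRUE)
      s <- substring(tract, off, off + L - 1)
      s <- mutate_sequences(s, config$read_substitution_rate)
      flip <- stats::runif(nt) < 0.5
      s[flip] <- revcomp(s[flip])
      seqs[telo] <- s
    }
    seqs[!telo] <- random_dna(n - nt, L)
    list(reads = tibble::tibble(read_id = sprintf("read_%06d", seq_len(n)),
                                sequence = seqs),
         truth = list(telomeric = telo))
  })
}

#' @keywords internal
#' @noRd
power_law_distances <- function(n, alpha, s_min, s_max) {
  u <- stats::runif(n)
  if (abs(alpha - 1) < 1e-9) {
    s_min * (s_max / s_min)^u
  } else {
    (s_min^(1 - alpha) + u * (s_max^(1 - alpha) - s_min^(1 - alpha)))^(1 / (1 - alpha))
  }
}

#' @keywords internal
#' @noRd
draw_boosted_anchor <- function(n, len, zone_bp, beta) {
  zone_bp <- min(zone_bp, len / 2)
  f <- 2 * zone_bp / len
  q <- min(beta * f, 1)
  in_zone <- stats::runif(n) < q
  pos <- numeric(n)
  nz <- sum(in_zone)
  if (nz) {
    left <- stats::runif(nz) < 0.5
    u <- floor(stats::runif(nz) * zone_bp)
    pos[in_zone] <- ifelse(left, u, len - 1 - u)
  }
  if (n - nz) {
    pos[!in_zone] <- floor(zone_bp + stats::runif(n - nz) * (len - 2 * zone_bp))
  }
  pos
}

#' @keywords internal
#' @noRd
draw_decay_pairs <- function(n, genome, alpha) {
  chrom <- sample(genome$chrom, n, replace = TRUE,
                  prob = genome$length / sum(genome$length))
  len <- genome$length[match(chrom, genome$chrom)]
  pos1 <- floor(stats::runif(n) * len)
  s <- power_law_distances(n, alpha, 1000, pmax(2000, len / 2))
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  pos2 <- pos1 + sgn * round(s)
  oob <- pos2 < 0 | pos2 >= len
  pos2[oob] <- pos1[oob] - (sgn * round(s))[oob]
  pos2 <- pmin(pmax(pos2, 0), len - 1)
  tibble::tibble(chrom = chrom, len = len, pos1 = pos1, pos2 = pos2)
}

#' Simulate Hi-C valid pairs from a distance-decay contact model
#'
#' Cis pair distances follow a truncated power law with exponent `alpha`.
#' The subtelomeric boost `beta` multiplies the probability that a cis
#' contact involves an arm-end zone: candidate pairs are drawn from the
#' pure decay model with uniform anchors, and the emitted sample is
#' composed so that the fraction of pairs touching a zone is exactly
#' `beta` times the decay model's baseline fraction. A `beta = 2` run
#' against a `beta = 1` run therefore shows a 2-fold zone contact rate up
#' to sampling noise. A configurable fraction of pairs is trans, with both
#' ends drawn independently (per-end zone probability `min(beta * f, 1)`,
#' `f` the zone fraction).
#'
#' @param config A [sim_config()].
#' @param genome Assembly tibble (defaults to the config's genome).
#' @return List with `pairs` (valid-pair tibble as from
#'   [read_valid_pairs()]) and `truth` (per-pair trans flag and zone-touch
#'   flag).
#' @export
simulate_valid_pairs <- function(config, genome = config$genome) {
  with_sub_seed(config$seed, "pairs", {
    n <- config$n_pairs
    zone <- config$pair_zone_bp
    beta <- config$pair_beta
    trans <- stats::runif(n) < config$pair_trans_fraction
    n_trans <- sum(trans)
    n_cis <- n - n_trans

    in_zone <- function(pos, len) {
      z <- pmin(zone, len / 2)
      pos < z | pos >= len - z
    }

    chrom1 <- character(n); chrom2 <- character(n)
    pos1 <- numeric(n); pos2 <- numeric(n)
    touch <- logical(n)

    if (n_trans) {
      for (side in 1:2) {
        chr <- sample(genome$chrom, n_trans, replace = TRUE,
                      prob = genome$length / sum(genome$length))
        len <- genome$length[match(chr, genome$chrom)]
        pos <- numeric(n_trans)
        for (c2 in unique(chr)) {
          i <- which(chr == c2)
          pos[i] <- draw_boosted_anchor(length(i),
                                        genome$length[genome$chrom == c2],
                                        zone, beta)
        }
        if (side == 1) {
          chrom1[trans] <- chr; pos1[trans] <- pos
          touch[trans] <- in_zone(pos, len)
        } else {
          chrom2[trans] <- chr; pos2[trans] <- pos
          touch[trans] <- touch[trans] | in_zone(pos, len)
        }
      }
    }

    if (n_cis) {
      # oversample candidates so both strata can be filled without
      # replacement, topping up in the rare case a stratum runs short
      cand <- draw_decay_pairs(ceiling(n_cis * (1 + beta)) + 1000, genome,
                               config$pair_alpha)
      cand_touch <- in_zone(cand$pos1, cand$len) | in_zone(cand$pos2, cand$len)
      f0 <- mean(cand_touch)
      n_touch <- round(min(beta * f0, 1) * n_cis)
      while (sum(cand_touch) < n_touch || sum(!cand_touch) < n_cis - n_touch) {
        extra <- draw_decay_pairs(n_cis, genome, config$pair_alpha)
        cand <- dplyr::bind_rows(cand, extra)
        cand_touch <- c(cand_touch,
                        in_zone(extra$pos1, extra$len) |
                          in_zone(extra$pos2, extra$len))
      }
      sel <- c(utils::head(which(cand_touch), n_touch),
               utils::head(which(!cand_touch), n_cis - n_touch))
      ci <- which(!trans)
      chrom1[ci] <- cand$chrom[sel]; chrom2[ci] <- cand$chrom[sel]
      pos1[ci] <- cand$pos1[sel]; pos2[ci] <- cand$pos2[sel]
      touch[ci] <- cand_touch[sel]
    }

    pairs <- tibble::tibble(
      read_id = sprintf("pair_%07d", seq_len(n)),
      chrom1 = chrom1, pos1 = pos1 + 1,
      strand1 = sample(c("+", "-"), n, replace = TRUE),
      chrom2 = chrom2, pos2 = pos2 + 1,
      strand2 = sample(c("+", "-"), n, replace = TRUE)
    )
    list(pairs = pairs,
         truth = list(trans = trans, touches_zone = touch))
  })
}

#' Simulate a TE consensus library (synthetic sequences)
#'
#' Random sequences under the configured family names; no real consensus
#' content is reproduced -- the library only needs to be internally
#' consistent with the simulated insertions.
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `family`, `superfamily`, `sequence`.
#' @export
simulate_consensus_library <- function(config) {
  with_sub_seed(config$seed, "consensus", {
    fam <- config$te_families
    seqs <- vapply(fam$consensus_length, function(L) random_dna(1, L), "")
    tibble::tibble(family = fam$family, superfamily = fam$superfamily,
                   sequence = seqs)
  })
}

#' Simulate paired case/control variant calls and TE insertions
#'
#' Shared baseline variants appear in both samples; case-specific variants
#' are placed according to the configured genomic-category weights
#' (normalised with a warning if they do not sum to 1). Insertion sequences
#' are cut from the consensus library with substitutions applied and half of
#' them reverse complemented.
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_genome()].
#' @param library Consensus library from [simulate_consensus_library()].
#' @return List with `variants_case`, `variants_control` (variant tibbles),
#'   `insertions_case`, `insertions_control` (insertion tibbles with
#'   `sequence`), and `truth` (planted categories and families).
#' @export
simulate_variants_and_insertions <- function(config, sim, library) {
  genome <- sim$genome
  genes <- sim$genes
  w <- config$variant_category_weights
  if (abs(sum(w) - 1) > 1e-8) {
    warning("variant category weights normalised to sum to 1")
    w <- w / sum(w)
  }
  with_sub_seed(config$seed, "variants", {
    nt <- c("A", "C", "G", "T")
    rand_variants <- function(chrom, pos0, id_prefix) {
      n <- length(pos0)
      if (n == 0) {
        return(tibble::tibble(chrom = character(), pos = numeric(),
                              ref = character(), alt = character(),
                              vtype = character(), id = character()))
      }
      is_snv <- stats::runif(n) < 0.8
      ref <- sample(nt, n, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1), "")
      ins <- !is_snv & stats::runif(n) < 0.5
      alt[ins] <- paste0(ref[ins], random_dna(sum(ins), 3))
      del <- !is_snv & !ins
      ref[del] <- paste0(ref[del], random_dna(sum(del), 3))
      alt[del] <- substr(ref[del], 1, 1)
      tibble::tibble(chrom = chrom, pos = pos0 + 1, ref = ref, alt = alt,
                     vtype = ifelse(is_snv, "SNV", "indel"),
                     id = paste0(id_prefix, seq_len(n)))
    }
    # shared baseline: uniform positions
    n_sh <- config$n_shared_variants
    sh_chrom <- sample(genome$chrom, n_sh, replace = TRUE,
                       prob = genome$length / sum(genome$length))
    sh_pos <- floor(stats::runif(n_sh) *
                      genome$length[match(sh_chrom, genome$chrom)])
    shared <- rand_variants(sh_chrom, sh_pos, "shared_")

    # case-specific: category-weighted placement by batched rejection
    quota <- stats::setNames(rep(0L, length(genomic_categories())),
                             genomic_categories())
    draw <- table(factor(sample(names(w), config$n_case_variants,
                                replace = TRUE, prob = w),
                         levels = genomic_categories()))
    quota[names(draw)] <- as.integer(draw)
    got_chrom <- character(); got_pos <- numeric(); got_cat <- character()
    tries <- 0
    while (sum(quota) > 0 && tries < 400) {
      tries <- tries + 1
      m <- 20000
      b_chrom <- sample(genome$chrom, m, replace = TRUE,
                        prob = genome$length / sum(genome$length))
      b_pos <- floor(stats::runif(m) *
                       genome$length[match(b_chrom, genome$chrom)])
      cls <- classify_genomic_category(
        tibble::tibble(chrom = b_chrom, pos = b_pos), genes)$category
      for (cat in names(quota)[quota > 0]) {
        idx <- which(as.character(cls) == cat)
        take <- utils::head(idx, quota[cat])
        if (length(take)) {
          got_chrom <- c(got_chrom, b_chrom[take])
          got_pos <- c(got_pos, b_pos[take])
          got_cat <- c(got_cat, rep(cat, length(take)))
          quota[cat] <- quota[cat] - length(take)
        }
      }
    }
    if (sum(quota) > 0) {
      stop("could not place variants in categories: ",
           paste(names(quota)[quota > 0], collapse = ", "), call. = FALSE)
    }
    case_specific <- rand_variants(got_chrom, got_pos, "case_")

    # insertions cut from the consensus library
    mix <- config$insertion_family_mix
    mix <- mix / sum(mix)
    cons <- stats::setNames(library$sequence, library$family)
    make_ins <- function(n, prefix) {
      if (n == 0) {
        return(list(calls = tibble::tibble(chrom = character(), pos = numeric(),
                                           sequence = character(),
                                           id = character()),
                    family = character()))
      }
      fam <- sample(names(mix), n, replace = TRUE, prob = mix)
      lo <- config$insertion_length_range[1]
      hi <- config$insertion_length_range[2]
      seqs <- vapply(fam, function(f) {
        cl <- nchar(cons[[f]])
        L <- round(stats::runif(1, lo, min(hi, cl)))
        s0 <- sample.int(cl - L + 1, 1)
        substr(cons[[f]], s0, s0 + L - 1)
      }, "", USE.NAMES = FALSE)
      seqs <- mutate_sequences(seqs, config$insertion_substitution_rate)
      flip <- stats::runif(n) < 0.5
      seqs[flip] <- revcomp(seqs[flip])
      chrom <- sample(genome$chrom, n, replace = TRUE,
                      prob = genome$length / sum(genome$length))
      pos <- floor(stats::runif(n) * genome$length[match(chrom, genome$chrom)]) + 1
      list(calls = tibble::tibble(chrom = chrom, pos = pos, sequence = seqs,
                                  id = paste0(prefix, seq_len(n))),
           family = fam)
    }
    ins_case <- make_ins(config$n_case_insertions, "ins_case_")
    ins_ctrl <- make_ins(config$n_control_insertions, "ins_ctrl_")

    list(
      variants_case = dplyr::bind_rows(shared, case_specific),
      variants_control = shared,
      insertions_case = ins_case$calls,
      insertions_control = ins_ctrl$calls,
      truth = list(case_variant_category = stats::setNames(got_cat,
                                                           case_specific$id),
                   case_insertion_family = stats::setNames(ins_case$family,
                                                           ins_case$calls$id),
                   control_insertion_family = stats::setNames(ins_ctrl$family,
                                                              ins_ctrl$calls$id))
    )
  })
}

#' Simulate a complete dataset
#'
#' Runs every sub-simulator under its own seed stream and collects the
#' outputs with their ground truth; [write_simulation()] serialises the
#' result to a self-contained directory.
#'
#' @param config A [sim_config()].
#' @return A `sim_dataset` list: `config`, `genome`, `genes`,
#'   `te_instances`, `de_table`, `reads`, `pairs`, `library`,
#'   `variants_case`, `variants_control`, `insertions_case`,
#'   `insertions_control`, `truth`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  sim <- simulate_genome(config)
  de <- simulate_de_table(sim, config)
  rd <- simulate_reads(config)
  vp <- simulate_valid_pairs(config)
  lib <- simulate_consensus_library(config)
  vi <- simulate_variants_and_insertions(config, sim, lib)
  structure(list(
    config = config,
    genome = sim$genome, genes = sim$genes, te_instances = sim$te_instances,
    de_table = de$de_table, reads = rd$reads, pairs = vp$pairs,
    library = lib,
    variants_case = vi$variants_case, variants_control = vi$variants_control,
    insertions_case = vi$insertions_case,
    insertions_control = vi$insertions_control,
    truth = c(sim$truth, de$truth, rd$truth,
              list(pair_trans = vp$truth$trans,
                   pair_touches_zone = vp$truth$touches_zone),
              vi$truth)
  ), class = "sim_dataset")
}
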