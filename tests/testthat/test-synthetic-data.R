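test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- sim_config(seed = 99, n_reads = 500, n_pairs = 1000,
                    n_case_variants = 50, n_shared_variants = 20,
                    n_case_insertions = 10, n_control_insertions = 5)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  for (nm in c("genes", "te_instances", "de_table", "reads", "pairs",
               "variants_case", "insertions_case")) {
    expect_identical(a[[nm]], b[[nm]], label = nm)
  }
  expect_identical(a$truth, b$truth)
})

test_that("sub-simulators draw from independent streams", {
  base <- sim_config(seed = 99, n_reads = 500, n_pairs = 1000)
  more_reads <- sim_config(seed = 99, n_reads = 800, n_pairs = 1000)
  expect_identical(simulate_valid_pairs(base)$pairs,
                   simulate_valid_pairs(more_reads)$pairs)
  expect_identical(simulate_genome(base)$te_instances,
                   simulate_genome(more_reads)$te_instances)
})

test_that("TE placement follows the subtelomeric mixture arithmetic", {
  lens <- calibration_genome_lengths()      # 500 kb zone = 10% everywhere
  fam <- calibration_te_family(20000L)
  # rho = 5, f = 0.1: expected zone fraction 5*0.1 / (5*0.1 + 0.9) = 35.7%
  cfg <- sim_config(seed = 51, chrom_lengths = lens, te_zone_bp = 5e5,
                    gene_density = 0, te_families = fam, te_bias = 5)
  sim <- simulate_genome(cfg)
  frac <- mean(sim$truth$te_subtelomeric)
  p <- 5 * 0.1 / (5 * 0.1 + 0.9)
  se <- sqrt(p * (1 - p) / 20000)
  expect_lt(abs(frac - p), 3 * se)
  # rho = 1 reduces to the uniform fraction
  cfg1 <- sim_config(seed = 52, chrom_lengths = lens, te_zone_bp = 5e5,
                     gene_density = 0, te_families = fam, te_bias = 1)
  frac1 <- mean(simulate_genome(cfg1)$truth$te_subtelomeric)
  expect_lt(abs(frac1 - 0.1), 3 * sqrt(0.1 * 0.9 / 20000))
})

test_that("zero TE copies give an empty annotation", {
  fam <- calibration_te_family(0L)
  cfg <- sim_config(seed = 53, te_families = fam, gene_density = 0)
  expect_equal(nrow(simulate_genome(cfg)$te_instances), 0)
})

test_that("planted DE labels follow the enrichment factor", {
  lens <- calibration_genome_lengths()
  cfg <- sim_config(seed = 54, chrom_lengths = lens, te_zone_bp = 5e5,
                    gene_density = 0, te_families = calibration_te_family(20000L),
                    de_up_rate = 0.02, de_enrichment_factor = 5)
  sim <- simulate_genome(cfg)
  de <- simulate_de_table(sim, cfg)
  up <- de$truth$de_label == "up"
  sub <- sim$truth$te_subtelomeric
  # subtelomeric up-rate = factor x baseline = 0.10; elsewhere 0.02
  expect_lt(abs(mean(up[sub]) - 0.10), 3 * sqrt(0.1 * 0.9 / sum(sub)))
  expect_lt(abs(mean(up[!sub]) - 0.02), 3 * sqrt(0.02 * 0.98 / sum(!sub)))
  # labeled instances pass the study filters, unlabeled fail them
  lab <- de$truth$de_label[de$de_table$instance_id]
  passes <- abs(de$de_table$log2fc) > log2(1.5) & de$de_table$pvalue < 0.05
  expect_true(all(passes[lab != "none"]))
  expect_true(all(!passes[lab == "none"]))
})

test_that("telomeric fraction zero yields no telomeric reads, and labels are exact", {
  rd0 <- simulate_reads(sim_config(seed = 55, n_reads = 1000,
                                   telomeric_fraction = 0))
  expect_equal(sum(rd0$truth$telomeric), 0)
  rd <- simulate_reads(sim_config(seed = 56, n_reads = 5000,
                                  telomeric_fraction = 0.02,
                                  read_substitution_rate = 0))
  expect_equal(is_telomeric_read(rd$reads$sequence), rd$truth$telomeric)
})

test_that("trans fraction zero keeps all pairs intra-chromosomal", {
  vp <- simulate_valid_pairs(sim_config(seed = 57, n_pairs = 2000,
                                        pair_trans_fraction = 0))
  expect_true(all(vp$pairs$chrom1 == vp$pairs$chrom2))
})

test_that("zero case-specific variants subtract to an empty set", {
  cfg <- sim_config(seed = 58, n_case_variants = 0, n_shared_variants = 30,
                    n_case_insertions = 0, n_control_insertions = 0)
  sim <- simulate_genome(cfg)
  lib <- simulate_consensus_library(cfg)
  vi <- simulate_variants_and_insertions(cfg, sim, lib)
  expect_equal(nrow(subtract_baseline(vi$variants_case,
                                      vi$variants_control)), 0)
})

test_that("a written simulation round-trips through the package readers", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 59, n_reads = 200, n_pairs = 500,
                    n_case_variants = 40, n_shared_variants = 20,
                    n_case_insertions = 8, n_control_insertions = 4)
  ds <- simulate_dataset(cfg)
  write_simulation(ds, dir)

  g <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  expect_equal(g, ds$genome)

  genes <- read_bed(file.path(dir, "genes.bed12"), "BED12")
  expect_equal(genes$start, ds$genes$start)
  expect_equal(genes$exon_starts, ds$genes$exon_starts)
  expect_equal(genes$exon_ends, ds$genes$exon_ends)

  te <- read_bed(file.path(dir, "te.bed"), "BED6")
  expect_equal(te$start, ds$te_instances$start)
  expect_equal(te$name, ds$te_instances$family)

  de <- read_de_table(file.path(dir, "de_table.tsv"))
  expect_equal(de, ds$de_table)

  reads <- read_sequences(file.path(dir, "reads.fastq"), "fastq")
  expect_equal(reads$sequence, ds$reads$sequence)
  expect_equal(reads$read_id, ds$reads$read_id)

  vp <- read_valid_pairs(file.path(dir, "pairs.allValidPairs"), g)
  expect_equal(vp$pos1, ds$pairs$pos1)
  expect_equal(vp$chrom2, ds$pairs$chrom2)

  vcf <- read_vcf_minimal(file.path(dir, "case.vcf"))
  expect_equal(nrow(vcf$variants), nrow(ds$variants_case))
  expect_equal(vcf$variants$pos, ds$variants_case$pos)
  expect_equal(vcf$insertions$sequence, ds$insertions_case$sequence)

  lib <- read_sequences(file.path(dir, "consensus.fa"), "fasta")
  expect_equal(lib$sequence, ds$library$sequence)

  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(length(truth$telomeric), nrow(ds$reads))
})

test_that("insertions derived from the consensus recover their family downstream", {
  cfg <- sim_config(seed = 60, n_case_insertions = 50,
                    insertion_substitution_rate = 0.05)
  sim <- simulate_genome(cfg)
  lib <- simulate_consensus_library(cfg)
  vi <- simulate_variants_and_insertions(cfg, sim, lib)
  out <- classify_insertion_family(vi$insertions_case, lib)
  expect_gte(mean(out$family == vi$truth$case_insertion_family[out$id]), 0.95)
})
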