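test_that("pure telomeric repeats are recognised on both strands and all phases", {
  expect_true(is_telomeric_read(strrep("TTAGGG", 25)))
  expect_true(is_telomeric_read(strrep("CCCTAA", 25)))
  for (off in 0:5) {
    shifted <- substr(strrep("TTAGGG", 30), off + 1, off + 150)
    expect_true(is_telomeric_read(shifted))
    expect_true(is_telomeric_read(revcomp(shifted)))
  }
})

test_that("coverage arithmetic rejects reads with short repeat tracts", {
  set.seed(31)
  tail150 <- paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE),
                   collapse = "")
  read <- paste0(strrep("TTAGGG", 10), tail150)   # 60 of 150 bp repeat
  expect_equal(telomeric_coverage(read), 0.4, tolerance = 0.05)
  expect_false(is_telomeric_read(read))           # 0.4 < default 0.7
  expect_true(is_telomeric_read(read, min_coverage_fraction = 0.3))
  expect_false(is_telomeric_read("TTAGG"))        # shorter than one unit
})

test_that("classification is reverse-complement invariant", {
  rd <- simulate_reads(sim_config(seed = 32, n_reads = 500,
                                  telomeric_fraction = 0.5,
                                  read_substitution_rate = 0.02))
  fwd <- is_telomeric_read(rd$reads$sequence, max_mismatches_per_unit = 1)
  rev <- is_telomeric_read(revcomp(rd$reads$sequence),
                           max_mismatches_per_unit = 1)
  expect_equal(fwd, rev)
})

test_that("mismatch tolerance admits per-unit substitutions", {
  # one substitution in every unit: rejected at 0 mismatches, accepted at 1
  read <- strrep("TTAGGA", 25)
  expect_false(is_telomeric_read(read))
  expect_true(is_telomeric_read(read, max_mismatches_per_unit = 1))
})

test_that("telomeric read rate normalises per million reads", {
  rd <- simulate_reads(sim_config(seed = 33, n_reads = 20000,
                                  telomeric_fraction = 0.01))
  rate <- telomeric_read_rate(rd$reads$sequence)
  expect_equal(rate$telomeric_count, sum(rd$truth$telomeric))
  expect_equal(rate$per_million,
               rate$telomeric_count / rate$total_count * 1e6)
  expect_error(telomeric_read_rate(character()), "no reads")
})

test_that("peak classification tallies are consistent and reproduce the printed percentage", {
  g <- genome_assembly(paste0("chr", 1:4), rep(100e6, 4))
  # plant 512 peaks of which exactly 200 subtelomeric and 123 of those on TEs
  set.seed(34)
  # grid placement (2 kb spacing) keeps planted peaks from overlapping each
  # other's TE annotations: 50 subtelomeric + 78 interior peaks per chromosome
  sub_slots <- seq(0, 1e6 - 2000, by = 2000)
  int_slots <- seq(2e6, 98e6, by = 2000)
  chrom <- rep(g$chrom, each = 128)
  sub <- rep(rep(c(TRUE, FALSE), c(50, 78)), 4)
  start <- as.vector(vapply(seq_len(4), function(i) {
    c(sample(sub_slots, 50), sample(int_slots, 78))
  }, numeric(128)))
  n <- length(start)
  on_te <- logical(n)
  on_te[sample(which(sub), 123)] <- TRUE
  on_te[sample(which(!sub), 80)] <- TRUE
  peaks <- tibble::tibble(chrom = chrom, start = start, end = start + 500,
                          direction = "decreased")
  te_start <- start[on_te] - 100
  te <- tibble::tibble(chrom = chrom[on_te], start = te_start,
                       end = te_start + 200)
  cls <- classify_peaks(peaks, te, g, subtelomere_threshold = 1e6)
  counts <- peak_class_counts(cls)
  expect_equal(counts$n_peaks, 512)
  expect_equal(counts$subtelomeric, 200)
  expect_equal(counts$subtelomeric_retrotransposon, 123)
  expect_equal(round(counts$subtelomeric_percent), 39)
  # 2x2 consistency
  expect_lte(counts$subtelomeric_retrotransposon,
             min(counts$on_retrotransposon, counts$subtelomeric))
  expect_equal(counts$on_retrotransposon + counts$subtelomeric -
                 counts$subtelomeric_retrotransposon + counts$other,
               counts$n_peaks)
})

test_that("a midpoint peak with no TE overlap falls in the other class", {
  g <- genome_assembly("chr1", 100e6)
  peaks <- tibble::tibble(chrom = "chr1", start = 50e6, end = 50e6 + 1000)
  cls <- classify_peaks(peaks, te_annotation = NULL, genome = g,
                        subtelomere_threshold = 1e6)
  expect_equal(peak_class_counts(cls)$other, 1)
})

test_that("metagene medians collect flanking genes by side and window", {
  peaks <- tibble::tibble(chrom = "chr1", start = 1e6, end = 1e6 + 2000,
                          direction = "decreased")
  genes <- dplyr::bind_rows(
    make_gene("a", "chr1", 1e6 - 5000, 1e6 - 1000, "+"),  # TSS 4 kb 5' of peak
    make_gene("b", "chr1", 1e6 - 9000, 1e6 - 6000, "+"),  # TSS 8 kb 5'
    make_gene("c", "chr1", 1e6 - 20000, 1e6 - 15000, "+") # TSS 19 kb 5'
  )
  genes$log2fc <- c(1, 2, 3)
  mg <- metagene_flanking_fc(peaks, genes, windows = c(10000, 50000))
  m10 <- mg[mg$side == "5prime" & mg$window == 10000, ]
  expect_equal(m10$n_genes, 2)
  expect_equal(m10$median_log2fc, 1.5)
  m50 <- mg[mg$side == "5prime" & mg$window == 50000, ]
  expect_equal(m50$n_genes, 3)
  expect_equal(m50$median_log2fc, 2)
  expect_equal(mg$n_genes[mg$side == "3prime" & mg$window == 10000], 0)
  # no peaks -> empty table
  expect_equal(nrow(metagene_flanking_fc(peaks[0, ], genes, 1000)), 0)
})

test_that("metagene is invariant to peak order and recovers a planted signal", {
  g <- genome_assembly("chr1", 50e6)
  set.seed(35)
  n_pk <- 40
  pk_start <- sort(sample(seq(2e6, 48e6, by = 1e4), n_pk))
  peaks <- tibble::tibble(chrom = "chr1", start = pk_start,
                          end = pk_start + 2000,
                          direction = sample(c("decreased", "increased"),
                                             n_pk, replace = TRUE))
  # plant +1 log2FC on genes just left of decreased peaks, 0 elsewhere
  near <- tibble::tibble(chrom = "chr1", start = pk_start - 6000,
                         end = pk_start - 2000, strand = "+",
                         gene_id = paste0("near", seq_len(n_pk)))
  near$exon_starts <- as.list(near$start)
  near$exon_ends <- as.list(near$end)
  near$log2fc <- ifelse(peaks$direction == "decreased", 1, 0)
  far_start <- pk_start - 900000
  far <- tibble::tibble(chrom = "chr1", start = far_start,
                        end = far_start + 2000, strand = "+",
                        gene_id = paste0("far", seq_len(n_pk)))
  far$exon_starts <- as.list(far$start)
  far$exon_ends <- as.list(far$end)
  far$log2fc <- 0
  genes <- dplyr::bind_rows(near, far)
  mg <- metagene_flanking_fc(peaks, genes, windows = c(10000, 2e6))
  dec_small <- mg[mg$direction == "decreased" & mg$side == "5prime" &
                    mg$window == 10000, ]
  dec_big <- mg[mg$direction == "decreased" & mg$side == "5prime" &
                  mg$window == 2e6, ]
  expect_equal(dec_small$median_log2fc, 1)
  expect_lt(dec_big$median_log2fc, dec_small$median_log2fc)
  shuffled <- metagene_flanking_fc(peaks[sample(n_pk), ], genes,
                                   windows = c(10000, 2e6))
  expect_equal(dplyr::arrange(mg, direction, side, window),
               dplyr::arrange(shuffled, direction, side, window))
})
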