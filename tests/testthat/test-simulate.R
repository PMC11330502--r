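test_that("identical config and seed give byte-identical outputs", {
  cfg <- sim_config(n_chromosome_pairs = 2L, genes_per_chromosome = 10L,
                    codons_per_gene = 20L, b_length = 6000L, seed = 5L)
  s1 <- simulate_allopolyploid(cfg)
  s2 <- simulate_allopolyploid(cfg)
  expect_identical(s1, s2)
  b1 <- simulate_b_chromosome(s1$genome, cfg)
  b2 <- simulate_b_chromosome(s2$genome, cfg)
  expect_identical(b1, b2)
  o1 <- simulate_observations(b1$genome, cfg)
  o2 <- simulate_observations(b2$genome, cfg)
  expect_identical(o1, o2)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_genome(b1$genome, d1)
  p2 <- write_genome(b2$genome, d2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("zero divergence leaves homoeologous CDS identical", {
  cfg <- sim_config(n_chromosome_pairs = 2L, genes_per_chromosome = 10L,
                    codons_per_gene = 30L, subgenome_divergence_ks = 0,
                    loss_fraction_A = 0, loss_fraction_D = 0,
                    tandem_rate = 0, seed = 9L)
  sim <- simulate_allopolyploid(cfg)
  g <- sim$genome$genes
  cds_a <- stats::setNames(g$cds[g$subgenome == "A"], g$ancestor[g$subgenome == "A"])
  cds_d <- stats::setNames(g$cds[g$subgenome == "D"], g$ancestor[g$subgenome == "D"])
  expect_identical(cds_a[names(cds_d)], cds_d)
  ks <- vapply(names(cds_a), function(a) compute_ks(cds_a[[a]], cds_d[[a]])$ks,
               numeric(1))
  expect_true(all(ks == 0))
})

test_that("gene loss is conserved and directional under asymmetric fractions", {
  cfg <- sim_config(n_chromosome_pairs = 4L, genes_per_chromosome = 500L,
                    codons_per_gene = 5L, subgenome_divergence_ks = 0.01,
                    loss_fraction_A = 0.15, loss_fraction_D = 0.10,
                    tandem_rate = 0, repeats_per_chromosome = 2L, seed = 31L)
  sim <- simulate_allopolyploid(cfg)
  truth <- sim$truth
  n <- cfg$n_chromosome_pairs * cfg$genes_per_chromosome
  retained_a <- sum(truth$syntelogs$retained_a)
  retained_d <- sum(truth$syntelogs$retained_d)
  expect_identical(retained_a + length(truth$deleted_a), n)
  expect_identical(retained_d + length(truth$deleted_d), n)
  # D loses less, so more ancestor genes survive in D than in A
  expect_gt(retained_d, retained_a)
  # genome annotation agrees with the truth tables
  g <- sim$genome$genes[!sim$genome$genes$tandem, ]
  expect_setequal(g$ancestor[g$subgenome == "A"],
                  truth$syntelogs$ancestor[truth$syntelogs$retained_a])
  expect_setequal(g$ancestor[g$subgenome == "D"],
                  truth$syntelogs$ancestor[truth$syntelogs$retained_d])
})

test_that("synonymous divergence is calibrated to the Jukes-Cantor expectation", {
  pairs <- get_ks_pairs(0.2)
  g <- get_ks_sim(0.2)$genome$genes
  cds <- stats::setNames(g$cds, g$id)
  ps <- vapply(seq_len(nrow(pairs)), function(i) {
    compute_ks(cds[[pairs$gene_a[i]]], cds[[pairs$gene_b[i]]])$ps
  }, numeric(1))
  expected <- 0.75 * (1 - exp(-4 / 3 * 0.2))
  se <- stats::sd(ps) / sqrt(length(ps))
  expect_gte(length(ps), 1000L)
  expect_lt(abs(mean(ps) - expected), 3 * se)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(loss_fraction_A = 1), "loss fractions")
  expect_error(sim_config(subgenome_divergence_ks = 3.5), "Jukes-Cantor")
  expect_error(sim_config(ploidy = 5), "ploidy")
  expect_error(sim_config(b_source_fraction = 1.2), "b_source_fraction")
  expect_error(sim_config(mean_depth = 0), "mean_depth")
})

test_that("B chromosome mosaicking respects the source fraction extremes", {
  cfg1 <- sim_config(n_chromosome_pairs = 2L, genes_per_chromosome = 15L,
                     codons_per_gene = 40L, b_source_fraction = 1,
                     b_segment_noise = 0, b_length = 9000L, seed = 13L)
  sim <- simulate_allopolyploid(cfg1)
  bs <- simulate_b_chromosome(sim$genome, cfg1)
  src <- bs$truth$b_source
  expect_identical(nrow(src), 30L)
  b <- bs$genome$chromosomes[["chrB"]]
  # every 300-bp tile is an exact copy of its recorded source
  for (i in seq_len(nrow(src))) {
    tile <- substr(b, src$b_start[i] + 1L, src$b_end[i])
    orig <- substr(sim$genome$chromosomes[[src$chrom[i]]],
                   src$start[i] + 1L, src$end[i])
    expect_identical(tile, orig)
  }

  cfg0 <- sim_config(n_chromosome_pairs = 2L, genes_per_chromosome = 15L,
                     codons_per_gene = 40L, b_source_fraction = 0,
                     b_length = 9000L, seed = 13L)
  bs0 <- simulate_b_chromosome(simulate_allopolyploid(cfg0)$genome, cfg0)
  expect_identical(nrow(bs0$truth$b_source), 0L)
  expect_identical(bs0$truth$b_source_fraction, 0)
})

test_that("allele fractions at heterozygous sites converge to 1/2 and 1/3", {
  for (pl in c(4L, 6L)) {
    cfg <- sim_config(n_chromosome_pairs = 2L, genes_per_chromosome = 30L,
                      codons_per_gene = 100L, loss_fraction_A = 0,
                      loss_fraction_D = 0, tandem_rate = 0, ploidy = pl,
                      mean_depth = 200, heterozygosity_syn = 0.02,
                      heterozygosity_nonsyn = 0.02, seed = 17L)
    obs <- simulate_observations(simulate_allopolyploid(cfg)$genome, cfg)
    total <- obs$allele_depth$ref_depth + obs$allele_depth$alt_depth
    frac <- mean(obs$allele_depth$alt_depth / total)
    target <- if (pl == 4L) 0.5 else 1 / 3
    expect_gt(nrow(obs$allele_depth), 500)
    expect_lt(abs(frac - target), 0.01)
  }
})

test_that("coverage track scales with B dosage and collapses at zero copies", {
  base <- function(bc, seed) {
    sim_config(n_chromosome_pairs = 1L, genes_per_chromosome = 10L,
               codons_per_gene = 30L, b_length = 30000L, b_copies = bc,
               mean_depth = 60, seed = seed)
  }
  cfg <- base(0L, 23L)
  bs <- simulate_b_chromosome(simulate_allopolyploid(cfg)$genome, cfg)
  obs <- simulate_observations(bs$genome, cfg)
  on_b <- obs$coverage$chrom == "chrB"
  expect_lt(mean(obs$coverage$depth[on_b]), 0.05 * cfg$mean_depth)
  expect_gt(mean(obs$coverage$depth[!on_b]), 0.9 * cfg$mean_depth)
})

test_that("genome files round-trip through FASTA/GFF3/BED", {
  cfg <- sim_config(n_chromosome_pairs = 2L, genes_per_chromosome = 10L,
                    codons_per_gene = 20L, seed = 5L)
  sim <- simulate_allopolyploid(cfg)
  d <- withr::local_tempdir()
  paths <- write_genome(sim$genome, d)
  g <- read_genome(paths["fasta"], paths["gff3"], paths["bed"])
  expect_identical(g$chromosomes, sim$genome$chromosomes)
  a <- sim$genome$genes[order(sim$genome$genes$id), ]
  b <- g$genes[order(g$genes$id), ]
  expect_identical(a$cds, b$cds)
  expect_identical(as.integer(a$start), as.integer(b$start))
  expect_identical(a$strand, b$strand)
  expect_identical(a$family, b$family)
  # masks survive as a set of intervals
  m1 <- sim$genome$masks[order(sim$genome$masks$chrom, sim$genome$masks$start), ]
  m2 <- g$masks[order(g$masks$chrom, g$masks$start), ]
  expect_identical(as.integer(m1$start), as.integer(m2$start))
  expect_identical(as.integer(m1$end), as.integer(m2$end))
})

test_that("allele-depth tables round-trip and reject multiallelic rows", {
  tab <- data.frame(chrom = c("c1", "c1", "c2"), pos = c(10L, 20L, 5L),
                    ref = c("A", "C", "G"), alt = c("G", "T,G", "A"),
                    ref_depth = c(12L, 5L, 8L), alt_depth = c(13L, 6L, 9L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_allele_depth(tab, f)
  back <- read_allele_depth(f)
  expect_identical(nrow(back), 2L)
  expect_identical(attr(back, "n_multiallelic"), 1L)
  expect_identical(back$pos, c(10L, 5L))

  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##contig=<ID=c1>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    paste("c1", "10", ".", "A", "G", ".", "PASS", ".", "AD", "12,13", sep = "\t"),
    paste("c1", "20", ".", "C", "T,G", ".", "PASS", ".", "AD", "5,6,7", sep = "\t")
  ), vcf)
  v <- read_allele_depth_vcf(vcf)
  expect_identical(nrow(v), 1L)
  expect_identical(v$ref_depth, 12L)
  expect_identical(v$alt_depth, 13L)
  expect_identical(attr(v, "n_multiallelic"), 1L)
})
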