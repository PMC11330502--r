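# a hand-built two-gene genome: one plus-strand and one minus-strand gene
mk_toy_genome <- function() {
  cds1 <- "ATGGATTGGAAA"          # M D W K
  cds2 <- "ATGTGCGGA"             # M C G, placed on the minus strand
  spacer <- "TTTTTTTTTT"
  chrom <- paste0(spacer, cds1, spacer, subgenomics:::revcomp(cds2), spacer)
  genes <- data.frame(
    id = c("gp", "gm"), chrom = "c1",
    start = c(10L, 10L + 12L + 10L),
    end = c(22L, 10L + 12L + 10L + 9L),
    strand = c("+", "-"), family = c("f1", "f2"),
    subgenome = "A", ancestor = c("gp", "gm"), tandem = FALSE,
    cds = c(cds1, cds2), stringsAsFactors = FALSE
  )
  structure(list(chromosomes = c(c1 = chrom), genes = genes,
                 masks = data.frame(chrom = character(0), start = integer(0),
                                    end = integer(0), class = character(0))),
            class = "annotated_genome")
}

test_that("codon consequences follow the genetic code, strand-aware", {
  gen <- mk_toy_genome()
  # GAT -> GAC (Asp -> Asp): third position of codon 2 in gp is chrom pos 16
  sites <- data.frame(chrom = "c1", pos = c(16L, 19L),
                      ref = c("T", "G"), alt = c("C", "A"),
                      ref_depth = c(20L, 20L), alt_depth = c(20L, 20L))
  eff <- annotate_effects(sites, gen)
  expect_identical(eff$consequence[1], "synonymous")
  expect_identical(eff$impact[1], "LOW")
  expect_false(eff$deleterious[1])
  # TGG -> TGA (Trp -> stop): nonsense, HIGH, deleterious
  expect_identical(eff$consequence[2], "nonsense")
  expect_identical(eff$impact[2], "HIGH")
  expect_true(eff$deleterious[2])

  # minus-strand gene: TGC codon, CDS position 5 sits at chrom pos 36 (G on -)
  # chrom carries the reverse complement; alt T on the chromosome is A in CDS:
  # TGC -> TAC (Cys -> Tyr) = missense
  g <- gen$genes[2, ]
  cds_off <- 4L  # 0-based offset of the middle base of codon 2
  pos <- g$end - cds_off  # 1-based genomic position of that CDS base
  ref <- subgenomics:::comp_base(substr(g$cds, cds_off + 1L, cds_off + 1L))
  site_m <- data.frame(chrom = "c1", pos = pos, ref = ref, alt = "T",
                       ref_depth = 20L, alt_depth = 20L)
  eff_m <- annotate_effects(site_m, gen)
  expect_identical(eff_m$gene, "gm")
  expect_identical(eff_m$consequence, "missense")
  expect_identical(eff_m$impact, "MODERATE")

  # intergenic site
  eff_i <- annotate_effects(data.frame(chrom = "c1", pos = 3L, ref = "T",
                                       alt = "A", ref_depth = 1L, alt_depth = 1L),
                            gen)
  expect_identical(eff_i$consequence, "intergenic")
  expect_identical(eff_i$impact, "NONE")

  # inconsistent reference allele errors out
  expect_error(
    annotate_effects(data.frame(chrom = "c1", pos = 16L, ref = "G", alt = "C",
                                ref_depth = 1L, alt_depth = 1L), gen),
    "inconsistent"
  )
})

test_that("planted variant classes are recovered without error", {
  cfg <- sim_config(n_chromosome_pairs = 2L, genes_per_chromosome = 30L,
                    codons_per_gene = 60L, heterozygosity_syn = 0.01,
                    heterozygosity_nonsyn = 0.01, seed = 61L)
  sim <- simulate_allopolyploid(cfg)
  obs <- simulate_observations(sim$genome, cfg)
  eff <- annotate_effects(obs$allele_depth, sim$genome)
  truth <- obs$truth$sites
  key <- paste(eff$chrom, eff$pos)
  tkey <- paste(truth$chrom, truth$pos)
  got <- ifelse(eff$consequence[match(tkey, key)] == "synonymous",
                "synonymous", "nonsynonymous")
  expect_gt(length(tkey), 100)
  expect_identical(got, truth$class)
})

test_that("NG86 site counting conserves total sites", {
  gen <- mk_toy_genome()
  cs <- callable_sites(gen)
  n_codons <- sum(nchar(gen$genes$cds)) / 3
  expect_equal(cs$syn_sites + cs$nonsyn_sites, 3 * n_codons, tolerance = 1e-12)
})

test_that("pi estimates are zero without variants and recover the ratio", {
  gen <- mk_toy_genome()
  empty <- annotate_effects(
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), ref_depth = integer(0), alt_depth = integer(0)),
    gen
  )
  ds <- pi_by_class(empty, gen)
  expect_identical(ds$pi_syn, 0)
  expect_identical(ds$pi_nonsyn, 0)
  expect_true(is.na(ds$ratio))
})

test_that("ratio_table reproduces printed precision", {
  rt <- ratio_table(data.frame(accession = "X", pi_nonsyn = 0.002, pi_syn = 0.002))
  expect_identical(rt$ratio, 1)
  summaries <- list(
    a = structure(list(pi_nonsyn = 0.0030001, pi_syn = 0.0060002),
                  class = "diversity_summary"),
    b = structure(list(pi_nonsyn = 0.004, pi_syn = 0.002),
                  class = "diversity_summary")
  )
  rt2 <- ratio_table(summaries)
  expect_identical(rt2$ratio, c(0.5, 2))
  expect_identical(rt2$pi_nonsyn, c(0.003, 0.004))
})
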