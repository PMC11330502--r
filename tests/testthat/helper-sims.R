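# Shared simulation fixtures, cached per test run so several test files can
# reuse the heavier ones.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}

# small genome with a strong phasing signal
cfg_phase <- function(seed = 42L, fold = 2) {
  sim_config(n_chromosome_pairs = 3L, genes_per_chromosome = 30L,
             codons_per_gene = 60L, repeats_per_chromosome = 60L,
             repeat_family_fold = fold, seed = seed)
}

# genome sized for >= 5000 heterozygous sites at depth 60
cfg_maf <- function(ploidy, seed = 42L) {
  sim_config(n_chromosome_pairs = 2L, genes_per_chromosome = 50L,
             codons_per_gene = 300L, subgenome_divergence_ks = 0.05,
             loss_fraction_A = 0, loss_fraction_D = 0, tandem_rate = 0,
             repeats_per_chromosome = 5L, ploidy = ploidy, mean_depth = 60,
             heterozygosity_syn = 0.03, heterozygosity_nonsyn = 0.03,
             seed = seed)
}

# 1000 syntelog pairs of 300 codons at a chosen divergence
cfg_ks <- function(ks_true, seed = 101L) {
  sim_config(n_chromosome_pairs = 4L, genes_per_chromosome = 250L,
             codons_per_gene = 300L, subgenome_divergence_ks = ks_true,
             loss_fraction_A = 0, loss_fraction_D = 0, tandem_rate = 0,
             repeats_per_chromosome = 5L, seed = seed)
}

get_ks_sim <- function(ks_true, seed = 101L) {
  cached(sprintf("kssim_%g_%d", ks_true, seed),
         simulate_allopolyploid(cfg_ks(ks_true, seed)))
}

get_ks_pairs <- function(ks_true, seed = 101L) {
  cached(sprintf("kspairs_%g_%d", ks_true, seed), {
    sim <- get_ks_sim(ks_true, seed)
    ga <- sim$genome$genes[sim$genome$genes$subgenome == "A", ]
    gd <- sim$genome$genes[sim$genome$genes$subgenome == "D", ]
    syntelog_ks(find_syntelogs(ga, gd), sim$genome)
  })
}

get_maf_genome <- function(ploidy) {
  cached(sprintf("mafgenome_%d", ploidy), simulate_allopolyploid(cfg_maf(ploidy)))
}

# observations for a cached MAF genome under a different observation seed
maf_mode_for_seed <- function(ploidy, seed) {
  sim <- get_maf_genome(ploidy)
  cfg <- cfg_maf(ploidy, seed = seed)
  obs <- simulate_observations(sim$genome, cfg)
  flt <- filter_sites(obs$allele_depth)
  maf_profile(flt)
}

true_labels_of <- function(truth) {
  stats::setNames(c(truth$pairing$label1, truth$pairing$label2),
                  c(truth$pairing$member1, truth$pairing$member2))
}
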