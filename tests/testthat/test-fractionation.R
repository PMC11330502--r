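test_that("retention table aggregates and validates", {
  ids <- paste0("g", 1:10)
  full <- build_retention(ids, ids, ids)
  expect_identical(full$aggregates$both, 10L)
  expect_identical(full$aggregates$a_only + full$aggregates$d_only +
                     full$aggregates$neither, 0L)
  expect_error(build_retention(ids, c(ids, "ghost"), ids), "unknown ancestor")

  part <- build_retention(ids, ids[1:6], ids[4:10])
  agg <- part$aggregates
  expect_identical(agg$both, 3L)
  expect_identical(agg$a_only, 3L)
  expect_identical(agg$d_only, 4L)
  expect_identical(agg$neither, 0L)
  expect_identical(agg$both + agg$a_only + agg$d_only + agg$neither, agg$total)
})

test_that("retention from a simulation matches the deletion truth exactly", {
  cfg <- sim_config(n_chromosome_pairs = 3L, genes_per_chromosome = 60L,
                    codons_per_gene = 10L, loss_fraction_A = 0.15,
                    loss_fraction_D = 0.10, tandem_rate = 0, seed = 33L)
  sim <- simulate_allopolyploid(cfg)
  truth <- sim$truth
  g <- sim$genome$genes
  ret <- build_retention(truth$syntelogs$ancestor,
                         g$ancestor[g$subgenome == "A"],
                         g$ancestor[g$subgenome == "D"])
  expect_identical(ret$aggregates$a_only + ret$aggregates$both +
                     length(truth$deleted_a), nrow(truth$syntelogs))
  expect_setequal(ret$table$gene[!ret$table$retained_a], truth$deleted_a)
  expect_setequal(ret$table$gene[!ret$table$retained_d], truth$deleted_d)
})

test_that("goodness-of-fit chi-square matches its closed form", {
  even <- loss_bias_test(100, 100)
  expect_identical(even$chi2, 0)
  expect_identical(even$p, 1)
  expect_error(loss_bias_test(0, 0), "zero")

  # closed form: with counts a and d, chi2 = (a - d)^2 / (a + d)
  t1 <- loss_bias_test(2367, 1921)
  expect_equal(t1$chi2, (2367 - 1921)^2 / (2367 + 1921), tolerance = 1e-12)
  expect_equal(t1$chi2, 2 * 223^2 / 2144, tolerance = 1e-12)
  expect_identical(round(t1$chi2, 2), 46.39)
  expect_equal(t1$p, stats::pchisq(t1$chi2, 1, lower.tail = FALSE),
               tolerance = 1e-15)
  # the 2x2 contingency variant is also exposed
  t2 <- loss_bias_test(2367, 1921, both = 5361)
  expect_true(t2$chi2_2x2 > 0 && t2$p_2x2 < 0.05)
})

test_that("reported p matches a quadrature oracle of the chi-square density", {
  dens <- function(x) exp(-x / 2) / sqrt(2 * pi * x)  # chi-square df = 1
  for (q in c(1, 5, 20)) {
    # counts (q, 0) give chi2 = (a - d)^2 / (a + d) = q exactly
    res <- loss_bias_test(q, 0)
    expect_equal(res$chi2, q, tolerance = 1e-12)
    oracle <- stats::integrate(dens, q, Inf, rel.tol = 1e-13)$value
    expect_lt(abs(res$p - oracle), 1e-10)
  }
})

test_that("sliding retention windows tile, bound and average correctly", {
  ids <- paste0("g", 1:120)
  anc <- data.frame(id = ids, chrom = rep(c("c1", "c2"), each = 60))
  set.seed(8)
  ra <- sample(ids, 80)
  rd <- sample(ids, 100)
  ret <- build_retention(ids, ra, rd)

  prof <- retention_windows(ret, anc, window = 20, step = 5)
  expect_true(all(prof$frac_a >= 0 & prof$frac_a <= 1))
  expect_true(all(prof$n_genes == 20 | prof$window == max(prof$window)))

  # uniform retention gives all-1 windows
  full <- build_retention(ids, ids, ids)
  pf <- retention_windows(full, anc, window = 10, step = 10)
  expect_true(all(pf$frac_a == 1) && all(pf$frac_d == 1))

  # window = chromosome size reproduces the global fraction
  pg <- retention_windows(ret, anc, window = 60, step = 60)
  expect_identical(nrow(pg), 2L)
  expect_equal(stats::weighted.mean(pg$frac_a, pg$n_genes),
               mean(ret$table$retained_a), tolerance = 1e-12)

  # non-overlapping tiling: occupancy-weighted mean equals global retention
  pt <- retention_windows(ret, anc, window = 25, step = 25)
  expect_equal(stats::weighted.mean(pt$frac_d, pt$n_genes),
               mean(ret$table$retained_d), tolerance = 1e-12)

  expect_error(retention_windows(ret, anc, window = 61), "exceeds")
  expect_error(retention_windows(ret, anc, window = 1), "at least 2")
})

test_that("biased loss shows up in more windows of the dominant subgenome", {
  cfg <- sim_config(n_chromosome_pairs = 4L, genes_per_chromosome = 120L,
                    codons_per_gene = 5L, loss_fraction_A = 0.15,
                    loss_fraction_D = 0.10, tandem_rate = 0,
                    subgenome_divergence_ks = 0.01, seed = 14L)
  sim <- simulate_allopolyploid(cfg)
  g <- sim$genome$genes
  anc <- sim$truth$syntelogs[, c("ancestor", "chrom_pair")]
  names(anc) <- c("id", "chrom")
  ret <- build_retention(anc$id, g$ancestor[g$subgenome == "A"],
                         g$ancestor[g$subgenome == "D"])
  prof <- retention_windows(ret, anc, window = 40, step = 10)
  by_chr <- tapply(prof$frac_d - prof$frac_a, prof$chrom, mean)
  expect_gte(sum(by_chr > 0), 3L)  # D dominates on most chromosomes
})
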