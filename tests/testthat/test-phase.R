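test_that("canonical k-mer counting folds reverse complements", {
  m <- count_kmers(c(chr = "AAAA"), k = 3)
  expect_identical(m$counts$kmer, "AAA")
  expect_identical(m$counts$count, 2L)

  # a genome and its reverse complement give identical matrices
  set.seed(1)
  s <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  m1 <- count_kmers(c(x = s), k = 9)
  m2 <- count_kmers(c(x = subgenomics:::revcomp(s)), k = 9)
  expect_identical(
    m1$counts[order(m1$counts$kmer), c("kmer", "count")],
    m2$counts[order(m2$counts$kmer), c("kmer", "count")]
  )

  expect_error(count_kmers(c(tiny = "ACGT"), k = 9), "shorter than k")
  expect_error(count_kmers(c(x = s), k = 8), "odd")
})

test_that("counts equal a direct sliding-window recount", {
  set.seed(2)
  s <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  k <- 7L
  m <- count_kmers(c(x = s), k = k)
  # brute-force recount: walk every window, canonicalise by hand
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  tallies <- new.env(parent = emptyenv())
  for (i in seq_len(nchar(s) - k + 1L)) {
    w <- substr(s, i, i + k - 1L)
    rc <- paste(rev(comp[strsplit(w, "")[[1]]]), collapse = "")
    key <- if (w <= rc) w else rc
    tallies[[key]] <- (if (is.null(tallies[[key]])) 0L else tallies[[key]]) + 1L
  }
  got <- stats::setNames(m$counts$count, m$counts$kmer)
  expect_identical(length(got), length(ls(tallies)))
  for (key in ls(tallies)) expect_identical(unname(got[key]), tallies[[key]])
})

test_that("differential filter keeps private k-mers and drops balanced ones", {
  counts <- data.table::data.table(
    chrom = c("c1", "c2", "c1", "c2"),
    kmer = c("AAACAAACAAACA", "AAACAAACAAACA", "AAAGAAAGAAAGA", "AAAGAAAGAAAGA"),
    count = c(200L, 0L, 150L, 150L)
  )
  counts <- rbind(counts, data.table::data.table(chrom = "c1",
                                                 kmer = "AAATAAATAAATA",
                                                 count = 10L))
  mat <- structure(list(counts = counts, lengths = c(c1 = 50000L, c2 = 50000L),
                        k = 13L), class = "kmer_matrix")
  pairs <- data.frame(member1 = "c1", member2 = "c2")
  kept <- select_differential_kmers(mat, pairs, min_total = 100, min_fold = 2)
  expect_setequal(unique(kept$counts$kmer), "AAACAAACAAACA")
})

test_that("raising min_fold never grows the retained k-mer set", {
  sim <- cached("phase_42", simulate_allopolyploid(cfg_phase(42L)))
  km <- cached("phase_42_km", count_kmers(sim$genome$chromosomes, k = 13))
  kept_at <- function(f) {
    tryCatch(
      unique(select_differential_kmers(km, sim$truth$pairing,
                                       min_fold = f)$counts$kmer),
      error = function(e) character(0)  # "no phasing signal" = empty set
    )
  }
  prev <- NULL
  for (f in c(1.5, 2, 4)) {
    ks <- kept_at(f)
    if (!is.null(prev)) expect_true(all(ks %in% prev))
    prev <- ks
  }
  expect_gt(length(kept_at(1.5)), 0L)
})

test_that("retained set covers the planted repeat k-mers of both families", {
  sim <- cached("phase_42", simulate_allopolyploid(cfg_phase(42L)))
  km <- cached("phase_42_km", count_kmers(sim$genome$chromosomes, k = 13))
  kept <- select_differential_kmers(km, sim$truth$pairing,
                                    min_total = 100, min_fold = 2)
  keptk <- unique(kept$counts$kmer)
  for (cons in sim$truth$repeat_consensus) {
    n <- nchar(cons)
    w <- substring(cons, seq_len(n - 12L), seq_len(n - 12L) + 12L)
    rc <- subgenomics:::revcomp(w)
    planted <- unique(ifelse(w <= rc, w, rc))
    expect_true(all(planted %in% keptk))
  }
})

test_that("assignment recovers the true subgenomes up to label swap", {
  sim <- cached("phase_42", simulate_allopolyploid(cfg_phase(42L)))
  km <- cached("phase_42_km", count_kmers(sim$genome$chromosomes, k = 13))
  kept <- select_differential_kmers(km, sim$truth$pairing)
  asg <- assign_subgenomes(kept, sim$truth$pairing)
  expect_true(assignment_matches_truth(asg, true_labels_of(sim$truth)))
  expect_true(all(asg$assignment$score > 0))
  # homoeologous partners always receive different labels
  lab <- stats::setNames(asg$assignment$label, asg$assignment$chromosome)
  expect_true(all(lab[sim$truth$pairing$member1] != lab[sim$truth$pairing$member2]))
})

test_that("assignment is invariant to chromosome input order", {
  sim <- cached("phase_42", simulate_allopolyploid(cfg_phase(42L)))
  chroms <- sim$genome$chromosomes
  km1 <- count_kmers(chroms, k = 13)
  km2 <- count_kmers(rev(chroms), k = 13)
  a1 <- assign_subgenomes(select_differential_kmers(km1, sim$truth$pairing),
                          sim$truth$pairing)
  a2 <- assign_subgenomes(select_differential_kmers(km2, sim$truth$pairing),
                          sim$truth$pairing)
  expect_identical(a1$assignment, a2$assignment)
})

test_that("absence of subgenome-specific repeats fails loudly", {
  cfg <- sim_config(n_chromosome_pairs = 2L, genes_per_chromosome = 15L,
                    codons_per_gene = 40L, repeat_family_fold = 1,
                    repeats_per_chromosome = 40L, seed = 3L)
  sim <- simulate_allopolyploid(cfg)
  km <- count_kmers(sim$genome$chromosomes, k = 13)
  expect_error(
    select_differential_kmers(km, sim$truth$pairing, min_total = 100, min_fold = 2),
    "no phasing signal"
  )
})
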