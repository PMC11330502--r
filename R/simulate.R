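# Synthetic allopolyploid genome generator. An ancestral diploid gene
# complement is duplicated into subgenomes A and D, diverged under a
# codon-aware substitution process, fractionated by per-subgenome gene loss,
# expanded by tandem duplication, and decorated with subgenome-specific
# repeat families. All stochastic draws come from R's generator seeded from
# the config, so identical configs give byte-identical outputs.

#' Simulation configuration
#'
#' Parameters of the synthetic allopolyploid generator. Defaults describe a
#' small allotetraploid with the divergence, loss bias and repeat structure
#' every downstream estimator assumes: expected synonymous divergence between
#' homoeologs of 0.2 substitutions/site, biased fractionation (15% of
#' ancestral genes lost from subgenome A versus 10% from D), and a two-fold
#' enrichment of each subgenome's private repeat family.
#'
#' @param n_chromosome_pairs number of homoeologous chromosome pairs.
#' @param genes_per_chromosome ancestral genes per chromosome.
#' @param codons_per_gene codons per coding sequence.
#' @param subgenome_divergence_ks expected synonymous substitutions per
#'   synonymous site between homoeologs (total over both lineages).
#' @param omega dN/dS ratio in (0, 1]; nonsynonymous divergence is
#'   `omega * subgenome_divergence_ks`.
#' @param loss_fraction_A,loss_fraction_D per-subgenome probability that an
#'   ancestral gene is lost (fractionated); must be in [0, 1).
#' @param tandem_rate expected number of extra tandem copies per retained
#'   gene (Poisson).
#' @param tandem_copy_divergence substitution rate applied to each tandem
#'   copy relative to its source gene.
#' @param repeat_family_fold enrichment of a subgenome's private repeat
#'   family over its homoeologous partner (>= 1).
#' @param repeats_per_chromosome copies of the own-subgenome repeat family
#'   planted per chromosome; the partner subgenome receives
#'   `round(repeats_per_chromosome / repeat_family_fold)` copies.
#' @param repeat_length length of each repeat consensus (bp).
#' @param spacer_length intergenic spacer length (bp).
#' @param b_source_fraction fraction of the B chromosome mosaicked from
#'   main-chromosome segments, in [0, 1].
#' @param b_length B-chromosome length (bp; rounded down to whole segments).
#' @param b_segment_length length of each mosaicked segment (bp).
#' @param b_segment_noise per-base substitution probability applied to copied
#'   B segments.
#' @param ploidy homoeologous copy count of the simulated individual, 4 or 6.
#' @param b_copies B-chromosome copies carried by the individual (>= 0);
#'   main chromosomes are present in 2 copies per subgenome pair.
#' @param mean_depth mean sequencing depth (reads per site).
#' @param heterozygosity_syn,heterozygosity_nonsyn per-site heterozygosity at
#'   synonymous and nonsynonymous coding positions.
#' @param mismap_depth_fraction read depth observed on absent sequence
#'   (mismapping), as a fraction of `mean_depth`.
#' @param coverage_bin resolution of the emitted read-depth track (bp).
#' @param seed integer seed; derived stages use `seed + 1` (B chromosome) and
#'   `seed + 2` (observations).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_chromosome_pairs = 3L,
                       genes_per_chromosome = 40L,
                       codons_per_gene = 100L,
                       subgenome_divergence_ks = 0.2,
                       omega = 0.3,
                       loss_fraction_A = 0.15,
                       loss_fraction_D = 0.10,
                       tandem_rate = 0.1,
                       tandem_copy_divergence = 0.01,
                       repeat_family_fold = 2,
                       repeats_per_chromosome = 60L,
                       repeat_length = 500L,
                       spacer_length = 200L,
                       b_source_fraction = 0.25,
                       b_length = 60000L,
                       b_segment_length = 300L,
                       b_segment_noise = 0.02,
                       ploidy = 4L,
                       b_copies = 2L,
                       mean_depth = 60,
                       heterozygosity_syn = 0.003,
                       heterozygosity_nonsyn = 0.0015,
                       mismap_depth_fraction = 0.01,
                       coverage_bin = 100L,
                       seed = 42L) {
  cfg <- as.list(environment())
  counts <- c("n_chromosome_pairs", "genes_per_chromosome", "codons_per_gene",
              "repeats_per_chromosome", "repeat_length", "spacer_length",
              "b_length", "b_segment_length", "coverage_bin")
  for (nm in counts) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] < 1) {
      stop("'", nm, "' must be a positive count")
    }
  }
  if (cfg$loss_fraction_A < 0 || cfg$loss_fraction_A >= 1 ||
      cfg$loss_fraction_D < 0 || cfg$loss_fraction_D >= 1) {
    stop("loss fractions must lie in [0, 1)")
  }
  if (cfg$subgenome_divergence_ks < 0) stop("subgenome_divergence_ks must be >= 0")
  if (cfg$subgenome_divergence_ks >= 3) {
    stop("subgenome_divergence_ks too high: expected synonymous differences ",
         "approach saturation and the Jukes-Cantor correction is undefined")
  }
  if (cfg$omega <= 0 || cfg$omega > 1) stop("omega must be in (0, 1]")
  if (cfg$repeat_family_fold < 1) stop("repeat_family_fold must be >= 1")
  if (cfg$b_source_fraction < 0 || cfg$b_source_fraction > 1) {
    stop("b_source_fraction must lie in [0, 1]")
  }
  if (!cfg$ploidy %in% c(4L, 6L)) stop("ploidy must be 4 or 6")
  if (cfg$b_copies < 0) stop("b_copies must be >= 0")
  if (cfg$mean_depth <= 0) stop("mean_depth must be > 0")
  if (cfg$tandem_rate < 0) stop("tandem_rate must be >= 0")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>",
      sprintf("%d chromosome pairs x %d genes x %d codons",
              x$n_chromosome_pairs, x$genes_per_chromosome, x$codons_per_gene),
      sprintf("Ks = %g (omega = %g), loss A/D = %g/%g, ploidy = %dx, B copies = %d",
              x$subgenome_divergence_ks, x$omega, x$loss_fraction_A,
              x$loss_fraction_D, x$ploidy, x$b_copies),
      sep = "\n")
  invisible(x)
}

get_chromosomes <- function(genome) {
  if (inherits(genome, "annotated_genome")) genome$chromosomes else unlist(genome)
}

#' Simulate an allotetraploid genome with recorded ground truth
#'
#' Duplicates an ancestral gene complement into subgenomes A and D, applies
#' codon-aware divergence (synonymous proposals always accepted,
#' nonsynonymous with probability `omega`, stop-gaining proposals rejected),
#' deletes genes per subgenome at the configured loss fractions, inserts
#' tandem copies adjacent to their source genes, and plants subgenome-specific
#' repeat families in intergenic space at `repeat_family_fold` enrichment.
#' Intergenic spacers descend from shared ancestral sequence and diverge at
#' the same per-site rate as synonymous coding positions.
#'
#' @param config a [sim_config()].
#' @return list with elements `genome` (class `annotated_genome`: named
#'   chromosome sequences, a gene table with CDS, a repeat-mask table) and
#'   `truth` (pairing of homoeologous chromosomes, syntelog table, deleted
#'   gene lists, planted tandem arrays, repeat consensus sequences).
#' @export
simulate_allopolyploid <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tb <- codon_tables()
  npair <- config$n_chromosome_pairs
  gpc <- config$genes_per_chromosome
  n_genes <- npair * gpc
  half_ks <- config$subgenome_divergence_ks / 2
  p_spacer <- 0.75 * (1 - exp(-4 / 3 * half_ks))

  anc_id <- sprintf("g%05d", seq_len(n_genes))
  fam_id <- sprintf("fam%05d", seq_len(n_genes))
  anc_chrom <- rep(seq_len(npair), each = gpc)
  anc_cds <- lapply(seq_len(n_genes), function(i) random_codons(config$codons_per_gene))

  # ancestral intergenic spacers: one per gene slot plus a trailing one
  anc_spacer <- lapply(seq_len(npair), function(p) {
    vapply(seq_len(gpc + 1L), function(i) random_dna(config$spacer_length), character(1))
  })

  # which physical member (1 or 2) of each chromosome pair carries subgenome A
  a_member <- sample(1:2, npair, replace = TRUE)
  pair_name <- sprintf("chr%02d", seq_len(npair))
  member_name <- function(p, m) sprintf("%s_%d", pair_name[p], m)

  deleted <- list(
    A = stats::runif(n_genes) < config$loss_fraction_A,
    D = stats::runif(n_genes) < config$loss_fraction_D
  )

  # diverge coding sequence of each subgenome by half the pair divergence
  sub_cds <- list()
  for (sg in c("A", "D")) {
    all_cod <- evolve_codons(unlist(anc_cds), half_ks, config$omega)
    sub_cds[[sg]] <- split(all_cod, rep(seq_len(n_genes), each = config$codons_per_gene))
  }

  n_extra <- list(
    A = ifelse(deleted$A, 0L, stats::rpois(n_genes, config$tandem_rate)),
    D = ifelse(deleted$D, 0L, stats::rpois(n_genes, config$tandem_rate))
  )

  rep_consensus <- list(A = random_dna(config$repeat_length),
                        D = random_dna(config$repeat_length))
  own_n <- as.integer(config$repeats_per_chromosome)
  cross_n <- as.integer(round(own_n / config$repeat_family_fold))

  chroms <- list()
  gene_rows <- list()
  mask_rows <- list()
  tandem_rows <- list()

  for (p in seq_len(npair)) {
    gidx <- which(anc_chrom == p)
    for (sg in c("A", "D")) {
      member <- if (sg == "A") a_member[p] else 3L - a_member[p]
      cname <- member_name(p, member)
      other <- setdiff(c("A", "D"), sg)
      # repeats assigned to gene slots (slot s = before gene s; slot gpc+1 trails)
      own_slots <- tabulate(sample.int(gpc + 1L, own_n, replace = TRUE), gpc + 1L)
      cross_slots <- tabulate(sample.int(gpc + 1L, cross_n, replace = TRUE), gpc + 1L)

      seqs <- character(0)
      meta <- list()
      gene_counter <- 0L
      add <- function(seq, type, id = NA_character_, family = NA_character_,
                      ancestor = NA_character_, strand = NA_character_,
                      cds = NA_character_, tandem = FALSE, mclass = NA_character_) {
        seqs[[length(seqs) + 1L]] <<- seq
        meta[[length(meta) + 1L]] <<- list(type = type, id = id, family = family,
                                           ancestor = ancestor, strand = strand,
                                           cds = cds, tandem = tandem, mclass = mclass)
      }
      emit_gene <- function(cds_codons, id, family, ancestor, tandem) {
        gene_counter <<- gene_counter + 1L
        strand <- if (gene_counter %% 2L == 1L) "+" else "-"
        cds <- paste(cds_codons, collapse = "")
        gseq <- if (strand == "+") cds else revcomp(cds)
        add(gseq, "gene", id = id, family = family, ancestor = ancestor,
            strand = strand, cds = cds, tandem = tandem)
      }
      emit_repeats <- function(slot) {
        if (own_slots[slot] > 0L) {
          for (r in seq_len(own_slots[slot])) add(rep_consensus[[sg]], "repeat", mclass = "repeat")
        }
        if (cross_slots[slot] > 0L) {
          for (r in seq_len(cross_slots[slot])) add(rep_consensus[[other]], "repeat", mclass = "repeat")
        }
      }
      for (s in seq_along(gidx)) {
        g <- gidx[s]
        add(mutate_noncoding(anc_spacer[[p]][s], p_spacer), "spacer")
        emit_repeats(s)
        if (!deleted[[sg]][g]) {
          gid <- paste0(anc_id[g], "_", sg)
          emit_gene(sub_cds[[sg]][[g]], gid, fam_id[g], anc_id[g], FALSE)
          if (n_extra[[sg]][g] > 0L) {
            members <- gid
            for (tcp in seq_len(n_extra[[sg]][g])) {
              add(random_dna(100L), "spacer")
              tid <- sprintf("%s_t%d", gid, tcp)
              tc <- evolve_codons(sub_cds[[sg]][[g]],
                                  config$tandem_copy_divergence, config$omega)
              emit_gene(tc, tid, fam_id[g], anc_id[g], TRUE)
              members <- c(members, tid)
            }
            tandem_rows[[length(tandem_rows) + 1L]] <- data.frame(
              subgenome = sg, chrom = cname, source_gene = gid,
              family = fam_id[g], size = length(members),
              members = paste(members, collapse = ","),
              stringsAsFactors = FALSE
            )
          }
        }
      }
      add(mutate_noncoding(anc_spacer[[p]][gpc + 1L], p_spacer), "spacer")
      emit_repeats(gpc + 1L)

      lens <- nchar(unlist(seqs))
      starts <- cumsum(c(0L, lens[-length(lens)]))
      chroms[[cname]] <- paste(unlist(seqs), collapse = "")
      for (i in seq_along(meta)) {
        m <- meta[[i]]
        if (m$type == "gene") {
          gene_rows[[length(gene_rows) + 1L]] <- data.frame(
            id = m$id, chrom = cname, start = starts[i], end = starts[i] + lens[i],
            strand = m$strand, family = m$family, subgenome = sg,
            ancestor = m$ancestor, tandem = m$tandem, cds = m$cds,
            stringsAsFactors = FALSE
          )
        } else if (m$type == "repeat") {
          mask_rows[[length(mask_rows) + 1L]] <- data.frame(
            chrom = cname, start = starts[i], end = starts[i] + lens[i],
            class = "repeat", stringsAsFactors = FALSE
          )
        }
      }
    }
  }

  genes <- do.call(rbind, gene_rows)
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  masks <- do.call(rbind, mask_rows)
  rownames(masks) <- NULL

  genome <- structure(
    list(chromosomes = unlist(chroms), genes = genes, masks = masks),
    class = "annotated_genome"
  )

  syntelogs <- data.frame(
    ancestor = anc_id, family = fam_id,
    chrom_pair = pair_name[anc_chrom],
    gene_a = ifelse(deleted$A, NA_character_, paste0(anc_id, "_A")),
    gene_d = ifelse(deleted$D, NA_character_, paste0(anc_id, "_D")),
    retained_a = !deleted$A, retained_d = !deleted$D,
    stringsAsFactors = FALSE
  )
  pairing <- data.frame(
    pair = pair_name,
    member1 = member_name(seq_len(npair), 1L),
    member2 = member_name(seq_len(npair), 2L),
    label1 = ifelse(a_member == 1L, "A", "D"),
    label2 = ifelse(a_member == 1L, "D", "A"),
    stringsAsFactors = FALSE
  )
  truth <- list(
    pairing = pairing,
    syntelogs = syntelogs,
    deleted_a = anc_id[deleted$A],
    deleted_d = anc_id[deleted$D],
    tandem_arrays = if (length(tandem_rows)) do.call(rbind, tandem_rows) else
      data.frame(subgenome = character(0), chrom = character(0),
                 source_gene = character(0), family = character(0),
                 size = integer(0), members = character(0)),
    repeat_consensus = rep_consensus,
    true_ks = config$subgenome_divergence_ks,
    seed = config$seed
  )
  list(genome = genome, truth = truth)
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("<annotated_genome> ", length(x$chromosomes), " chromosomes (",
      sum(nchar(x$chromosomes)), " bp), ", nrow(x$genes), " genes, ",
      nrow(x$masks), " masked intervals\n", sep = "")
  invisible(x)
}

#' Append a mosaicked B chromosome to a simulated genome
#'
#' The B chromosome is a concatenation of fixed-length segments. A fraction
#' `b_source_fraction` of segments (exact count, randomly interleaved) are
#' copied from recorded coordinates on the main chromosomes -- sampled
#' proportional to chromosome length and outside repeat masks -- with
#' per-base substitution noise `b_segment_noise`; the remainder is random
#' repeat-like filler with no match in the main genome.
#'
#' @param genome an `annotated_genome` with at least one main chromosome.
#' @param config a [sim_config()]; uses `seed + 1`.
#' @param b_name name of the appended chromosome.
#' @return list with updated `genome` and `truth` (a table of true source
#'   coordinates plus the realised source fraction).
#' @export
simulate_b_chromosome <- function(genome, config, b_name = "chrB") {
  stopifnot(inherits(config, "sim_config"))
  if (!length(genome$chromosomes)) stop("genome has no main chromosome")
  set.seed(config$seed + 1L)
  seg <- as.integer(config$b_segment_length)
  n_seg <- max(1L, config$b_length %/% seg)
  n_src <- round(config$b_source_fraction * n_seg)
  src_slots <- sort(sample.int(n_seg, n_src))

  chrs <- genome$chromosomes
  clen <- nchar(chrs)
  masks <- genome$masks

  # mask complement: intervals long enough to host a segment, sampled
  # proportional to the number of valid start positions they contain
  free <- do.call(rbind, lapply(names(chrs), function(cm) {
    mm <- masks[masks$chrom == cm, , drop = FALSE]
    mm <- mm[order(mm$start), , drop = FALSE]
    bounds_s <- c(0L, mm$end)
    bounds_e <- c(mm$start, clen[[cm]])
    keep <- bounds_e - bounds_s >= seg
    if (!any(keep)) return(NULL)
    data.frame(chrom = cm, start = bounds_s[keep], end = bounds_e[keep],
               stringsAsFactors = FALSE)
  }))
  if (is.null(free) || !nrow(free)) {
    stop("no unmasked main-chromosome interval can host a ", seg, " bp segment")
  }
  n_starts <- free$end - free$start - seg + 1L
  sample_source <- function() {
    i <- sample.int(nrow(free), 1L, prob = n_starts)
    list(chrom = free$chrom[i],
         start = free$start[i] + sample.int(n_starts[i], 1L) - 1L)
  }

  tiles <- character(n_seg)
  src_rows <- list()
  for (i in seq_len(n_seg)) {
    if (i %in% src_slots) {
      src <- sample_source()
      piece <- substr(chrs[[src$chrom]], src$start + 1L, src$start + seg)
      tiles[i] <- mutate_noncoding(piece, config$b_segment_noise)
      src_rows[[length(src_rows) + 1L]] <- data.frame(
        b_start = (i - 1L) * seg, b_end = i * seg,
        chrom = src$chrom, start = src$start, end = src$start + seg,
        stringsAsFactors = FALSE
      )
    } else {
      tiles[i] <- random_dna(seg)
    }
  }
  genome$chromosomes[[b_name]] <- paste(tiles, collapse = "")
  truth <- list(
    b_name = b_name,
    b_source = if (length(src_rows)) do.call(rbind, src_rows) else
      data.frame(b_start = integer(0), b_end = integer(0), chrom = character(0),
                 start = integer(0), end = integer(0)),
    b_source_fraction = n_src / n_seg
  )
  list(genome = genome, truth = truth)
}

#' Simulate allele-depth and read-depth observations
#'
#' Heterozygous sites are placed along every annotated CDS: position `i` with
#' synonymous opportunity `f_i` (NG86 fraction of its three single-base
#' changes that are synonymous) becomes a synonymous heterozygote with
#' probability `heterozygosity_syn * f_i` and a nonsynonymous one with
#' probability `heterozygosity_nonsyn * (1 - f_i)`, so each class's expected
#' heterozygosity per NG86 site equals the configured rate. Each site carries
#' one divergent copy out of `ploidy / 2` homoeologue-resolved copies, giving
#' a true alternate-allele fraction of 1/2 (4x) or 1/3 (6x). Per-site total
#' depth is Poisson(`mean_depth`) and alternate depth Binomial. The windowed
#' depth track scales with local copy number: main chromosomes at the 2-copy
#' baseline, the B chromosome at `b_copies`, plus `mismap_depth_fraction`
#' background on the B.
#'
#' @param genome an `annotated_genome` (with or without a B chromosome).
#' @param config a [sim_config()]; uses `seed + 2`.
#' @param b_name chromosome treated as the B when present.
#' @return list with `allele_depth` (chrom, pos 1-based, ref, alt, ref_depth,
#'   alt_depth), `coverage` (chrom, start, end, depth at `coverage_bin`
#'   resolution), and `truth` (per-site consequence class and generative
#'   heterozygosities).
#' @export
simulate_observations <- function(genome, config, b_name = "chrB") {
  stopifnot(inherits(config, "sim_config"))
  if (!config$ploidy %in% c(4L, 6L)) stop("ploidy must be 4 or 6")
  set.seed(config$seed + 2L)
  tb <- codon_tables()
  af <- if (config$ploidy == 4L) 0.5 else 1 / 3
  genes <- genome$genes

  cods <- lapply(genes$cds, split_codons)
  ncod <- lengths(cods)
  all_cod <- unlist(cods)
  idx <- match(all_cod, tb$codons)
  npos <- 3L * length(all_cod)
  f_syn <- as.vector(t(tb$syn_count[idx, , drop = FALSE])) / 3

  u <- stats::runif(npos)
  hs <- config$heterozygosity_syn
  hn <- config$heterozygosity_nonsyn
  syn_sel <- u < hs * f_syn
  nonsyn_sel <- !syn_sel & u < hs * f_syn + hn * (1 - f_syn)
  sel <- which(syn_sel | nonsyn_sel)

  gene_row <- rep(rep(seq_len(nrow(genes)), ncod), each = 3L)
  cds_off <- unlist(lapply(ncod, function(k) seq_len(3L * k))) - 1L
  cod_of_pos <- rep(all_cod, each = 3L)
  within <- rep_len(1:3, npos)

  rows <- list()
  for (i in sel) {
    cod <- cod_of_pos[i]
    p <- within[i]
    alts <- if (syn_sel[i]) tb$syn_alts[[cod]][[p]] else tb$nonsyn_alts[[cod]][[p]]
    if (!length(alts)) next
    alt_cds <- alts[sample.int(length(alts), 1L)]
    rows[[length(rows) + 1L]] <- list(
      gene_row = gene_row[i], cds_off = cds_off[i],
      ref_cds = substr(cod, p, p), alt_cds = alt_cds,
      class = if (syn_sel[i]) "synonymous" else "nonsynonymous"
    )
  }

  if (length(rows)) {
    dt <- data.table::rbindlist(rows)
    g <- genes[dt$gene_row, ]
    plus <- g$strand == "+"
    pos0 <- ifelse(plus, g$start + dt$cds_off, g$end - 1L - dt$cds_off)
    ref <- ifelse(plus, dt$ref_cds, comp_base(dt$ref_cds))
    alt <- ifelse(plus, dt$alt_cds, comp_base(dt$alt_cds))
    n <- nrow(dt)
    total <- stats::rpois(n, config$mean_depth)
    alt_depth <- stats::rbinom(n, total, af)
    allele_depth <- data.frame(
      chrom = g$chrom, pos = pos0 + 1L, ref = ref, alt = alt,
      ref_depth = total - alt_depth, alt_depth = alt_depth,
      stringsAsFactors = FALSE
    )
    truth_sites <- data.frame(
      chrom = g$chrom, pos = pos0 + 1L, gene = g$id, class = dt$class,
      stringsAsFactors = FALSE
    )
    ord <- order(allele_depth$chrom, allele_depth$pos)
    allele_depth <- allele_depth[ord, ]
    truth_sites <- truth_sites[ord, ]
    rownames(allele_depth) <- rownames(truth_sites) <- NULL
  } else {
    allele_depth <- data.frame(chrom = character(0), pos = integer(0),
                               ref = character(0), alt = character(0),
                               ref_depth = integer(0), alt_depth = integer(0))
    truth_sites <- data.frame(chrom = character(0), pos = integer(0),
                              gene = character(0), class = character(0))
  }

  # windowed depth track
  bin <- as.integer(config$coverage_bin)
  cov_rows <- lapply(names(genome$chromosomes), function(cm) {
    len <- nchar(genome$chromosomes[[cm]])
    starts <- seq(0L, len - 1L, by = bin)
    width <- pmin(bin, len - starts)
    copy <- if (cm == b_name) config$b_copies else 2
    lambda <- width * config$mean_depth *
      (copy / 2 + if (cm == b_name) config$mismap_depth_fraction else 0)
    data.frame(chrom = cm, start = starts, end = starts + width,
               depth = stats::rpois(length(starts), lambda) / width,
               stringsAsFactors = FALSE)
  })
  coverage <- do.call(rbind, cov_rows)
  rownames(coverage) <- NULL

  list(
    allele_depth = allele_depth,
    coverage = coverage,
    truth = list(
      sites = truth_sites,
      true_allele_fraction = af,
      true_ploidy = config$ploidy,
      true_b_copies = config$b_copies,
      true_pi_syn = hs,
      true_pi_nonsyn = hn
    )
  )
}
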