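# Coding-consequence annotation and per-class nucleotide diversity. Variants
# are placed in codon context (strand-aware), classified as synonymous /
# missense / nonsense with LOW / MODERATE / HIGH impact (HIGH or MODERATE
# counts as deleterious), and per-class diversity is the summed per-site
# heterozygosity divided by the NG86 fractional site count of that class.

#' Annotate coding consequences of variant sites
#'
#' Each variant is located in its gene and codon; the alternate codon is
#' translated and the change classified: synonymous (LOW impact), missense
#' (MODERATE), stop gained or lost (nonsense, HIGH). Sites outside any gene
#' are `intergenic` with impact NONE. Minus-strand genes are handled by
#' complementing the alleles into CDS orientation. Sites whose reference
#' allele disagrees with the genome sequence raise an error.
#'
#' @param sites allele-depth data frame (chrom, pos 1-based, ref, alt, and
#'   optionally ref_depth / alt_depth, carried through).
#' @param genome an `annotated_genome`.
#' @return data frame of class `effect_table`: the input columns plus `gene`,
#'   `codon`, `alt_codon`, `consequence`, `impact`, `deleterious`.
#' @export
annotate_effects <- function(sites, genome) {
  genes <- genome$genes
  tb <- codon_tables()
  n <- nrow(sites)
  gene_id <- rep(NA_character_, n)
  gene_row <- rep(NA_integer_, n)
  for (cm in unique(sites$chrom)) {
    si <- which(sites$chrom == cm)
    gsub <- genes[genes$chrom == cm, , drop = FALSE]
    if (!nrow(gsub)) next
    pos0 <- sites$pos[si] - 1L
    gi <- findInterval(pos0, gsub$start)
    inside <- gi >= 1L & pos0 < gsub$end[pmax(gi, 1L)]
    gene_id[si[inside]] <- gsub$id[gi[inside]]
    gene_row[si[inside]] <- which(genes$chrom == cm)[gi[inside]]
  }

  # verify the stated reference allele against the genome sequence
  chrom_seq <- genome$chromosomes
  ref_obs <- substr(chrom_seq[sites$chrom], sites$pos, sites$pos)
  bad <- which(ref_obs != sites$ref)
  if (length(bad)) {
    stop("variant reference allele inconsistent with the genome sequence at ",
         sites$chrom[bad[1]], ":", sites$pos[bad[1]],
         " (", length(bad), " site(s))")
  }

  consequence <- rep("intergenic", n)
  impact <- rep("NONE", n)
  codon <- rep(NA_character_, n)
  alt_codon <- rep(NA_character_, n)

  coding <- which(!is.na(gene_row))
  if (length(coding)) {
    g <- genes[gene_row[coding], , drop = FALSE]
    pos0 <- sites$pos[coding] - 1L
    plus <- g$strand == "+"
    cds_off <- ifelse(plus, pos0 - g$start, g$end - 1L - pos0)
    ref_cds <- ifelse(plus, sites$ref[coding], comp_base(sites$ref[coding]))
    alt_cds <- ifelse(plus, sites$alt[coding], comp_base(sites$alt[coding]))
    ci <- cds_off %/% 3L
    within <- cds_off %% 3L + 1L
    old_cod <- substr(g$cds, 3L * ci + 1L, 3L * ci + 3L)
    stopifnot(all(substr(old_cod, within, within) == ref_cds))
    new_cod <- old_cod
    substr(new_cod, within, within) <- alt_cds
    aa_old <- unname(tb$code[old_cod])
    aa_new <- unname(tb$code[new_cod])
    cons <- ifelse(aa_new == aa_old, "synonymous",
                   ifelse(aa_new == "*" | aa_old == "*", "nonsense", "missense"))
    imp <- c(synonymous = "LOW", missense = "MODERATE", nonsense = "HIGH")[cons]
    consequence[coding] <- cons
    impact[coding] <- imp
    codon[coding] <- old_cod
    alt_codon[coding] <- new_cod
  }

  out <- cbind(
    sites,
    data.frame(gene = gene_id, codon = codon, alt_codon = alt_codon,
               consequence = consequence, impact = impact,
               deleterious = impact %in% c("HIGH", "MODERATE"),
               stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  class(out) <- c("effect_table", class(out))
  out
}

#' NG86 fractional synonymous/nonsynonymous site totals of a genome
#'
#' @param genome an `annotated_genome`.
#' @return list with `syn_sites`, `nonsyn_sites` summed over every annotated
#'   CDS (they add to 3 x total codons).
#' @export
callable_sites <- function(genome) {
  tb <- codon_tables()
  idx <- match(unlist(lapply(genome$genes$cds, split_codons)), tb$codons)
  idx <- idx[!is.na(idx)]
  s <- sum(tb$syn_sites[idx])
  list(syn_sites = s, nonsyn_sites = 3 * length(idx) - s)
}

#' Per-class nucleotide diversity and the piN/piS ratio
#'
#' Single-individual diversity: every variant site contributes the expected
#' heterozygosity of n = 2 sampled alleles, `2 p (1 - p) * n / (n - 1)`, with
#' `p` the within-individual allele fraction estimated from read depths.
#' Class sums are divided by the NG86 fractional site totals of the annotated
#' CDS, so piN and piS are per-site quantities comparable across genomes with
#' different codon usage. Missense and nonsense sites count towards piN,
#' synonymous sites towards piS.
#'
#' @param effects an `effect_table` from [annotate_effects()] with depth
#'   columns.
#' @param genome the `annotated_genome` that defines the callable CDS space.
#' @return object of class `diversity_summary`: `pi_nonsyn`, `pi_syn`,
#'   `ratio` (NA when piS is 0), `site_counts`, `callable`.
#' @export
pi_by_class <- function(effects, genome) {
  if (!all(c("ref_depth", "alt_depth") %in% names(effects))) {
    stop("effects table lacks read-depth columns")
  }
  cs <- callable_sites(genome)
  if (cs$syn_sites <= 0) stop("zero callable synonymous sites")
  total <- effects$ref_depth + effects$alt_depth
  ok <- total > 0
  p <- effects$alt_depth[ok] / total[ok]
  w <- 2 * p * (1 - p) * 2  # n/(n-1) with n = 2 allele draws
  cons <- effects$consequence[ok]
  pi_syn <- sum(w[cons == "synonymous"]) / cs$syn_sites
  pi_nonsyn <- sum(w[cons %in% c("missense", "nonsense")]) / cs$nonsyn_sites
  structure(
    list(
      pi_nonsyn = pi_nonsyn,
      pi_syn = pi_syn,
      ratio = if (pi_syn > 0) pi_nonsyn / pi_syn else NA_real_,
      site_counts = table(factor(cons, levels = c("synonymous", "missense",
                                                  "nonsense", "intergenic"))),
      callable = cs
    ),
    class = "diversity_summary"
  )
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf("<diversity_summary> piN = %.6f, piS = %.6f, piN/piS = %s\n",
              x$pi_nonsyn, x$pi_syn,
              if (is.na(x$ratio)) "undefined" else sprintf("%.2f", x$ratio)))
  invisible(x)
}

#' Format a per-accession diversity table
#'
#' Rounds to the conventional printed precision: diversities to six decimals
#' and the ratio to two.
#'
#' @param x data frame with columns `accession`, `pi_nonsyn`, `pi_syn`, or a
#'   named list of `diversity_summary` objects.
#' @return data frame: accession, pi_nonsyn, pi_syn, ratio.
#' @export
ratio_table <- function(x) {
  if (!is.data.frame(x)) {
    stopifnot(length(x) >= 1L)
    x <- data.frame(
      accession = names(x),
      pi_nonsyn = vapply(x, function(s) s$pi_nonsyn, numeric(1)),
      pi_syn = vapply(x, function(s) s$pi_syn, numeric(1)),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("accession", "pi_nonsyn", "pi_syn") %in% names(x)))
  out <- data.frame(
    accession = x$accession,
    pi_nonsyn = round(x$pi_nonsyn, 6),
    pi_syn = round(x$pi_syn, 6),
    ratio = round(x$pi_nonsyn / x$pi_syn, 2),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
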