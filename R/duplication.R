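# Tandem-duplication detection and gene-set statistics: maximal same-family
# runs along a chromosome, one-sided Fisher (hypergeometric) term enrichment
# with four multiplicity adjustments, Venn partitions of per-lineage term
# sets, and a 2x2 overlap test between gene sets.

#' Detect tandem arrays
#'
#' A tandem array is a maximal run of genes of the same family on one
#' chromosome in which consecutive members are separated by at most `max_gap`
#' intervening genes. Arrays have at least two members; the total member
#' count is the "tandem duplicate" count.
#'
#' @param genes data frame with columns `id`, `chrom`, `start`, `family`,
#'   ordered by chromosome and start (an error is raised otherwise).
#' @param max_gap maximum number of intervening genes between consecutive
#'   array members.
#' @return data frame: `array_id`, `chrom`, `family`, `size`, `members`
#'   (comma-separated ids), `first_start`.
#' @export
find_tandem_arrays <- function(genes, max_gap = 10L) {
  need <- c("id", "chrom", "start", "family")
  stopifnot(all(need %in% names(genes)))
  if (!nrow(genes)) {
    return(data.frame(array_id = character(0), chrom = character(0),
                      family = character(0), size = integer(0),
                      members = character(0), first_start = numeric(0)))
  }
  disord <- unlist(tapply(genes$start, genes$chrom, function(s) any(diff(s) < 0)))
  if (any(disord)) stop("genes must be ordered by chromosome and start")
  out <- list()
  aid <- 0L
  for (cm in unique(genes$chrom)) {
    sub <- genes[genes$chrom == cm, ]
    pos <- seq_len(nrow(sub))
    for (fam in unique(sub$family[duplicated(sub$family)])) {
      idx <- pos[sub$family == fam]
      grp <- cumsum(c(1L, diff(idx) > max_gap + 1L))
      for (g in unique(grp)) {
        mem <- idx[grp == g]
        if (length(mem) < 2L) next
        aid <- aid + 1L
        out[[aid]] <- data.frame(
          array_id = sprintf("arr%04d", aid), chrom = cm, family = fam,
          size = length(mem),
          members = paste(sub$id[mem], collapse = ","),
          first_start = sub$start[mem[1L]],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(array_id = character(0), chrom = character(0),
                      family = character(0), size = integer(0),
                      members = character(0), first_start = numeric(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$first_start), ]
  rownames(res) <- NULL
  res
}

#' One-sided Fisher term enrichment with multiplicity control
#'
#' Per term, the upper hypergeometric tail of the study-set hit count given
#' the population composition (equivalent to a one-sided Fisher exact test on
#' the 2x2 table). Adjusted p-values are reported for Bonferroni, Sidak,
#' Holm and Benjamini-Hochberg FDR over the tested terms; only terms with at
#' least one population hit are tested.
#'
#' @param study character vector of study gene ids (must be a subset of
#'   `population`).
#' @param population character vector of population (universe) gene ids.
#' @param term_map term-to-gene map: a data frame with columns `term`, `gene`
#'   or a named list of gene id vectors.
#' @return data frame of class `enrichment_result`: term, study_hits,
#'   study_size, pop_hits, pop_size, p, p_bonferroni, p_sidak, p_holm, p_fdr.
#' @export
go_enrichment <- function(study, population, term_map) {
  study <- unique(study)
  population <- unique(population)
  missing <- setdiff(study, population)
  if (length(missing)) {
    stop("study gene(s) absent from population: ",
         paste(utils::head(missing), collapse = ", "))
  }
  if (is.data.frame(term_map)) {
    stopifnot(all(c("term", "gene") %in% names(term_map)))
    term_map <- split(term_map$gene, term_map$term)
  }
  nn <- length(population)
  ns <- length(study)
  rows <- lapply(names(term_map), function(tm) {
    tg <- intersect(unique(term_map[[tm]]), population)
    k_pop <- length(tg)
    if (k_pop == 0L) return(NULL)
    k_study <- length(intersect(tg, study))
    p <- stats::phyper(k_study - 1L, k_pop, nn - k_pop, ns, lower.tail = FALSE)
    data.frame(term = tm, study_hits = k_study, study_size = ns,
               pop_hits = k_pop, pop_size = nn, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no term has any gene in the population")
  res <- do.call(rbind, rows)
  m <- nrow(res)
  res$p_bonferroni <- pmin(res$p * m, 1)
  res$p_sidak <- pmin(1 - (1 - res$p)^m, 1)
  res$p_holm <- stats::p.adjust(res$p, method = "holm")
  res$p_fdr <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$term), ]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", class(res))
  res
}

#' Venn partition counts of per-lineage term sets
#'
#' @param term_sets named list (>= 2 entries) of character vectors, e.g.
#'   significantly enriched terms per lineage.
#' @return named integer vector: one entry per non-empty membership class
#'   (names like `"CN"`, `"CN&EU"`), summing to the size of the union.
#' @export
lineage_specific_terms <- function(term_sets) {
  if (length(term_sets) < 2L) stop("need at least two lineages")
  if (is.null(names(term_sets)) || any(names(term_sets) == "")) {
    names(term_sets) <- paste0("set", seq_along(term_sets))
  }
  universe <- unique(unlist(term_sets))
  if (!length(universe)) return(stats::setNames(integer(0), character(0)))
  member <- vapply(term_sets, function(s) universe %in% s, logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(universe, names(term_sets)))
  sig <- apply(member, 1, function(r) paste(colnames(member)[r], collapse = "&"))
  tab <- table(sig)
  stats::setNames(as.integer(tab), names(tab))
}

#' Overlap fraction and Fisher exact test between two gene sets
#'
#' Reports `|set1 ∩ set2| / |set1|` and the one-sided (enrichment) Fisher
#' exact p-value of the 2x2 membership table within a universe of
#' `universe_size` genes.
#'
#' @param set1,set2 character vectors of gene ids.
#' @param universe_size size of the gene universe both sets are drawn from.
#' @return list with `overlap`, `fraction`, `p`, and the 2x2 `table`.
#' @export
set_overlap_test <- function(set1, set2, universe_size) {
  set1 <- unique(set1)
  set2 <- unique(set2)
  if (universe_size < 1) stop("empty universe")
  if (length(set1) > universe_size || length(set2) > universe_size) {
    stop("set larger than the universe")
  }
  ov <- length(intersect(set1, set2))
  n1 <- length(set1)
  n2 <- length(set2)
  neither <- universe_size - n1 - n2 + ov
  if (neither < 0) stop("sets overlap less than the universe allows; check universe_size")
  tab <- matrix(c(ov, n1 - ov, n2 - ov, neither), nrow = 2,
                dimnames = list(c("in_set1", "out_set1"),
                                c("in_set2", "out_set2")))
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  list(overlap = ov, fraction = if (n1 > 0) ov / n1 else NA_real_,
       p = p, table = tab)
}
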