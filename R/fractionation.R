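# Fractionation-bias analysis: per-ancestor-gene retention flags for the two
# subgenomes, a chi-square test of biased loss, and sliding-window retention
# profiles along the ancestral gene order.

#' Build a per-ancestor-gene retention table
#'
#' @param ancestor_order character vector of ancestor gene ids in genomic
#'   order, or a data frame with columns `id` (and optionally `chrom`).
#' @param retained_a,retained_d ancestor gene ids with a surviving syntelog
#'   in subgenome A / D.
#' @return object of class `retention_table`: `$table` (gene, retained_a,
#'   retained_d) and `$aggregates` (both, a_only, d_only, neither, total).
#' @export
build_retention <- function(ancestor_order, retained_a, retained_d) {
  ids <- if (is.data.frame(ancestor_order)) ancestor_order$id else ancestor_order
  unknown <- setdiff(c(retained_a, retained_d), ids)
  if (length(unknown)) {
    stop("syntelog references unknown ancestor gene(s): ",
         paste(utils::head(unknown), collapse = ", "))
  }
  ra <- ids %in% retained_a
  rd <- ids %in% retained_d
  agg <- list(
    both = sum(ra & rd), a_only = sum(ra & !rd),
    d_only = sum(!ra & rd), neither = sum(!ra & !rd),
    total = length(ids)
  )
  stopifnot(agg$both + agg$a_only + agg$d_only + agg$neither == agg$total)
  structure(
    list(table = data.frame(gene = ids, retained_a = ra, retained_d = rd,
                            stringsAsFactors = FALSE),
         aggregates = agg),
    class = "retention_table"
  )
}

#' @export
print.retention_table <- function(x, ...) {
  a <- x$aggregates
  cat("<retention_table>", a$total, "ancestor genes | both:", a$both,
      " A-only:", a$a_only, " D-only:", a$d_only, " neither:", a$neither, "\n")
  invisible(x)
}

#' Chi-square test of biased fractionation
#'
#' Goodness-of-fit chi-square of the differentially lost gene counts against
#' a 50:50 split (df = 1), i.e. `a_only` genes retained only in A versus
#' `d_only` retained only in D. When `both` is supplied, a 2x2 contingency
#' variant (subgenome x retained/lost, Pearson chi-square without continuity
#' correction) is also reported, since the two constructions answer slightly
#' different questions.
#'
#' @param a_only genes retained in A but lost from D.
#' @param d_only genes retained in D but lost from A.
#' @param both optionally, genes retained in both subgenomes.
#' @return list with `chi2`, `p` (goodness of fit, df = 1), `expected`, and
#'   when `both` is given, `chi2_2x2`, `p_2x2`.
#' @export
loss_bias_test <- function(a_only, d_only, both = NULL) {
  if (a_only < 0 || d_only < 0) stop("counts must be nonnegative")
  n <- a_only + d_only
  if (n == 0) stop("zero differentially retained genes: no test possible")
  e <- n / 2
  chi2 <- (a_only - e)^2 / e + (d_only - e)^2 / e
  out <- list(
    chi2 = chi2,
    p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
    df = 1L, expected = e,
    a_only = a_only, d_only = d_only
  )
  if (!is.null(both)) {
    # retained/lost per subgenome relative to the union of syntelogs
    m <- rbind(A = c(retained = both + a_only, lost = d_only),
               D = c(retained = both + d_only, lost = a_only))
    ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    out$chi2_2x2 <- unname(ct$statistic)
    out$p_2x2 <- ct$p.value
  }
  out
}

#' Sliding-window retention profile along the ancestral gene order
#'
#' Windows of `window` consecutive ancestor genes advanced by `step`; the
#' terminal window on each chromosome is allowed to be shorter so that every
#' gene is covered. Reports the retained fraction per subgenome per window.
#'
#' @param retention a `retention_table` from [build_retention()].
#' @param ancestor_order data frame with columns `id`, `chrom` in ancestral
#'   gene order (a bare character vector is treated as a single chromosome).
#' @param window window size in genes (>= 2).
#' @param step step size in genes.
#' @return data frame: chrom, window index, first/last gene index, n_genes,
#'   frac_a, frac_d; class `retention_profile`.
#' @export
retention_windows <- function(retention, ancestor_order, window = 100L, step = 10L) {
  stopifnot(inherits(retention, "retention_table"))
  if (window < 2L) stop("window must span at least 2 genes")
  if (step < 1L) stop("step must be >= 1")
  if (is.data.frame(ancestor_order)) {
    ids <- ancestor_order$id
    chrom <- if ("chrom" %in% names(ancestor_order)) ancestor_order$chrom else "anc"
  } else {
    ids <- ancestor_order
    chrom <- rep("anc", length(ids))
  }
  flag <- retention$table
  ra <- stats::setNames(flag$retained_a, flag$gene)
  rd <- stats::setNames(flag$retained_d, flag$gene)
  if (anyNA(ra[ids])) stop("ancestor_order contains genes absent from the retention table")
  out <- list()
  for (cm in unique(chrom)) {
    cid <- ids[chrom == cm]
    n <- length(cid)
    if (window > n) stop("window (", window, ") exceeds genes on ", cm, " (", n, ")")
    starts <- seq(1L, max(1L, n - window + 1L), by = step)
    last_end <- starts[length(starts)] + window - 1L
    if (last_end < n) starts <- c(starts, last_end + 1L)
    for (w in seq_along(starts)) {
      s <- starts[w]
      e <- min(s + window - 1L, n)
      g <- cid[s:e]
      out[[length(out) + 1L]] <- data.frame(
        chrom = cm, window = w, first = s, last = e, n_genes = e - s + 1L,
        frac_a = mean(ra[g]), frac_d = mean(rd[g]),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("retention_profile", class(res))
  res
}
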