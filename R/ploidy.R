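# Ploidy inference from the minor-allele-frequency (MAF) distribution of
# read depths at heterozygous sites. With homoeologue-resolved mapping an
# allotetraploid behaves as a functional diploid (MAF mode near 1/2) and an
# allohexaploid carries one divergent copy in three (mode near 1/3).

#' Filter allele-depth sites for MAF analysis
#'
#' Retains sites with total depth within `[min_total, max_total]` and minor
#' allele depth at least `min_minor` (the conventional "coverage higher than
#' 7" filter read strictly, i.e. >= 8). Removal counts per rule are attached
#' as attribute `removed`.
#'
#' @param table allele-depth data frame (chrom, pos, ref, alt, ref_depth,
#'   alt_depth).
#' @param min_total,max_total total-depth bounds.
#' @param min_minor minimum minor-allele depth.
#' @return filtered table, with attribute `removed` (named counts).
#' @export
filter_sites <- function(table, min_total = 20L, max_total = 200L, min_minor = 8L) {
  total <- table$ref_depth + table$alt_depth
  minor <- pmin(table$ref_depth, table$alt_depth)
  low <- total < min_total
  high <- total > max_total
  weak <- !low & !high & minor < min_minor
  keep <- !(low | high | weak)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(below_min_total = sum(low),
                            above_max_total = sum(high),
                            minor_below_min = sum(weak))
  if (!nrow(out)) warning("no sites survive the depth filters")
  out
}

#' MAF density, primary mode and ploidy call
#'
#' Folded minor-allele frequency `min(ref, alt) / (ref + alt)` per retained
#' site; Gaussian kernel density on (0, 0.5] with reflection at the 0.5
#' boundary (without it the mode of a tetraploid, which piles up at 0.5,
#' would be shrunk inward). The ploidy call follows the primary mode:
#' [0.40, 0.50] tetraploid-like, [0.30, 0.35] hexaploid-like, anything else
#' ambiguous. The unfolded alternate-allele fraction summary is reported
#' alongside, but the call uses the folded MAF so reference polarity cannot
#' bend the density.
#'
#' @param table filtered allele-depth table (see [filter_sites()]).
#' @param bandwidth KDE bandwidth.
#' @param min_sites minimum number of sites required.
#' @return object of class `maf_profile`: `maf` values, `grid`, `density`,
#'   `mode`, `call`, `mean_alt_fraction`.
#' @export
maf_profile <- function(table, bandwidth = 0.02, min_sites = 200L) {
  total <- table$ref_depth + table$alt_depth
  if (any(total <= 0)) {
    table <- table[total > 0, , drop = FALSE]
    total <- table$ref_depth + table$alt_depth
  }
  if (nrow(table) < min_sites) {
    stop("too few sites for a MAF density (", nrow(table), " < ", min_sites, ")")
  }
  maf <- pmin(table$ref_depth, table$alt_depth) / total
  aug <- c(maf, 1 - maf)  # reflection at the 0.5 boundary
  d <- stats::density(aug, bw = bandwidth, from = 0, to = 0.5, n = 501L)
  keep <- d$x > 0
  grid <- d$x[keep]
  dens <- d$y[keep]
  mode <- grid[which.max(dens)]
  call <- if (mode >= 0.40 && mode <= 0.50) {
    "tetraploid-like"
  } else if (mode >= 0.30 && mode <= 0.35) {
    "hexaploid-like"
  } else {
    "ambiguous"
  }
  structure(
    list(maf = maf, grid = grid, density = dens, mode = mode, call = call,
         mean_alt_fraction = mean(table$alt_depth / total),
         n_sites = length(maf), bandwidth = bandwidth),
    class = "maf_profile"
  )
}

#' @export
print.maf_profile <- function(x, ...) {
  cat(sprintf("<maf_profile> %d sites | mode = %.3f -> %s\n",
              x$n_sites, x$mode, x$call))
  invisible(x)
}
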