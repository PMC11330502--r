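# Syntelog detection and Ks-based divergence dating. Collinear chains of
# shared gene families identify homoeologous (syntenic) gene pairs; per-pair
# synonymous divergence is estimated by NG86 + Jukes-Cantor (see codon.R),
# the Ks distribution is summarised by kernel-density modes, and modes are
# converted to ages through a calibrated substitution-rate clock.

# longest strictly increasing chain over (x, y); returns indices into x/y
.longest_chain <- function(x, y) {
  n <- length(x)
  if (!n) return(integer(0))
  ord <- order(x, y)
  xs <- x[ord]
  ys <- y[ord]
  best <- rep(1L, n)
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (xs[j] < xs[i] && ys[j] < ys[i] && best[j] + 1L > best[i]) {
        best[i] <- best[j] + 1L
        prev[i] <- j
      }
    }
  }
  i <- which.max(best)
  chain <- integer(best[i])
  k <- best[i]
  while (i > 0L) {
    chain[k] <- i
    k <- k - 1L
    i <- prev[i]
  }
  ord[chain]
}

#' Find syntelogs between two ordered gene lists
#'
#' Genes sharing a family id are candidate matches; within every chromosome
#' pair, maximal collinear chains (same or reversed orientation, longest
#' chain by dynamic programming) of at least `min_block` matches are reported
#' as syntenic blocks, and matched genes are paired one-to-one.
#'
#' @param genes_x,genes_y data frames with columns `id`, `chrom`, `start`,
#'   `family` (and anything else, carried along); ordered or orderable by
#'   chromosome and start.
#' @param min_block minimum number of collinear matches per block.
#' @return data frame of syntelog pairs: `gene_a`, `gene_b`, `chrom_a`,
#'   `chrom_b`, `block`, `orientation`.
#' @export
find_syntelogs <- function(genes_x, genes_y, min_block = 5L) {
  if (!nrow(genes_x) || !nrow(genes_y)) stop("empty gene list")
  need <- c("id", "chrom", "start", "family")
  stopifnot(all(need %in% names(genes_x)), all(need %in% names(genes_y)))
  gx <- genes_x[order(genes_x$chrom, genes_x$start), need]
  gy <- genes_y[order(genes_y$chrom, genes_y$start), need]
  gx$ix <- stats::ave(seq_len(nrow(gx)), gx$chrom, FUN = seq_along)
  gy$iy <- stats::ave(seq_len(nrow(gy)), gy$chrom, FUN = seq_along)

  m <- merge(
    data.table::as.data.table(gx)[, c("id", "chrom", "family", "ix")],
    data.table::as.data.table(gy)[, c("id", "chrom", "family", "iy")],
    by = "family", allow.cartesian = TRUE, suffixes = c("_x", "_y")
  )
  if (!nrow(m)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      chrom_a = character(0), chrom_b = character(0),
                      block = character(0), orientation = character(0)))
  }
  out <- list()
  blk <- 0L
  combos <- unique(m[, c("chrom_x", "chrom_y")])
  for (ci in seq_len(nrow(combos))) {
    sub <- m[m$chrom_x == combos$chrom_x[ci] & m$chrom_y == combos$chrom_y[ci], ]
    if (nrow(sub) < min_block) next
    repeat {
      fwd <- .longest_chain(sub$ix, sub$iy)
      rev_ <- .longest_chain(sub$ix, -sub$iy)
      use_fwd <- length(fwd) >= length(rev_)
      chain <- if (use_fwd) fwd else rev_
      if (length(chain) < min_block) break
      blk <- blk + 1L
      sel <- sub[chain, ]
      out[[blk]] <- data.frame(
        gene_a = sel$id_x, gene_b = sel$id_y,
        chrom_a = sel$chrom_x, chrom_b = sel$chrom_y,
        block = sprintf("blk%04d", blk),
        orientation = if (use_fwd) "+" else "-",
        stringsAsFactors = FALSE
      )
      sub <- sub[!(sub$id_x %in% sel$id_x) & !(sub$id_y %in% sel$id_y), ]
      if (nrow(sub) < min_block) break
    }
  }
  if (!length(out)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      chrom_a = character(0), chrom_b = character(0),
                      block = character(0), orientation = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Add NG86 Ks/Ka estimates to a syntelog table
#'
#' @param pairs syntelog pairs from [find_syntelogs()] (columns `gene_a`,
#'   `gene_b`).
#' @param genome an `annotated_genome` (or gene data frame with `id`, `cds`)
#'   holding both genes of every pair.
#' @return `pairs` with numeric columns `ks` and `ka` appended (NA when the
#'   corresponding class is Jukes-Cantor saturated).
#' @export
syntelog_ks <- function(pairs, genome) {
  genes <- if (inherits(genome, "annotated_genome")) genome$genes else genome
  cds <- stats::setNames(genes$cds, genes$id)
  miss <- setdiff(c(pairs$gene_a, pairs$gene_b), names(cds))
  if (length(miss)) stop("genes absent from genome: ", paste(utils::head(miss), collapse = ", "))
  est <- lapply(seq_len(nrow(pairs)), function(i) {
    compute_ks(cds[[pairs$gene_a[i]]], cds[[pairs$gene_b[i]]])
  })
  pairs$ks <- vapply(est, function(e) e$ks, numeric(1))
  pairs$ka <- vapply(est, function(e) e$ka, numeric(1))
  pairs
}

#' Kernel-density modes of a Ks distribution
#'
#' Gaussian kernel density on [0, `ks_filter_max`]; modes are local maxima of
#' the density above 10% of its global maximum. Values above `ks_filter_max`
#' (saturated, unreliable) are excluded before estimation.
#'
#' @param ks numeric vector of Ks values (NAs and values > `ks_filter_max`
#'   dropped) or a syntelog table with a `ks` column.
#' @param bandwidth Gaussian kernel bandwidth in Ks units.
#' @param ks_filter_max upper Ks cutoff.
#' @param grid_step density evaluation step.
#' @param min_n minimum number of usable Ks values.
#' @return object of class `ks_distribution`: retained `values`, `grid`,
#'   `density`, and `modes` (data frame, ascending `location` with `height`).
#' @export
ks_modes <- function(ks, bandwidth = 0.02, ks_filter_max = 5,
                     grid_step = 0.005, min_n = 30L) {
  if (is.data.frame(ks)) ks <- ks$ks
  ks <- ks[is.finite(ks) & ks >= 0 & ks <= ks_filter_max]
  if (length(ks) < min_n) {
    stop("too few usable Ks values (", length(ks), " < ", min_n, ")")
  }
  ngrid <- as.integer(round(ks_filter_max / grid_step)) + 1L
  d <- stats::density(ks, bw = bandwidth, from = 0, to = ks_filter_max, n = ngrid)
  y <- d$y
  n <- length(y)
  left <- c(-Inf, y[-n])
  right <- c(y[-1], -Inf)
  is_max <- y >= left & y > right
  is_max[1] <- y[1] > right[1]
  is_max[n] <- y[n] > left[n]
  is_max <- is_max & y >= 0.1 * max(y)
  modes <- data.frame(location = d$x[is_max], height = y[is_max])
  modes <- modes[order(modes$location), , drop = FALSE]
  rownames(modes) <- NULL
  structure(
    list(values = ks, grid = d$x, density = y, modes = modes,
         bandwidth = bandwidth, ks_filter_max = ks_filter_max),
    class = "ks_distribution"
  )
}

#' @export
print.ks_distribution <- function(x, ...) {
  cat("<ks_distribution>", length(x$values), "Ks values, bw =", x$bandwidth, "\n")
  print(x$modes, row.names = FALSE)
  invisible(x)
}

#' Primary (highest) mode of a Ks distribution
#' @param x a `ks_distribution`.
#' @return Ks location of the highest density mode.
#' @export
primary_mode <- function(x) {
  stopifnot(inherits(x, "ks_distribution"))
  x$modes$location[which.max(x$modes$height)]
}

#' Calibrate a substitution-rate clock from a dated event
#'
#' A Ks peak of known age `t_cal` (years) implies a substitution rate
#' `r = ks_cal / (2 t_cal)` per site per year, because both lineages
#' accumulate substitutions since the split.
#'
#' @param ks_cal Ks of the calibration peak (> 0).
#' @param t_cal age of the calibration event in years (> 0).
#' @return object of class `calibrated_clock` with `rate`, `ks_cal`, `t_cal`.
#' @export
calibrate <- function(ks_cal, t_cal) {
  if (!is.numeric(ks_cal) || ks_cal <= 0 || !is.numeric(t_cal) || t_cal <= 0) {
    stop("calibration Ks and age must be positive")
  }
  structure(list(rate = ks_cal / (2 * t_cal), ks_cal = ks_cal, t_cal = t_cal),
            class = "calibrated_clock")
}

#' @export
print.calibrated_clock <- function(x, ...) {
  cat(sprintf("<calibrated_clock> r = %.4g subst/site/yr (Ks %.3g at %.4g yr)\n",
              x$rate, x$ks_cal, x$t_cal))
  invisible(x)
}

#' Date a Ks value with a calibrated clock
#'
#' @param clock a `calibrated_clock` from [calibrate()].
#' @param ks Ks value(s) to date.
#' @return age(s) in years: `ks / (2 r)`, linear in `ks`.
#' @export
date_divergence <- function(clock, ks) {
  stopifnot(inherits(clock, "calibrated_clock"))
  ks / (2 * clock$rate)
}
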