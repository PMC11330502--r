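# B-chromosome copy number and origin tracing. Copy number comes from the
# ratio of mean masked-window read depth on the B versus all other
# chromosomes; origins are traced by tiling the B into fixed-length fragments
# and mapping each against the main chromosomes by seeded ungapped alignment.

#' Aggregate a depth table into masked fixed-width windows
#'
#' Mean depth per `window`-bp window (terminal windows may be shorter),
#' weighted by overlap with the input intervals. Windows with at least
#' `mask_fraction` of their length under a repeat mask are flagged `repeat`.
#' Windows whose depth exceeds `artifact_fold` times the genome-wide median
#' in this track *and* in every additional lineage track supplied are flagged
#' `artifact` (collapsed organellar insertions and assembly errors spike in
#' every lineage, unlike true copy-number differences).
#'
#' @param depth data frame (chrom, start, end, depth), 0-based half-open
#'   intervals at any resolution that nests within `window`.
#' @param masks optional data frame (chrom, start, end, class); only rows
#'   with class `repeat` mask windows.
#' @param window window width in bp.
#' @param extra_depth list of depth tables from other lineages used by the
#'   artifact rule.
#' @param artifact_fold artifact threshold as a multiple of the median.
#' @param mask_fraction minimum masked fraction for the repeat flag.
#' @return data frame of class `coverage_track`: chrom, start, end, depth,
#'   mask (NA, `"repeat"` or `"artifact"`).
#' @export
window_coverage <- function(depth, masks = NULL, window = 1000L,
                            extra_depth = list(), artifact_fold = 3,
                            mask_fraction = 0.5) {
  wtrack <- .windowed_depth(depth, window)
  wtrack$mask <- NA_character_
  if (!is.null(masks) && nrow(masks)) {
    rep_m <- masks[masks$class == "repeat", , drop = FALSE]
    if (nrow(rep_m)) {
      mfrac <- .window_overlap_fraction(wtrack, rep_m)
      wtrack$mask[mfrac >= mask_fraction] <- "repeat"
    }
  }
  med <- stats::median(wtrack$depth[is.na(wtrack$mask)])
  hot <- wtrack$depth > artifact_fold * med
  for (ex in extra_depth) {
    exw <- .windowed_depth(ex, window)
    key <- paste(wtrack$chrom, wtrack$start)
    exd <- stats::setNames(exw$depth, paste(exw$chrom, exw$start))[key]
    exmed <- stats::median(exw$depth)
    hot <- hot & !is.na(exd) & exd > artifact_fold * exmed
  }
  wtrack$mask[hot & is.na(wtrack$mask)] <- "artifact"
  class(wtrack) <- c("coverage_track", class(wtrack))
  wtrack
}

.windowed_depth <- function(depth, window) {
  dt <- data.table::as.data.table(depth[, c("chrom", "start", "end", "depth")])
  win <- dt[, {
    lim <- max(end)
    st <- seq(0L, lim - 1L, by = as.integer(window))
    list(start = st, end = pmin(st + as.integer(window), lim))
  }, by = "chrom"]
  data.table::setkey(win, chrom, start, end)
  data.table::setkey(dt, chrom, start, end)
  ov <- data.table::foverlaps(dt, win, nomatch = NULL)
  ov[, `:=`(w = pmin(i.end, end) - pmax(i.start, start))]
  agg <- ov[, list(depth = sum(depth * w) / sum(w)), by = c("chrom", "start", "end")]
  out <- as.data.frame(agg[order(chrom, start)])
  rownames(out) <- NULL
  out
}

.window_overlap_fraction <- function(wtrack, intervals) {
  win <- data.table::as.data.table(wtrack[, c("chrom", "start", "end")])
  win[, `:=`(idx = .I)]
  iv <- data.table::as.data.table(intervals[, c("chrom", "start", "end")])
  data.table::setkey(iv, chrom, start, end)
  data.table::setkey(win, chrom, start, end)
  ov <- data.table::foverlaps(win, iv, nomatch = NULL)
  frac <- numeric(nrow(wtrack))
  if (nrow(ov)) {
    ov[, `:=`(w = pmin(i.end, end) - pmax(i.start, start))]
    agg <- ov[, list(w = sum(w)), by = "idx"]
    frac[agg$idx] <- agg$w / (wtrack$end[agg$idx] - wtrack$start[agg$idx])
  }
  frac
}

#' B-chromosome copy number from coverage ratios
#'
#' Ratio of mean unmasked-window depth on the B chromosome to the mean over
#' all other chromosomes. Main chromosomes sit at a 2-copy baseline, so the
#' ratio approximates B copies / 2: about 1 at standard dosage, about 2 when
#' doubled, and at or below ~0.4 the B is likely absent with only residual
#' mismapping.
#'
#' @param track a `coverage_track` from [window_coverage()].
#' @param b_chromosome name of the B chromosome in the track.
#' @return list of class `b_copy_estimate`: `depth_b`, `depth_rest`, `ratio`,
#'   `interpretation`.
#' @export
b_copy_ratio <- function(track, b_chromosome = "chrB") {
  if (!b_chromosome %in% track$chrom) {
    stop("chromosome '", b_chromosome, "' absent from the coverage track")
  }
  ok <- is.na(track$mask)
  on_b <- track$chrom == b_chromosome
  if (!any(ok & on_b) || !any(ok & !on_b)) {
    stop("all windows masked on one side of the comparison")
  }
  depth_b <- mean(track$depth[ok & on_b])
  depth_rest <- mean(track$depth[ok & !on_b])
  if (depth_rest <= 0) stop("zero mean depth on the non-B chromosomes")
  ratio <- depth_b / depth_rest
  interp <- if (ratio <= 0.4) {
    "B chromosome likely absent; residual depth consistent with mismapping"
  } else {
    sprintf("approximately %.1f B copies relative to the 2-copy baseline", 2 * ratio)
  }
  structure(list(depth_b = depth_b, depth_rest = depth_rest, ratio = ratio,
                 interpretation = interp),
            class = "b_copy_estimate")
}

#' @export
print.b_copy_estimate <- function(x, ...) {
  cat(sprintf("<b_copy_estimate> ratio = %.3f (B %.2f / rest %.2f): %s\n",
              x$ratio, x$depth_b, x$depth_rest, x$interpretation))
  invisible(x)
}

#' Trace B-chromosome origins against the main chromosomes
#'
#' The B sequence is tiled into consecutive `fragment`-bp pieces (a terminal
#' remainder is kept when at least half a fragment long). Each fragment is
#' seeded into the main chromosomes by exact `seed_k`-mer matches on both
#' strands and scored by ungapped alignment at every seeded placement. A
#' fragment maps "primarily" when its best placement is unique (strictly
#' better than any other candidate), with identity at least `min_identity`
#' over at least `min_cov` of the fragment.
#'
#' @param b_sequence B-chromosome sequence (character string).
#' @param main_genome named character vector of main-chromosome sequences, or
#'   an `annotated_genome` (a chromosome named like the B is excluded).
#' @param fragment tile length in bp (>= 50).
#' @param min_identity minimum alignment identity for a primary hit.
#' @param min_cov minimum fraction of the fragment covered by the placement.
#' @param seed_k exact-match seed length.
#' @param seed_stride spacing of seeds along each fragment.
#' @param b_name B chromosome name to exclude when `main_genome` is an
#'   `annotated_genome`.
#' @return object of class `fragment_trace`: `$fragments` (per-fragment best
#'   hit with identity, coverage and primary flag), `$n_fragments`,
#'   `$n_primary`, `$fraction` (= n_primary / n_fragments), `$per_chromosome`
#'   primary-hit counts.
#' @export
trace_origins <- function(b_sequence, main_genome, fragment = 300L,
                          min_identity = 0.8, min_cov = 0.5,
                          seed_k = 15L, seed_stride = 5L, b_name = "chrB") {
  if (fragment < 50L) stop("fragment must be at least 50 bp")
  chroms <- get_chromosomes(main_genome)
  chroms <- chroms[setdiff(names(chroms), b_name)]
  if (!length(chroms)) stop("empty main genome")
  blen <- nchar(b_sequence)
  n_full <- blen %/% fragment
  rem <- blen %% fragment
  starts <- (seq_len(n_full) - 1L) * fragment
  lens <- rep(as.integer(fragment), n_full)
  if (rem >= fragment / 2) {
    starts <- c(starts, n_full * fragment)
    lens <- c(lens, rem)
  }
  nfrag <- length(starts)
  if (!nfrag) stop("B sequence shorter than half a fragment")
  frags <- substring(b_sequence, starts + 1L, starts + lens)
  frags_rc <- revcomp(frags)

  index <- data.table::rbindlist(lapply(names(chroms), function(nm) {
    s <- chroms[[nm]]
    n <- nchar(s)
    if (n < seed_k) return(NULL)
    data.table::data.table(
      kmer = substring(s, seq_len(n - seed_k + 1L), seq_len(n - seed_k + 1L) + seed_k - 1L),
      chrom = nm,
      pos = seq_len(n - seed_k + 1L) - 1L
    )
  }))
  data.table::setkey(index, kmer)

  seed_dt <- data.table::rbindlist(lapply(seq_len(nfrag), function(i) {
    fl <- lens[i]
    if (fl < seed_k) return(NULL)
    off <- seq(1L, fl - seed_k + 1L, by = seed_stride)
    data.table::rbindlist(list(
      data.table::data.table(frag = i, off = off, strand = "+",
                             kmer = substring(frags[i], off, off + seed_k - 1L)),
      data.table::data.table(frag = i, off = off, strand = "-",
                             kmer = substring(frags_rc[i], off, off + seed_k - 1L))
    ))
  }))
  hits <- index[seed_dt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  rec <- vector("list", nfrag)
  if (nrow(hits)) {
    hits[, `:=`(place = pos - (off - 1L))]
    cand <- unique(hits[, c("frag", "chrom", "place", "strand")])
    clen <- vapply(chroms, nchar, integer(1))
    flen <- lens[cand$frag]
    gs <- pmax(cand$place, 0L)
    ge <- pmin(cand$place + flen, clen[cand$chrom])
    keep <- ge - gs > 0L
    cand <- cand[keep]
    gs <- gs[keep]; ge <- ge[keep]; flen <- flen[keep]
    if (nrow(cand)) {
      gsub <- substr(chroms[cand$chrom], gs + 1L, ge)
      qseq <- ifelse(cand$strand == "+", frags[cand$frag], frags_rc[cand$frag])
      qoff <- gs - cand$place  # fragment offset where the genomic slice begins
      qsub <- substr(qseq, qoff + 1L, qoff + (ge - gs))
      ident <- vapply(seq_len(nrow(cand)), function(i) {
        a <- utf8ToInt(gsub[i])
        b <- utf8ToInt(qsub[i])
        mean(a == b)
      }, numeric(1))
      cand[, `:=`(identity = ident, coverage = (ge - gs) / flen)]
      cand <- cand[cand$coverage >= min_cov]
      if (nrow(cand)) {
        data.table::setorder(cand, frag, -identity)
        for (fi in unique(cand$frag)) {
          sub <- cand[cand$frag == fi]
          best <- sub[1L]
          unique_best <- nrow(sub) == 1L || best$identity > sub$identity[2L] + 1e-9
          rec[[fi]] <- data.frame(
            b_start = starts[fi], b_end = starts[fi] + lens[fi],
            chrom = best$chrom, pos = best$place, strand = best$strand,
            identity = best$identity, coverage = best$coverage,
            primary = unique_best && best$identity >= min_identity,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  nohit <- vapply(rec, is.null, logical(1))
  for (fi in which(nohit)) {
    rec[[fi]] <- data.frame(
      b_start = starts[fi], b_end = starts[fi] + lens[fi],
      chrom = NA_character_, pos = NA_integer_, strand = NA_character_,
      identity = NA_real_, coverage = NA_real_, primary = FALSE,
      stringsAsFactors = FALSE
    )
  }
  fragments <- do.call(rbind, rec)
  rownames(fragments) <- NULL
  n_primary <- sum(fragments$primary)
  per_chrom <- table(fragments$chrom[fragments$primary])
  structure(
    list(fragments = fragments, n_fragments = nfrag, n_primary = n_primary,
         fraction = n_primary / nfrag,
         per_chromosome = stats::setNames(as.integer(per_chrom), names(per_chrom))),
    class = "fragment_trace"
  )
}

#' @export
print.fragment_trace <- function(x, ...) {
  cat(sprintf("<fragment_trace> %d of %d fragments mapped primarily (%.2f%%)\n",
              x$n_primary, x$n_fragments, 100 * x$fraction))
  invisible(x)
}

#' Fraction of primarily mapped fragments
#'
#' @param n_primary number of fragments with a unique best hit passing the
#'   identity and coverage thresholds.
#' @param n_fragments total number of fragments tiled from the B chromosome.
#' @param percent report a percentage (default) or a proportion.
#' @return numeric fraction sourced from the main chromosomes.
#' @export
fraction_primary <- function(n_primary, n_fragments, percent = TRUE) {
  if (n_fragments < 1) stop("n_fragments must be positive")
  if (n_primary < 0 || n_primary > n_fragments) {
    stop("n_primary must lie in [0, n_fragments]")
  }
  f <- n_primary / n_fragments
  if (percent) 100 * f else f
}
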