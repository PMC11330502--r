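# Codon-level machinery shared by the simulator, the NG86 Ks estimator and
# the variant-effect annotator. All lookup tables are derived from the
# standard genetic code (Biostrings::GENETIC_CODE) and cached per session.

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# row i = alternatives to BASES[i]
.ALT_BASES <- rbind(
  c("C", "G", "T"),
  c("A", "G", "T"),
  c("A", "C", "T"),
  c("A", "C", "G")
)

.codon_cache <- new.env(parent = emptyenv())

#' Reverse complement of DNA strings
#' @param x character vector of DNA sequences (ACGT alphabet).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(x) chartr("ACGT", "TGCA", x)

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# n random sense (non-stop) codons
random_codons <- function(n) {
  cod <- paste0(
    sample(BASES, n, replace = TRUE),
    sample(BASES, n, replace = TRUE),
    sample(BASES, n, replace = TRUE)
  )
  bad <- which(cod %in% STOP_CODONS)
  while (length(bad)) {
    cod[bad] <- paste0(
      sample(BASES, length(bad), replace = TRUE),
      sample(BASES, length(bad), replace = TRUE),
      sample(BASES, length(bad), replace = TRUE)
    )
    bad <- bad[cod[bad] %in% STOP_CODONS]
  }
  cod
}

split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length not divisible by 3")
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Per-codon mutational opportunity tables
#'
#' For every sense codon and codon position, how many of the three possible
#' single-base changes are synonymous, and which target bases give a
#' synonymous or a nonsynonymous (non-stop) codon. Changes creating a stop
#' codon count as nonsynonymous for site totals (so synonymous + nonsynonymous
#' site fractions sum to one), but are never offered as nonsynonymous
#' alternatives when sampling variants.
#'
#' @return list with elements `codons`, `aa`, `syn_count` (64 x 3 integer
#'   matrix), `syn_sites` (numeric, NG86 synonymous sites per codon),
#'   `syn_alts`, `nonsyn_alts` (nested lists codon -> position -> bases).
#' @keywords internal
codon_tables <- function() {
  if (!is.null(.codon_cache$tables)) return(.codon_cache$tables)
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  aa <- unname(code)
  ncod <- length(codons)
  cod_mat <- do.call(rbind, strsplit(codons, ""))
  syn_count <- matrix(0L, ncod, 3L, dimnames = list(codons, NULL))
  syn_alts <- vector("list", ncod)
  nonsyn_alts <- vector("list", ncod)
  names(syn_alts) <- names(nonsyn_alts) <- codons
  for (i in seq_len(ncod)) {
    sa <- vector("list", 3L)
    na_ <- vector("list", 3L)
    for (p in 1:3) {
      alts <- setdiff(BASES, cod_mat[i, p])
      mut <- vapply(alts, function(b) {
        cc <- cod_mat[i, ]
        cc[p] <- b
        paste(cc, collapse = "")
      }, character(1))
      maa <- unname(code[mut])
      syn <- maa == aa[i]
      syn_count[i, p] <- sum(syn)
      sa[[p]] <- alts[syn]
      na_[[p]] <- alts[!syn & maa != "*"]
    }
    syn_alts[[i]] <- sa
    nonsyn_alts[[i]] <- na_
  }
  out <- list(
    codons = codons, aa = aa, code = code,
    syn_count = syn_count, syn_sites = rowSums(syn_count) / 3,
    syn_alts = syn_alts, nonsyn_alts = nonsyn_alts
  )
  .codon_cache$tables <- out
  out
}

.perm_rows <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  if (k == 2L) return(rbind(c(1L, 2L), c(2L, 1L)))
  rbind(
    c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
    c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)
  )
}

# NG86 pathway-averaged synonymous/nonsynonymous difference counts for one
# codon pair. Every ordering of the differing positions is walked; paths that
# pass through a stop codon are excluded (all paths are used if none avoids a
# stop). Returns c(syn, nonsyn).
.ng86_pair_counts <- function(c1, c2, code) {
  if (c1 == c2) return(c(0, 0))
  v1 <- strsplit(c1, "")[[1]]
  v2 <- strsplit(c2, "")[[1]]
  diffpos <- which(v1 != v2)
  perms <- .perm_rows(length(diffpos))
  path_s <- numeric(0)
  path_n <- numeric(0)
  path_ok <- logical(0)
  for (r in seq_len(nrow(perms))) {
    cur <- v1
    s <- 0
    n <- 0
    ok <- TRUE
    for (p in diffpos[perms[r, ]]) {
      nxt <- cur
      nxt[p] <- v2[p]
      aa_cur <- unname(code[paste(cur, collapse = "")])
      aa_nxt <- unname(code[paste(nxt, collapse = "")])
      if (aa_nxt == "*" || aa_cur == "*") ok <- FALSE
      if (identical(aa_cur, aa_nxt)) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    path_s <- c(path_s, s)
    path_n <- c(path_n, n)
    path_ok <- c(path_ok, ok)
  }
  if (any(path_ok)) {
    c(mean(path_s[path_ok]), mean(path_n[path_ok]))
  } else {
    c(mean(path_s), mean(path_n))
  }
}

# 64 x 64 pathway-averaged difference matrices, built once and cached.
ng86_tables <- function() {
  if (!is.null(.codon_cache$ng86)) return(.codon_cache$ng86)
  tb <- codon_tables()
  ncod <- length(tb$codons)
  sd_mat <- matrix(0, ncod, ncod, dimnames = list(tb$codons, tb$codons))
  nd_mat <- sd_mat
  for (i in seq_len(ncod - 1L)) {
    for (j in seq((i + 1L), ncod)) {
      cnt <- .ng86_pair_counts(tb$codons[i], tb$codons[j], tb$code)
      sd_mat[i, j] <- sd_mat[j, i] <- cnt[1]
      nd_mat[i, j] <- nd_mat[j, i] <- cnt[2]
    }
  }
  out <- list(sd = sd_mat, nd = nd_mat)
  .codon_cache$ng86 <- out
  out
}

#' Jukes-Cantor distance correction
#'
#' @param p observed proportion of differences per site.
#' @return corrected distance, or `NA` when `p >= 3/4` (saturation: the
#'   correction is undefined).
#' @export
jukes_cantor <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 / 3 * p))
}

#' Pairwise Ka/Ks by the Nei-Gojobori (1986) method
#'
#' Counts synonymous and nonsynonymous sites by the fractional NG86 scheme
#' (changes to a stop codon count towards nonsynonymous sites so that S + N =
#' 3 x codons), averages observed differences over all minimal mutational
#' pathways between each codon pair, and applies the Jukes-Cantor multiple-hit
#' correction to each class.
#'
#' @param cds_a,cds_b in-frame, gap-free coding sequences of equal length.
#' @return list with `ks`, `ka` (NA when the class is saturated), observed
#'   proportions `ps`, `pn`, and site counts `syn_sites`, `nonsyn_sites`.
#' @examples
#' compute_ks("ATGGCT", "ATGGCC")
#' @export
compute_ks <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b)) stop("sequences differ in length")
  cod_a <- split_codons(cds_a)
  cod_b <- split_codons(cds_b)
  tb <- codon_tables()
  ia <- match(cod_a, tb$codons)
  ib <- match(cod_b, tb$codons)
  keep <- !is.na(ia) & !is.na(ib)
  ia <- ia[keep]
  ib <- ib[keep]
  if (!length(ia)) stop("no unambiguous codons shared by the two sequences")
  if (any(tb$aa[ia] == "*") || any(tb$aa[ib] == "*")) {
    stop("internal stop codon in coding sequence")
  }
  s_sites <- sum((tb$syn_sites[ia] + tb$syn_sites[ib]) / 2)
  n_sites <- 3 * length(ia) - s_sites
  ng <- ng86_tables()
  sd_tot <- sum(ng$sd[cbind(ia, ib)])
  nd_tot <- sum(ng$nd[cbind(ia, ib)])
  ps <- if (s_sites > 0) sd_tot / s_sites else NA_real_
  pn <- if (n_sites > 0) nd_tot / n_sites else NA_real_
  list(
    ks = jukes_cantor(ps), ka = jukes_cantor(pn),
    ps = ps, pn = pn,
    syn_sites = s_sites, nonsyn_sites = n_sites
  )
}

# Codon-aware substitution process used by the simulator. Mutation events
# arrive as a Poisson process with `rate` expected proposals per nucleotide
# site; each event proposes one of the three alternative bases uniformly.
# Synonymous proposals are always accepted, nonsynonymous ones with
# probability `omega`, and proposals creating a stop codon are rejected, so
# the expected accepted synonymous substitutions per synonymous site equal
# `rate` and the CDS stays translatable. Codons hit by a single event are
# processed vectorised; multiply-hit codons are evolved event by event.
evolve_codons <- function(codons, rate, omega) {
  L <- length(codons)
  if (L == 0L || rate <= 0) return(codons)
  tb <- codon_tables()
  code <- tb$code
  npos <- 3L * L
  n_ev <- stats::rpois(1L, npos * rate)
  if (n_ev == 0L) return(codons)
  pos <- sample.int(npos, n_ev, replace = TRUE)
  ci <- (pos - 1L) %/% 3L + 1L
  off <- (pos - 1L) %% 3L + 1L
  multi <- unique(ci[duplicated(ci)])
  single <- !(ci %in% multi)
  if (any(single)) {
    sci <- ci[single]
    soff <- off[single]
    cur <- codons[sci]
    curbase <- substr(cur, soff, soff)
    pick <- sample.int(3L, length(cur), replace = TRUE)
    newbase <- .ALT_BASES[cbind(match(curbase, BASES), pick)]
    newcod <- cur
    substr(newcod, soff, soff) <- newbase
    aa_old <- unname(code[cur])
    aa_new <- unname(code[newcod])
    u <- stats::runif(length(cur))
    acc <- aa_new == aa_old | (aa_new != "*" & u < omega)
    codons[sci[acc]] <- newcod[acc]
  }
  if (length(multi)) {
    ord <- which(ci %in% multi)
    for (e in ord) {
      cd <- codons[ci[e]]
      p <- off[e]
      curbase <- substr(cd, p, p)
      newbase <- .ALT_BASES[match(curbase, BASES), sample.int(3L, 1L)]
      newcod <- cd
      substr(newcod, p, p) <- newbase
      aa_old <- unname(code[cd])
      aa_new <- unname(code[newcod])
      if (aa_new == aa_old || (aa_new != "*" && stats::runif(1L) < omega)) {
        codons[ci[e]] <- newcod
      }
    }
  }
  codons
}

# Uniform substitution noise on non-coding sequence: each base substituted
# with probability p_sub, drawing uniformly among the three alternatives.
mutate_noncoding <- function(seq, p_sub) {
  if (p_sub <= 0 || nchar(seq) == 0L) return(seq)
  v <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(v)) < p_sub)
  if (length(hit)) {
    v[hit] <- .ALT_BASES[cbind(
      match(v[hit], BASES),
      sample.int(3L, length(hit), replace = TRUE)
    )]
    seq <- paste(v, collapse = "")
  }
  seq
}
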