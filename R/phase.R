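# Subgenome phasing from subgenome-specific k-mers. Chromosomes of an
# allopolyploid carry private repeat families expanded after hybridisation;
# counting canonical k-mers, keeping those that are abundant and differential
# between homoeologous partners, and clustering chromosomes on the retained
# profile separates the two subgenomes.

#' Count canonical k-mers per chromosome
#'
#' Canonical form is the lexicographic minimum of a k-mer and its reverse
#' complement (unique because k is odd). Windows containing ambiguous bases
#' are skipped.
#'
#' @param genome an `annotated_genome` or named character vector of sequences.
#' @param k odd k-mer length between 3 and 21 (13 is the conventional choice
#'   for repeat-based phasing).
#' @return object of class `kmer_matrix`: sparse per-chromosome counts
#'   (`$counts`: chrom, kmer, count), chromosome lengths and `k`.
#' @export
count_kmers <- function(genome, k = 13L) {
  k <- as.integer(k)
  if (k %% 2L != 1L || k < 3L || k > 21L) stop("k must be odd and in [3, 21]")
  chroms <- get_chromosomes(genome)
  chroms <- chroms[order(names(chroms))]
  counts <- data.table::rbindlist(lapply(names(chroms), function(nm) {
    s <- chroms[[nm]]
    n <- nchar(s)
    if (n < k) stop("chromosome '", nm, "' is shorter than k = ", k)
    km <- substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
    if (grepl("[^ACGT]", s)) km <- km[!grepl("[^ACGT]", km)]
    tab <- table(km)
    uk <- names(tab)
    rc <- revcomp(uk)
    dt <- data.table::data.table(
      kmer = ifelse(uk <= rc, uk, rc),
      count = as.integer(tab)
    )
    dt <- dt[, list(count = sum(count)), by = "kmer"]
    dt[, `:=`(chrom = nm)]
    dt
  }))
  structure(
    list(counts = counts[, c("chrom", "kmer", "count")],
         lengths = vapply(chroms, nchar, integer(1)),
         k = k),
    class = "kmer_matrix"
  )
}

#' @export
print.kmer_matrix <- function(x, ...) {
  cat("<kmer_matrix> k =", x$k, "|", length(unique(x$counts$kmer)),
      "distinct canonical k-mers across", length(x$lengths), "chromosomes\n")
  invisible(x)
}

#' Total count per canonical k-mer
#' @param mat a `kmer_matrix`.
#' @return named integer vector of genome-wide counts.
#' @export
kmer_totals <- function(mat) {
  tot <- mat$counts[, list(total = sum(count)), by = "kmer"]
  stats::setNames(tot$total, tot$kmer)
}

# wide chromosome x kmer count matrix (all chromosomes, zero-filled)
.kmer_wide <- function(mat) {
  w <- data.table::dcast(mat$counts, kmer ~ chrom, value.var = "count", fill = 0L)
  km <- w$kmer
  w[, `:=`(kmer = NULL)]
  m <- as.matrix(w)
  rownames(m) <- km
  missing <- setdiff(names(mat$lengths), colnames(m))
  if (length(missing)) {
    m <- cbind(m, matrix(0L, nrow(m), length(missing),
                         dimnames = list(NULL, missing)))
  }
  m[, order(colnames(m)), drop = FALSE]
}

.check_pairs <- function(pairs, chrom_names) {
  need <- c("member1", "member2")
  if (!all(need %in% names(pairs))) stop("pairs must have columns member1, member2")
  members <- c(pairs$member1, pairs$member2)
  if (anyDuplicated(members)) stop("a chromosome appears in more than one pair")
  uncovered <- setdiff(chrom_names, members)
  if (length(uncovered)) {
    stop("pairing does not cover chromosome(s): ", paste(uncovered, collapse = ", "))
  }
  unknown <- setdiff(members, chrom_names)
  if (length(unknown)) {
    stop("pairing names unknown chromosome(s): ", paste(unknown, collapse = ", "))
  }
  invisible(pairs)
}

#' Select subgenome-differential k-mers
#'
#' Retains k-mers whose genome-wide count is at least `min_total` and whose
#' fold change between the two members of a homoeologous pair is at least
#' `min_fold` in a majority of pairs. The fold change is max/min of the two
#' raw counts; a pseudocount of 1 replaces a zero denominator.
#'
#' @param mat a `kmer_matrix` from [count_kmers()].
#' @param pairs data frame of homoeologous chromosome pairs (columns
#'   `member1`, `member2`) covering every chromosome of `mat`.
#' @param min_total minimum genome-wide count (abundance filter).
#' @param min_fold minimum between-homoeolog fold change.
#' @return filtered `kmer_matrix` containing only the differential k-mers.
#' @export
select_differential_kmers <- function(mat, pairs, min_total = 100, min_fold = 2) {
  stopifnot(inherits(mat, "kmer_matrix"))
  .check_pairs(pairs, names(mat$lengths))
  tot <- kmer_totals(mat)
  cand <- names(tot)[tot >= min_total]
  if (!length(cand)) {
    stop("no phasing signal: no k-mer reaches total count ", min_total,
         "; lower min_total or check that the assembly carries ",
         "subgenome-specific repeats")
  }
  sub <- mat
  sub$counts <- mat$counts[mat$counts$kmer %in% cand, ]
  wide <- .kmer_wide(sub)
  npair <- nrow(pairs)
  fold_ok <- matrix(FALSE, nrow(wide), npair)
  for (i in seq_len(npair)) {
    a <- wide[, pairs$member1[i]]
    b <- wide[, pairs$member2[i]]
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    fold <- ifelse(lo == 0, hi + 1, hi / lo)
    fold_ok[, i] <- fold >= min_fold
  }
  keep <- rownames(wide)[rowSums(fold_ok) > npair / 2]
  if (!length(keep)) {
    stop("no phasing signal: no abundant k-mer is differential at fold ",
         min_fold, " in a majority of homoeologous pairs; the subgenomes may ",
         "lack private repeat families or min_fold may be too strict")
  }
  out <- mat
  out$counts <- mat$counts[mat$counts$kmer %in% keep, ]
  out
}

#' Assign chromosomes to subgenomes
#'
#' Clusters chromosomes on their length-normalised differential k-mer
#' profiles (correlation distance, average-linkage hierarchical clustering
#' cut at two groups) and checks that every homoeologous pair is split
#' between the groups. Labels A and D are arbitrary up to a global swap; the
#' group containing the alphabetically first chromosome is called A. The
#' per-chromosome score is a silhouette-style separation (mean between-group
#' minus mean within-group distance over their maximum).
#'
#' @param mat a differential `kmer_matrix` from [select_differential_kmers()].
#' @param pairs homoeologous pair table as in [select_differential_kmers()].
#' @return object of class `subgenome_assignment`: `$assignment` (chromosome,
#'   label, score), `$diagnostic_kmers` (kmer, subgenome), `$k`.
#' @export
assign_subgenomes <- function(mat, pairs) {
  stopifnot(inherits(mat, "kmer_matrix"))
  .check_pairs(pairs, names(mat$lengths))
  if (!nrow(mat$counts)) stop("differential k-mer matrix is empty")
  wide <- .kmer_wide(mat)
  norm <- sweep(wide, 2, mat$lengths[colnames(wide)], `/`)
  x <- t(norm)  # chromosomes in rows
  cc <- suppressWarnings(stats::cor(t(x)))
  cc[!is.finite(cc)] <- 0
  d <- stats::as.dist(1 - cc)
  hc <- stats::hclust(d, method = "average")
  grp <- stats::cutree(hc, k = 2L)
  split_ok <- grp[pairs$member1] != grp[pairs$member2]
  if (!all(split_ok)) {
    stop("no phasing signal: homoeologous pair(s) ",
         paste(pairs$member1[!split_ok], pairs$member2[!split_ok],
               sep = "/", collapse = ", "),
         " were not separated by the differential k-mer profile")
  }
  first <- sort(names(grp))[1L]
  labels <- ifelse(grp == grp[[first]], "A", "D")
  dm <- as.matrix(d)
  score <- vapply(names(grp), function(cm) {
    own <- setdiff(names(grp)[grp == grp[[cm]]], cm)
    oth <- names(grp)[grp != grp[[cm]]]
    a <- if (length(own)) mean(dm[cm, own]) else 0
    b <- mean(dm[cm, oth])
    (b - a) / max(a, b)
  }, numeric(1))
  mean_a <- rowMeans(norm[, names(labels)[labels == "A"], drop = FALSE])
  mean_d <- rowMeans(norm[, names(labels)[labels == "D"], drop = FALSE])
  diag_km <- data.frame(
    kmer = rownames(norm),
    subgenome = ifelse(mean_a >= mean_d, "A", "D"),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      assignment = data.frame(chromosome = names(grp), label = unname(labels),
                              score = unname(score), stringsAsFactors = FALSE),
      diagnostic_kmers = diag_km,
      k = mat$k
    ),
    class = "subgenome_assignment"
  )
}

#' @export
print.subgenome_assignment <- function(x, ...) {
  cat("<subgenome_assignment> k =", x$k, "\n")
  print(x$assignment, row.names = FALSE)
  invisible(x)
}

#' Compare a subgenome assignment with a true labelling up to label swap
#'
#' @param assignment a `subgenome_assignment` or data frame with columns
#'   `chromosome`, `label`.
#' @param truth_labels named character vector of true labels per chromosome.
#' @return TRUE if the assignment matches the truth under the identity or the
#'   swapped labelling.
#' @export
assignment_matches_truth <- function(assignment, truth_labels) {
  a <- if (inherits(assignment, "subgenome_assignment")) assignment$assignment else assignment
  lab <- stats::setNames(a$label, a$chromosome)
  truth <- truth_labels[names(lab)]
  swap <- c(A = "D", D = "A")
  all(lab == truth) || all(lab == swap[truth])
}
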