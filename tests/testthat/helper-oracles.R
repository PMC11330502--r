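# Independent oracles used to validate the package implementations. They are
# deliberately written with different algorithms (recursion, explicit
# enumeration, log-scale combinatorics) than the code they check.

.oracle_code <- Biostrings::GENETIC_CODE

# --- NG86 oracle: explicit per-codon enumeration + recursive pathways ------
oracle_ng86 <- function(a, b) {
  stopifnot(nchar(a) == nchar(b), nchar(a) %% 3 == 0)
  idx <- seq(1, nchar(a), by = 3)
  cods_a <- substring(a, idx, idx + 2)
  cods_b <- substring(b, idx, idx + 2)

  site_count <- function(cod) {
    s <- 0
    for (p in 1:3) {
      for (nt in setdiff(c("A", "C", "G", "T"), substr(cod, p, p))) {
        m <- cod
        substr(m, p, p) <- nt
        if (.oracle_code[[m]] == .oracle_code[[cod]]) s <- s + 1 / 3
      }
    }
    s
  }

  pair_diffs <- function(c1, c2) {
    dp <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(dp)) return(c(0, 0))
    acc <- list()
    walk <- function(cur, remaining, s, n, ok) {
      if (!length(remaining)) {
        acc[[length(acc) + 1]] <<- c(s, n, ok)
        return(invisible(NULL))
      }
      for (p in remaining) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        syn <- .oracle_code[[cur]] == .oracle_code[[nxt]]
        stopped <- .oracle_code[[cur]] == "*" || .oracle_code[[nxt]] == "*"
        walk(nxt, setdiff(remaining, p),
             s + as.integer(syn), n + as.integer(!syn), ok && !stopped)
      }
    }
    walk(c1, dp, 0L, 0L, TRUE)
    m <- do.call(rbind, acc)
    valid <- m[, 3] == 1
    if (any(valid)) c(mean(m[valid, 1]), mean(m[valid, 2]))
    else c(mean(m[, 1]), mean(m[, 2]))
  }

  S <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(cods_a)) {
    S <- S + (site_count(cods_a[i]) + site_count(cods_b[i])) / 2
    d <- pair_diffs(cods_a[i], cods_b[i])
    Sd <- Sd + d[1]
    Nd <- Nd + d[2]
  }
  N <- 3 * length(cods_a) - S
  jc <- function(p) if (p >= 0.75) NA_real_ else -3 / 4 * log(1 - 4 * p / 3)
  list(ks = jc(Sd / S), ka = jc(Nd / N), ps = Sd / S, pn = Nd / N,
       syn_sites = S, nonsyn_sites = N)
}

# --- hypergeometric upper tail by exhaustive log-scale summation -----------
oracle_hyper_tail <- function(k, pop_hits, pop_size, draws) {
  i <- seq(k, min(pop_hits, draws))
  if (!length(i) || k > min(pop_hits, draws)) return(0)
  sum(exp(lchoose(pop_hits, i) + lchoose(pop_size - pop_hits, draws - i) -
            lchoose(pop_size, draws)))
}

# --- single-mutation consequence oracle ------------------------------------
oracle_effect <- function(codon, pos, alt) {
  new <- codon
  substr(new, pos, pos) <- alt
  a1 <- .oracle_code[[codon]]
  a2 <- .oracle_code[[new]]
  if (a1 == a2) "synonymous"
  else if (a1 == "*" || a2 == "*") "nonsense"
  else "missense"
}

# --- random in-frame CDS material for oracle comparisons -------------------
oracle_random_cds <- function(n_codons) {
  repeat {
    cod <- paste0(sample(c("A", "C", "G", "T"), n_codons, TRUE),
                  sample(c("A", "C", "G", "T"), n_codons, TRUE),
                  sample(c("A", "C", "G", "T"), n_codons, TRUE))
    if (!any(cod %in% c("TAA", "TAG", "TGA"))) return(paste(cod, collapse = ""))
  }
}

oracle_mutate_cds <- function(cds, n_mut) {
  v <- strsplit(cds, "")[[1]]
  done <- 0L
  tries <- 0L
  while (done < n_mut && tries < 50L * n_mut) {
    tries <- tries + 1L
    p <- sample(length(v), 1L)
    nb <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
    w <- v
    w[p] <- nb
    ci <- (p - 1L) %/% 3L
    cod <- paste(w[(3L * ci + 1L):(3L * ci + 3L)], collapse = "")
    if (.oracle_code[[cod]] == "*") next
    v <- w
    done <- done + 1L
  }
  paste(v, collapse = "")
}
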