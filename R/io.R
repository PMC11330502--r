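# Readers and writers for the standard interchange formats. FASTA goes
# through Biostrings, GFF3/BED through rtracklayer; internal coordinates are
# 0-based half-open, GFF3 is emitted 1-based closed and BED 0-based half-open
# by the respective exporters.

#' Write a simulated or imported genome to FASTA + GFF3 + BED
#'
#' @param genome an `annotated_genome`.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return named character vector of the written paths, invisibly.
#' @export
write_genome <- function(genome, dir, prefix = "genome") {
  stopifnot(inherits(genome, "annotated_genome"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fa"))
  gff <- file.path(dir, paste0(prefix, ".gff3"))
  bed <- file.path(dir, paste0(prefix, "_masks.bed"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome$chromosomes), fa
  )
  g <- genome$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = g$strand
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "subgenomics", type = "gene",
    ID = g$id, family = g$family, subgenome = g$subgenome,
    ancestor = g$ancestor, tandem = tolower(as.character(g$tandem))
  )
  rtracklayer::export(gr, gff, format = "gff3")
  m <- genome$masks
  if (!is.null(m) && nrow(m)) {
    mr <- GenomicRanges::GRanges(
      seqnames = m$chrom,
      ranges = IRanges::IRanges(start = m$start + 1L, end = m$end)
    )
    S4Vectors::mcols(mr)$name <- m$class
    rtracklayer::export(mr, bed, format = "bed")
  } else {
    file.create(bed)
  }
  invisible(c(fasta = fa, gff3 = gff, bed = bed))
}

#' Read a genome from FASTA + GFF3 (+ optional BED masks)
#'
#' Gene CDS are reconstructed from the chromosome sequence (genes are modelled
#' as single-exon CDS spans; minus-strand genes are reverse-complemented).
#'
#' @param fasta,gff3,bed file paths; `bed` may be `NULL`.
#' @return an `annotated_genome`.
#' @export
read_genome <- function(fasta, gff3, bed = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  chroms <- as.character(seqs)
  names(chroms) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(gff3, format = "gff3")
  md <- S4Vectors::mcols(gr)
  genes <- data.frame(
    id = as.character(md$ID),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    family = if ("family" %in% names(md)) as.character(md$family) else NA_character_,
    subgenome = if ("subgenome" %in% names(md)) as.character(md$subgenome) else NA_character_,
    ancestor = if ("ancestor" %in% names(md)) as.character(md$ancestor) else NA_character_,
    tandem = if ("tandem" %in% names(md)) as.character(md$tandem) == "true" else FALSE,
    stringsAsFactors = FALSE
  )
  gseq <- substr(chroms[genes$chrom], genes$start + 1L, genes$end)
  genes$cds <- ifelse(genes$strand == "+", gseq, revcomp(gseq))
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  masks <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), class = character(0))
  if (!is.null(bed) && file.exists(bed) && file.size(bed) > 0) {
    br <- rtracklayer::import(bed, format = "bed")
    masks <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(br)),
      start = GenomicRanges::start(br) - 1L,
      end = GenomicRanges::end(br),
      class = as.character(S4Vectors::mcols(br)$name),
      stringsAsFactors = FALSE
    )
  }
  structure(list(chromosomes = chroms, genes = genes, masks = masks),
            class = "annotated_genome")
}

#' Write / read a per-site allele-depth table
#'
#' Columns: chrom, pos (1-based), ref, alt, ref_depth, alt_depth. Rows whose
#' alt field lists more than one allele are rejected at parse time and
#' counted in the `n_multiallelic` attribute.
#'
#' @param x allele-depth data frame.
#' @param path TSV file path.
#' @return `read_allele_depth` returns the table with attribute
#'   `n_multiallelic`.
#' @export
write_allele_depth <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}

#' @rdname write_allele_depth
#' @export
read_allele_depth <- function(path) {
  dt <- data.table::fread(path, sep = "\t", colClasses = list(character = c("chrom", "ref", "alt")))
  need <- c("chrom", "pos", "ref", "alt", "ref_depth", "alt_depth")
  if (!all(need %in% names(dt))) {
    stop("allele-depth table must have columns: ", paste(need, collapse = ", "))
  }
  multi <- grepl(",", dt$alt) | grepl(",", dt$ref)
  out <- as.data.frame(dt[!multi, ])
  attr(out, "n_multiallelic") <- sum(multi)
  out
}

#' Read an allele-depth table from a VCF (AD genotype field)
#'
#' Takes the first sample's AD field; multiallelic records are dropped and
#' counted in the `n_multiallelic` attribute.
#'
#' @param path VCF file path.
#' @param sample sample name or index (default first sample).
#' @return allele-depth data frame as in [read_allele_depth()].
#' @export
read_allele_depth_vcf <- function(path, sample = 1L) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  ad <- ad[, sample]
  multi <- grepl(",", fix$ALT)
  parts <- strsplit(ad, ",", fixed = TRUE)
  ref_depth <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 1L)))
  alt_depth <- suppressWarnings(as.integer(vapply(parts, function(p) {
    if (length(p) >= 2L) p[2L] else NA_character_
  }, character(1))))
  keep <- !multi & !is.na(ref_depth) & !is.na(alt_depth)
  out <- data.frame(
    chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
    ref = fix$REF[keep], alt = fix$ALT[keep],
    ref_depth = ref_depth[keep], alt_depth = alt_depth[keep],
    stringsAsFactors = FALSE
  )
  attr(out, "n_multiallelic") <- sum(multi)
  out
}

#' Write / read a windowed coverage table (chrom, start, end, depth)
#' @param x coverage data frame.
#' @param path TSV file path.
#' @export
write_coverage <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}

#' @rdname write_coverage
#' @export
read_coverage <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  need <- c("chrom", "start", "end", "depth")
  if (!all(need %in% names(dt))) {
    stop("coverage table must have columns: ", paste(need, collapse = ", "))
  }
  as.data.frame(dt)
}

#' Serialise simulation ground truth to JSON
#' @param truth ground-truth list from the simulator.
#' @param path output JSON path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
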