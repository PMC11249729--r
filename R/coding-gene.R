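# Validated codon-partitioned ORFs. A coding gene keeps its codons including
# the stop; structural oddities (non-ATG start, missing stop, internal stop)
# are recorded as flags rather than rejected, so loaders can report them.

#' Construct a coding gene from an in-frame sequence
#'
#' @param gene_id gene identifier.
#' @param seq in-frame coding nucleotide sequence including the stop codon
#'   (DNA or mRNA alphabet), or a character vector of codons.
#' @param annotation one of `"verified"`, `"uncharacterized"`, `"dubious"`,
#'   `"pseudogene"`, `"other"`.
#' @return an object of class `coding_gene` with fields `gene_id`, `codons`
#'   (including the stop), `length_nt`, `annotation` and a character vector
#'   `flags` (possibly empty) from `"non_atg_start"`, `"no_stop"`,
#'   `"internal_stop"`.
#' @export
coding_gene <- function(gene_id, seq,
                        annotation = c("verified", "uncharacterized",
                                       "dubious", "pseudogene", "other")) {
  annotation <- match.arg(annotation)
  if (length(seq) == 1L && nchar(seq[1L]) > 3L) {
    seq <- normalize_codon(seq)
    if (nchar(seq) %% 3L != 0L) {
      stop("sequence length not divisible by 3 for gene ", gene_id)
    }
    codons <- split_codons(seq)
  } else {
    codons <- normalize_codon(seq)
    if (any(nchar(codons) != 3L)) stop("codons must be 3-letter strings")
  }
  if (length(codons) < 2L) stop("gene ", gene_id, " shorter than 6 nt")
  if (!all(grepl("^[ACGT]{3}$", codons))) {
    stop("non-ACGT characters in gene ", gene_id)
  }
  flags <- character()
  if (codons[1L] != "ATG") flags <- c(flags, "non_atg_start")
  n <- length(codons)
  if (!codons[n] %in% stop_codons) flags <- c(flags, "no_stop")
  if (any(codons[-n] %in% stop_codons)) flags <- c(flags, "internal_stop")
  structure(list(gene_id = gene_id, codons = codons,
                 length_nt = 3L * n, annotation = annotation, flags = flags),
            class = "coding_gene")
}

#' Number of sense codons of a gene (stop excluded)
#' @param gene a `coding_gene`.
#' @return integer count of codons before the terminal stop.
#' @export
n_sense_codons <- function(gene) {
  stopifnot(inherits(gene, "coding_gene"))
  length(gene$codons) - 1L
}

#' @export
print.coding_gene <- function(x, ...) {
  cat(sprintf("<coding_gene %s: %d nt, %d codons incl. stop, %s%s>\n",
              x$gene_id, x$length_nt, length(x$codons), x$annotation,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Load coding ORFs from FASTA with the standard inclusion filters
#'
#' Reads in-frame CDS FASTA and applies the dataset filters: identifiers on
#' an exclusion list (typically dubious ORFs and pseudogenes) are dropped,
#' as are ORFs shorter than `min_nt` nucleotides (default 303 nt = 100 amino
#' acids plus the stop codon; the boundary length is kept). Sequences whose
#' length is not a multiple of 3 are skipped with a warning. The returned
#' list carries a load report: kept/dropped counts by reason, conserving
#' kept + dropped = input.
#'
#' @param path FASTA file of coding sequences (stop codon included).
#' @param exclusions character vector of gene ids to drop, or a path read via
#'   [load_exclusions()]; `NULL` for none.
#' @param min_nt minimum nucleotide length, inclusive.
#' @return list of `coding_gene`, with attribute `"report"` (a list with
#'   `input`, `kept`, and a named `dropped` vector by reason).
#' @export
load_cds <- function(path, exclusions = NULL, min_nt = 303L) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  chars <- as.character(seqs)
  dropped <- c(excluded = 0L, length = 0L, frame = 0L)
  genes <- vector("list", length(seqs))
  keep <- logical(length(seqs))
  for (i in seq_along(seqs)) {
    if (!is.null(exclusions) && ids[i] %in% exclusions) {
      dropped["excluded"] <- dropped["excluded"] + 1L
      next
    }
    len <- nchar(chars[i])
    if (len %% 3L != 0L) {
      warning("skipping ", ids[i], ": length ", len, " not divisible by 3")
      dropped["frame"] <- dropped["frame"] + 1L
      next
    }
    if (len < min_nt) {
      dropped["length"] <- dropped["length"] + 1L
      next
    }
    genes[[i]] <- coding_gene(ids[i], chars[i])
    keep[i] <- TRUE
  }
  genes <- genes[keep]
  report <- list(input = length(seqs), kept = length(genes), dropped = dropped)
  stopifnot(report$kept + sum(dropped) == report$input)
  attr(genes, "report") <- report
  genes
}

#' Read a plain-text exclusion list (one gene id per line)
#'
#' Decouples annotation-status filtering (dubious ORFs, pseudogenes) from any
#' particular annotation file dialect.
#'
#' @param path text file, one id per line; blank lines and `#` comments
#'   ignored.
#' @return character vector of ids.
#' @export
load_exclusions <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Write coding genes to FASTA
#' @param genes list of `coding_gene`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cds <- function(genes, path) {
  seqs <- Biostrings::DNAStringSet(
    vapply(genes, function(g) paste(g$codons, collapse = ""), character(1)))
  names(seqs) <- vapply(genes, `[[`, character(1), "gene_id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
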