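# Codon-usage counting and first-window-vs-rest enrichment. Counting always
# omits codon position 1 (the constant initiator ATG) and the stop codon, so
# "whole" = "initial_window" + "rest", codon-wise.

#' Count codon usage over a region of a gene set
#'
#' @param genes non-empty list of `coding_gene`.
#' @param region `"initial_window"` (codon positions 2..window), `"rest"`
#'   (positions window+1..N-1) or `"whole"` (positions 2..N-1); stop codons
#'   are never counted.
#' @param window window width in codons (default 40).
#' @return object of class `usage_table`: named integer vector over the 61
#'   sense codons with attributes `region` and `window`.
#' @export
count_usage <- function(genes,
                        region = c("initial_window", "rest", "whole"),
                        window = 40L) {
  region <- match.arg(region)
  window <- as.integer(window)
  if (!length(genes)) stop("empty gene list")
  counts <- stats::setNames(integer(length(sense_codons)), sense_codons)
  for (g in genes) {
    n_sense <- n_sense_codons(g)
    idx <- switch(region,
      initial_window = if (n_sense >= 2L) 2:min(window, n_sense) else integer(),
      rest = if (n_sense >= window + 1L) (window + 1L):n_sense else integer(),
      whole = if (n_sense >= 2L) 2:n_sense else integer())
    if (!length(idx)) next
    tab <- table(factor(g$codons[idx], levels = sense_codons))
    counts <- counts + as.integer(tab)
  }
  structure(counts, region = region, window = window, class = "usage_table")
}

#' @export
print.usage_table <- function(x, ...) {
  cat(sprintf("<usage_table: region=%s, window=%d, total=%d codons>\n",
              attr(x, "region"), attr(x, "window"), sum(x)))
  invisible(x)
}

#' First-window enrichment ratios per codon
#'
#' For each sense codon, the relative frequency (over all 61 sense codons)
#' in the initial window divided by its relative frequency in the rest of
#' the gene. Ratios above 1 mean enrichment in the window. Codons unobserved
#' in the rest region give `NA` (flagged, not infinite); no pseudocount is
#' applied.
#'
#' @param initial `usage_table` for the initial window.
#' @param rest `usage_table` for the rest of the genes.
#' @return named numeric vector of ratios over the 61 sense codons, with
#'   attribute `undefined` naming codons with no denominator frequency.
#' @export
enrichment_ratios <- function(initial, rest) {
  stopifnot(inherits(initial, "usage_table"), inherits(rest, "usage_table"))
  if (sum(initial) == 0 || sum(rest) == 0) stop("usage tables must be non-empty")
  f_init <- as.numeric(initial) / sum(initial)
  f_rest <- as.numeric(rest) / sum(rest)
  ratio <- ifelse(f_rest > 0, f_init / f_rest, NA_real_)
  names(ratio) <- sense_codons
  structure(ratio, undefined = sense_codons[f_rest == 0])
}

#' Within-amino-acid codon frequencies
#'
#' For each amino acid, the fraction of its occurrences encoded by each
#' synonymous codon (fractions sum to 1 whenever the amino acid occurs).
#'
#' @param usage a `usage_table`.
#' @param genetic_code named character vector codon -> one-letter amino acid;
#'   defaults to the standard code.
#' @return named list: one numeric vector of fractions per amino acid.
#' @export
per_aa_frequencies <- function(usage, genetic_code = NULL) {
  stopifnot(inherits(usage, "usage_table"))
  code <- if (is.null(genetic_code)) codon_to_aa[sense_codons] else {
    genetic_code[names(genetic_code) %in% names(usage)]
  }
  aas <- sort(unique(unname(code)))
  out <- lapply(aas, function(aa) {
    codons <- names(code)[code == aa]
    cnt <- as.numeric(usage[codons])
    total <- sum(cnt)
    stats::setNames(if (total > 0) cnt / total else rep(NA_real_, length(cnt)),
                    codons)
  })
  stats::setNames(out, aas)
}

#' Write a codon usage/enrichment report as TSV
#'
#' Columns: codon, amino acid, initial-window count, rest count, enrichment
#' ratio.
#'
#' @param initial,rest `usage_table`s for the two regions.
#' @param path output path.
#' @return the report data.frame, invisibly.
#' @export
write_usage_report <- function(initial, rest, path) {
  ratio <- enrichment_ratios(initial, rest)
  out <- data.frame(codon = sense_codons,
                    amino_acid = unname(codon_to_aa[sense_codons]),
                    initial_count = as.integer(initial),
                    rest_count = as.integer(rest),
                    ratio = as.numeric(ratio),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
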