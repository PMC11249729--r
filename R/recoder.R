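# Synonymous recoding of reporter leaders: slow / medium / fast encodings of
# a fixed amino-acid sequence, plus insertion of the CGA-CGG putative
# ribosome collision site (PCS).

# allowed synonym set for one codon under the avoid_starts rule
synonym_choices <- function(codon, avoid_starts) {
  syn <- aa_to_codons[[codon_to_aa[[codon]]]]
  if (avoid_starts) {
    kept <- setdiff(syn, start_like_codons)
    if (length(kept)) syn <- kept
  }
  sort(syn)
}

#' Recode a leader window with synonymous slow/medium/fast codons
#'
#' Within codon positions `2..window` each codon is replaced by a synonym:
#' `"fast"` takes the per-position minimum RRT, `"slow"` the maximum, and
#' `"medium"` the synonym closest to the table's neutral value. Ties are
#' broken by the lexicographically smallest codon, so recoding is
#' deterministic. Position 1 (ATG) and everything beyond the window,
#' including the stop, are untouched, and the amino-acid sequence is
#' preserved exactly. With `avoid_starts` (the default), Start-like codons
#' (ATG, ATT, TTG, ATA) are not introduced when an alternative synonym
#' exists, mirroring their depletion in natural 5' leaders.
#'
#' @param source a `coding_gene`.
#' @param rrt an `rrt_table`.
#' @param target `"slow"`, `"medium"` or `"fast"`.
#' @param window number of leader codons (default 41); must leave the stop
#'   untouched.
#' @param avoid_starts logical, see above.
#' @param name construct name (defaults to source id + target).
#' @return object of class `recoded_construct`: list with `name`, `gene`
#'   (the recoded `coding_gene`), `target`, `window`, `mean_rrt_window`
#'   (mean RRT over positions 1..window), `rit` (with the same window) and
#'   `pcs_position` (NA until [insert_collision_pair()] is applied via a
#'   construct).
#' @export
recode_window <- function(source, rrt, target = c("slow", "medium", "fast"),
                          window = 41L, avoid_starts = TRUE, name = NULL) {
  target <- match.arg(target)
  stopifnot(inherits(source, "coding_gene"))
  window <- as.integer(window)
  if (window > length(source$codons) - 1L) {
    stop("window extends into the stop codon")
  }
  codons <- source$codons
  for (i in 2:window) {
    choices <- synonym_choices(codons[i], avoid_starts)
    vals <- rrt_lookup(rrt, choices)
    pick <- switch(target,
      fast = choices[order(vals, choices)][1L],
      slow = choices[order(-vals, choices)][1L],
      medium = choices[order(abs(vals - rrt$neutral_value), choices)][1L])
    codons[i] <- pick
  }
  gene <- coding_gene(if (is.null(name)) paste(source$gene_id, target, sep = "_")
                      else name, codons, annotation = source$annotation)
  as_construct(gene, rrt, target = target, window = window)
}

as_construct <- function(gene, rrt, target = NA_character_, window = 41L,
                         pcs_position = NA_integer_) {
  profile <- speed_profile(gene, rrt)
  structure(list(name = gene$gene_id, gene = gene, target = target,
                 window = as.integer(window),
                 mean_rrt_window = mean(profile[1:window]),
                 rit = rit(gene, rrt, window = window)$rit,
                 pcs_position = pcs_position),
            class = "recoded_construct")
}

#' @export
print.recoded_construct <- function(x, ...) {
  cat(sprintf(
    "<construct %s: target=%s, window=%d, mean RRT %.4f, rit %+.4f%s>\n",
    x$name, x$target, x$window, x$mean_rrt_window, x$rit,
    if (!is.na(x$pcs_position)) sprintf(", PCS at %d", x$pcs_position) else ""))
  invisible(x)
}

#' Insert a slow codon pair (putative collision site)
#'
#' Replaces the codons at `position` and `position + 1` by `pair` (default
#' CGA-CGG, the rare arginine pair replacing Asn-Asp AAT-GAT in the
#' reporter). The amino acids change, as intended; gene length does not.
#'
#' @param gene a `coding_gene`.
#' @param position 1-based codon index of the first codon of the pair;
#'   `position + 1` must still be a sense codon.
#' @param pair two codons.
#' @return a new `coding_gene`.
#' @export
insert_collision_pair <- function(gene, position, pair = c("CGA", "CGG")) {
  stopifnot(inherits(gene, "coding_gene"), length(pair) == 2L)
  position <- as.integer(position)
  n <- length(gene$codons)
  if (position < 1L || position + 1L > n - 1L) {
    stop("collision pair at position ", position,
         " would overlap the stop codon (gene has ", n - 1L, " sense codons)")
  }
  codons <- gene$codons
  codons[position:(position + 1L)] <- normalize_codon(pair)
  coding_gene(gene$gene_id, codons, annotation = gene$annotation)
}

#' Report leader mean RRT and RIT for a set of constructs
#'
#' For each construct, the mean RRT over leader codon positions
#' `from..window` and the RIT statistic with the same window. `from = 1`
#' averages the full leader including the initiator ATG; `from = 2` is the
#' convention that omits it — both are provided since either may match a
#' given published leader average.
#'
#' @param constructs list of `coding_gene` or `recoded_construct` objects.
#' @param rrt an `rrt_table`.
#' @param window leader width in codons (default 41).
#' @param from first leader position included in the mean (1 or 2).
#' @return data.frame: name, mean_rrt_window, rit.
#' @export
construct_report <- function(constructs, rrt, window = 41L, from = 1L) {
  window <- as.integer(window)
  from <- as.integer(from)
  stopifnot(from %in% c(1L, 2L))
  rows <- lapply(constructs, function(x) {
    gene <- if (inherits(x, "recoded_construct")) x$gene else x
    profile <- speed_profile(gene, rrt)
    data.frame(name = gene$gene_id,
               mean_rrt_window = mean(profile[from:window]),
               rit = rit(gene, rrt, window = window)$rit,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "window") <- window
  attr(out, "from") <- from
  out
}
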