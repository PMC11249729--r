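# Encoded translation speed: per-codon profiles, the relative initial
# translation speed (RIT) statistic, metaprofiles, and genome-wide terminal
# slowdown estimates.
#
# RIT = log2( mean RRT over codons 2..W  /  mean RRT over codons W+1..N-1 )
# for the 5' end (N = stop position). Codon 1 is omitted because essentially
# all genes start with ATG, an unusually fast codon that would skew the
# ratio; the stop codon is omitted because it has no residence time.
# Positive RIT = slow start.

#' Per-codon speed profile of a gene
#'
#' One residence time per sense codon (positions 1..N-1); the stop codon is
#' omitted. Internal stop codons are an error: encoded speed is undefined
#' past a premature stop.
#'
#' @param gene a `coding_gene`.
#' @param rrt an `rrt_table`.
#' @return numeric vector of RRT values, length `n_sense_codons(gene)`.
#' @export
speed_profile <- function(gene, rrt) {
  stopifnot(inherits(gene, "coding_gene"))
  sense <- gene$codons[-length(gene$codons)]
  internal <- which(sense %in% stop_codons)
  if (length(internal)) {
    stop("internal stop codon at position ", internal[1L],
         " of gene ", gene$gene_id)
  }
  rrt_lookup(rrt, sense)
}

# numerator/denominator position index sets for rit(); N = stop position
rit_positions <- function(n_codons, window, end) {
  n_sense <- n_codons - 1L
  if (n_sense < window + 2L) {
    stop("gene too short for window ", window, ": needs >= ", window + 2L,
         " sense codons, has ", n_sense)
  }
  if (end == "five_prime") {
    list(num = 2:window, den = (window + 1L):n_sense)
  } else {
    list(num = (n_sense - window + 1L):n_sense, den = 2:(n_sense - window))
  }
}

#' Relative initial (or terminal) translation speed of one gene
#'
#' For the 5' end, the log2 ratio of mean RRT over codon positions
#' `2..window` to mean RRT over positions `window+1..N-1` (N = stop
#' position). For the 3' end, the numerator is the last `window` sense
#' codons and the denominator positions `2..N-window-1`. Positive values
#' indicate a slow (high-RRT) terminus.
#'
#' @param gene a `coding_gene` with at least `window + 2` sense codons.
#' @param rrt an `rrt_table`.
#' @param window window width W in codons (default 40).
#' @param end `"five_prime"` or `"three_prime"`.
#' @return an object of class `rit_record`: list with `gene_id`, `window`,
#'   `rit`, `mean_num`, `mean_den`, `n_numerator`, `n_denominator`, `end`.
#' @export
rit <- function(gene, rrt, window = 40L, end = c("five_prime", "three_prime")) {
  end <- match.arg(end)
  profile <- speed_profile(gene, rrt)
  pos <- rit_positions(length(gene$codons), as.integer(window), end)
  mean_num <- mean(profile[pos$num])
  mean_den <- mean(profile[pos$den])
  structure(list(gene_id = gene$gene_id, window = as.integer(window),
                 rit = log2(mean_num / mean_den),
                 mean_num = mean_num, mean_den = mean_den,
                 n_numerator = length(pos$num), n_denominator = length(pos$den),
                 end = end),
            class = "rit_record")
}

#' @export
print.rit_record <- function(x, ...) {
  cat(sprintf("<rit %s: window %d (%s), rit = %+.4f (%s)>\n",
              x$gene_id, x$window, x$end, x$rit, classify_rit(x)))
  invisible(x)
}

#' Classify a gene as slow or fast initial translation
#'
#' SIT (slow initial translation) iff rit strictly exceeds the threshold;
#' a tie at exactly 0 is FIT.
#'
#' @param record an `rit_record` (or a bare rit value).
#' @param threshold classification threshold on the rit scale.
#' @return `"SIT"` or `"FIT"`.
#' @export
classify_rit <- function(record, threshold = 0) {
  value <- if (inherits(record, "rit_record")) record$rit else record
  ifelse(value > threshold, "SIT", "FIT")
}

#' RIT for a whole gene set, as a data frame
#'
#' Genes too short for the window are skipped (recorded in attribute
#' `n_skipped`).
#'
#' @inheritParams rit
#' @param genes list of `coding_gene`.
#' @return data.frame with columns gene_id, window, end, rit, mean_num,
#'   mean_den, n_numerator, n_denominator, class.
#' @export
rit_table <- function(genes, rrt, window = 40L,
                      end = c("five_prime", "three_prime")) {
  end <- match.arg(end)
  window <- as.integer(window)
  eligible <- vapply(genes, function(g) n_sense_codons(g) >= window + 2L,
                     logical(1))
  recs <- lapply(genes[eligible], rit, rrt = rrt, window = window, end = end)
  out <- data.frame(
    gene_id = vapply(recs, `[[`, character(1), "gene_id"),
    window = window, end = end,
    rit = vapply(recs, `[[`, numeric(1), "rit"),
    mean_num = vapply(recs, `[[`, numeric(1), "mean_num"),
    mean_den = vapply(recs, `[[`, numeric(1), "mean_den"),
    n_numerator = vapply(recs, `[[`, integer(1), "n_numerator"),
    n_denominator = vapply(recs, `[[`, integer(1), "n_denominator"),
    stringsAsFactors = FALSE)
  out$class <- classify_rit(out$rit)
  attr(out, "n_skipped") <- sum(!eligible)
  out
}

#' Genome-wide terminal slowdown estimate
#'
#' Averages the per-gene RRT ratio: `mean_ratio_pct = 100 * mean(2^rit - 1)`,
#' positive when the terminal window is slower (higher RRT) than the body.
#' Significance is the paired two-sided Wilcoxon signed-rank test of the
#' per-gene window mean against the per-gene body mean. On the `"speed"`
#' scale the same comparison is made on inverse-RRT means (percent by which
#' the window is slower in speed terms); the two scales differ slightly.
#'
#' @param genes list of `coding_gene`.
#' @param rrt an `rrt_table`.
#' @param window window width in codons.
#' @param end `"five_prime"` or `"three_prime"`.
#' @param scale `"rrt"` (default) or `"speed"` (inverse RRT).
#' @return object of class `slowdown_summary`: list with `window`, `end`,
#'   `scale`, `mean_ratio_pct`, `p_value`, `n_genes`, and the per-gene `rit`
#'   data frame.
#' @export
genomewide_slowdown <- function(genes, rrt, window = 40L,
                                end = c("five_prime", "three_prime"),
                                scale = c("rrt", "speed")) {
  end <- match.arg(end)
  scale <- match.arg(scale)
  tab <- rit_table(genes, rrt, window = window, end = end)
  if (nrow(tab) < 2L) stop("need at least 2 eligible genes")
  if (scale == "rrt") {
    num <- tab$mean_num
    den <- tab$mean_den
    mean_ratio_pct <- 100 * mean(num / den - 1)
  } else {
    # inverse-RRT (speed) means per region, recomputed per gene
    window <- as.integer(window)
    inv <- vapply(genes, function(g) {
      if (n_sense_codons(g) < window + 2L) return(c(NA_real_, NA_real_))
      profile <- 1 / speed_profile(g, rrt)
      pos <- rit_positions(length(g$codons), window, end)
      c(mean(profile[pos$num]), mean(profile[pos$den]))
    }, numeric(2))
    keep <- !is.na(inv[1L, ])
    num <- inv[1L, keep]   # window speed; slower window = lower speed
    den <- inv[2L, keep]   # body speed
    mean_ratio_pct <- 100 * mean(1 - num / den)
  }
  diffs <- num - den
  p_value <- if (all(diffs == 0)) 1 else {
    suppressWarnings(stats::wilcox.test(num, den, paired = TRUE,
                                        exact = FALSE)$p.value)
  }
  structure(list(window = as.integer(window), end = end, scale = scale,
                 mean_ratio_pct = mean_ratio_pct, p_value = p_value,
                 n_genes = nrow(tab), rit = tab),
            class = "slowdown_summary")
}

#' @export
print.slowdown_summary <- function(x, ...) {
  lab <- if (x$end == "five_prime") "first" else "last"
  cat(sprintf(
    "Genome-wide terminal slowdown (%s %d codons vs rest, %s scale)\n",
    lab, x$window, x$scale))
  cat(sprintf("  n = %d genes; mean slowdown = %+.3f%%; Wilcoxon p = %.3g\n",
              x$n_genes, x$mean_ratio_pct, x$p_value))
  cat(sprintf("  SIT fraction: %.1f%%\n",
              100 * mean(x$rit$rit > 0)))
  invisible(x)
}

#' Positional speed metaprofile across a gene set
#'
#' Mean inverse RRT (speed) per codon position, averaging over all genes
#' long enough to contain that position; position 1 (the constant ATG) is
#' omitted. Optionally smoothed with a centred moving average.
#'
#' @param genes list of `coding_gene`.
#' @param rrt an `rrt_table`.
#' @param max_pos last codon position to report (>= 2).
#' @param smooth odd moving-average width; 1 = no smoothing.
#' @return data.frame with columns `position`, `mean_inv_rrt`, `n`.
#' @export
metaprofile <- function(genes, rrt, max_pos, smooth = 1L) {
  max_pos <- as.integer(max_pos)
  smooth <- as.integer(smooth)
  if (max_pos < 2L) stop("max_pos must be >= 2")
  if (smooth < 1L || smooth %% 2L == 0L) stop("smooth must be a positive odd integer")
  sums <- numeric(max_pos)
  ns <- integer(max_pos)
  for (g in genes) {
    profile <- 1 / speed_profile(g, rrt)
    upto <- min(length(profile), max_pos)
    if (upto >= 2L) {
      idx <- 2:upto
      sums[idx] <- sums[idx] + profile[idx]
      ns[idx] <- ns[idx] + 1L
    }
  }
  pos <- 2:max_pos
  mean_inv <- ifelse(ns[pos] > 0L, sums[pos] / ns[pos], NA_real_)
  if (smooth > 1L) {
    half <- (smooth - 1L) %/% 2L
    sm <- vapply(seq_along(mean_inv), function(i) {
      lo <- max(1L, i - half); hi <- min(length(mean_inv), i + half)
      mean(mean_inv[lo:hi], na.rm = TRUE)
    }, numeric(1))
    mean_inv <- sm
  }
  data.frame(position = pos, mean_inv_rrt = mean_inv, n = ns[pos])
}

#' Write a RIT table or metaprofile as TSV
#' @param x data.frame from [rit_table()] or [metaprofile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
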