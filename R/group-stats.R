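# Tertile grouping, group comparisons and correlations linking RIT,
# conservation, expression and ribosome density.

#' Split genes into tertiles by a ranked value
#'
#' Genes are ranked ascending by value (ties broken by gene id, so the split
#' is deterministic) and divided into thirds; when n is not divisible by 3
#' the remainder goes to the top-most groups.
#'
#' @param values a `gene_value_table` or named numeric vector.
#' @return named list of three character vectors of gene ids: `bottom`,
#'   `middle`, `top`.
#' @export
tertile_split <- function(values) {
  if (length(values) < 3L) stop("need at least 3 genes to split into thirds")
  ids <- names(values)[order(as.numeric(values), names(values))]
  n <- length(ids)
  base <- n %/% 3L
  r <- n %% 3L
  sizes <- c(bottom = base, middle = base + (r >= 2L), top = base + (r >= 1L))
  split(ids, rep(c("bottom", "middle", "top"), times = sizes))[
    c("bottom", "middle", "top")]
}

#' Compare a response metric across three gene groups
#'
#' Two-sided unpaired rank-sum (Mann-Whitney) tests between each pair of
#' groups, Holm-Bonferroni adjusted over the three comparisons. Groups hold
#' different genes, so the unpaired form is the valid rank test here; the
#' paired signed-rank form is used only for within-gene window-vs-body
#' comparisons ([genomewide_slowdown()]). Genes missing from `response` are
#' dropped with a count.
#'
#' @param groups list of three character vectors of gene ids (as from
#'   [tertile_split()]).
#' @param response a `gene_value_table` or named numeric vector.
#' @param grouping_metric,response_metric labels carried into the result.
#' @return object of class `grouped_comparison`: list with `groups`,
#'   `summary` (per-group n/mean/median), `pairwise_p` (Holm-adjusted),
#'   `raw_p`, `n_missing`, `method`, and the metric labels.
#' @export
compare_groups <- function(groups, response, grouping_metric = "value",
                           response_metric = "response") {
  stopifnot(is.list(groups), length(groups) == 3L)
  if (is.null(names(groups))) names(groups) <- c("bottom", "middle", "top")
  vals <- lapply(groups, function(ids) {
    v <- as.numeric(response[match(ids, names(response))])
    v[!is.na(v)]
  })
  n_missing <- sum(lengths(groups)) - sum(lengths(vals))
  if (any(lengths(vals) == 0L)) {
    stop("group(s) empty after dropping genes without a response value: ",
         paste(names(vals)[lengths(vals) == 0L], collapse = ", "))
  }
  pairs <- utils::combn(names(groups), 2L)
  raw_p <- apply(pairs, 2L, function(pr) {
    a <- vals[[pr[1L]]]; b <- vals[[pr[2L]]]
    if (length(a) == length(b) && all(sort(a) == sort(b))) return(1)
    suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
  })
  names(raw_p) <- paste(pairs[1L, ], pairs[2L, ], sep = " vs ")
  adj_p <- stats::p.adjust(raw_p, method = "holm")
  summary <- data.frame(
    group = names(groups), n = lengths(vals),
    mean = vapply(vals, mean, numeric(1)),
    median = vapply(vals, stats::median, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(grouping_metric = grouping_metric,
                 response_metric = response_metric,
                 groups = groups, summary = summary,
                 pairwise_p = adj_p, raw_p = raw_p,
                 n_missing = n_missing,
                 method = "Mann-Whitney rank-sum, Holm-Bonferroni adjusted"),
            class = "grouped_comparison")
}

#' @export
print.grouped_comparison <- function(x, ...) {
  cat(sprintf("Group comparison: %s tertiles vs %s (%s)\n",
              x$grouping_metric, x$response_metric, x$method))
  print(x$summary, row.names = FALSE)
  cat("adjusted p:\n")
  for (nm in names(x$pairwise_p)) {
    cat(sprintf("  %-18s %.4g\n", nm, x$pairwise_p[[nm]]))
  }
  if (x$n_missing > 0) {
    cat(sprintf("  (%d gene(s) without a response value dropped)\n",
                x$n_missing))
  }
  invisible(x)
}

#' Spearman correlation between two gene-value tables
#'
#' Computed over the gene-id intersection; ties are handled by average
#' ranks.
#'
#' @param x,y `gene_value_table`s or named numeric vectors.
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  shared <- intersect(names(x), names(y))
  if (length(shared) < 3L) stop("fewer than 3 shared genes")
  ct <- suppressWarnings(
    stats::cor.test(as.numeric(x[match(shared, names(x))]),
                    as.numeric(y[match(shared, names(y))]),
                    method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(shared))
}

#' Two-sample two-sided Kolmogorov-Smirnov comparison
#'
#' @param dist_a,dist_b non-empty numeric vectors.
#' @return list with `statistic`, `p`.
#' @export
ks_compare <- function(dist_a, dist_b) {
  if (!length(dist_a) || !length(dist_b)) stop("both samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(dist_a, dist_b))
  list(statistic = unname(kt$statistic), p = kt$p.value)
}

#' Write a grouped-comparison report as TSV
#' @param x a `grouped_comparison`.
#' @param path output path.
#' @return the report data.frame, invisibly.
#' @export
write_comparison_report <- function(x, path) {
  stopifnot(inherits(x, "grouped_comparison"))
  pw <- data.frame(pair = names(x$pairwise_p),
                   adjusted_p = as.numeric(x$pairwise_p),
                   stringsAsFactors = FALSE)
  out <- merge(x$summary,
               data.frame(group = c("bottom", "middle", "top")),
               by = "group", sort = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  suppressWarnings(utils::write.table(pw, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(out)
}
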