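# Gene -> scalar tables (mRNA read counts, ribosome densities, derived
# statistics) used by the grouping and correlation analyses.

#' Construct a gene-value table
#'
#' @param values named numeric vector, names = gene ids (no duplicates).
#' @param kind `"read_count"`, `"ribosome_density"` or `"other"`. Read-count
#'   tables are filtered at `min_count` (genes with fewer reads are dropped
#'   as too noisy); other kinds are not filtered.
#' @param min_count inclusive threshold for read counts (default 10: counts
#'   below 10 are omitted, 10 itself is kept).
#' @return an object of class `gene_value_table`: the filtered named numeric
#'   vector with attributes `kind`, `min_count` and `n_dropped`.
#' @export
gene_value_table <- function(values,
                             kind = c("read_count", "ribosome_density", "other"),
                             min_count = 10) {
  kind <- match.arg(kind)
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    stop("values must be named by gene id")
  }
  if (anyDuplicated(names(values))) {
    dup <- unique(names(values)[duplicated(names(values))])
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
  }
  vals <- as.numeric(values)
  if (anyNA(vals) || any(!is.finite(vals))) stop("values must be finite numbers")
  if (kind %in% c("read_count", "ribosome_density") && any(vals < 0)) {
    stop(kind, " values must be non-negative")
  }
  names(vals) <- names(values)
  n_dropped <- 0L
  if (kind == "read_count") {
    keep <- vals >= min_count
    n_dropped <- sum(!keep)
    vals <- vals[keep]
  }
  structure(vals, kind = kind, min_count = min_count,
            n_dropped = n_dropped, class = "gene_value_table")
}

#' Read a two-column gene-value TSV
#'
#' @param path TSV with columns gene_id, value (header optional).
#' @param kind see [gene_value_table()].
#' @param min_count see [gene_value_table()].
#' @return a `gene_value_table`.
#' @export
load_gene_values <- function(path,
                             kind = c("read_count", "ribosome_density", "other"),
                             min_count = 10) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("gene_id", "value"),
                           colClasses = c("character", "character"))
  header <- nrow(tab) && is.na(suppressWarnings(as.numeric(tab$value[1L])))
  if (header) tab <- tab[-1L, , drop = FALSE]
  if (!nrow(tab)) stop("empty gene-value table: ", path)
  vals <- suppressWarnings(as.numeric(tab$value))
  if (anyNA(vals)) {
    line <- which(is.na(vals))[1L] + as.integer(header)
    stop("non-numeric value at line ", line, " of ", path)
  }
  gene_value_table(stats::setNames(vals, tab$gene_id), kind = kind,
                   min_count = min_count)
}

#' @export
print.gene_value_table <- function(x, ...) {
  cat(sprintf("<gene_value_table: %d genes, kind=%s%s>\n",
              length(x), attr(x, "kind"),
              if (attr(x, "n_dropped") > 0)
                sprintf(", %d dropped below min_count=%g",
                        attr(x, "n_dropped"), attr(x, "min_count"))
              else ""))
  invisible(x)
}
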