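# Ribosome residence time (RRT) tables: the per-codon speed model that every
# downstream statistic consumes. RRT is dimensionless ribosome occupancy of a
# codon in the A-site; higher = slower translation.

#' Construct an RRT table
#'
#' An RRT table maps each of the 61 sense codons to a positive residence
#' time. Stop codons are deliberately absent: looking one up is an error,
#' because encoded-speed statistics never include the stop.
#'
#' @param values named numeric vector: names are 3-letter DNA codons (U is
#'   accepted and mapped to T), values are positive residence times. All 61
#'   sense codons must be present exactly once.
#' @param neutral_value positive real used by [neutralize()]; the default
#'   1.0189 is the neutral residence time used when masking Start-like codons.
#' @return an object of class `rrt_table`.
#' @seealso [load_rrt_table()], [neutralize()], [rrt_lookup()]
#' @export
rrt_table <- function(values, neutral_value = 1.0189) {
  if (is.null(names(values)) || any(names(values) == "")) {
    stop("rrt values must be a named vector (codon -> value)")
  }
  codons <- normalize_codon(names(values))
  if (anyDuplicated(codons)) {
    dup <- unique(codons[duplicated(codons)])
    stop("duplicate codon(s) in RRT table: ", paste(dup, collapse = ", "))
  }
  bad <- setdiff(codons, sense_codons)
  if (length(bad)) {
    stop("not a sense codon: ", paste(bad, collapse = ", "))
  }
  missing <- setdiff(sense_codons, codons)
  if (length(missing)) {
    stop("RRT table incomplete; missing codon(s): ",
         paste(missing, collapse = ", "))
  }
  vals <- as.numeric(values)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all RRT values must be finite and positive")
  }
  if (!is.numeric(neutral_value) || length(neutral_value) != 1L ||
      !is.finite(neutral_value) || neutral_value <= 0) {
    stop("neutral_value must be a single positive number")
  }
  entries <- stats::setNames(vals, codons)[sense_codons]
  structure(list(entries = entries, neutral_value = neutral_value),
            class = "rrt_table")
}

#' Read an RRT table from two-column delimited text
#'
#' The file has one row per sense codon: codon, residence time. Comma, tab or
#' whitespace delimited; a header line is detected and skipped. Codons are
#' upper-cased and U is mapped to T, so mRNA-style tables are accepted.
#'
#' @param path file path.
#' @param neutral_value passed to [rrt_table()].
#' @return an `rrt_table` with all 61 sense codons.
#' @export
load_rrt_table <- function(path, neutral_value = 1.0189) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  tab <- utils::read.table(path, sep = sep, header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("codon", "rrt"),
                           colClasses = c("character", "character"))
  # header row: second field not numeric
  if (nrow(tab) && is.na(suppressWarnings(as.numeric(tab$rrt[1L])))) {
    tab <- tab[-1L, , drop = FALSE]
  }
  if (!nrow(tab)) stop("empty RRT table: ", path)
  vals <- suppressWarnings(as.numeric(tab$rrt))
  if (anyNA(vals)) {
    stop("non-numeric RRT value at line ", which(is.na(vals))[1L])
  }
  rrt_table(stats::setNames(vals, tab$codon), neutral_value = neutral_value)
}

#' Write an RRT table as two-column TSV
#'
#' @param rrt an `rrt_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rrt_table <- function(rrt, path) {
  stopifnot(inherits(rrt, "rrt_table"))
  utils::write.table(
    data.frame(codon = names(rrt$entries), rrt = unname(rrt$entries)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Look up residence times for codons
#'
#' Vectorised; stop codons and unknown strings are hard errors (the stop
#' codon never contributes to an encoded-speed statistic).
#'
#' @param rrt an `rrt_table`.
#' @param codons character vector of codons.
#' @return numeric vector of residence times.
#' @export
rrt_lookup <- function(rrt, codons) {
  stopifnot(inherits(rrt, "rrt_table"))
  codons <- normalize_codon(codons)
  out <- rrt$entries[codons]
  if (anyNA(out)) {
    bad <- unique(codons[is.na(out)])
    stop("no RRT for codon(s): ", paste(bad, collapse = ", "),
         " (stop codons have no residence time)")
  }
  unname(out)
}

#' Mask codons with the neutral residence time
#'
#' Returns a copy of the table in which each listed codon is assigned the
#' table's neutral value (default 1.0189). Used to ask how much of a terminal
#' slowdown survives when Start-like codons (ATG, ATT, TTG, ATA) are made
#' neutral. The input table is not modified.
#'
#' @param rrt an `rrt_table`.
#' @param codons character vector of sense codons (may be empty).
#' @return a new `rrt_table`.
#' @export
neutralize <- function(rrt, codons) {
  stopifnot(inherits(rrt, "rrt_table"))
  codons <- normalize_codon(unique(codons))
  if (length(codons)) {
    bad <- setdiff(codons, sense_codons)
    if (length(bad)) {
      stop("cannot neutralize non-sense codon(s): ",
           paste(bad, collapse = ", "))
    }
    rrt$entries[codons] <- rrt$neutral_value
  }
  rrt
}

#' @export
print.rrt_table <- function(x, ...) {
  cat("RRT table: 61 sense codons\n")
  cat(sprintf("  range %.4f - %.4f, neutral value %.4f\n",
              min(x$entries), max(x$entries), x$neutral_value))
  slow <- names(sort(x$entries, decreasing = TRUE))[1:5]
  fast <- names(sort(x$entries))[1:5]
  cat("  slowest:", paste(slow, collapse = " "), "\n")
  cat("  fastest:", paste(fast, collapse = " "), "\n")
  invisible(x)
}
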