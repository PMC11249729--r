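# Windowed terminal Conservation Scores from protein BLAST hit geometry.
#
# Each query protein is split in half, each half BLASTed against a panel of
# related species. A species "qualifies" if it has any HSP with bit-score
# >= 50; its contribution to a window's score is the number of window
# positions covered by the union of its HSP query intervals with bit-score
# >= 200 (the "red" high-homology regions of the BLAST graphic summary).
# The Conservation Score of a 40-aa window is the mean coverage over
# qualified species: 0 (no species has homology in the window) to 40 (every
# species covered from the first position).

#' Read BLAST tabular output (outfmt 6) into HSP records
#'
#' Expects the standard 12 columns (qseqid, sseqid, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore). Hits with
#' bit-score below `min_bits` are dropped at load, as are hits whose subject
#' is missing from the species map (with a warning).
#'
#' @param path BLAST tabular file.
#' @param species_map named character vector subject_id -> species, or a
#'   path to a 2-column TSV.
#' @param min_bits qualifying bit-score threshold (default 50).
#' @param half `"first"` or `"second"`: which protein half this BLAST ran on.
#' @return data.frame of class `blast_hsp` with columns query_id,
#'   subject_id, species, bit_score, query_start, query_end, half.
#' @export
read_blast_hits <- function(path, species_map, min_bits = 50,
                            half = c("first", "second")) {
  half <- match.arg(half)
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 12L) stop("expected >= 12 outfmt-6 columns, got ", ncol(tab))
  names(tab)[c(1, 2, 7, 8, 12)] <-
    c("qseqid", "sseqid", "qstart", "qend", "bitscore")
  if (is.character(species_map) && is.null(names(species_map)) &&
      length(species_map) == 1L && file.exists(species_map)) {
    species_map <- load_species_map(species_map)
  }
  hits <- blast_hsp(query_id = tab$qseqid, subject_id = tab$sseqid,
                    species = unname(species_map[tab$sseqid]),
                    bit_score = tab$bitscore,
                    query_start = tab$qstart, query_end = tab$qend,
                    half = half)
  unmapped <- is.na(hits$species)
  if (any(unmapped)) {
    warning(sum(unmapped), " hit(s) dropped: subject id not in species map (",
            paste(utils::head(unique(hits$subject_id[unmapped]), 3), collapse = ", "),
            if (length(unique(hits$subject_id[unmapped])) > 3) ", ..." else "", ")")
    hits <- hits[!unmapped, , drop = FALSE]
  }
  hits[hits$bit_score >= min_bits, , drop = FALSE]
}

#' Construct HSP records directly
#'
#' @param query_id,subject_id,species character vectors (recycled).
#' @param bit_score positive numeric.
#' @param query_start,query_end 1-based inclusive query coordinates.
#' @param half `"first"` or `"second"`.
#' @return data.frame of class `blast_hsp`.
#' @export
blast_hsp <- function(query_id, subject_id, species, bit_score,
                      query_start, query_end, half = "first") {
  out <- data.frame(query_id = query_id, subject_id = subject_id,
                    species = species, bit_score = bit_score,
                    query_start = as.integer(query_start),
                    query_end = as.integer(query_end),
                    half = half, stringsAsFactors = FALSE)
  bad <- !is.na(out$query_start) &
    (out$query_start < 1L | out$query_start > out$query_end)
  if (any(bad)) stop("invalid HSP coordinates (need 1 <= start <= end)")
  if (any(out$bit_score <= 0)) stop("bit scores must be positive")
  class(out) <- c("blast_hsp", "data.frame")
  out
}

#' Read a subject -> species map from 2-column TSV
#' @param path TSV: subject_id, species.
#' @return named character vector.
#' @export
load_species_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("subject_id", "species"))
  if (anyDuplicated(tab$subject_id)) stop("duplicate subject ids in species map")
  stats::setNames(tab$species, tab$subject_id)
}

#' Keep each species' best subject only
#'
#' Sequence collections contain multiple submissions of the same species.
#' For each (query, half, species), only HSPs of the subject whose best HSP
#' bit-score is maximal for that species are kept; ties go to the
#' lexicographically smallest subject id (deterministic).
#'
#' @param hits a `blast_hsp` data frame.
#' @return filtered `blast_hsp` data frame.
#' @export
dedupe_by_species <- function(hits) {
  stopifnot(inherits(hits, "blast_hsp"))
  if (!nrow(hits)) return(hits)
  key <- paste(hits$query_id, hits$half, hits$species, sep = "\r")
  best <- vapply(split(seq_len(nrow(hits)), key), function(idx) {
    sub <- hits[idx, ]
    top <- vapply(split(sub$bit_score, sub$subject_id), max, numeric(1))
    names(top)[order(-top, names(top))][1L]
  }, character(1))
  keep <- hits$subject_id == best[key]
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Terminal window scheme for a protein
#'
#' Three 40-aa windows: N-terminal `[1,40]`; "middle" = the first 40
#' positions of the second half, `[floor(M/2)+1, floor(M/2)+40]` (displaced
#' 20 aa C-terminal from the exact middle); C-terminal `[M-39, M]`. The
#' halves used for BLAST are `[1, floor(M/2)]` and `[floor(M/2)+1, M]`.
#' An alternative middle window, the last 40 positions of the first half,
#' is available via `middle = "end_of_first_half"`.
#'
#' @param protein_length protein length M in amino acids (>= 100).
#' @param middle `"start_of_second_half"` (default) or `"end_of_first_half"`.
#' @return object of class `window_scheme`: list with `protein_length`,
#'   `half_split`, `n_window`, `mid_window`, `c_window`, `middle`.
#' @export
window_scheme <- function(protein_length,
                          middle = c("start_of_second_half",
                                     "end_of_first_half")) {
  middle <- match.arg(middle)
  m <- as.integer(protein_length)
  if (m < 100L) {
    stop("protein shorter than 100 amino acids (too_short): M = ", m)
  }
  h <- m %/% 2L
  mid <- if (middle == "start_of_second_half") c(h + 1L, h + 40L)
         else c(h - 39L, h)
  structure(list(protein_length = m, half_split = h,
                 n_window = c(1L, 40L), mid_window = mid,
                 c_window = c(m - 39L, m), middle = middle),
            class = "window_scheme")
}

#' @export
print.window_scheme <- function(x, ...) {
  cat(sprintf(
    "<window_scheme M=%d: N [%d,%d], mid [%d,%d], C [%d,%d]; halves 1:%d / %d:%d>\n",
    x$protein_length, x$n_window[1], x$n_window[2], x$mid_window[1],
    x$mid_window[2], x$c_window[1], x$c_window[2], x$half_split,
    x$half_split + 1L, x$protein_length))
  invisible(x)
}

# positions of `window` covered by the union of intervals [starts, ends]
interval_coverage <- function(starts, ends, window) {
  lo <- pmax(starts, window[1L])
  hi <- pmin(ends, window[2L])
  ok <- lo <= hi
  if (!any(ok)) return(0L)
  lo <- lo[ok]; hi <- hi[ok]
  ord <- order(lo, hi)
  lo <- lo[ord]; hi <- hi[ord]
  covered <- 0L
  cur_lo <- lo[1L]; cur_hi <- hi[1L]
  for (i in seq_along(lo)[-1L]) {
    if (lo[i] > cur_hi + 1L) {
      covered <- covered + (cur_hi - cur_lo + 1L)
      cur_lo <- lo[i]; cur_hi <- hi[i]
    } else if (hi[i] > cur_hi) {
      cur_hi <- hi[i]
    }
  }
  covered + (cur_hi - cur_lo + 1L)
}

#' Conservation Score of one window
#'
#' Qualified species have at least one HSP with bit-score >= `qual_bits`
#' among `hits` (the hits for one query and half, already deduplicated).
#' Each qualified species contributes the number of window positions
#' covered by the union of its HSP intervals with bit-score >=
#' `region_bits`; a qualified species with no such region contributes 0.
#' The score is the mean contribution over qualified species, equivalently
#' the sum over homology lengths L of L times the proportion of qualified
#' species with that coverage.
#'
#' @param hits `blast_hsp` data frame for one query/half, on the same
#'   coordinate system as `window`.
#' @param window integer pair, 1-based inclusive.
#' @param qual_bits species-qualification threshold (default 50).
#' @param region_bits high-homology region threshold (default 200).
#' @param min_species minimum qualified species for status `"ok"`
#'   (default 40).
#' @return object of class `conservation_record`: list with `query_id`,
#'   `window`, `score`, `n_species`, `status`.
#' @export
conservation_score <- function(hits, window, qual_bits = 50,
                               region_bits = 200, min_species = 40L) {
  stopifnot(inherits(hits, "blast_hsp"), length(window) == 2L)
  query_id <- if (nrow(hits)) hits$query_id[1L] else NA_character_
  qualified <- unique(hits$species[hits$bit_score >= qual_bits])
  n_species <- length(qualified)
  width <- window[2L] - window[1L] + 1L
  if (n_species == 0L) {
    score <- NA_real_
  } else {
    strong <- hits[hits$bit_score >= region_bits &
                     hits$species %in% qualified, , drop = FALSE]
    cov <- stats::setNames(numeric(n_species), qualified)
    if (nrow(strong)) {
      by_sp <- split(strong, strong$species)
      for (sp in names(by_sp)) {
        cov[sp] <- interval_coverage(by_sp[[sp]]$query_start,
                                     by_sp[[sp]]$query_end, window)
      }
    }
    score <- mean(cov)
    stopifnot(score >= 0, score <= width)
  }
  structure(list(query_id = query_id, window = as.integer(window),
                 score = score, n_species = n_species,
                 status = if (n_species >= min_species) "ok"
                          else "too_few_species"),
            class = "conservation_record")
}

#' @export
print.conservation_record <- function(x, ...) {
  cat(sprintf("<conservation %s [%d,%d]: score %s over %d species (%s)>\n",
              x$query_id, x$window[1], x$window[2],
              if (is.na(x$score)) "NA" else sprintf("%.2f", x$score),
              x$n_species, x$status))
  invisible(x)
}

#' Score the N, middle and C windows of one protein
#'
#' The N window is scored from the first-half BLAST; the middle and C
#' windows from the second-half BLAST, whose query coordinates (1-based
#' within the second half) are shifted by `+floor(M/2)` onto full-protein
#' coordinates. With the alternative scheme (`middle = "end_of_first_half"`),
#' the middle window is scored from the first-half hits instead.
#'
#' @param hits_first_half,hits_second_half `blast_hsp` data frames for one
#'   query, already deduplicated, each on its own half's query coordinates.
#' @param scheme a `window_scheme`.
#' @inheritParams conservation_score
#' @return named list of three `conservation_record`s: `n`, `mid`, `c`.
#' @export
score_all_windows <- function(hits_first_half, hits_second_half, scheme,
                              qual_bits = 50, region_bits = 200,
                              min_species = 40L) {
  stopifnot(inherits(scheme, "window_scheme"))
  shifted <- hits_second_half
  if (nrow(shifted)) {
    shifted$query_start <- shifted$query_start + scheme$half_split
    shifted$query_end <- shifted$query_end + scheme$half_split
  }
  mid_hits <- if (scheme$middle == "start_of_second_half") shifted
              else hits_first_half
  list(
    n = conservation_score(hits_first_half, scheme$n_window,
                           qual_bits, region_bits, min_species),
    mid = conservation_score(mid_hits, scheme$mid_window,
                             qual_bits, region_bits, min_species),
    c = conservation_score(shifted, scheme$c_window,
                           qual_bits, region_bits, min_species))
}

#' Conservation scores for many proteins, as a data frame
#'
#' @param hits_first_half,hits_second_half `blast_hsp` data frames covering
#'   all queries (deduplication is applied here).
#' @param protein_lengths named integer vector query_id -> length in aa.
#' @inheritParams conservation_score
#' @param middle passed to [window_scheme()].
#' @return data.frame: query_id, window label (n/mid/c), start, end, score,
#'   n_species, status (including `"too_short"` rows for proteins < 100 aa).
#' @export
conservation_table <- function(hits_first_half, hits_second_half,
                               protein_lengths, qual_bits = 50,
                               region_bits = 200, min_species = 40L,
                               middle = "start_of_second_half") {
  h1 <- dedupe_by_species(hits_first_half)
  h2 <- dedupe_by_species(hits_second_half)
  rows <- list()
  for (qid in names(protein_lengths)) {
    m <- protein_lengths[[qid]]
    if (m < 100L) {
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = qid, window = c("n", "mid", "c"),
        start = NA_integer_, end = NA_integer_, score = NA_real_,
        n_species = 0L, status = "too_short", stringsAsFactors = FALSE)
      next
    }
    scheme <- window_scheme(m, middle = middle)
    recs <- score_all_windows(
      h1[h1$query_id == qid, , drop = FALSE],
      h2[h2$query_id == qid, , drop = FALSE],
      scheme, qual_bits, region_bits, min_species)
    rows[[length(rows) + 1L]] <- data.frame(
      query_id = qid, window = c("n", "mid", "c"),
      start = c(scheme$n_window[1], scheme$mid_window[1], scheme$c_window[1]),
      end = c(scheme$n_window[2], scheme$mid_window[2], scheme$c_window[2]),
      score = vapply(recs, `[[`, numeric(1), "score"),
      n_species = vapply(recs, `[[`, integer(1), "n_species"),
      status = vapply(recs, `[[`, character(1), "status"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
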