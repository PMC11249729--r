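# Shared fixtures, all built in code.

# deterministic RRT table with a given value per codon (default flat), with
# selected overrides
fixture_rrt <- function(..., default = 1) {
  overrides <- c(...)
  vals <- stats::setNames(rep(default, length(codonramp:::sense_codons)),
                          codonramp:::sense_codons)
  if (length(overrides)) vals[names(overrides)] <- overrides
  rrt_table(vals)
}

# a varied but reproducible RRT table
fixture_rrt_varied <- function(seed = 7) synthetic_rrt(seed)

# gene from codon strings; appends TAA unless the last codon is a stop
fixture_gene <- function(codons, id = "G1") {
  if (!codons[length(codons)] %in% c("TAA", "TAG", "TGA")) {
    codons <- c(codons, "TAA")
  }
  coding_gene(id, codons)
}

# gene of n_sense copies of `codon` after the ATG start
fixture_repeat_gene <- function(codon, n_sense = 60, id = "G1") {
  fixture_gene(c("ATG", rep(codon, n_sense - 1)), id = id)
}

# random in-frame gene (no internal stops), n_sense sense codons
fixture_random_gene <- function(n_sense, id = "G1") {
  body <- sample(codonramp:::sense_codons, n_sense - 1, replace = TRUE)
  fixture_gene(c("ATG", body), id = id)
}

write_fasta_fixture <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(as.character(unlist(lapply(names(seqs), function(id) {
    c(paste0(">", id), seqs[[id]])
  }))), path)
  path
}

write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# independent brute-force conservation oracle: for each window position, the
# fraction of qualified species whose strong intervals cover it, summed
oracle_conservation <- function(hits, window, qual_bits = 50,
                                region_bits = 200) {
  qualified <- unique(hits$species[hits$bit_score >= qual_bits])
  if (!length(qualified)) return(NA_real_)
  total <- 0
  for (p in window[1]:window[2]) {
    covering <- unique(hits$species[
      hits$bit_score >= region_bits &
        hits$species %in% qualified &
        hits$query_start <= p & hits$query_end >= p])
    total <- total + length(covering) / length(qualified)
  }
  total
}

# random HSP set for one query on a coordinate span
random_hits <- function(n_species, max_hsp = 4, span = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (s in seq_len(n_species)) {
    k <- sample.int(max_hsp, 1)
    start <- sample.int(span, k, replace = TRUE)
    len <- sample.int(40, k, replace = TRUE)
    rows[[s]] <- blast_hsp(
      "Q1", sprintf("subj%02d", s), sprintf("sp%02d", s),
      bit_score = sample(c(30, 60, 150, 250, 400), k, replace = TRUE),
      query_start = start, query_end = pmin(start + len, span + 40))
  }
  do.call(rbind, rows)
}
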