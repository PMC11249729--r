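# Synthetic data with the statistical structure the pipeline assumes.
#
# The terminus-turnover ("young spandrel") genome model: codon choice in
# gene bodies is under selection against slow codons, with per-amino-acid
# synonym probabilities proportional to exp(-s * RRT(codon)). A fraction
# tau of genes has recently acquired a new terminus: its first K codons
# (after the ATG) are drawn uniformly among synonyms, i.e. selection-free.
# Because the uniform mixture has a higher expected RRT than the selected
# one, turned-over termini are slower on average, and the expected
# genome-wide slowdown has a closed form from the two codon distributions —
# which makes parameter-recovery tests exact.

#' Specify a spandrel genome model
#'
#' @param n_genes number of genes.
#' @param length_dist function(n) returning n sense-codon counts (>= 101);
#'   the default draws from a truncated lognormal centred near 350 codons,
#'   a realistic ORF-length scale.
#' @param selection_s body selection strength s >= 0; synonym probability
#'   within an amino acid is proportional to `exp(-s * RRT)`.
#' @param turnover_prob probability tau that a gene's 5' terminus is young
#'   (selection-free).
#' @param turnover_len K, codons affected by 5' turnover (positions
#'   2..K+1).
#' @param turnover_prob3,turnover_len3 same for the 3' end (last K codons);
#'   default off.
#' @param aa_composition named numeric over the 20 amino acids (need not be
#'   normalised); default uniform.
#' @return object of class `spandrel_model`.
#' @export
spandrel_model <- function(n_genes, length_dist = NULL, selection_s = 1,
                           turnover_prob = 0.5, turnover_len = 40L,
                           turnover_prob3 = 0, turnover_len3 = 40L,
                           aa_composition = NULL) {
  if (is.null(length_dist)) {
    length_dist <- function(n) {
      pmin(pmax(round(stats::rlnorm(n, log(350), 0.4)), 101L), 1500L)
    }
  }
  aas <- sort(unique(unname(codon_to_aa[sense_codons])))
  if (is.null(aa_composition)) {
    aa_composition <- stats::setNames(rep(1, length(aas)), aas)
  }
  stopifnot(setequal(names(aa_composition), aas),
            all(aa_composition >= 0), sum(aa_composition) > 0,
            selection_s >= 0, turnover_prob >= 0, turnover_prob <= 1,
            turnover_prob3 >= 0, turnover_prob3 <= 1)
  structure(list(n_genes = as.integer(n_genes), length_dist = length_dist,
                 selection_s = selection_s,
                 turnover_prob = turnover_prob,
                 turnover_len = as.integer(turnover_len),
                 turnover_prob3 = turnover_prob3,
                 turnover_len3 = as.integer(turnover_len3),
                 aa_composition = aa_composition / sum(aa_composition)),
            class = "spandrel_model")
}

# codon-level mixture weights and RRT moments for the uniform (selection-
# free) and selected regimes, blended over the amino-acid composition
codon_regime_moments <- function(model, rrt) {
  weights <- function(selected) {
    w <- stats::setNames(numeric(length(sense_codons)), sense_codons)
    for (aa in names(model$aa_composition)) {
      syn <- aa_to_codons[[aa]]
      v <- rrt_lookup(rrt, syn)
      p <- if (selected) exp(-model$selection_s * v) else rep(1, length(syn))
      w[syn] <- model$aa_composition[[aa]] * p / sum(p)
    }
    w
  }
  vals <- rrt_lookup(rrt, sense_codons)
  mom <- function(w) {
    e <- sum(w * vals)
    list(mean = e, var = sum(w * vals^2) - e^2, weights = w)
  }
  list(uniform = mom(weights(FALSE)), selected = mom(weights(TRUE)))
}

#' Choose the selection strength giving a target expected slowdown
#'
#' Solves `100 * (E_uniform[RRT] / E_selected[RRT] - 1) = delta_pct` for s,
#' so that a fully turned-over terminal window (tau = 1) is slower than the
#' body by `delta_pct` percent in expectation.
#'
#' @param delta_pct target slowdown in percent (> 0).
#' @param rrt an `rrt_table`.
#' @param aa_composition as in [spandrel_model()].
#' @return selection strength s.
#' @export
calibrate_selection <- function(delta_pct, rrt, aa_composition = NULL) {
  stopifnot(delta_pct > 0)
  f <- function(s) {
    m <- codon_regime_moments(
      spandrel_model(1, selection_s = s, aa_composition = aa_composition),
      rrt)
    100 * (m$uniform$mean / m$selected$mean - 1) - delta_pct
  }
  stats::uniroot(f, c(1e-6, 60), tol = 1e-10)$root
}

#' Generate a synthetic genome under the spandrel model
#'
#' Every gene starts with ATG, ends with a random stop codon, and has its
#' amino acids drawn from the model's composition. Body codons follow the
#' selected synonym distribution; in turned-over genes the terminal window
#' is selection-free. The truth record carries the per-gene turnover flags
#' and the regime moments, from which [expected_slowdown()] computes the
#' closed-form expected genome-wide slowdown for any analysis window.
#'
#' @param model a `spandrel_model`.
#' @param rrt an `rrt_table`.
#' @param seed integer seed; the generator is a pure function of
#'   (model, rrt, seed).
#' @return list with `genes` (list of `coding_gene`) and `truth` (class
#'   `spandrel_truth`: per-gene table, regime moments, and the
#'   parameter-level `delta_expected_pct = 100 * tau * (E_u/E_s - 1)`).
#' @export
gen_genome <- function(model, rrt, seed) {
  stopifnot(inherits(model, "spandrel_model"))
  set.seed(as.integer(seed))
  n <- model$n_genes
  lens <- model$length_dist(n)   # sense codons per gene
  stopifnot(all(lens >= 101L))
  turned5 <- stats::runif(n) < model$turnover_prob
  turned3 <- stats::runif(n) < model$turnover_prob3
  mom <- codon_regime_moments(model, rrt)

  # flatten: one row per variable position (2..L per gene)
  gene_of <- rep.int(seq_len(n), lens - 1L)
  pos <- unlist(lapply(lens, function(L) 2:L), use.names = FALSE)
  aas <- names(model$aa_composition)
  aa_idx <- sample.int(length(aas), length(pos), replace = TRUE,
                       prob = model$aa_composition)
  uniform_pos <- (turned5[gene_of] & pos <= model$turnover_len + 1L) |
    (turned3[gene_of] & pos > lens[gene_of] - model$turnover_len3)
  codons <- character(length(pos))
  for (k in seq_along(aas)) {
    syn <- aa_to_codons[[aas[k]]]
    v <- rrt_lookup(rrt, syn)
    p_sel <- exp(-model$selection_s * v)
    for (u in c(TRUE, FALSE)) {
      sel <- aa_idx == k & uniform_pos == !u
      m <- sum(sel)
      if (!m) next
      prob <- if (u) p_sel else rep(1, length(syn))
      codons[sel] <- syn[sample.int(length(syn), m, replace = TRUE,
                                    prob = prob)]
    }
  }
  stops <- sample(stop_codons, n, replace = TRUE)
  genes <- vector("list", n)
  starts <- c(1L, cumsum(lens - 1L)[-n] + 1L)
  for (i in seq_len(n)) {
    body <- codons[starts[i]:(starts[i] + lens[i] - 2L)]
    genes[[i]] <- coding_gene(sprintf("SYN%04d", i),
                              c("ATG", body, stops[i]))
  }
  truth <- structure(list(
    model = model,
    genes = data.frame(gene_id = sprintf("SYN%04d", seq_len(n)),
                       n_sense = lens, turned5 = turned5, turned3 = turned3,
                       stringsAsFactors = FALSE),
    moments = mom,
    delta_expected_pct = 100 * model$turnover_prob *
      (mom$uniform$mean / mom$selected$mean - 1)),
    class = "spandrel_truth")
  list(genes = genes, truth = truth)
}

#' Closed-form expected slowdown for a generated genome
#'
#' Conditions on which genes actually turned over and on gene lengths, and
#' computes the expectation of the genome-wide mean RRT ratio
#' (`mean(2^rit)`) for the given analysis window, including the
#' second-order correction for the finite body window
#' (`E[num/den] ~ (E num / E den) * (1 + Var(den)/E(den)^2)`).
#'
#' @param truth a `spandrel_truth`.
#' @param window analysis window in codons.
#' @param end `"five_prime"` or `"three_prime"`.
#' @return list with `delta_pct` (expected `100*(mean ratio - 1)`) and the
#'   per-gene expected ratios `ratio`.
#' @export
expected_slowdown <- function(truth, window = 40L,
                              end = c("five_prime", "three_prime")) {
  end <- match.arg(end)
  stopifnot(inherits(truth, "spandrel_truth"))
  model <- truth$model
  mom <- truth$moments
  window <- as.integer(window)
  g <- truth$genes
  ratio <- numeric(nrow(g))
  for (i in seq_len(nrow(g))) {
    L <- g$n_sense[i]
    pos <- rit_positions(L + 1L, window, end)
    is_unif <- function(p) {
      (g$turned5[i] & p <= model$turnover_len + 1L) |
        (g$turned3[i] & p > L - model$turnover_len3)
    }
    reg_mean <- function(p) {
      u <- is_unif(p)
      mean(ifelse(u, mom$uniform$mean, mom$selected$mean))
    }
    reg_var_of_mean <- function(p) {
      u <- is_unif(p)
      sum(ifelse(u, mom$uniform$var, mom$selected$var)) / length(p)^2
    }
    e_num <- reg_mean(pos$num)
    e_den <- reg_mean(pos$den)
    ratio[i] <- e_num / e_den * (1 + reg_var_of_mean(pos$den) / e_den^2)
  }
  list(delta_pct = 100 * (mean(ratio) - 1), ratio = ratio)
}

#' Specify a homology (BLAST hit geometry) model
#'
#' Emulates the hit structure of a protein-vs-species-panel BLAST: per
#' species one orthologous subject whose homology block starts at a sampled
#' offset from the terminus (terminal loss) and runs to the end of the
#' query half.
#'
#' @param n_species number of subject species.
#' @param terminal_loss_dist function(n) returning n 1-based homology-block
#'   start offsets (1 = conserved from the first residue). The default
#'   mixes full conservation with geometric terminal loss.
#' @param region_bits_mean mean sampled bit score; scores below 200 make a
#'   species qualify without contributing coverage.
#' @param region_bits_sd standard deviation of sampled bit scores.
#' @return object of class `homology_model`.
#' @export
homology_model <- function(n_species = 60L, terminal_loss_dist = NULL,
                           region_bits_mean = 400, region_bits_sd = 80) {
  if (is.null(terminal_loss_dist)) {
    terminal_loss_dist <- function(n) {
      ifelse(stats::runif(n) < 0.4, 1L,
             1L + stats::rgeom(n, prob = 0.05))
    }
  }
  stopifnot(n_species >= 1L)
  structure(list(n_species = as.integer(n_species),
                 terminal_loss_dist = terminal_loss_dist,
                 region_bits_mean = region_bits_mean,
                 region_bits_sd = region_bits_sd),
            class = "homology_model")
}

#' Generate BLAST hit tables with controlled homology geometry
#'
#' For each protein and each half, every species contributes one subject
#' with a single HSP `[offset, half_end]` on half-query coordinates, with a
#' sampled bit score. The truth record stores each window's exact mean
#' coverage (computed from the sampled offsets and bit scores by direct
#' interval arithmetic), so conservation scoring can be checked against the
#' generator's own bookkeeping.
#'
#' @param proteins data.frame with columns `id` and `length` (aa, >= 100).
#' @param model a `homology_model`.
#' @param seed integer seed.
#' @return list with `first` and `second` (`blast_hsp` data frames on
#'   half-query coordinates), `species_map` (named vector), and `truth`
#'   (data.frame query_id, n_cov, mid_cov, c_cov, n_species).
#' @export
gen_blast_hits <- function(proteins, model, seed) {
  stopifnot(inherits(model, "homology_model"),
            all(c("id", "length") %in% names(proteins)),
            all(proteins$length >= 100))
  set.seed(as.integer(seed))
  species <- sprintf("species_%03d", seq_len(model$n_species))
  subjects <- sprintf("subj_%03d", seq_len(model$n_species))
  species_map <- stats::setNames(species, subjects)
  sample_bits <- function(n) {
    pmax(50, stats::rnorm(n, model$region_bits_mean, model$region_bits_sd))
  }
  rows1 <- list(); rows2 <- list(); truth <- list()
  for (j in seq_len(nrow(proteins))) {
    m <- as.integer(proteins$length[j])
    h <- m %/% 2L
    len1 <- h; len2 <- m - h
    off1 <- pmin(model$terminal_loss_dist(model$n_species), len1)
    off2 <- pmin(model$terminal_loss_dist(model$n_species), len2)
    bits1 <- sample_bits(model$n_species)
    bits2 <- sample_bits(model$n_species)
    rows1[[j]] <- blast_hsp(proteins$id[j], subjects, species, bits1,
                            off1, len1, half = "first")
    rows2[[j]] <- blast_hsp(proteins$id[j], subjects, species, bits2,
                            off2, len2, half = "second")
    # exact window coverages: block [off, half_end], strong iff bits >= 200
    n_cov <- mean(ifelse(bits1 >= 200 & off1 <= 40L, 41L - off1, 0L))
    mid_cov <- mean(ifelse(bits2 >= 200 & off2 <= 40L, 41L - off2, 0L))
    c_cov <- mean(ifelse(bits2 >= 200, pmin(40L, len2 - off2 + 1L), 0L))
    truth[[j]] <- data.frame(query_id = proteins$id[j], n_cov = n_cov,
                             mid_cov = mid_cov, c_cov = c_cov,
                             n_species = model$n_species,
                             stringsAsFactors = FALSE)
  }
  list(first = do.call(rbind, rows1), second = do.call(rbind, rows2),
       species_map = species_map, truth = do.call(rbind, truth))
}

#' Generate gene-level values coupled to terminal selection
#'
#' Emulates expression / ribosome-density tables whose values correlate
#' with how strongly a gene's terminus was under selection: the per-gene
#' covariate is minus the expected terminal slowdown (in percent), so with
#' positive coupling, genes with fast (selected) termini get high values —
#' the pattern seen in real expression data.
#'
#' @param truth a `spandrel_truth` from [gen_genome()].
#' @param kind `"read_count"`, `"ribosome_density"` or `"other"`.
#' @param coupling coefficient linking the covariate to the (log) value.
#' @param noise_sd standard deviation of the added Gaussian noise.
#' @param seed integer seed.
#' @param window analysis window defining the covariate (default 40).
#' @return a `gene_value_table` (read counts are exponentiated around a
#'   median of ~200 and rounded to non-negative integers, then filtered at
#'   the usual minimum count).
#' @export
gen_gene_values <- function(truth, kind = c("read_count", "ribosome_density",
                                            "other"),
                            coupling = 1, noise_sd = 0.5, seed = 1L,
                            window = 40L) {
  kind <- match.arg(kind)
  stopifnot(inherits(truth, "spandrel_truth"))
  set.seed(as.integer(seed))
  covariate <- -(expected_slowdown(truth, window = window)$ratio - 1) * 100
  n <- length(covariate)
  noise <- stats::rnorm(n, 0, noise_sd)
  vals <- switch(kind,
    read_count = pmax(0, round(exp(log(200) + coupling * covariate + noise))),
    ribosome_density = exp(log(0.01) + coupling * covariate + noise),
    other = coupling * covariate + noise)
  gene_value_table(stats::setNames(vals, truth$genes$gene_id), kind = kind)
}

#' Write BLAST hit tables in outfmt-6 layout
#'
#' Fills the alignment-statistics columns the scorer ignores with
#' placeholder values consistent with the coordinates.
#'
#' @param hits a `blast_hsp` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  len <- hits$query_end - hits$query_start + 1L
  out <- data.frame(hits$query_id, hits$subject_id, 90.0, len, 0L, 0L,
                    hits$query_start, hits$query_end, 1L, len, 1e-30,
                    hits$bit_score)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a subject -> species map as TSV
#' @param species_map named character vector subject_id -> species.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_species_map <- function(species_map, path) {
  utils::write.table(
    data.frame(subject_id = names(species_map), species = unname(species_map)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
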