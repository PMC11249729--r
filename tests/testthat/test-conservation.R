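# Windowed terminal conservation scores from BLAST HSP geometry.

test_that("window schemes follow the halving rule", {
  ws <- window_scheme(709)
  expect_equal(ws$n_window, c(1L, 40L))
  expect_equal(ws$mid_window, c(355L, 394L))
  expect_equal(ws$c_window, c(670L, 709L))
  expect_equal(ws$half_split, 354L)

  ws100 <- window_scheme(100)
  expect_equal(ws100$n_window, c(1L, 40L))
  expect_equal(ws100$mid_window, c(51L, 90L))
  expect_equal(ws100$c_window, c(61L, 100L))

  expect_error(window_scheme(99), "too_short")

  alt <- window_scheme(709, middle = "end_of_first_half")
  expect_equal(alt$mid_window, c(315L, 354L))
})

test_that("species deduplication keeps only the best subject per species", {
  hits <- blast_hsp(
    query_id = "Q1",
    subject_id = c("s1", "s1", "s2", "s3"),
    species = c("spA", "spA", "spA", "spB"),
    bit_score = c(300, 80, 250, 120),
    query_start = c(1, 50, 1, 1), query_end = c(40, 90, 40, 40))
  kept <- dedupe_by_species(hits)
  expect_setequal(kept$subject_id, c("s1", "s3"))
  expect_equal(nrow(kept[kept$subject_id == "s1", ]), 2L)  # all its HSPs

  # one subject per species: identity
  solo <- blast_hsp("Q1", c("s1", "s2"), c("spA", "spB"), c(100, 100),
                    c(1, 1), c(40, 40))
  expect_equal(nrow(dedupe_by_species(solo)), 2L)

  # tie in best bit-score -> lexicographically smallest subject
  tie <- blast_hsp("Q1", c("s2", "s1"), c("spA", "spA"), c(200, 200),
                   c(1, 1), c(40, 40))
  expect_equal(unique(dedupe_by_species(tie)$subject_id), "s1")
})

test_that("conservation scores span 0 to the window width and average species coverage", {
  win <- c(1L, 40L)
  # >= 40 species qualified, none with a strong region in the window
  hits0 <- blast_hsp("Q1", sprintf("s%02d", 1:45), sprintf("sp%02d", 1:45),
                     bit_score = rep(60, 45),
                     query_start = rep(50, 45), query_end = rep(90, 45))
  rec0 <- conservation_score(hits0, win)
  expect_equal(rec0$score, 0)
  expect_equal(rec0$status, "ok")

  # every species fully covers the window from position 1
  hits40 <- blast_hsp("Q1", sprintf("s%02d", 1:45), sprintf("sp%02d", 1:45),
                      bit_score = rep(300, 45),
                      query_start = rep(1, 45), query_end = rep(60, 45))
  expect_equal(conservation_score(hits40, win)$score, 40)

  # coverages 40 and 20 -> mean 30
  two <- blast_hsp("Q1", c("s1", "s2"), c("spA", "spB"), c(250, 250),
                   c(1, 21), c(40, 45))
  rec2 <- conservation_score(two, win, min_species = 2)
  expect_equal(rec2$score, 30)
  expect_equal(rec2$n_species, 2L)

  # closed 1-based intervals: HSP [35,60] covers positions 35..40 -> 6
  one <- blast_hsp("Q1", "s1", "spA", 250, 35, 60)
  expect_equal(conservation_score(one, win, min_species = 1)$score, 6)

  # a qualified species below the region threshold drags the mean down
  mix <- blast_hsp("Q1", c("s1", "s2"), c("spA", "spB"), c(250, 100),
                   c(1, 1), c(40, 40))
  expect_equal(conservation_score(mix, win, min_species = 2)$score, 20)

  # below min_species the status flags the record
  expect_equal(conservation_score(two, win)$status, "too_few_species")
})

test_that("scores equal the per-position brute-force oracle on random HSP sets", {
  set.seed(101)
  for (i in 1:300) {
    hits <- random_hits(n_species = sample(3:12, 1))
    win <- sort(sample.int(80, 2))
    rec <- conservation_score(hits, win, min_species = 1)
    oracle <- oracle_conservation(hits, win)
    if (is.na(oracle)) {
      expect_true(is.na(rec$score))
    } else {
      expect_equal(rec$score, oracle, tolerance = 1e-12)
    }
  }
})

test_that("coverage is monotone in added HSPs and invariant to interval splitting", {
  set.seed(102)
  for (i in 1:50) {
    hits <- random_hits(n_species = 6)
    win <- c(1L, 40L)
    base <- conservation_score(hits, win, min_species = 1)$score
    extra <- blast_hsp("Q1", hits$subject_id[1], hits$species[1], 400, 5, 25)
    grown <- conservation_score(rbind(hits, extra), win,
                                min_species = 1)$score
    expect_gte(grown, base)
  }

  # split one interval into two abutting halves: same score
  whole <- blast_hsp("Q1", "s1", "spA", 300, 3, 30)
  split2 <- blast_hsp("Q1", c("s1", "s1"), c("spA", "spA"), c(300, 300),
                      c(3, 15), c(14, 30))
  expect_equal(conservation_score(whole, c(1L, 40L), min_species = 1)$score,
               conservation_score(split2, c(1L, 40L), min_species = 1)$score)
})

test_that("three-window scoring offsets second-half coordinates onto the full protein", {
  scheme <- window_scheme(709)
  # second-half HSP at half coordinates [1,40] -> full [355,394]: covers mid fully
  h2 <- blast_hsp("Q1", "s1", "spA", 300, 1, 40, half = "second")
  empty <- h2[0, , drop = FALSE]
  recs <- score_all_windows(empty, h2, scheme, min_species = 1)
  expect_equal(recs$mid$score, 40)
  # C window untouched by that HSP
  expect_equal(recs$c$score, 0)
  # N window has no first-half evidence
  expect_equal(recs$n$status, "too_few_species")

  # C-window scoring ignores first-half hits entirely
  h1 <- blast_hsp("Q1", "s1", "spA", 300, 670, 709, half = "first")
  recs2 <- score_all_windows(h1, empty, scheme, min_species = 1)
  expect_equal(recs2$c$status, "too_few_species")

  # second-half HSP reaching the half end covers the C window
  h2c <- blast_hsp("Q1", "s1", "spA", 300, 300, 355, half = "second")
  recs3 <- score_all_windows(empty, h2c, scheme, min_species = 1)
  expect_equal(recs3$c$score, 40)
})

test_that("the BLAST tabular reader filters, maps species, and drops unmapped subjects", {
  lines <- c(
    "Q1\ts1\t90.0\t40\t4\t0\t1\t40\t1\t40\t1e-20\t250",
    "Q1\ts2\t85.0\t40\t6\t0\t5\t44\t1\t40\t1e-10\t45",
    "Q1\tmystery\t85.0\t40\t6\t0\t5\t44\t1\t40\t1e-10\t300")
  p <- write_tsv_fixture(lines)
  smap <- c(s1 = "spA", s2 = "spB")
  expect_warning(hits <- read_blast_hits(p, smap), "species map")
  expect_equal(nrow(hits), 1L)           # s2 below 50 bits, mystery unmapped
  expect_equal(hits$species, "spA")
  expect_equal(hits$query_start, 1L)

  # species map round-trips through its TSV form
  mp <- tempfile()
  write_species_map(smap, mp)
  expect_equal(load_species_map(mp), smap)
})

test_that("conservation_table labels short proteins and scores the rest", {
  h1 <- blast_hsp(rep("Q1", 2), c("s1", "s2"), c("spA", "spB"),
                  c(300, 250), c(1, 1), c(40, 40), half = "first")
  h2 <- blast_hsp(rep("Q1", 2), c("s1", "s2"), c("spA", "spB"),
                  c(300, 250), c(1, 1), c(60, 60), half = "second")
  tab <- conservation_table(h1, h2, c(Q1 = 200L, Q2 = 80L), min_species = 2)
  expect_equal(nrow(tab), 6L)
  expect_equal(tab$score[tab$query_id == "Q1" & tab$window == "n"], 40)
  expect_true(all(tab$status[tab$query_id == "Q2"] == "too_short"))
})
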