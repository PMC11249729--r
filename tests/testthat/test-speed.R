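# Speed profiles, RIT, neutralization, genome-wide slowdown, metaprofiles.

test_that("speed profiles map codons to residence times, stop excluded", {
  rrt <- fixture_rrt(c(ATG = 0.7, GCT = 1.1))
  g <- fixture_gene(c("ATG", "GCT"))
  expect_equal(speed_profile(g, rrt), c(0.7, 1.1))

  g2 <- fixture_repeat_gene("GCT", n_sense = 10)
  expect_equal(speed_profile(g2, rrt)[-1], rep(1.1, 8 + 1))
  expect_length(speed_profile(g2, rrt), length(g2$codons) - 1L)

  g3 <- coding_gene("X", c("ATG", "GCT", "TAA", "GCT", "TAA"))
  expect_error(speed_profile(g3, rrt), "position 3")
})

test_that("rit is zero for identical window/body codon multisets and follows the log2 ratio", {
  rrt <- fixture_rrt_varied()
  # identical multisets: same codon everywhere
  g <- fixture_repeat_gene("GAA", n_sense = 101)
  expect_equal(rit(g, rrt, window = 40)$rit, 0)

  # numerator mean 1.2 vs denominator mean 1.0
  rrt2 <- fixture_rrt(c(TGC = 1.2, GCT = 1.0))
  g2 <- fixture_gene(c("ATG", "TGC", rep("GCT", 10)))
  rec <- rit(g2, rrt2, window = 2)
  expect_equal(rec$rit, log2(1.2), tolerance = 1e-12)
  expect_equal(rec$n_numerator, 1L)
  expect_equal(rec$n_denominator, 10L)

  expect_error(rit(fixture_repeat_gene("GCT", 30), rrt, window = 40),
               "too short")
})

test_that("three-prime rit uses the last window codons against the earlier body", {
  rrt <- fixture_rrt(c(TGC = 2, GCT = 1))
  # 1 ATG + 50 GCT + 10 TGC + stop: last 10 sense codons are the slow ones
  g <- fixture_gene(c("ATG", rep("GCT", 50), rep("TGC", 10)))
  rec <- rit(g, rrt, window = 10, end = "three_prime")
  expect_equal(rec$rit, log2(2))
  expect_equal(rec$n_numerator, 10L)
  expect_equal(rec$n_denominator, 50L)
})

test_that("rit is scale invariant and negates when regions swap", {
  rrt <- fixture_rrt_varied()
  set.seed(11)
  genes <- lapply(1:20, function(i) fixture_random_gene(120, sprintf("g%d", i)))
  r1 <- vapply(genes, function(g) rit(g, rrt, 40)$rit, numeric(1))

  scaled <- rrt_table(rrt$entries * 3.7)
  r2 <- vapply(genes, function(g) rit(g, scaled, 40)$rit, numeric(1))
  expect_equal(r1, r2, tolerance = 1e-12)

  # swap: numerator multiset <-> denominator multiset negates rit
  g <- fixture_gene(c("ATG", rep("TGC", 39), rep("GCT", 60)),
                    id = "fwd")
  g_sw <- fixture_gene(c("ATG", rep("GCT", 39), rep("TGC", 60)),
                       id = "swapped")
  rrt2 <- fixture_rrt(c(TGC = 1.8, GCT = 0.9))
  # equalise region sizes so multisets exchange exactly
  g <- fixture_gene(c("ATG", rep("TGC", 40), rep("GCT", 40)))
  g_sw <- fixture_gene(c("ATG", rep("GCT", 40), rep("TGC", 40)))
  expect_equal(rit(g, rrt2, 41)$rit, -rit(g_sw, rrt2, 41)$rit,
               tolerance = 1e-12)
})

test_that("classification is SIT above the threshold, FIT at or below", {
  expect_equal(classify_rit(0.208), "SIT")
  expect_equal(classify_rit(-0.166), "FIT")
  expect_equal(classify_rit(0), "FIT")
  rrt <- fixture_rrt(c(TGC = 1.2, GCT = 1.0))
  g <- fixture_gene(c("ATG", "TGC", rep("GCT", 10)))
  expect_equal(classify_rit(rit(g, rrt, 2)), "SIT")
})

test_that("neutralize masks exactly the requested codons and copies the table", {
  rrt <- fixture_rrt_varied()
  expect_equal(neutralize(rrt, character())$entries, rrt$entries)

  n1 <- neutralize(rrt, "ATG")
  expect_equal(rrt_lookup(n1, "ATG"), 1.0189)
  expect_false(rrt_lookup(rrt, "ATG") == 1.0189)  # input untouched

  n4 <- neutralize(rrt, c("ATG", "ATT", "TTG", "ATA"))
  changed <- names(rrt$entries)[n4$entries != rrt$entries]
  expect_setequal(changed, c("ATG", "ATT", "TTG", "ATA"))

  expect_error(neutralize(rrt, "TAA"), "TAA")

  # neutralizing a codon at its existing value is the identity downstream
  rrt_id <- rrt
  rrt_id$entries[["GCT"]] <- rrt$neutral_value
  g <- fixture_random_gene(120)
  expect_equal(rit(g, neutralize(rrt_id, "GCT"), 40)$rit,
               rit(g, rrt_id, 40)$rit)
})

test_that("a null genome of repeat genes shows zero slowdown with p = 1", {
  rrt <- fixture_rrt_varied()
  genes <- lapply(1:10, function(i) {
    fixture_repeat_gene(c("GCT", "GAA", "TGC")[i %% 3 + 1], 120,
                        sprintf("g%d", i))
  })
  s <- genomewide_slowdown(genes, rrt, window = 40)
  expect_equal(s$mean_ratio_pct, 0)
  expect_equal(s$p_value, 1)
  expect_equal(s$n_genes, 10L)
})

test_that("slowdown on the RRT and speed scales agree in sign and roughly in size", {
  rrt <- fixture_rrt_varied()
  s <- calibrate_selection(2, rrt)
  sim <- gen_genome(spandrel_model(150, selection_s = s, turnover_prob = 1),
                    rrt, seed = 5)
  a <- genomewide_slowdown(sim$genes, rrt, scale = "rrt")
  b <- genomewide_slowdown(sim$genes, rrt, scale = "speed")
  expect_gt(a$mean_ratio_pct, 0)
  expect_gt(b$mean_ratio_pct, 0)
  expect_equal(a$mean_ratio_pct, b$mean_ratio_pct, tolerance = 0.5)
})

test_that("metaprofile is flat for a uniform table, with attrition in n and identity smoothing", {
  rrt <- fixture_rrt(default = 1.25)
  set.seed(3)
  genes <- c(lapply(1:5, function(i) fixture_random_gene(150, sprintf("a%d", i))),
             lapply(1:5, function(i) fixture_random_gene(110, sprintf("b%d", i))))
  prof <- metaprofile(genes, rrt, max_pos = 140)
  expect_equal(prof$mean_inv_rrt, rep(1 / 1.25, nrow(prof)))
  expect_true(all(diff(prof$n) <= 0))
  expect_equal(prof$n[prof$position == 120], 5L)

  rrt2 <- fixture_rrt_varied()
  p1 <- metaprofile(genes, rrt2, max_pos = 100, smooth = 1)
  p2 <- metaprofile(genes, rrt2, max_pos = 100)
  expect_equal(p1, p2)
  p3 <- metaprofile(genes, rrt2, max_pos = 100, smooth = 5)
  expect_false(isTRUE(all.equal(p1$mean_inv_rrt, p3$mean_inv_rrt)))
  expect_error(metaprofile(genes, rrt2, max_pos = 100, smooth = 2), "odd")
})
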