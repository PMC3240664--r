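# intervals below are written in 0-based half-open notation in comments;
# constructors take 1-based closed coordinates.

test_that("the worked redundancy example reduces to r = 1", {
  # i = {[0,10), [20,30), [40,50)}, j = {[25,45)}
  ti <- binding_track(rep("c", 3), c(1, 21, 41), c(10, 30, 50), 1, "i")
  tj <- binding_track("c", 26, 45, 1, "j")
  red <- reduce_redundancy(ti, tj)
  expect_equal(red$m_prime, 2)  # [0,10) untouched + one of the two binders
  expect_equal(red$n_prime, 1)
  expect_equal(red$k, 1)
  s <- similarity(ti, tj)
  expect_equal(s$r, 1.0)
  # symmetric call
  s2 <- similarity(tj, ti)
  expect_equal(s2$r, 1.0)
  expect_equal(s2$k, 1)
})

test_that("disjoint and identical tracks are left unchanged", {
  ti <- binding_track(rep("c", 2), c(1, 101), c(50, 150), 1, "i")
  tj <- binding_track(rep("c", 2), c(300, 500), c(350, 550), 1, "j")
  red <- reduce_redundancy(ti, tj)
  expect_equal(red$m_prime, 2)
  expect_equal(red$n_prime, 2)
  expect_equal(red$k, 0)
  expect_equal(similarity(ti, tj)$r, 0)

  same <- reduce_redundancy(ti, ti)
  expect_equal(same$k, 2)
  expect_equal(same$m_prime, 2)
  expect_equal(similarity(ti, ti)$r, 1)
})

test_that("k equals the maximum-matching size on crossing configurations", {
  # containment/crossing case where naive keep-leftmost greedy undercounts:
  # i = {[0,100), [40,60)}, j = {[30,35), [50,55)} -> max matching 2
  ti <- binding_track(rep("c", 2), c(1, 41), c(100, 60), 1, "i")
  tj <- binding_track(rep("c", 2), c(31, 51), c(35, 55), 1, "j")
  expect_equal(similarity(ti, tj)$k, 2)
  expect_equal(similarity(ti, tj)$r, 1)
})

test_that("k matches the igraph matching oracle on random instances", {
  set.seed(99)
  for (trial in 1:120) {
    ti <- random_small_track(25, name = "i")
    tj <- random_small_track(25, name = "j")
    s <- similarity(ti, tj)
    expect_equal(s$k, igraph_matching_size(ti, tj),
                 label = paste("trial", trial))
    # after reduction, the fragments overlapping the counterpart are exactly
    # the k matched ones, on both sides (every other kept fragment is
    # overlap-free)
    red <- reduce_redundancy(ti, tj)
    expect_equal(sum(GenomicRanges::countOverlaps(red$reduced_i,
                                                  red$reduced_j) > 0), s$k)
    expect_equal(sum(GenomicRanges::countOverlaps(red$reduced_j,
                                                  red$reduced_i) > 0), s$k)
    expect_lte(s$k, min(s$m_prime, s$n_prime))
  }
})

test_that("r is symmetric and invariant to fragment order", {
  set.seed(5)
  ti <- random_small_track(30, name = "i")
  tj <- random_small_track(30, name = "j")
  expect_equal(similarity(ti, tj)$r, similarity(tj, ti)$r)
  perm <- sample(length(ti))
  ti_shuf <- binding_track(as.character(GenomicRanges::seqnames(ti))[perm],
                           GenomicRanges::start(ti)[perm],
                           GenomicRanges::end(ti)[perm], 1, "i")
  expect_equal(similarity(ti_shuf, tj)$r, similarity(ti, tj)$r)
})

test_that("similarity_matrix structure", {
  tr <- binding_track(rep("c", 2), c(1, 101), c(50, 150), 1, "a")
  tracks <- list(a = tr, b = tr, c = tr)
  R <- similarity_matrix(tracks)
  expect_true(all(R == 1))
  expect_identical(R, t(R))
  D <- to_dissimilarity(R)
  expect_true(all(diag(D) == 0))
})

test_that("degenerate similarity (empty reduced track) is flagged r = 0", {
  e <- binding_track(character(), integer(), integer(), numeric(), "e")
  tr <- binding_track("c", 1, 50, 1, "a")
  s <- similarity(tr, e)
  expect_true(s$degenerate)
  expect_equal(s$r, 0)
})

test_that("block partition counts and en arithmetic", {
  expect_equal(length(block_partition(reference_genome(), 3000)), 40000)
  gb <- genome_build("chrA", 10000)
  blocks <- block_partition(gb, 3000)
  expect_equal(GenomicRanges::width(blocks), c(3000, 3000, 3000, 1000))
  # en = l*m/n and halves when n doubles at fixed l, m
  expect_equal(100 * 200 / 40000, 0.5)
  bt_args <- function(n) 100 * 200 / n
  expect_equal(bt_args(80000), bt_args(40000) / 2)
})

test_that("block_test matches the stats::chisq.test oracle on a toy", {
  gb <- genome_build("chrA", 90000)   # 30 blocks of 3 kb
  blocks <- block_partition(gb, 3000)
  expect_length(blocks, 30)
  # hand-placed fragments: i in blocks 1-10, j in blocks 6-15
  ti <- binding_track(rep("chrA", 10), (0:9) * 3000 + 100, (0:9) * 3000 + 200,
                      1, "i")
  tj <- binding_track(rep("chrA", 10), (5:14) * 3000 + 100,
                      (5:14) * 3000 + 200, 1, "j")
  bt <- block_test(ti, tj, blocks)
  expect_equal(bt$a, 5); expect_equal(bt$b, 5)
  expect_equal(bt$c, 5); expect_equal(bt$d, 15)
  expect_equal(bt$l, 10); expect_equal(bt$m, 10); expect_equal(bt$n, 30)
  expect_equal(bt$en, 10 * 10 / 30)
  oracle <- suppressWarnings(
    chisq.test(matrix(c(5, 5, 5, 15), 2), correct = FALSE))
  expect_equal(bt$chi2, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(bt$p_value, oracle$p.value, tolerance = 1e-12)
  # continuity-corrected variant agrees with the corrected oracle
  bty <- block_test(ti, tj, blocks, correct = TRUE)
  oracle_y <- suppressWarnings(
    chisq.test(matrix(c(5, 5, 5, 15), 2), correct = TRUE))
  expect_equal(bty$chi2, unname(oracle_y$statistic), tolerance = 1e-12)
})

test_that("degenerate block_test margins are flagged, not crashed", {
  gb <- genome_build("chrA", 30000)
  blocks <- block_partition(gb, 3000)
  e <- binding_track(character(), integer(), integer(), numeric(), "e")
  tr <- binding_track("chrA", 100, 200, 1, "a")
  bt <- block_test(tr, e, blocks)
  expect_true(bt$degenerate)
  expect_true(is.na(bt$p_value))
})

test_that("planted worlds: within-active similarity exceeds between-group", {
  w <- generate_world(small_cfg(seed = 17))
  R <- similarity_matrix(w$tracks, prepare = TRUE)
  act <- names(w$cfg$active_proteins)
  sil <- names(w$cfg$silent_proteins)
  within <- R[act, act][upper.tri(diag(length(act)))]
  between <- R[act, sil]
  expect_gt(mean(within), mean(between))
})
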