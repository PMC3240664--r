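make_anchors <- function(n = 13, gb = toy_genome()) {
  anchor_set(sprintf("A%02d", seq_len(n)),
             rep(gb$arm, length.out = n),
             seq(200000, by = 37000, length.out = n), genome = gb)
}

test_that("bound_fraction endpoints and a planted 9-of-13 case", {
  gb <- toy_genome()
  anc <- make_anchors()
  spanning <- binding_track(gb$arm, rep(1, 4), gb$length, 1, "all", gb)
  expect_equal(bound_fraction(spanning, anc, 5000, gb), 100)
  empty <- binding_track(character(), integer(), integer(), numeric(), "none")
  expect_equal(bound_fraction(empty, anc, 5000, gb), 0)

  planted <- binding_track(anc$chrom[1:9], anc$position[1:9] - 100,
                           anc$position[1:9] + 100, 1, "nine", gb)
  expect_equal(bound_fraction(planted, anc, 5000, gb), 69.2)  # 9/13
  # brute-force per-bp check of the overlap calls
  for (i in 1:13) {
    win <- (anc$position[i] - 5000 + 1):(anc$position[i] + 5000)
    sel <- as.character(GenomicRanges::seqnames(planted)) == anc$chrom[i]
    manual <- any(vapply(which(sel), function(j) {
      brute_overlap(GenomicRanges::start(planted)[j],
                    GenomicRanges::end(planted)[j], min(win), max(win))
    }, logical(1)))
    expect_equal(manual, i <= 9)
  }
})

test_that("segment heat-map cells: single-segment fragment gives 7.7%", {
  gb <- toy_genome()
  anc <- make_anchors()
  spec <- window_spec(5000, 500)
  # fragment exactly covering segment 10 of anchor 1:
  # segment s spans [pos - 5000 + 500(s-1), pos - 5000 + 500 s) 0-based
  s <- 10
  st0 <- anc$position[1] - 5000 + 500 * (s - 1)
  tr <- binding_track(anc$chrom[1], st0 + 1, st0 + 500, 1, "one", gb)
  M <- heatmap_matrix(list(one = tr), anc, spec, gb)
  expect_equal(dim(M), c(1, 20))
  expect_equal(M[1, s], 7.7)  # 1/13 anchors
  expect_equal(sum(M), 7.7)

  prof <- segment_profile(tr, anc[1, ], spec, gb)
  expect_equal(which(prof), s)

  # fragment spanning the whole window binds all 20 segments
  big <- binding_track(anc$chrom[2], anc$position[2] - 6000,
                       anc$position[2] + 6000, 1, "big", gb)
  expect_true(all(segment_profile(big, anc[2, ], spec, gb)))
})

test_that("constructive active profile: 2-kb centered fragments fill the core", {
  cfg <- small_cfg(seed = 8, active_proteins = c(A = 1),
                   silent_proteins = c(S = "silent_pcg"),
                   anchor_jitter_bp = 0, background_rate = 0,
                   frag_meanlog = log(2000), frag_sdlog = 1e-4,
                   frag_min_bp = 1900, frag_max_bp = 2100)
  w <- generate_world(cfg)
  M <- heatmap_matrix(w$tracks["A"], w$anchors, window_spec(5000, 500),
                      w$genome)
  # fragment [pos-1000, pos+1000) covers segments 9..12 at every anchor
  expect_true(all(M[1, 9:12] == 100))
  expect_true(all(M[1, c(1:7, 14:20)] == 0))
})

test_that("class_profile percentages and error handling", {
  gb <- toy_genome()
  anc <- make_anchors(2)
  spec <- window_spec(2000, 500)
  mk <- function(nm, bind) {
    if (bind) binding_track(anc$chrom[1], anc$position[1] - 100,
                            anc$position[1] + 100, 1, nm, gb)
    else binding_track(character(), integer(), integer(), numeric(), nm)
  }
  tracks <- list(p1 = mk("p1", TRUE), p2 = mk("p2", TRUE),
                 p3 = mk("p3", FALSE), p4 = mk("p4", FALSE))
  cm <- c(p1 = "active", p2 = "active", p3 = "active", p4 = "active")
  # (empty tracks share no seqlevels with the segments; benign warning)
  cp <- suppressWarnings(class_profile(tracks, cm, anc, spec, gb))
  # 2 of 4 proteins bound at the central segments of anchor 1
  central <- cp[["A01"]]["active", c("s4", "s5")]
  expect_true(all(central == 50))
  expect_true(all(cp[["A02"]]["active", ] == 0))
  expect_error(class_profile(tracks, c(p1 = "a"), anc, spec, gb), "missing")
})

test_that("class_profile agrees with a hand recount on a synthetic world", {
  w <- generate_world(small_cfg(seed = 9))
  spec <- window_spec(2000, 500)
  cm <- setNames(ifelse(w$truth$protein_group == "active", "active",
                        "silent"), names(w$truth$protein_group))
  cp <- class_profile(w$tracks, cm, w$anchors[1:2, ], spec, w$genome)
  # recount class percentages via plain coordinate arithmetic
  for (a in 1:2) {
    pos <- w$anchors$position[a]; arm <- w$anchors$chrom[a]
    for (s in c(1, 4, 8)) {
      seg_lo <- pos - 2000 + (s - 1) * 500 + 1
      seg_hi <- seg_lo + 499
      for (cl in c("active", "silent")) {
        members <- names(cm)[cm == cl]
        bound <- vapply(members, function(nm) {
          tr <- filter_positive(w$tracks[[nm]])
          sel <- as.character(GenomicRanges::seqnames(tr)) == arm
          any(GenomicRanges::start(tr)[sel] <= seg_hi &
                GenomicRanges::end(tr)[sel] >= seg_lo)
        }, logical(1))
        expect_equal(cp[[a]][cl, paste0("s", s)],
                     round_half_up(100 * mean(bound), 1))
      }
    }
  }
})

test_that("state composition: planted RED windows, half-half splits, sums", {
  gb <- genome_build("chrA", 1e6)
  anc <- anchor_set(c("r1", "r2"), "chrA", c(3e5, 6e5), genome = gb)
  all_red <- state_map("chrA", 1, 1e6, "RED", "five_color", gb)
  sc <- state_composition(all_red, anc, genome = gb)
  red <- sc[sc$state == "RED", ]
  expect_true(all(red$n_regions == 2))
  expect_true(all(red$pct_bp == 100))

  # half RED half YELLOW around each anchor
  half <- state_map("chrA", c(1, 3e5 + 1, 6e5 + 1),
                    c(3e5, 6e5, 1e6), c("RED", "YELLOW", "RED"),
                    "five_color", gb)
  r <- state_enrichment_ratio(half, anc[1, ], 2000, "RED", "YELLOW", gb)
  expect_equal(r$share_a, 0.5)
  expect_equal(r$share_b, 0.5)
  expect_equal(r$ratio, 1)

  # shares (including unassigned) sum to 100 at every width
  gaps <- state_map("chrA", c(1, 4e5), c(2e5, 7e5), c("BLUE", "GREEN"),
                    "five_color", gb)
  sc2 <- state_composition(gaps, anc, genome = gb)
  sums <- tapply(sc2$pct_bp, sc2$width_bp, sum)
  expect_true(all(abs(sums - 100) <= 0.3))  # one-decimal rounding slack
})

test_that("ratio arithmetic and undefined denominators", {
  gb <- genome_build("chrA", 1e5)
  anc <- anchor_set("r", "chrA", 5e4, genome = gb)
  # 60% RED, 20% YELLOW, 20% BLACK within a 10 kb window
  m <- state_map("chrA", c(45001, 51001, 53001), c(51000, 53000, 55000),
                 c("RED", "YELLOW", "BLACK"), "five_color", gb)
  r <- state_enrichment_ratio(m, anc, 10000, "RED", "YELLOW", gb)
  expect_equal(r$ratio, 3)
  und <- state_enrichment_ratio(m, anc, 10000, "RED", "BLUE", gb)
  expect_false(und$defined)
  expect_true(is.na(und$ratio))
})

test_that("planted worlds show RED enrichment that tightens near the anchor", {
  w <- generate_world(sim_config(seed = 21))
  near <- state_enrichment_ratio(w$states, w$anchors, 4000, "RED", "YELLOW",
                                 w$genome)
  far <- state_enrichment_ratio(w$states, w$anchors, 10000, "RED", "YELLOW",
                                w$genome)
  expect_true(near$defined && far$defined)
  expect_gt(near$ratio, far$ratio)
  # at 2 kb the window sits wholly inside the planted 3-kb RED locus
  core <- state_enrichment_ratio(w$states, w$anchors, 2000, "RED", "YELLOW",
                                 w$genome)
  expect_gte(core$share_a, near$share_a)

  # brute-force bp tally of the RED share at 4 kb
  wins <- anchor_windows(w$anchors, 2000, w$genome)
  red <- w$states[w$states$state == "RED"]
  tot_red <- 0
  for (i in seq_along(wins)) {
    sel <- as.character(GenomicRanges::seqnames(red)) ==
      as.character(GenomicRanges::seqnames(wins))[i]
    ov <- pmin(GenomicRanges::end(red)[sel], GenomicRanges::end(wins)[i]) -
      pmax(GenomicRanges::start(red)[sel], GenomicRanges::start(wins)[i]) + 1
    tot_red <- tot_red + sum(pmax(ov, 0))
  }
  expect_equal(near$share_a, tot_red / sum(GenomicRanges::width(wins)))
})

test_that("windows clip at arm edges with a warning", {
  gb <- genome_build("chrA", 1e5)
  anc <- anchor_set("edge", "chrA", 2000, genome = gb)
  expect_warning(w <- anchor_windows(anc, 5000, gb), "clipped")
  expect_equal(GenomicRanges::start(w), 1)
})

test_that("interband border heuristic finds the bound core", {
  gb <- toy_genome()
  anc <- anchor_set("r", "chr2R", 1e6, genome = gb)
  spec <- window_spec(5000, 500)
  mk <- function(nm) binding_track("chr2R", 1e6 - 1500, 1e6 + 1500, 1, nm, gb)
  tracks <- list(a = mk("a"), b = mk("b"))
  # fragment [pos-1500, pos+1500] touches segments 7 (ends pos-1500) .. 13
  bor <- interband_borders(tracks, anc, spec, quorum = 0.5, genome = gb)
  expect_equal(bor$from_segment, 7)
  expect_equal(bor$to_segment, 13)
  none <- interband_borders(
    list(e = binding_track(character(), integer(), integer(), numeric(), "e")),
    anc, spec, genome = gb)
  expect_true(is.na(none$from_segment))
})
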