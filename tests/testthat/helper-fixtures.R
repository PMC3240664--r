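# shared fixtures and independent oracles

toy_genome <- function() genome_build(c("chr2R", "chr3L", "chr3R", "chrX"),
                                      c(2e6, 2e6, 2e6, 2e6))

# a quick small simulation config for unit tests (not the default world)
small_cfg <- function(seed = 1, n_loci = 60, ...) {
  sim_config(seed = seed,
             genome = genome_build(c("chr2R", "chr3L", "chr3R", "chrX"),
                                   c(9e5, 9e5, 9e5, 9e5)),
             n_loci = n_loci, ...)
}

# uniform random track: n fragments of length len placed uniformly
unif_track <- function(n, len, genome, name = "u", seed = NULL) {
  draw <- function() {
    al <- arm_lengths(genome)
    arm <- sample(names(al), n, TRUE, prob = al / sum(al))
    st <- floor(runif(n, 1, al[arm] - len))
    binding_track(arm, st, st + len - 1, score = 1, name, genome)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# per-bp brute force: which base pairs of [1, arm_len] are covered
brute_coverage <- function(track, arm, arm_len) {
  cov <- logical(arm_len)
  sel <- as.character(GenomicRanges::seqnames(track)) == arm
  st <- GenomicRanges::start(track)[sel]
  en <- GenomicRanges::end(track)[sel]
  for (i in seq_along(st)) cov[st[i]:en[i]] <- TRUE
  cov
}

# brute-force interval overlap (1-based closed): any shared bp
brute_overlap <- function(s1, e1, s2, e2) s1 <= e2 && s2 <= e1

# independent maximum bipartite matching size via igraph; edges found by
# plain coordinate arithmetic (outer comparisons), not the package's own
# overlap machinery
igraph_matching_size <- function(track_i, track_j) {
  ni <- length(track_i); nj <- length(track_j)
  if (ni == 0 || nj == 0) return(0L)
  ov <- outer(as.character(GenomicRanges::seqnames(track_i)),
              as.character(GenomicRanges::seqnames(track_j)), "==") &
    outer(GenomicRanges::start(track_i),
          GenomicRanges::end(track_j), "<=") &
    outer(GenomicRanges::end(track_i),
          GenomicRanges::start(track_j), ">=")
  idx <- which(ov, arr.ind = TRUE)
  if (!nrow(idx)) return(0L)
  edges <- as.vector(t(cbind(idx[, 1], ni + idx[, 2])))
  g <- igraph::make_bipartite_graph(c(rep(FALSE, ni), rep(TRUE, nj)),
                                    edges = edges)
  igraph::max_bipartite_match(g)$matching_size
}

# random small track on one arm for matching-oracle trials
random_small_track <- function(n_max, arm_len = 5000, name = "t") {
  n <- sample.int(n_max, 1)
  st <- sample.int(arm_len - 100, n, replace = TRUE)
  len <- sample(5:300, n, replace = TRUE)
  binding_track(rep("chrT", n), st, pmin(st + len, arm_len), score = 1, name)
}

# brute-force average-linkage (UPGMA) agglomeration heights
brute_upgma_heights <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq((i + 1), length(clusters))) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < bd) { bd <- d; best <- c(i, j) }
      }
    }
    heights <- c(heights, bd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# lower-tail binomial probability by exhaustive 2^13 outcome enumeration
enum_binom_lower <- function(p, m, n13 = 13) {
  stopifnot(n13 <= 16)
  outcomes <- as.matrix(expand.grid(rep(list(0:1), n13)))
  s <- rowSums(outcomes)
  w <- ifelse(s == 0, (1 - p)^n13,
              ifelse(s == n13, p^n13, p^s * (1 - p)^(n13 - s)))
  sum(w[s <= m])
}
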