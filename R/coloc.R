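#' Pairwise co-localization of binding tracks
#'
#' The similarity rate between two tracks is r = k / min(m', n'), where m'
#' and n' are the track sizes after mutual redundancy removal and k is the
#' number of overlapping fragment pairs that remain. Redundancy removal drops
#' every fragment that overlaps the partner track only through counterparts
#' already claimed by other fragments; afterwards exactly k fragments on each
#' side overlap the other side. Operationally this is a maximum matching on
#' the bipartite interval-overlap graph: k is the matching size, and each
#' reduced track keeps its matched fragments plus its fragments that overlap
#' nothing. Because the maximum-matching size is unique, k, m', n' and r do
#' not depend on tie-breaking; fragments are processed left-to-right so the
#' retained fragment identities are reproducible too.
#'
#' Tracks should already be restricted to positive scores and, per the
#' reference procedure, fragments shorter than 10 kb (see
#' [filter_positive()], [filter_max_length()]); `prepare = TRUE` applies
#' both filters.
#'
#' @name colocalization
NULL

# maximum bipartite matching via augmenting paths (Kuhn's algorithm).
# adj: list over left vertices of integer vectors of right neighbours.
# returns integer vector match_left: for each left vertex the matched right
# vertex or NA.
max_matching <- function(adj, n_right) {
  n_left <- length(adj)
  match_right <- integer(n_right)      # 0 = free
  match_left <- rep(NA_integer_, n_left)
  seen <- logical(n_right)
  try_kuhn <- function(u) {
    for (v in adj[[u]]) {
      if (!seen[v]) {
        seen[v] <<- TRUE
        if (match_right[v] == 0L || try_kuhn(match_right[v])) {
          match_right[v] <<- u
          match_left[u] <<- v
          return(TRUE)
        }
      }
    }
    FALSE
  }
  for (u in seq_len(n_left)) {
    if (length(adj[[u]])) {
      seen[] <- FALSE
      try_kuhn(u)
    }
  }
  match_left
}

overlap_adjacency <- function(track_i, track_j) {
  hits <- GenomicRanges::findOverlaps(track_i, track_j, ignore.strand = TRUE)
  adj <- vector("list", length(track_i))
  adj[] <- list(integer())
  if (length(hits)) {
    sp <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
    adj[as.integer(names(sp))] <- lapply(sp, as.integer)
  }
  adj
}

#' @rdname colocalization
#' @param track_i,track_j binding tracks (GRanges with scores)
#' @param prepare apply the positive-score and <10 kb filters first
#' @return `reduce_redundancy`: list with `reduced_i`, `reduced_j` (tracks),
#'   `k` (number of one-to-one overlapping pairs), `m_prime`, `n_prime`
#' @export
reduce_redundancy <- function(track_i, track_j, prepare = FALSE) {
  if (prepare) {
    track_i <- filter_max_length(filter_positive(track_i), 10000)
    track_j <- filter_max_length(filter_positive(track_j), 10000)
  }
  adj <- overlap_adjacency(track_i, track_j)
  ml <- max_matching(adj, length(track_j))
  deg_i <- lengths(adj) > 0
  deg_j <- logical(length(track_j))
  deg_j[unique(unlist(adj, use.names = FALSE))] <- TRUE
  keep_i <- !deg_i | !is.na(ml)
  keep_j <- !deg_j
  keep_j[ml[!is.na(ml)]] <- TRUE
  ri <- track_i[keep_i]
  rj <- track_j[keep_j]
  S4Vectors::metadata(ri)$protein <- track_protein(track_i)
  S4Vectors::metadata(rj)$protein <- track_protein(track_j)
  list(reduced_i = ri, reduced_j = rj,
       k = sum(!is.na(ml)),
       m_prime = sum(keep_i), n_prime = sum(keep_j))
}

#' @rdname colocalization
#' @return `similarity`: list with `protein_i`, `protein_j`, `m_prime`,
#'   `n_prime`, `k`, `r` (the similarity rate, 0 when both reduced tracks are
#'   empty, flagged by `degenerate = TRUE`)
#' @export
similarity <- function(track_i, track_j, prepare = FALSE) {
  red <- reduce_redundancy(track_i, track_j, prepare = prepare)
  denom <- min(red$m_prime, red$n_prime)
  degenerate <- denom == 0
  list(protein_i = track_protein(track_i),
       protein_j = track_protein(track_j),
       m_prime = red$m_prime, n_prime = red$n_prime, k = red$k,
       r = if (degenerate) 0 else red$k / denom,
       degenerate = degenerate)
}

#' @rdname colocalization
#' @param tracks named list of binding tracks (>= 2); names default to the
#'   tracks' protein names
#' @return `similarity_matrix`: symmetric matrix of r values, unit diagonal
#' @export
similarity_matrix <- function(tracks, prepare = FALSE) {
  stopifnot(length(tracks) >= 2)
  nms <- names(tracks) %||% vapply(tracks, track_protein, character(1))
  if (is.null(names(tracks))) names(tracks) <- nms
  n <- length(tracks)
  R <- diag(1, n)
  dimnames(R) <- list(nms, nms)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      R[i, j] <- R[j, i] <- similarity(tracks[[i]], tracks[[j]],
                                       prepare = prepare)$r
    }
  }
  R
}

#' @rdname colocalization
#' @param R a similarity matrix
#' @return `to_dissimilarity`: the matrix 1 - R with zero diagonal
#' @export
to_dissimilarity <- function(R) {
  stopifnot(isSymmetric(unname(R)))
  D <- 1 - R
  diag(D) <- 0
  D
}

#' Non-overlapping genome blocks
#'
#' Tiles every arm left-to-right with fixed-size blocks; the last partial
#' block of an arm is kept. At the reference scale (120 Mb, 3-kb blocks —
#' the median bound-fragment size) this yields the canonical n = 40000
#' blocks.
#'
#' @param genome a [genome_build()]
#' @param block_bp block size in bp (default 3000)
#' @return `GRanges` of blocks
#' @export
block_partition <- function(genome, block_bp = 3000) {
  stopifnot(block_bp > 0)
  grl <- GenomicRanges::tileGenome(
    GenomeInfoDb::seqlengths(genome_seqinfo(genome)),
    tilewidth = block_bp, cut.last.tile.in.chrom = TRUE)
  grl
}

#' Block 2x2 chi-square co-localization test
#'
#' Each block is scored positive for a protein when at least one positive
#' fragment overlaps it. The 2x2 table over n blocks (both, i-only, j-only,
#' neither) is tested against independence with a 1-df chi-square; the
#' expected number of co-occupied blocks under independence is
#' en = l*m/n for marginal positive-block counts l and m.
#'
#' @param track_i,track_j binding tracks (positive scores assumed; apply
#'   [filter_positive()] upstream)
#' @param blocks from [block_partition()]
#' @param correct apply Yates' continuity correction (default FALSE)
#' @return list with `l`, `m`, `n`, cells `a`,`b`,`c`,`d`, `en`, `chi2`,
#'   `p_value`, and `degenerate` (TRUE when a margin is empty or full, in
#'   which case the test is undefined and `chi2`/`p_value` are NA)
#' @export
block_test <- function(track_i, track_j, blocks, correct = FALSE) {
  pos_i <- GenomicRanges::countOverlaps(blocks, track_i,
                                        ignore.strand = TRUE) > 0
  pos_j <- GenomicRanges::countOverlaps(blocks, track_j,
                                        ignore.strand = TRUE) > 0
  n <- length(blocks)
  a <- sum(pos_i & pos_j); b <- sum(pos_i & !pos_j)
  c_ <- sum(!pos_i & pos_j); d <- n - a - b - c_
  l <- a + b; m <- a + c_
  en <- l * m / n
  degenerate <- l == 0 || m == 0 || l == n || m == n
  if (degenerate) {
    chi2 <- NA_real_; p <- NA_real_
  } else {
    obs <- c(a, b, c_, d)
    exp_ <- c(l * m, l * (n - m), (n - l) * m, (n - l) * (n - m)) / n
    dev <- abs(obs - exp_)
    if (correct) dev <- pmax(dev - 0.5, 0)
    chi2 <- sum(dev^2 / exp_)
    p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  list(protein_i = track_protein(track_i), protein_j = track_protein(track_j),
       l = l, m = m, n = n, a = a, b = b, c = c_, d = d,
       en = en, chi2 = chi2, p_value = p, degenerate = degenerate)
}

#' Pairwise co-localization report
#'
#' Runs [similarity()] and [block_test()] over all track pairs.
#'
#' @param tracks named list of binding tracks
#' @param genome a [genome_build()]
#' @param block_bp block size for the contingency test
#' @param prepare apply positive/<10 kb filters for the similarity statistic
#' @return data.frame, one row per unordered pair: k, m', n', r, l, m, en,
#'   chi2, p_value
#' @export
coloc_report <- function(tracks, genome, block_bp = 3000, prepare = TRUE) {
  nms <- names(tracks) %||% vapply(tracks, track_protein, character(1))
  blocks <- block_partition(genome, block_bp)
  prepped <- lapply(tracks, function(t) {
    if (prepare) filter_max_length(filter_positive(t), 10000) else t
  })
  rows <- list()
  for (i in seq_len(length(tracks) - 1)) {
    for (j in seq((i + 1), length(tracks))) {
      s <- similarity(prepped[[i]], prepped[[j]])
      bt <- block_test(prepped[[i]], prepped[[j]], blocks)
      rows[[length(rows) + 1]] <- data.frame(
        protein_i = nms[i], protein_j = nms[j],
        k = s$k, m_prime = s$m_prime, n_prime = s$n_prime, r = s$r,
        l = bt$l, m = bt$m, n = bt$n, en = bt$en,
        chi2 = bt$chi2, p_value = bt$p_value,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
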