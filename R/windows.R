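#' Window specification for anchored profiles
#'
#' Windows are centered on anchor positions: a 10-kb window means 5 kb to
#' each side, split into 0.5-kb segments (20 per window in the reference
#' layout). The half width must be a multiple of the segment size.
#'
#' @param half_width_bp half window width in bp (5000 for the 10-kb window,
#'   2000 for the 4-kb one)
#' @param segment_bp segment size in bp (default 500)
#' @return a `window_spec` list with `half_width_bp`, `segment_bp`,
#'   `n_segments`
#' @export
window_spec <- function(half_width_bp = 5000, segment_bp = 500) {
  stopifnot(half_width_bp > 0, segment_bp > 0,
            half_width_bp %% segment_bp == 0)
  structure(list(half_width_bp = as.integer(half_width_bp),
                 segment_bp = as.integer(segment_bp),
                 n_segments = as.integer(2 * half_width_bp / segment_bp)),
            class = "window_spec")
}

#' Windows and segments around anchors
#'
#' `anchor_windows` builds one window per anchor (`[pos - hw, pos + hw)`,
#' width `2*hw`); `anchor_segments` splits each window into its segments,
#' numbered 1..n left to right along the genome. Windows running off an arm
#' edge are clipped with a warning; composition shares are then computed
#' over the covered base pairs only.
#'
#' @param anchors an [anchor_set()]
#' @param half_width_bp half window width in bp (or pass `spec`)
#' @param genome optional [genome_build()] used for edge clipping
#' @param spec a [window_spec()] (for `anchor_segments`)
#' @return `GRanges` of windows (with `region_name`), or of segments (with
#'   `region_name`, `segment`)
#' @export
anchor_windows <- function(anchors, half_width_bp, genome = NULL) {
  st <- anchors$position - half_width_bp + 1
  en <- anchors$position + half_width_bp
  if (!is.null(genome)) {
    al <- arm_lengths(genome)
    lim <- al[anchors$chrom]
    clipped <- st < 1 | en > lim
    if (any(clipped)) {
      warning("window(s) clipped at arm edge: ",
              paste(anchors$region_name[clipped], collapse = ", "))
      st <- pmax(st, 1)
      en <- pmin(en, lim)
    }
  } else if (any(st < 1)) {
    warning("window(s) clipped at arm start")
    st <- pmax(st, 1)
  }
  GenomicRanges::GRanges(anchors$chrom, IRanges::IRanges(st, en),
                         region_name = anchors$region_name)
}

#' @rdname anchor_windows
#' @export
anchor_segments <- function(anchors, spec, genome = NULL) {
  hw <- spec$half_width_bp; seg <- spec$segment_bp
  n <- spec$n_segments
  idx <- rep(seq_len(nrow(anchors)), each = n)
  s <- rep(seq_len(n), times = nrow(anchors))
  st <- anchors$position[idx] - hw + (s - 1) * seg + 1
  en <- st + seg - 1
  keep <- rep(TRUE, length(st))
  if (!is.null(genome)) {
    al <- arm_lengths(genome)
    lim <- al[anchors$chrom[idx]]
    out_of_arm <- en < 1 | st > lim
    if (any(st < 1 | en > lim)) {
      warning("segment(s) clipped at arm edge")
      st <- pmax(st, 1); en <- pmin(en, lim)
      keep <- !out_of_arm & st <= en
    }
  }
  GenomicRanges::GRanges(anchors$chrom[idx][keep],
                         IRanges::IRanges(st[keep], en[keep]),
                         region_name = anchors$region_name[idx][keep],
                         segment = s[keep])
}

#' Fraction of anchor regions bound by a track
#'
#' A region counts as bound when at least one positive-score fragment shares
#' at least one bp with its window (single-hit counting). Returns the percent
#' of regions bound, half-up rounded to one decimal as reported in the
#' reference figures.
#'
#' @param track a binding track
#' @param anchors an [anchor_set()]
#' @param half_width_bp half window width in bp
#' @param genome optional [genome_build()] for edge clipping
#' @return percent in [0, 100]
#' @export
bound_fraction <- function(track, anchors, half_width_bp, genome = NULL) {
  stopifnot(nrow(anchors) >= 1)
  wins <- anchor_windows(anchors, half_width_bp, genome)
  pos <- filter_positive(track)
  hit <- GenomicRanges::countOverlaps(wins, pos, ignore.strand = TRUE) > 0
  round_half_up(100 * sum(hit) / nrow(anchors), 1)
}

#' Per-segment binding profile at one anchor
#'
#' @param track a binding track
#' @param anchor a single-row [anchor_set()]
#' @param spec a [window_spec()]
#' @param genome optional [genome_build()]
#' @return logical vector of length `spec$n_segments`: segment overlapped by
#'   a positive fragment
#' @export
segment_profile <- function(track, anchor, spec, genome = NULL) {
  stopifnot(nrow(anchor) == 1)
  segs <- anchor_segments(anchor, spec, genome)
  pos <- filter_positive(track)
  out <- logical(spec$n_segments)
  out[segs$segment] <-
    GenomicRanges::countOverlaps(segs, pos, ignore.strand = TRUE) > 0
  out
}

#' Segment heat-map matrix over all anchors
#'
#' Rows are tracks, columns the window segments left to right; a cell is the
#' percent of anchor regions whose segment is overlapped by at least one
#' positive fragment of the track.
#'
#' @param tracks named list of binding tracks
#' @param anchors an [anchor_set()]
#' @param spec a [window_spec()]
#' @param genome optional [genome_build()]
#' @return numeric matrix (tracks x segments), percents to one decimal
#' @export
heatmap_matrix <- function(tracks, anchors, spec, genome = NULL) {
  nms <- names(tracks) %||% vapply(tracks, track_protein, character(1))
  segs <- anchor_segments(anchors, spec, genome)
  M <- matrix(0, nrow = length(tracks), ncol = spec$n_segments,
              dimnames = list(nms, paste0("s", seq_len(spec$n_segments))))
  for (i in seq_along(tracks)) {
    pos <- filter_positive(tracks[[i]])
    hit <- GenomicRanges::countOverlaps(segs, pos, ignore.strand = TRUE) > 0
    bound_per_seg <- tapply(hit, segs$segment, sum)
    M[i, as.integer(names(bound_per_seg))] <-
      round_half_up(100 * as.numeric(bound_per_seg) / nrow(anchors), 1)
  }
  M
}

#' Per-region class profile
#'
#' For each anchor and each 0.5-kb segment, the percent of a protein class's
#' tracks that bind the segment (the combined per-class profile of the
#' reference figures).
#'
#' @param tracks named list of binding tracks
#' @param class_map named character vector protein -> class; every track
#'   must be present
#' @param anchors an [anchor_set()]
#' @param spec a [window_spec()]
#' @param genome optional [genome_build()]
#' @return named list (one per anchor region) of matrices class x segment
#' @export
class_profile <- function(tracks, class_map, anchors, spec, genome = NULL) {
  nms <- names(tracks) %||% vapply(tracks, track_protein, character(1))
  missing <- setdiff(nms, names(class_map))
  if (length(missing)) stop("protein(s) missing from class_map: ",
                            paste(missing, collapse = ", "))
  classes <- unique(unname(class_map[nms]))
  if (!length(classes)) stop("empty class map")
  bound <- array(FALSE, dim = c(length(tracks), nrow(anchors),
                                spec$n_segments))
  for (i in seq_along(tracks)) {
    for (a in seq_len(nrow(anchors))) {
      bound[i, a, ] <- segment_profile(tracks[[i]],
                                       anchors[a, , drop = FALSE],
                                       spec, genome)
    }
  }
  out <- list()
  for (a in seq_len(nrow(anchors))) {
    M <- matrix(NA_real_, nrow = length(classes), ncol = spec$n_segments,
                dimnames = list(classes,
                                paste0("s", seq_len(spec$n_segments))))
    for (cl in classes) {
      members <- which(class_map[nms] == cl)
      frac <- colMeans(matrix(bound[members, a, ], nrow = length(members)))
      M[cl, ] <- round_half_up(100 * frac, 1)
    }
    out[[anchors$region_name[a]]] <- M
  }
  out
}

# bp of each state within each window; returns matrix windows x states
# (including "unassigned"), entries in bp
state_bp_by_window <- function(map, wins) {
  states <- c(state_alphabet(S4Vectors::metadata(map)$scheme %||%
                               "five_color"), "unassigned")
  M <- matrix(0, nrow = length(wins), ncol = length(states),
              dimnames = list(wins$region_name, states))
  hits <- GenomicRanges::findOverlaps(wins, map, ignore.strand = TRUE)
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    ov <- pmin(GenomicRanges::end(wins)[q], GenomicRanges::end(map)[s]) -
      pmax(GenomicRanges::start(wins)[q], GenomicRanges::start(map)[s]) + 1
    for (lev in setdiff(states, "unassigned")) {
      sel <- map$state[s] == lev
      if (any(sel)) {
        tot <- tapply(ov[sel], q[sel], sum)
        M[as.integer(names(tot)), lev] <- as.numeric(tot)
      }
    }
  }
  M[, "unassigned"] <- GenomicRanges::width(wins) - rowSums(M)
  M
}

#' Chromatin-state composition around anchors
#'
#' For each centered window width, reports per state (a) the number of
#' anchor regions whose window contains at least `min_bp` of the state and
#' (b) the percent of window base pairs in the state, pooled over anchors.
#' Uncovered base pairs are reported as state `"unassigned"`.
#'
#' @param map a [state_map()]
#' @param anchors an [anchor_set()]
#' @param widths_bp vector of full window widths in bp (default 1..10 kb)
#' @param genome optional [genome_build()]
#' @param min_bp minimum bp of a state inside the window for the region to
#'   count as associated (default 1)
#' @return data.frame: width_bp, state, n_regions, pct_bp
#' @export
state_composition <- function(map, anchors, widths_bp = seq(1000, 10000, 1000),
                              genome = NULL, min_bp = 1) {
  rows <- list()
  for (w in widths_bp) {
    wins <- anchor_windows(anchors, w / 2, genome)
    M <- state_bp_by_window(map, wins)
    tot <- sum(GenomicRanges::width(wins))
    for (st in colnames(M)) {
      rows[[length(rows) + 1]] <- data.frame(
        width_bp = w, state = st,
        n_regions = sum(M[, st] >= min_bp),
        pct_bp = round_half_up(100 * sum(M[, st]) / tot, 1),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Ratio of two states' bp shares around anchors
#'
#' Pooled over all anchor windows of the given width. When the denominator
#' state has zero share the ratio is undefined: `defined = FALSE` and
#' `ratio = NA` (no error).
#'
#' @param map a [state_map()]
#' @param anchors an [anchor_set()]
#' @param width_bp full window width in bp
#' @param state_a,state_b state labels
#' @param genome optional [genome_build()]
#' @return list with `ratio`, `share_a`, `share_b`, `defined`
#' @export
state_enrichment_ratio <- function(map, anchors, width_bp,
                                   state_a, state_b, genome = NULL) {
  wins <- anchor_windows(anchors, width_bp / 2, genome)
  M <- state_bp_by_window(map, wins)
  tot <- sum(GenomicRanges::width(wins))
  sa <- sum(M[, state_a]) / tot
  sb <- sum(M[, state_b]) / tot
  list(ratio = if (sb > 0) sa / sb else NA_real_,
       share_a = sa, share_b = sb, defined = sb > 0)
}

#' Heuristic interband borders from segment profiles
#'
#' The reference figures draw interband borders by eye; this helper emits
#' the maximal run of consecutive segments where at least a quorum of the
#' given tracks is bound. Explicitly heuristic.
#'
#' @param tracks named list of binding tracks (typically the active class)
#' @param anchor single-row [anchor_set()]
#' @param spec a [window_spec()]
#' @param quorum fraction of tracks that must be bound (default 0.5)
#' @param genome optional [genome_build()]
#' @return list with `from_segment`, `to_segment` (NA when no segment
#'   reaches quorum)
#' @export
interband_borders <- function(tracks, anchor, spec, quorum = 0.5,
                              genome = NULL) {
  prof <- vapply(tracks, segment_profile, logical(spec$n_segments),
                 anchor = anchor, spec = spec, genome = genome)
  ok <- rowMeans(prof) >= quorum
  if (!any(ok)) return(list(from_segment = NA_integer_,
                            to_segment = NA_integer_))
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  best <- which(runs$values)[which.max(runs$lengths[runs$values])]
  list(from_segment = starts[best], to_segment = ends[best])
}
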