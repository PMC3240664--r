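#' Simulation configuration
#'
#' The generator emulates the statistical structure of the reference data at
#' one tenth of its genomic scale: a ~12 Mb four-arm genome carrying planted
#' interband-like loci (default 350, scaling the estimated ~3500
#' genome-wide); a group of "active" open-chromatin proteins whose tracks
#' place a fragment over each locus with a per-protein detection
#' probability, plus uniform background fragments; "silent" Polycomb-group
#' and insulator proteins whose fragments avoid loci; anchors at 13 sampled
#' loci with the reference 1:3:4:5 arm distribution and +/- 500 bp jitter;
#' and a chromatin-state map painting a RED-analog segment over each locus.
#' Fragment lengths are drawn from a log-normal truncated to [0.2, 11] kb
#' whose defaults put well over 70% of fragments into the 1-3 kb class, the
#' dominant class of the reference length table.
#'
#' @param seed integer master seed; per-track substreams are derived from it
#'   and the protein name, so adding a track never reshuffles the others
#' @param genome a [genome_build()]; default four arms totalling 12 Mb
#' @param n_loci planted loci (default 350)
#' @param active_proteins named numeric vector: active protein ->
#'   detection probability in [0, 1]
#' @param silent_proteins named character vector: silent protein -> group
#'   (`"silent_pcg"` or `"silent_insulator"`)
#' @param background_rate background fragments per Mb per track (default 20)
#' @param silent_rate fragments per Mb for silent tracks (default 40)
#' @param frag_meanlog,frag_sdlog log-normal fragment-length parameters
#'   (default log(1800), 0.45)
#' @param frag_min_bp,frag_max_bp truncation bounds (default 200, 11000)
#' @param anchor_jitter_bp anchor offset from locus center, uniform in
#'   +/- this (default 500)
#' @param n_anchors number of anchors (default 13)
#' @param anchor_arm_counts per-arm anchor counts (default
#'   chr2R:1, chr3L:3, chr3R:4, chrX:5)
#' @param locus_halfwidth_bp half width of the locus window used for state
#'   painting and silent-track exclusion (default 1500, i.e. 3-kb loci, the
#'   median reference fragment class)
#' @param min_locus_spacing_bp minimum center-to-center spacing (default
#'   12000, above the maximum fragment length so loci stay separable)
#' @param state_scheme `"five_color"` or `"nine_state"`
#' @param decoy_nonpositive_frac fraction of background fragments given a
#'   non-positive score, exercising the positive-score filter (default 0.1)
#' @param silent_disjoint keep silent-track fragments off the loci
#'   (default TRUE)
#' @return a `sim_config` list
#' @export
sim_config <- function(seed = 1,
                       genome = genome_build(
                         c("chr2R", "chr3L", "chr3R", "chrX"),
                         c(2700000, 3000000, 3300000, 3000000)),
                       n_loci = 350,
                       active_proteins = c(CHRIZ = 0.95, RNApolII = 0.95,
                                           `BEAF-32` = 0.95, WDS = 0.95,
                                           ORC2 = 0.95, TRX = 0.95),
                       silent_proteins = c(PC = "silent_pcg",
                                           `E(Z)` = "silent_pcg",
                                           dRING = "silent_pcg",
                                           `SU(HW)` = "silent_insulator",
                                           `MOD(MDG4)` = "silent_insulator",
                                           CTCF = "silent_insulator"),
                       background_rate = 20, silent_rate = 40,
                       frag_meanlog = log(1800), frag_sdlog = 0.45,
                       frag_min_bp = 200, frag_max_bp = 11000,
                       anchor_jitter_bp = 500, n_anchors = 13,
                       anchor_arm_counts = c(chr2R = 1, chr3L = 3,
                                             chr3R = 4, chrX = 5),
                       locus_halfwidth_bp = 1500,
                       min_locus_spacing_bp = 12000,
                       state_scheme = c("five_color", "nine_state"),
                       decoy_nonpositive_frac = 0.1,
                       silent_disjoint = TRUE) {
  state_scheme <- match.arg(state_scheme)
  stopifnot(all(active_proteins >= 0), all(active_proteins <= 1),
            n_loci >= 1, anchor_jitter_bp >= 0,
            sum(anchor_arm_counts) == n_anchors,
            all(names(anchor_arm_counts) %in% genome$arm))
  structure(list(seed = as.integer(seed), genome = genome, n_loci = n_loci,
                 active_proteins = active_proteins,
                 silent_proteins = silent_proteins,
                 background_rate = background_rate, silent_rate = silent_rate,
                 frag_meanlog = frag_meanlog, frag_sdlog = frag_sdlog,
                 frag_min_bp = frag_min_bp, frag_max_bp = frag_max_bp,
                 anchor_jitter_bp = anchor_jitter_bp, n_anchors = n_anchors,
                 anchor_arm_counts = anchor_arm_counts,
                 locus_halfwidth_bp = locus_halfwidth_bp,
                 min_locus_spacing_bp = min_locus_spacing_bp,
                 state_scheme = state_scheme,
                 decoy_nonpositive_frac = decoy_nonpositive_frac,
                 silent_disjoint = silent_disjoint),
            class = "sim_config")
}

# truncated log-normal fragment lengths
draw_lengths <- function(n, cfg) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rlnorm(max(n, 10), meanlog = cfg$frag_meanlog, sdlog = cfg$frag_sdlog)
    out <- c(out, x[x >= cfg$frag_min_bp & x <= cfg$frag_max_bp])
  }
  round(out[seq_len(n)])
}

# place locus centers: per-arm counts ~ arm length (largest remainder),
# bumped so every arm with a required anchor count can host it; positions
# uniform with minimum spacing by rejection
place_loci <- function(cfg) {
  al <- arm_lengths(cfg$genome)
  margin <- cfg$min_locus_spacing_bp
  raw <- cfg$n_loci * al / sum(al)
  counts <- floor(raw)
  rem <- cfg$n_loci - sum(counts)
  if (rem > 0) {
    up <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[up] <- counts[up] + 1
  }
  need <- cfg$anchor_arm_counts
  counts[names(need)] <- pmax(counts[names(need)], need)
  chroms <- character(0); pos <- numeric(0)
  for (arm in names(counts)) {
    n <- counts[[arm]]
    if (n == 0) next
    lo <- margin; hi <- al[[arm]] - margin
    if (hi - lo < n * cfg$min_locus_spacing_bp) {
      stop("infeasible packing: ", n, " loci do not fit on ", arm)
    }
    p <- numeric(0)
    tries <- 0
    while (length(p) < n) {
      cand <- floor(runif(1, lo, hi + 1))
      if (!length(p) || min(abs(p - cand)) >= cfg$min_locus_spacing_bp) {
        p <- c(p, cand)
      }
      tries <- tries + 1
      if (tries > 10000 * n) stop("infeasible packing on ", arm)
    }
    chroms <- c(chroms, rep(arm, n)); pos <- c(pos, sort(p))
  }
  GenomicRanges::GRanges(chroms,
                         IRanges::IRanges(pos - cfg$locus_halfwidth_bp + 1,
                                          pos + cfg$locus_halfwidth_bp),
                         center = pos,
                         locus_id = paste0("L", seq_along(pos)))
}

# uniform background fragments across the genome; optionally avoiding loci
draw_background <- function(n, cfg, avoid = NULL) {
  al <- arm_lengths(cfg$genome)
  if (n == 0) {
    return(GenomicRanges::GRanges())
  }
  out <- GenomicRanges::GRanges()
  while (length(out) < n) {
    k <- n - length(out)
    arm <- sample(names(al), k, replace = TRUE, prob = al / sum(al))
    len <- draw_lengths(k, cfg)
    st <- floor(runif(k, 1, al[arm] - len + 2))
    gr <- GenomicRanges::GRanges(arm, IRanges::IRanges(st, st + len - 1))
    if (!is.null(avoid)) {
      gr <- gr[GenomicRanges::countOverlaps(gr, avoid,
                                            ignore.strand = TRUE) == 0]
    }
    out <- c(out, gr)
  }
  out[seq_len(n)]
}

make_track <- function(cfg, name, group, loci) {
  with_seed(derive_seed(cfg$seed, name), {
    al <- arm_lengths(cfg$genome)
    mb <- sum(al) / 1e6
    if (group == "active") {
      detect <- runif(length(loci)) < cfg$active_proteins[[name]]
      centers <- loci$center[detect] +
        round(runif(sum(detect), -cfg$anchor_jitter_bp, cfg$anchor_jitter_bp))
      len <- draw_lengths(sum(detect), cfg)
      st <- pmax(1, centers - floor(len / 2))
      en <- pmin(al[as.character(GenomicRanges::seqnames(loci))[detect]],
                 st + len - 1)
      on_locus <- GenomicRanges::GRanges(
        as.character(GenomicRanges::seqnames(loci))[detect],
        IRanges::IRanges(st, en))
      bg <- draw_background(rpois(1, cfg$background_rate * mb), cfg)
      gr <- c(on_locus, bg)
      origin <- c(loci$locus_id[detect], rep(NA_character_, length(bg)))
    } else {
      avoid <- if (cfg$silent_disjoint) loci else NULL
      gr <- draw_background(rpois(1, cfg$silent_rate * mb), cfg, avoid = avoid)
      detect <- logical(length(loci))
      origin <- rep(NA_character_, length(gr))
    }
    score <- round(rexp(length(gr), rate = 0.5) + 0.01, 3)
    n_bg <- sum(is.na(origin))
    if (n_bg > 0 && cfg$decoy_nonpositive_frac > 0) {
      bg_idx <- which(is.na(origin))
      decoy <- bg_idx[runif(n_bg) < cfg$decoy_nonpositive_frac]
      score[decoy] <- -round(rexp(length(decoy), rate = 0.5), 3)
    }
    tr <- binding_track(as.character(GenomicRanges::seqnames(gr)),
                        GenomicRanges::start(gr), GenomicRanges::end(gr),
                        score, name, cfg$genome)
    list(track = tr, detected = detect)
  })
}

paint_states <- function(cfg, loci) {
  with_seed(derive_seed(cfg$seed, "states"), {
    al <- arm_lengths(cfg$genome)
    planted <- if (cfg$state_scheme == "five_color") "RED" else "1"
    others <- setdiff(state_alphabet(cfg$state_scheme), planted)
    wts <- if (cfg$state_scheme == "five_color") {
      c(YELLOW = 0.20, BLUE = 0.15, GREEN = 0.15, BLACK = 0.50)
    } else setNames(rep(1 / length(others), length(others)), others)
    chroms <- character(0); st <- integer(0); en <- integer(0)
    lab <- character(0)
    for (arm in names(al)) {
      li <- loci[as.character(GenomicRanges::seqnames(loci)) == arm]
      bounds <- c(0, as.vector(rbind(GenomicRanges::start(li) - 1,
                                     GenomicRanges::end(li))), al[[arm]])
      if (length(li)) {
        chroms <- c(chroms, rep(arm, length(li)))
        st <- c(st, GenomicRanges::start(li)); en <- c(en,
                                                       GenomicRanges::end(li))
        lab <- c(lab, rep(planted, length(li)))
      }
      gap_st <- bounds[seq(1, length(bounds) - 1, by = 2)] + 1
      gap_en <- bounds[seq(2, length(bounds), by = 2)]
      for (g in seq_along(gap_st)) {
        a <- gap_st[g]; b <- gap_en[g]
        if (b < a) next
        while (a <= b) {
          seg_len <- max(1000, round(rexp(1, 1 / 8000)))
          e <- min(b, a + seg_len - 1)
          chroms <- c(chroms, arm); st <- c(st, a); en <- c(en, e)
          lab <- c(lab, sample(names(wts), 1, prob = wts))
          a <- e + 1
        }
      }
    }
    state_map(chroms, st, en, lab, cfg$state_scheme, cfg$genome)
  })
}

#' Generate a synthetic world
#'
#' Deterministic given the config's seed. Returns the genome, the ground
#' truth (planted loci, protein grouping, per-locus detection roster), one
#' binding track per protein, an anchor set over 13 sampled loci, and a
#' chromatin-state map with the planted state over each locus.
#'
#' @param cfg a [sim_config()]
#' @return list with `genome`, `truth`, `tracks`, `anchors`, `states`, `cfg`
#' @export
generate_world <- function(cfg = sim_config()) {
  loci <- with_seed(derive_seed(cfg$seed, "loci"), place_loci(cfg))
  groups <- c(setNames(rep("active", length(cfg$active_proteins)),
                       names(cfg$active_proteins)),
              cfg$silent_proteins)
  tracks <- list(); roster <- list()
  for (name in names(groups)) {
    res <- make_track(cfg, name, if (groups[[name]] == "active") "active"
                      else "silent", loci)
    tracks[[name]] <- res$track
    if (groups[[name]] == "active") roster[[name]] <- res$detected
  }
  anchors <- with_seed(derive_seed(cfg$seed, "anchors"), {
    sel <- integer(0)
    for (arm in names(cfg$anchor_arm_counts)) {
      cand <- which(as.character(GenomicRanges::seqnames(loci)) == arm)
      sel <- c(sel, sample(cand, cfg$anchor_arm_counts[[arm]]))
    }
    sel <- sort(sel)
    pos <- loci$center[sel] +
      round(runif(length(sel), -cfg$anchor_jitter_bp, cfg$anchor_jitter_bp))
    anchor_set(sprintf("IB%02d", seq_along(sel)),
               as.character(GenomicRanges::seqnames(loci))[sel], pos,
               note = loci$locus_id[sel], genome = cfg$genome)
  })
  states <- paint_states(cfg, loci)
  truth <- list(loci = loci, protein_group = groups,
                roster = do.call(cbind, roster))
  list(genome = cfg$genome, truth = truth, tracks = tracks,
       anchors = anchors, states = states, cfg = cfg)
}

#' Generate a structureless null world
#'
#' Same shape as [generate_world()] but with no planted loci: every track is
#' uniform background (expected fragment counts matched to the structured
#' world), anchors are placed uniformly within arms at the configured
#' per-arm counts, and the state map is painted without a planted state.
#' Used to calibrate the enrichment machinery.
#'
#' @param cfg a [sim_config()]
#' @return list with `genome`, `truth`, `tracks`, `anchors`, `states`, `cfg`
#' @export
null_world <- function(cfg = sim_config()) {
  al <- arm_lengths(cfg$genome)
  mb <- sum(al) / 1e6
  groups <- c(setNames(rep("active", length(cfg$active_proteins)),
                       names(cfg$active_proteins)),
              cfg$silent_proteins)
  tracks <- list()
  for (name in names(groups)) {
    tracks[[name]] <- with_seed(derive_seed(cfg$seed, paste0("null_", name)), {
      n <- if (groups[[name]] == "active") {
        rpois(1, cfg$n_loci * cfg$active_proteins[[name]] +
                cfg$background_rate * mb)
      } else rpois(1, cfg$silent_rate * mb)
      gr <- draw_background(n, cfg)
      score <- round(rexp(n, rate = 0.5) + 0.01, 3)
      decoy <- runif(n) < cfg$decoy_nonpositive_frac
      score[decoy] <- -round(rexp(sum(decoy), rate = 0.5), 3)
      binding_track(as.character(GenomicRanges::seqnames(gr)),
                    GenomicRanges::start(gr), GenomicRanges::end(gr),
                    score, name, cfg$genome)
    })
  }
  anchors <- with_seed(derive_seed(cfg$seed, "null_anchors"), {
    chrom <- rep(names(cfg$anchor_arm_counts), cfg$anchor_arm_counts)
    pad <- 5000
    pos <- floor(runif(length(chrom), pad + 1, al[chrom] - pad))
    ord <- order(chrom, pos)
    anchor_set(sprintf("RND%02d", seq_along(chrom)), chrom[ord], pos[ord],
               genome = cfg$genome)
  })
  empty_loci <- GenomicRanges::GRanges()
  S4Vectors::mcols(empty_loci) <- S4Vectors::DataFrame(
    center = numeric(0), locus_id = character(0))
  states <- paint_states(cfg, empty_loci)
  truth <- list(loci = empty_loci, protein_group = groups, roster = NULL)
  list(genome = cfg$genome, truth = truth, tracks = tracks,
       anchors = anchors, states = states, cfg = cfg)
}

#' Write a world's artifacts to a directory
#'
#' Emits genome.tsv, anchors.tsv, states.bed, one BED per protein track and
#' truth.json (protein groups and locus coordinates). Plain text only.
#'
#' @param world from [generate_world()] or [null_world()]
#' @param outdir output directory (created if needed)
#' @return named character vector of written paths
#' @export
write_world <- function(world, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(outdir, "genome.tsv"),
             anchors = file.path(outdir, "anchors.tsv"),
             states = file.path(outdir, "states.bed"),
             truth = file.path(outdir, "truth.json"))
  write_genome_tsv(world$genome, paths[["genome"]])
  write_anchor_table(world$anchors, paths[["anchors"]])
  write_state_map(world$states, paths[["states"]])
  loci <- world$truth$loci
  jsonlite::write_json(
    list(protein_group = as.list(world$truth$protein_group),
         loci = data.frame(
           locus_id = loci$locus_id,
           chrom = as.character(GenomicRanges::seqnames(loci)),
           start = GenomicRanges::start(loci),
           end = GenomicRanges::end(loci))),
    paths[["truth"]], auto_unbox = TRUE)
  for (name in names(world$tracks)) {
    fn <- file.path(outdir, paste0("track_", gsub("[^A-Za-z0-9._-]", "_",
                                                  name), ".bed"))
    write_bed(world$tracks[[name]], fn)
    paths[[paste0("track_", name)]] <- fn
  }
  paths
}
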