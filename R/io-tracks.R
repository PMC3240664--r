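#' Construct a binding track
#'
#' A binding track is the set of genomic fragments reported as significantly
#' bound by one protein, each carrying a score. It is represented as a
#' [GenomicRanges::GRanges] with a numeric `score` metadata column (NA when
#' the source file had no score) and the protein name stored in
#' `metadata(track)$protein`. Tracks are kept sorted by (arm, start); they may
#' contain overlapping fragments — [merged_view()] gives the reduced union.
#'
#' @param chrom,start,end vectors of arm name and 1-based closed coordinates
#' @param score numeric scores, NA allowed
#' @param protein protein name
#' @param genome optional [genome_build()]; when given, fragments must lie
#'   within arm bounds
#' @return a `GRanges` binding track
#' @export
binding_track <- function(chrom, start, end, score = NA_real_, protein,
                          genome = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = as.integer(start), end = as.integer(end)),
    score = as.numeric(score))
  if (!is.null(genome)) {
    al <- arm_lengths(genome)
    bad <- !(as.character(GenomicRanges::seqnames(gr)) %in% names(al))
    if (any(bad)) stop("fragments on unknown arms: ",
                       paste(unique(as.character(GenomicRanges::seqnames(gr))[bad]),
                             collapse = ", "))
    over <- GenomicRanges::end(gr) > al[as.character(GenomicRanges::seqnames(gr))]
    if (any(over)) stop("fragment beyond arm end")
  }
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  S4Vectors::metadata(gr)$protein <- as.character(protein)
  gr
}

#' @rdname binding_track
#' @param track a binding track
#' @export
track_protein <- function(track) S4Vectors::metadata(track)$protein %||% NA_character_

#' @rdname binding_track
#' @export
merged_view <- function(track) {
  out <- GenomicRanges::reduce(track, ignore.strand = TRUE)
  S4Vectors::metadata(out)$protein <- track_protein(track)
  out
}

#' Read a binding track from a GFF file
#'
#' Accepts GFF version 2 or 3; the body is the standard 9 tab-separated
#' columns, with 1-based inclusive coordinates and `"."` for a missing score.
#' Comment (`#`) and blank lines are ignored.
#'
#' @param path GFF file
#' @param protein protein name to attach to the track
#' @param genome optional [genome_build()] used to police arm names
#' @param on_unknown what to do with features on arms absent from `genome`:
#'   `"skip"` (drop with one warning, the default — the analysis concerns the
#'   euchromatic arms) or `"fail"`
#' @return a binding track ([binding_track()])
#' @export
read_track_gff <- function(path, protein,
                           genome = NULL, on_unknown = c("skip", "fail")) {
  on_unknown <- match.arg(on_unknown)
  lines <- readLines(path)
  body_idx <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(body_idx)) {
    return(binding_track(character(), integer(), integer(), numeric(), protein))
  }
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8)) {
    stop(sprintf("malformed GFF line %d in %s: expected >= 8 tab-separated fields, got %d",
                 body_idx[which(nf < 8)[1]], path, min(nf)))
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(start) | is.na(end) | start > end | start < 1)
  if (length(bad)) {
    stop(sprintf("malformed GFF line %d in %s: bad coordinates '%s'..'%s'",
                 body_idx[bad[1]], path, m[bad[1], 4], m[bad[1], 5]))
  }
  score <- suppressWarnings(as.numeric(ifelse(m[, 6] == ".", NA, m[, 6])))
  chrom <- m[, 1]
  if (!is.null(genome)) {
    unknown <- !(chrom %in% genome$arm)
    if (any(unknown)) {
      if (on_unknown == "fail") {
        stop("unknown chromosome(s) in ", path, ": ",
             paste(unique(chrom[unknown]), collapse = ", "))
      }
      warning(sprintf("%s: skipping %d feature(s) on unknown chromosome(s) %s",
                      path, sum(unknown),
                      paste(unique(chrom[unknown]), collapse = ", ")))
      keep <- !unknown
      chrom <- chrom[keep]; start <- start[keep]; end <- end[keep]
      score <- score[keep]
    }
  }
  binding_track(chrom, start, end, score, protein, genome)
}

#' Write a track (or plain intervals) to BED, and read it back
#'
#' BED uses 0-based half-open coordinates; the internal representation is
#' 1-based closed, so `start` is shifted by one on the way out and back in.
#' Scores are written verbatim in column 5 (NA as 0 with name column flag
#' `"."`). Round-tripping preserves coordinates exactly.
#'
#' @param track a binding track or any `GRanges`
#' @param path output BED path
#' @return `write_bed` returns `path` invisibly; `read_track_bed` a track
#' @export
write_bed <- function(track, path) {
  sc <- track$score
  if (is.null(sc)) sc <- rep(NA_real_, length(track))
  nm <- track$name
  if (is.null(nm)) {
    p <- track_protein(track)
    nm <- if (is.na(p)) rep(".", length(track)) else
      sprintf("%s_%d", p, seq_along(track))
  }
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(track)),
                   start = GenomicRanges::start(track) - 1L,
                   end = GenomicRanges::end(track),
                   name = nm,
                   score = ifelse(is.na(sc), ".", format(sc, trim = TRUE)))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @inheritParams read_track_gff
#' @export
read_track_bed <- function(path, protein, genome = NULL) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  comment.char = "#")
  if (!nrow(x)) {
    return(binding_track(character(), integer(), integer(), numeric(), protein))
  }
  score <- if (ncol(x) >= 5) {
    suppressWarnings(as.numeric(ifelse(x[[5]] == ".", NA, x[[5]])))
  } else rep(NA_real_, nrow(x))
  binding_track(x[[1]], as.integer(x[[2]]) + 1L, as.integer(x[[3]]),
                score, protein, genome)
}

#' Positive-score filter
#'
#' Keeps fragments whose score is present and strictly positive — the
#' inclusion rule used everywhere downstream ("positive fragments"). A
#' missing score counts as non-positive.
#'
#' @param track a binding track
#' @return the filtered track
#' @export
filter_positive <- function(track) {
  sc <- track$score
  if (is.null(sc)) sc <- rep(NA_real_, length(track))
  out <- track[!is.na(sc) & sc > 0]
  S4Vectors::metadata(out)$protein <- track_protein(track)
  out
}

#' Maximum-length filter
#'
#' Keeps fragments strictly shorter than `max_len_bp` (the co-localization
#' analysis considers fragments shorter than 10 kb). `NULL`/`Inf` means no
#' filtering.
#'
#' @param track a binding track
#' @param max_len_bp strict upper bound on fragment length in bp
#' @return the filtered track
#' @export
filter_max_length <- function(track, max_len_bp = 10000) {
  if (is.null(max_len_bp) || !is.finite(max_len_bp)) return(track)
  stopifnot(max_len_bp > 0)
  out <- track[GenomicRanges::width(track) < max_len_bp]
  S4Vectors::metadata(out)$protein <- track_protein(track)
  out
}
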