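#' Chromatin state maps
#'
#' A chromatin state map is a labeled partition of the genome into states:
#' either the five-color scheme (RED, YELLOW, BLUE, GREEN, BLACK) or a
#' nine-state scheme (labels "1".."9"). Segments are non-overlapping within
#' an arm; base pairs not covered by any segment are treated as "unassigned"
#' in composition summaries.
#'
#' @param chrom,start,end segment coordinates, 1-based closed
#' @param state state labels drawn from the scheme's alphabet
#' @param scheme `"five_color"` or `"nine_state"`
#' @param genome optional [genome_build()]
#' @return a `GRanges` with a `state` metadata column and the scheme in
#'   `metadata()$scheme`
#' @export
state_map <- function(chrom, start, end, state,
                      scheme = c("five_color", "nine_state"),
                      genome = NULL) {
  scheme <- match.arg(scheme)
  state <- as.character(state)
  bad <- setdiff(unique(state), state_alphabet(scheme))
  if (length(bad)) {
    stop("state label(s) outside the ", scheme, " alphabet: ",
         paste(bad, collapse = ", "))
  }
  gr <- GenomicRanges::GRanges(as.character(chrom),
                               IRanges::IRanges(as.integer(start),
                                                as.integer(end)),
                               state = state)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  if (length(gr) > 1) {
    same_arm <- as.character(GenomicRanges::seqnames(gr))[-1] ==
      as.character(GenomicRanges::seqnames(gr))[-length(gr)]
    ovl <- GenomicRanges::start(gr)[-1] <= GenomicRanges::end(gr)[-length(gr)]
    if (any(same_arm & ovl)) stop("state segments overlap within an arm")
  }
  if (!is.null(genome)) {
    al <- arm_lengths(genome)
    if (!all(as.character(GenomicRanges::seqnames(gr)) %in% names(al))) {
      stop("state segment on unknown arm")
    }
  }
  S4Vectors::metadata(gr)$scheme <- scheme
  gr
}

#' @rdname state_map
#' @export
state_alphabet <- function(scheme = c("five_color", "nine_state")) {
  scheme <- match.arg(scheme)
  if (scheme == "five_color") c("RED", "YELLOW", "BLUE", "GREEN", "BLACK")
  else as.character(1:9)
}

#' Read / write a state map (BED-like: chrom, start, end, state)
#'
#' Coordinates on disk follow BED (0-based half-open).
#'
#' @param path BED-like file
#' @param scheme `"five_color"` or `"nine_state"`
#' @param genome optional [genome_build()]
#' @return `read_state_map`: a [state_map()]
#' @export
read_state_map <- function(path, scheme = c("five_color", "nine_state"),
                           genome = NULL) {
  scheme <- match.arg(scheme)
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  comment.char = "#")
  if (!nrow(x)) {
    return(state_map(character(), integer(), integer(), character(), scheme))
  }
  state_map(x[[1]], as.integer(x[[2]]) + 1L, as.integer(x[[3]]), x[[4]],
            scheme, genome)
}

#' @rdname read_state_map
#' @param map a [state_map()]
#' @export
write_state_map <- function(map, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(map)),
                   start = GenomicRanges::start(map) - 1L,
                   end = GenomicRanges::end(map),
                   state = map$state)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
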