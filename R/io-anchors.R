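#' Anchor set: reference insertion coordinates
#'
#' Anchors are the mapped P-transposon insertion coordinates that define the
#' centers of the interband regions; all window analyses are centered on them.
#' The reference study has 13, distributed 1:3:4:5 over chr2R, chr3L, chr3R
#' and chrX — those per-arm counts double as the weights of the background
#' sampling plan.
#'
#' @param region_name character names of the regions (cytological labels)
#' @param chrom arm names
#' @param position 1-based bp coordinate of the insertion site
#' @param note optional free-text note per anchor
#' @param genome optional [genome_build()]; positions must lie within arms
#' @return an `anchor_set`: a data.frame with columns
#'   `region_name`, `chrom`, `position`, `note`
#' @export
anchor_set <- function(region_name, chrom, position, note = "",
                       genome = NULL) {
  df <- data.frame(region_name = as.character(region_name),
                   chrom = as.character(chrom),
                   position = as.numeric(position),
                   note = rep_len(as.character(note), length(region_name)),
                   stringsAsFactors = FALSE)
  if (any(df$position < 1)) stop("anchor positions must be >= 1")
  if (!is.null(genome)) {
    al <- arm_lengths(genome)
    unknown <- !(df$chrom %in% names(al))
    if (any(unknown)) stop("anchor on unknown arm: ",
                           paste(df$region_name[unknown], collapse = ", "))
    off <- df$position > al[df$chrom]
    if (any(off)) stop("anchor position off arm end: ",
                       paste(df$region_name[off], collapse = ", "))
  }
  structure(df, class = c("anchor_set", "data.frame"))
}

#' @rdname anchor_set
#' @param anchors an `anchor_set`
#' @export
anchor_arm_counts <- function(anchors) {
  tab <- table(anchors$chrom)
  setNames(as.integer(tab), names(tab))
}

#' Read / write an anchor table
#'
#' TSV with columns (name, chrom, position[, note]); a header line is
#' detected by a non-numeric third field.
#'
#' @param path TSV path
#' @param genome optional [genome_build()] for bounds checking
#' @return `read_anchor_table`: an [anchor_set()]
#' @export
read_anchor_table <- function(path, genome = NULL) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  comment.char = "#")
  if (nrow(x) && is.na(suppressWarnings(as.numeric(x[1, 3])))) {
    x <- x[-1, , drop = FALSE]
  }
  anchor_set(x[[1]], x[[2]], as.numeric(x[[3]]),
             if (ncol(x) >= 4) x[[4]] else "", genome)
}

#' @rdname read_anchor_table
#' @param anchors an [anchor_set()]
#' @export
write_anchor_table <- function(anchors, path) {
  write.table(data.frame(name = anchors$region_name, chrom = anchors$chrom,
                         position = format(anchors$position, scientific = FALSE,
                                           trim = TRUE),
                         note = anchors$note),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = c("name", "chrom", "position", "note"))
  invisible(path)
}
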