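#' Genome build: chromosome arms and lengths
#'
#' A minimal genome description used throughout the package: the euchromatic
#' chromosome arms and their lengths in base pairs. The total euchromatic
#' length (e.g. the 120 Mb used for block partitioning) is the sum of arm
#' lengths.
#'
#' @param arms character vector of arm names (e.g. `"chr2R"`)
#' @param lengths integer vector of arm lengths in bp
#' @return an object of class `genome_build`: a data.frame with columns
#'   `arm`, `length`
#' @examples
#' gb <- genome_build(c("chr2L", "chr2R"), c(23e6, 21e6))
#' genome_size(gb)
#' @export
genome_build <- function(arms, lengths) {
  stopifnot(length(arms) == length(lengths), length(arms) >= 1)
  if (anyDuplicated(arms)) stop("arm names must be unique")
  lengths <- as.numeric(lengths)
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("arm lengths must be positive")
  }
  structure(data.frame(arm = as.character(arms), length = lengths,
                       stringsAsFactors = FALSE),
            class = c("genome_build", "data.frame"))
}

#' @rdname genome_build
#' @param genome a `genome_build`
#' @export
genome_size <- function(genome) sum(genome$length)

#' @rdname genome_build
#' @export
arm_lengths <- function(genome) setNames(genome$length, genome$arm)

# Seqinfo view for GRanges construction
genome_seqinfo <- function(genome) {
  GenomeInfoDb::Seqinfo(seqnames = genome$arm,
                        seqlengths = as.integer(genome$length))
}

#' Read / write a genome table (arm<TAB>length)
#'
#' @param path TSV file with two columns, arm name and length in bp; a header
#'   line is optional (detected by a non-numeric second field).
#' @return `read_genome_tsv`: a [genome_build()]
#' @export
read_genome_tsv <- function(path) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  comment.char = "#")
  if (nrow(x) && is.na(suppressWarnings(as.numeric(x[1, 2])))) {
    x <- x[-1, , drop = FALSE]
  }
  genome_build(x[[1]], as.numeric(x[[2]]))
}

#' @rdname read_genome_tsv
#' @param genome a `genome_build`
#' @export
write_genome_tsv <- function(genome, path) {
  write.table(genome, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Reference genome build
#'
#' The euchromatic arm lengths used when reproducing the reference analysis
#' scale: a 120 Mb euchromatic genome split over the five major arms of
#' *D. melanogaster* (dm3-like proportions, rounded to 3-kb multiples so the
#' canonical 3-kb block partition tiles the arms without remainders).
#'
#' @return a [genome_build()] totalling 120 Mb
#' @export
reference_genome <- function() {
  genome_build(c("chr2L", "chr2R", "chr3L", "chr3R", "chrX"),
               c(23100000, 21000000, 24300000, 27900000, 23700000))
}
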