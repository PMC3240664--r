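#' Non-metric (ordinal) MDS embedding of a dissimilarity matrix
#'
#' Two-dimensional ordinal MDS: only the rank order of the dissimilarities
#' is fitted (Kruskal stress, isotonic regression), initialized from
#' classical metric scaling. Off-diagonal zero dissimilarities (identical
#' tracks) are lifted to a tiny positive value, as required by the stress
#' machinery; being rank-based, the solution is invariant to any monotone
#' transform of the input.
#'
#' @param D symmetric dissimilarity matrix with zero diagonal (e.g.
#'   [to_dissimilarity()] of a similarity matrix)
#' @param dims embedding dimension (default 2)
#' @param seed seed for the (rarely needed) degenerate-initialization jitter
#' @return list with `points` (items x dims matrix), `stress` (Kruskal
#'   stress, percent), `dims`
#' @export
nonmetric_mds <- function(D, dims = 2, seed = 1) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("D must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("D must have a zero diagonal")
  n <- nrow(D)
  if (n < dims + 1) stop("need more items than dimensions")
  eps <- max(D) * 1e-6 + 1e-9
  D[D <= 0] <- eps
  diag(D) <- 0
  d <- as.dist(D)
  init <- with_seed(seed, {
    y <- suppressWarnings(cmdscale(d, k = dims))
    if (ncol(y) < dims) {
      # degenerate classical solution: pad missing axes with tiny jitter
      y <- cbind(y, matrix(runif(n * (dims - ncol(y)), -eps, eps),
                           nrow = n))
    }
    if (anyDuplicated(round(y / (eps + 1e-12)))) {
      # coincident start points stall the majorization; jitter them apart
      y <- y + matrix(runif(n * dims, -eps, eps), nrow = n)
    }
    y
  })
  fit <- MASS::isoMDS(d, y = init, k = dims, trace = FALSE)
  rownames(fit$points) <- rownames(D)
  list(points = fit$points, stress = fit$stress, dims = dims)
}

#' Agglomerative hierarchical clustering of a dissimilarity matrix
#'
#' Standard agglomeration on the same dissimilarity used for the MDS
#' embedding; average linkage (UPGMA) by default, `"complete"` and
#' `"single"` available.
#'
#' @param D symmetric dissimilarity matrix, zero diagonal
#' @param linkage `"average"`, `"complete"` or `"single"`
#' @return an [stats::hclust] dendrogram
#' @export
ahc <- function(D, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("D must be symmetric")
  hclust(as.dist(D), method = linkage)
}

#' @rdname ahc
#' @param k number of groups to cut the dendrogram into
#' @return `groups`: named integer vector of cluster labels
#' @export
groups <- function(D, k = 3, linkage = "average") {
  if (k > nrow(as.matrix(D))) stop("k exceeds the number of items")
  cutree(ahc(D, linkage), k = k)
}
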