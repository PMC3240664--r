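#' End-to-end pipeline run
#'
#' Orchestrates simulate -> profile -> enrich -> lengths -> coloc -> cluster
#' from one configuration, writing plain-text TSV outputs plus a JSON
#' manifest (package version, seeds, per-file md5 hashes). Re-running the
#' same config reproduces byte-identical outputs.
#'
#' The config is a plain list (or a path to a JSON file): either a
#' `simulate` block (arguments for [sim_config()]) or paths to existing
#' inputs (`genome`, `anchors`, `states`, `tracks` = named BED/GFF paths),
#' plus optional `window_sizes`, `n_samples`, `block_bp`, `class_map`,
#' `seed`, `outdir`.
#'
#' @param config list or JSON path
#' @param outdir output directory; overrides `config$outdir`
#' @param seed overrides `config$seed`
#' @return (invisibly) the manifest list
#' @export
run_all <- function(config, outdir = NULL, seed = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  outdir <- outdir %||% config$outdir %||% stop("no output directory given")
  seed <- as.integer(seed %||% config$seed %||% 1)
  has_sim <- !is.null(config$simulate)
  has_paths <- !is.null(config$anchors) && !is.null(config$genome)
  if (!has_sim && !has_paths) {
    stop("config must contain either a 'simulate' block or input paths ",
         "('genome', 'anchors', 'tracks')")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  log_stage <- function(fmt, ...) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  }
  manifest <- list(package = "interbandscope",
                   version = as.character(utils::packageVersion("interbandscope")),
                   seed = seed, stages = list())
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    if (file.exists(path)) stop("output exists (write-once): ", path)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
    path
  }

  # -- stage: inputs ---------------------------------------------------
  if (has_sim) {
    log_stage("stage simulate")
    sim_args <- config$simulate
    if (isTRUE(is.list(sim_args$genome))) {
      sim_args$genome <- genome_build(sim_args$genome$arm,
                                      sim_args$genome$length)
    }
    sim_args$seed <- seed
    cfg <- do.call(sim_config, sim_args)
    world <- generate_world(cfg)
    simdir <- file.path(outdir, "simulate")
    written <- c(written, unname(write_world(world, simdir)))
    genome <- world$genome; anchors <- world$anchors
    tracks <- world$tracks; states <- world$states
  } else {
    log_stage("stage load")
    genome <- read_genome_tsv(config$genome)
    anchors <- read_anchor_table(config$anchors, genome)
    tracks <- list()
    for (name in names(config$tracks)) {
      p <- config$tracks[[name]]
      tracks[[name]] <- if (grepl("\\.gff3?$", p, ignore.case = TRUE)) {
        read_track_gff(p, name, genome)
      } else read_track_bed(p, name, genome)
    }
    states <- if (!is.null(config$states)) {
      read_state_map(config$states, config$state_scheme %||% "five_color",
                     genome)
    }
  }
  manifest$stages$inputs <- list(n_tracks = length(tracks),
                                 n_anchors = nrow(anchors))

  window_sizes <- unlist(config$window_sizes) %||% c(10000, 4000)
  n_samples <- config$n_samples %||% 13000
  block_bp <- config$block_bp %||% 3000

  # -- stage: profile --------------------------------------------------
  log_stage("stage profile")
  spec <- window_spec(max(window_sizes) / 2, config$segment_bp %||% 500)
  hm <- heatmap_matrix(tracks, anchors, spec, genome)
  emit(data.frame(protein = rownames(hm), hm, check.names = FALSE),
       "heatmap.tsv")
  bf <- do.call(rbind, lapply(names(tracks), function(nm) {
    data.frame(protein = nm,
               t(vapply(window_sizes, function(w) {
                 bound_fraction(tracks[[nm]], anchors, w / 2, genome)
               }, numeric(1))))
  }))
  names(bf)[-1] <- paste0("pct_bound_", window_sizes, "bp")
  emit(bf, "bound_fractions.tsv")
  if (!is.null(states)) {
    emit(state_composition(states, anchors, genome = genome),
         "state_composition.tsv")
  }
  if (!is.null(config$class_map)) {
    cm <- unlist(config$class_map)
    cp <- class_profile(tracks, cm, anchors, spec, genome)
    long <- do.call(rbind, lapply(names(cp), function(rn) {
      data.frame(region = rn, class = rownames(cp[[rn]]), cp[[rn]],
                 check.names = FALSE, row.names = NULL)
    }))
    emit(long, "class_profiles.tsv")
  }

  # -- stage: enrich ---------------------------------------------------
  log_stage("stage enrich")
  er <- enrichment_report(tracks, anchors, genome,
                          window_sizes = window_sizes,
                          n_samples = n_samples, seed = seed)
  emit(er, "enrichment.tsv")

  # -- stage: lengths --------------------------------------------------
  log_stage("stage lengths")
  emit(length_class_report(lapply(tracks, filter_positive)), "lengths.tsv")

  # -- stage: coloc ----------------------------------------------------
  log_stage("stage coloc")
  cr <- coloc_report(tracks, genome, block_bp = block_bp)
  emit(cr, "coloc.tsv")

  # -- stage: cluster --------------------------------------------------
  log_stage("stage cluster")
  R <- similarity_matrix(tracks, prepare = TRUE)
  D <- to_dissimilarity(R)
  emb <- nonmetric_mds(D, seed = seed)
  emit(data.frame(protein = rownames(emb$points),
                  dim1 = emb$points[, 1], dim2 = emb$points[, 2],
                  stress = emb$stress), "mds.tsv")
  lab <- groups(D, k = min(3, nrow(D) - 1))
  emit(data.frame(protein = names(lab), cluster = unname(lab)),
       "clusters.tsv")
  emit(data.frame(protein = rownames(R), R, check.names = FALSE),
       "similarity.tsv")

  manifest$stages$outputs <- basename(written)
  manifest$md5 <- as.list(tools::md5sum(sort(written)))
  names(manifest$md5) <- basename(sort(written))
  manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_stage("done in %.1f s", manifest$elapsed_sec)
  invisible(manifest)
}
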