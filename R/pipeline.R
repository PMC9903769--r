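#' Run the full analysis pipeline on a directory of input tables
#'
#' Executes dereplication, biogeography, marker novelty, the functional
#' landscape (occurrence matrix, filtering, clustering, differential
#' occurrence, gene-cluster consensus) and niche projection in order,
#' writing per-stage TSV outputs and a provenance log (config hash, seed,
#' stage timings) to \code{outdir}. A failure in any stage aborts with the
#' stage name and cause.
#'
#' @param input_dir directory holding \code{genomes.tsv}, \code{pairs.tsv},
#'   \code{metagenomes.tsv}, \code{recruitment.tsv},
#'   \code{annotations.tsv}, \code{function_meta.tsv}, \code{markers.tsv},
#'   \code{stations.tsv}, \code{grid_period1.tsv}, \code{grid_period2.tsv}
#'   (as written by \code{\link{write_bundle}}).
#' @param outdir output directory, created if needed.
#' @param config a \code{\link{pipeline_config}}.
#' @param subset metagenome subset label for the cosmopolitan score
#'   (NULL = all).
#' @param outgroup genome ids excluded from functional group extraction.
#' @param grid_resolution grid resolution in degrees for area integration.
#' @return invisibly, a list with the main stage results.
#' @export
run_pipeline <- function(input_dir, outdir, config = pipeline_config(),
                         subset = "station_subset_1", outgroup = character(0),
                         grid_resolution = 1) {
  validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("config_hash\t%s", config_hash(config)),
                 sprintf("rng_seed\t%d", config$rng_seed))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_lines <<- c(log_lines, sprintf("stage_%s_seconds\t%.3f", name,
                                       as.numeric(Sys.time() - t0, units = "secs")))
    out
  }
  inp <- function(f) file.path(input_dir, f)
  outp <- function(f) file.path(outdir, f)

  io <- stage("read_inputs", {
    list(genomes = read_table(inp("genomes.tsv"), "genomes"),
         pairs = read_table(inp("pairs.tsv"), "pairs"),
         metagenomes = read_table(inp("metagenomes.tsv"), "metagenomes"),
         recruitment = read_table(inp("recruitment.tsv"), "recruitment"),
         annotations = read_table(inp("annotations.tsv"), "annotations"),
         function_meta = read_table(inp("function_meta.tsv"), "function_meta"),
         markers = read_table(inp("markers.tsv"), "markers"),
         stations = read_table(inp("stations.tsv"), "station_env"),
         grid1 = read_table(inp("grid_period1.tsv"), "grid"),
         grid2 = read_table(inp("grid_period2.tsv"), "grid"))
  })

  derep <- stage("dereplication", {
    d <- dereplicate(io$genomes, io$pairs, config)
    utils::write.table(d$components, outp("derep_components.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(d$representatives, outp("derep_representatives.txt"))
    d
  })
  nr_genomes <- io$genomes[io$genomes$genome_id %in% derep$representatives, ,
                           drop = FALSE]

  biogeo <- stage("biogeography", {
    nr_recruit <- io$recruitment[
      io$recruitment$genome_id %in% derep$representatives, , drop = FALSE]
    b <- biogeography_summary(nr_recruit, io$metagenomes, nr_genomes,
                              subset = subset, config = config)
    frac <- fraction_recruited(b$profiles, io$metagenomes)
    utils::write.table(b$summary, outp("biogeography_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(metric = c("pooled_fraction_recruited"),
                 value = frac$pooled),
      outp("fraction_recruited.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    c(b, list(fraction = frac))
  })

  novelty <- stage("novelty", {
    nv <- novelty_table(io$markers, genome_ids = io$genomes$genome_id)
    utils::write.table(nv$results, outp("novelty.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    nv
  })

  funcland <- stage("functional_landscape", {
    mat <- build_occurrence_matrix(
      io$annotations[io$annotations$genome_id %in% derep$representatives, ,
                     drop = FALSE], nr_genomes)
    biggest <- nr_genomes$genome_id[which.max(nr_genomes$length)]
    fmat <- filter_functions(mat, exclusions = character(0),
                             cap_reference_genome = biggest,
                             function_meta = io$function_meta, config = config)
    cl <- cluster_genomes(fmat, outgroup = outgroup, config = config)
    diff <- differential_functions(fmat, cl$assignments, config = config)
    cons <- consensus_annotation(io$annotations)
    cons <- prevalence_filter(cons, io$annotations, nr_genomes$genome_id,
                              config)
    redund <- functional_redundancy(mat)
    utils::write.table(cl$assignments, outp("functional_groups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(diff$results, outp("differential_functions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(diff$games_howell, outp("games_howell.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cons, outp("consensus_groups.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(genome_id = names(redund), functional_redundancy = redund),
      outp("functional_redundancy.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    ape::write.tree(ape::as.phylo(cl$hclust_full), outp("dendrogram.nwk"))
    list(matrix = fmat, clusters = cl, differential = diff, consensus = cons,
         redundancy = redund)
  })

  niche <- stage("niche_projection", {
    det <- biogeo$summary[biogeo$summary$n_detected_stations >=
                            config$min_stations_for_niche, , drop = FALSE]
    rows <- list()
    for (g in det$genome_id) {
      p <- biogeo$profiles[biogeo$profiles$genome_id == g &
                             biogeo$profiles$detected, , drop = FALSE]
      st <- unique(p$station_id)
      st <- intersect(st, io$stations$station_id)
      if (length(st) < config$min_stations_for_niche) next
      model <- fit_niche(st, io$stations, config)
      p1 <- project_presence(model, io$grid1)
      p2 <- project_presence(model, io$grid2)
      a1 <- presence_area(p1, io$grid1, config, grid_resolution)
      a2 <- presence_area(p2, io$grid2, config, grid_resolution)
      attr_res <- attribute_drivers(model, io$grid1, io$grid2, config)
      top_driver <- if (nrow(attr_res$shares)) {
        s <- attr_res$shares[order(-attr_res$shares$share_percent), ]
        paste0(s$regime[1], ":", s$driver[1],
               sprintf(" (%.0f%%)", s$share_percent[1]))
      } else ""
      rows[[g]] <- data.frame(
        genome_id = g, n_presence_stations = model$n_presence_stations,
        area_period1_km2 = a1, area_period2_km2 = a2,
        delta_area_km2 = a2 - a1, top_driver = top_driver,
        stringsAsFactors = FALSE)
    }
    summary <- do.call(rbind, rows)
    if (is.null(summary)) {
      summary <- data.frame(genome_id = character(0),
                            n_presence_stations = integer(0),
                            area_period1_km2 = numeric(0),
                            area_period2_km2 = numeric(0),
                            delta_area_km2 = numeric(0),
                            top_driver = character(0))
    }
    rownames(summary) <- NULL
    utils::write.table(summary, outp("niche_projection_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary
  })

  writeLines(log_lines, outp("provenance.log"))
  invisible(list(dereplication = derep, biogeography = biogeo,
                 novelty = novelty, functional = funcland, niche = niche))
}
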