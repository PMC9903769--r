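#' @name synthetic_data
#' @title Synthetic pipeline inputs with planted, recoverable structure
#'
#' @description
#' Generates every table the pipeline consumes — genome records, pairwise
#' ANI, recruitment profiles, metagenome metadata, gene annotations,
#' marker best-hit identities, station environments and two-period gridded
#' climatologies — with known planted structure (redundancy components,
#' functional groups, niches, environmental shifts) recorded in a truth
#' object, so every downstream stage can be validated without external
#' data. All distributions are declared stand-ins chosen for recoverability
#' at desk scale, not claims about any observational dataset.
NULL

# run expr under a derived seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed %% .Machine$integer.max)
  expr
}

#' Simulation specification
#'
#' Parameters of the synthetic-data generator. Defaults are desk-scale:
#' large enough for every planted signal to be recoverable under the
#' default pipeline thresholds, small enough to run in seconds.
#'
#' @param n_genomes number of genomes (MAGs/SAGs).
#' @param n_redundant_pairs planted redundant pairs (disjoint; each pair
#'   gets ANI in (98.1, 99.9) and aligned fraction > 0.25).
#' @param n_stations sampling stations (each contributes one surface and
#'   one deep-chlorophyll-maximum metagenome).
#' @param n_functions orthologous groups outside markers/retrotransposons;
#'   half are designated unknown-function.
#' @param n_groups planted functional groups (>= 2).
#' @param group_effect_size added Poisson mean for a group's marker
#'   functions in member genomes.
#' @param markers_per_group marker functions per group (disjoint sets,
#'   half known / half unknown function).
#' @param lambda_base baseline Poisson mean of function occurrence.
#' @param completion_range percent completion interval genomes are drawn
#'   from.
#' @param n_retro_functions retrotransposon-flagged functions planted with
#'   high occurrence in the largest genome.
#' @param retro_count occurrence of each such function in the largest
#'   genome (above the 500 cap by default).
#' @param grid_resolution climatology grid resolution in degrees.
#' @param env_shift named per-parameter offsets added to the period-1 grid
#'   to form period 2 (default: +2 degrees C on SST only).
#' @param niche_width_range per-parameter niche widths are drawn uniformly
#'   from this range, in units of the parameter's across-station sd.
#' @param label_noise fraction of genes in an annotated gene cluster
#'   carrying a different orthologous-group label.
#' @param unknown_cluster_fraction fraction of gene clusters built from
#'   unannotated genes.
#' @param rng_seed integer seed; every generator output is a pure function
#'   of the spec including this seed.
#' @return object of class \code{simulation_spec}.
#' @export
simulation_spec <- function(n_genomes = 60L,
                            n_redundant_pairs = 5L,
                            n_stations = 40L,
                            n_functions = 300L,
                            n_groups = 4L,
                            group_effect_size = 5,
                            markers_per_group = 10L,
                            lambda_base = 1,
                            completion_range = c(5, 95),
                            n_retro_functions = 3L,
                            retro_count = 600L,
                            grid_resolution = 1,
                            env_shift = c(sst = 2, salinity = 0, silicate = 0,
                                          nitrate = 0, phosphate = 0, iron = 0,
                                          si_no3 = 0),
                            niche_width_range = c(0.6, 1.2),
                            label_noise = 0.1,
                            unknown_cluster_fraction = 0.3,
                            rng_seed = 1L) {
  spec <- list(n_genomes = as.integer(n_genomes),
               n_redundant_pairs = as.integer(n_redundant_pairs),
               n_stations = as.integer(n_stations),
               n_functions = as.integer(n_functions),
               n_groups = as.integer(n_groups),
               group_effect_size = group_effect_size,
               markers_per_group = as.integer(markers_per_group),
               lambda_base = lambda_base,
               completion_range = completion_range,
               n_retro_functions = as.integer(n_retro_functions),
               retro_count = as.integer(retro_count),
               grid_resolution = grid_resolution,
               env_shift = env_shift,
               niche_width_range = niche_width_range,
               label_noise = label_noise,
               unknown_cluster_fraction = unknown_cluster_fraction,
               rng_seed = as.integer(rng_seed))
  class(spec) <- "simulation_spec"
  if (spec$n_groups < 2L) stop("n_groups must be >= 2", call. = FALSE)
  if (spec$n_redundant_pairs > spec$n_genomes / 2) {
    stop("n_redundant_pairs exceeds n_genomes/2", call. = FALSE)
  }
  if (!all(ENV_PARAMS %in% names(spec$env_shift))) {
    stop("env_shift must name all seven parameters", call. = FALSE)
  }
  stopifnot(length(spec$completion_range) == 2,
            spec$completion_range[1] <= spec$completion_range[2],
            spec$completion_range[1] >= 0, spec$completion_range[2] <= 100)
  spec
}

#' Simulate genome records and pairwise similarities
#'
#' Genome lengths are log-uniform between 10 Mbp and 1.3 Gbp; completion
#' is uniform in the spec's range. Planted redundant pairs are disjoint and
#' receive ANI ~ U(98.1, 99.9) with aligned fraction ~ U(0.3, 0.9); all
#' other pairs get ANI ~ U(80, 97), safely below threshold.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @return list: \code{genomes} (genomes schema), \code{pairs} (pairs
#'   schema, all unordered pairs), \code{truth} (data.frame
#'   \code{genome_id}, \code{component_id}, \code{group_label}).
#' @export
simulate_genomes <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  .with_seed(spec$rng_seed + 101L, {
    n <- spec$n_genomes
    ids <- sprintf("GEN_%03d", seq_len(n))
    lengths <- round(10^stats::runif(n, log10(1e7), log10(1.3e9)))
    lineages <- sample(c("Alveolata", "Archaeplastida", "Haptista",
                         "Stramenopiles", "Opisthokonta", "Rhizaria"),
                       n, replace = TRUE)
    genomes <- data.frame(
      genome_id = ids,
      length = lengths,
      completion = stats::runif(n, spec$completion_range[1],
                                spec$completion_range[2]),
      redundancy = stats::runif(n, 0, 5),
      lineage = lineages,
      source = sample(c("MAG", "SAG"), n, replace = TRUE, prob = c(0.95, 0.05)),
      is_phytoplankton = stats::runif(n) < 0.4,
      stringsAsFactors = FALSE)

    # planted redundancy: disjoint pairs
    paired <- if (spec$n_redundant_pairs > 0) {
      sample(ids, 2L * spec$n_redundant_pairs)
    } else character(0)
    red_a <- paired[seq_len(spec$n_redundant_pairs)]
    red_b <- paired[spec$n_redundant_pairs + seq_len(spec$n_redundant_pairs)]
    allp <- utils::combn(ids, 2)
    pairs <- data.frame(genome_a = allp[1, ], genome_b = allp[2, ],
                        stringsAsFactors = FALSE)
    key <- paste(pmin(pairs$genome_a, pairs$genome_b),
                 pmax(pairs$genome_a, pairs$genome_b))
    redkey <- paste(pmin(red_a, red_b), pmax(red_a, red_b))
    is_red <- key %in% redkey
    pairs$ani <- ifelse(is_red, stats::runif(nrow(pairs), 98.1, 99.9),
                        stats::runif(nrow(pairs), 80, 97))
    pairs$aligned_fraction_smaller <-
      ifelse(is_red, stats::runif(nrow(pairs), 0.3, 0.9),
             stats::runif(nrow(pairs), 0, 1))

    comp <- seq_len(n)
    names(comp) <- ids
    comp[red_b] <- comp[red_a]
    truth <- data.frame(
      genome_id = ids,
      component_id = as.integer(match(comp[ids], unique(comp[ids]))),
      group_label = LETTERS[(seq_len(n) - 1L) %% spec$n_groups + 1L],
      stringsAsFactors = FALSE)
    list(genomes = genomes, pairs = pairs, truth = truth)
  })
}

# analytic land mask: two rectangular continents
.is_land <- function(lat, lon) {
  (lon >= -80 & lon <= -35 & lat >= -55 & lat <= 70) |
    (lon >= 10 & lon <= 50 & lat >= -35 & lat <= 35)
}

.env_fields <- function(lat, lon) {
  latr <- lat * pi / 180
  lonr <- lon * pi / 180
  data.frame(
    sst = -2 + 30 * cos(latr),
    salinity = 34 + 2 * cos(2 * latr),
    silicate = 10 + 40 * abs(lat) / 90,
    nitrate = 2 + 28 * abs(lat) / 90,
    phosphate = (2 + 28 * abs(lat) / 90) / 16,
    iron = 0.1 + 0.5 * (1 + sin(2 * lonr)) / 2,
    si_no3 = abs(sin(latr))
  )
}

#' Simulate station environments and two-period climatology grids
#'
#' Builds a lat/lon grid at the spec's resolution with smooth analytic
#' fields (SST decreasing poleward, macronutrients increasing poleward,
#' longitudinally varying iron) and a rectangular-continent land mask.
#' Period 2 equals period 1 plus the spec's per-parameter offsets. Stations
#' are sampled from ocean cells and carry the period-1 cell environment.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @return list: \code{stations} (station_env schema), \code{grid1},
#'   \code{grid2} (grid schema), \code{station_cells} (grid row index of
#'   each station).
#' @export
simulate_environment <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  .with_seed(spec$rng_seed + 202L, {
    res <- spec$grid_resolution
    lat <- seq(-90 + res / 2, 90 - res / 2, by = res)
    lon <- seq(-180 + res / 2, 180 - res / 2, by = res)
    cells <- expand.grid(lon = lon, lat = lat, KEEP.OUT.ATTRS = FALSE)
    grid1 <- cbind(data.frame(lat = cells$lat, lon = cells$lon,
                              ocean = !.is_land(cells$lat, cells$lon)),
                   .env_fields(cells$lat, cells$lon))
    grid2 <- grid1
    for (p in ENV_PARAMS) grid2[[p]] <- grid1[[p]] + spec$env_shift[[p]]
    ocean_idx <- which(grid1$ocean & abs(grid1$lat) < 70)  # sampled latitudes
    idx <- sample(ocean_idx, spec$n_stations)
    stations <- cbind(
      data.frame(station_id = sprintf("ST_%03d", seq_len(spec$n_stations))),
      grid1[idx, ENV_PARAMS])
    rownames(stations) <- NULL
    list(stations = stations, grid1 = grid1, grid2 = grid2,
         station_cells = idx)
  })
}

#' Simulate recruitment profiles from planted niches
#'
#' Each genome gets a planted Gaussian niche: its optimum is the
#' environment of a randomly chosen home station, with per-parameter
#' widths drawn from the spec's range (in across-station sd units). A
#' station is inside the niche when its mean squared standardized distance
#' to the optimum is below 1. Every station contributes two metagenomes
#' (SRF and DCM); profiles at inside stations draw breadth ~ U(0.3, 0.9)
#' and coverage ~ U(1, 10) (reads = coverage x length / 100 bp), outside
#' stations breadth ~ U(0, 0.2) and coverage ~ U(0, 0.2), so planted
#' detection labels sit clear of the 0.25 breadth threshold.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @param genomes genomes table from \code{\link{simulate_genomes}}.
#' @param stations station environments from
#'   \code{\link{simulate_environment}}.
#' @return list: \code{recruitment} (recruitment schema),
#'   \code{metagenomes} (metagenomes schema, all in
#'   \code{station_subset_1}), \code{truth} (list with \code{detection},
#'   a genome x station logical matrix, and \code{niches}, per-genome
#'   optima/widths on raw scales).
#' @export
simulate_recruitment <- function(spec, genomes, stations) {
  stopifnot(inherits(spec, "simulation_spec"))
  .with_seed(spec$rng_seed + 303L, {
    env <- as.matrix(stations[ENV_PARAMS])
    rownames(env) <- stations$station_id
    sds <- apply(env, 2, stats::sd)
    sds[sds <= 0] <- 1
    n <- nrow(genomes)
    home <- sample(stations$station_id, n, replace = TRUE)
    widths <- matrix(stats::runif(n * length(ENV_PARAMS),
                                  spec$niche_width_range[1],
                                  spec$niche_width_range[2]),
                     n, length(ENV_PARAMS),
                     dimnames = list(genomes$genome_id, ENV_PARAMS))
    widths <- sweep(widths, 2, sds, "*")
    optima <- env[home, , drop = FALSE]
    rownames(optima) <- genomes$genome_id

    detection <- matrix(FALSE, n, nrow(stations),
                        dimnames = list(genomes$genome_id,
                                        stations$station_id))
    for (i in seq_len(n)) {
      d2 <- rowSums(sweep(sweep(env, 2, optima[i, ]), 2, widths[i, ], "/")^2) /
        length(ENV_PARAMS)
      detection[i, ] <- d2 < 1
    }

    meta <- data.frame(
      metagenome_id = paste0(rep(stations$station_id, each = 2),
                             c("_SRF", "_DCM")),
      station_id = rep(stations$station_id, each = 2),
      depth_layer = rep(c("SRF", "DCM"), nrow(stations)),
      size_fraction = "0.8-2000",
      total_reads = 0,
      subset_labels = "station_subset_1",
      stringsAsFactors = FALSE)

    prof <- expand.grid(genome_id = genomes$genome_id,
                        metagenome_id = meta$metagenome_id,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    st <- meta$station_id[match(prof$metagenome_id, meta$metagenome_id)]
    inside <- detection[cbind(prof$genome_id, st)]
    m <- nrow(prof)
    prof$breadth <- ifelse(inside, stats::runif(m, 0.3, 0.9),
                           stats::runif(m, 0, 0.2))
    cov <- ifelse(inside, stats::runif(m, 1, 10), stats::runif(m, 0, 0.2))
    len <- genomes$length[match(prof$genome_id, genomes$genome_id)]
    prof$recruited_reads <- round(cov * len / 100)  # 100 bp reads
    prof$mean_coverage <- cov
    prof <- prof[c("genome_id", "metagenome_id", "recruited_reads",
                   "breadth", "mean_coverage")]

    tot <- tapply(prof$recruited_reads, prof$metagenome_id, sum)
    meta$total_reads <- round(as.numeric(tot[meta$metagenome_id]) * 8 + 1e6)
    list(recruitment = prof, metagenomes = meta,
         truth = list(detection = detection,
                      niches = list(optima = optima, widths = widths)))
  })
}

#' Simulate gene annotations with planted functional groups
#'
#' Function occurrence counts are Poisson(\code{lambda_base}) per genome
#' and function; each planted group owns a disjoint set of marker
#' functions whose mean is raised by \code{group_effect_size} in member
#' genomes (half the markers are known-function, half unknown, so group
#' structure is recoverable from either matrix slice).
#' Retrotransposon-flagged functions receive \code{retro_count} copies in
#' the largest genome. Genes are then materialized one row per gene copy,
#' and remote-homology gene clusters are built per function with a stated
#' fraction of label noise, plus clusters of unannotated genes.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @param genomes genomes table from \code{\link{simulate_genomes}}.
#' @param group_labels per-genome planted group labels (from the genome
#'   truth table).
#' @return list: \code{annotations} (annotations schema),
#'   \code{function_meta} (function_meta schema), \code{truth} (list:
#'   \code{group_labels}, \code{marker_functions} per group,
#'   \code{unknown_functions}, \code{retro_functions},
#'   \code{counts} genome x function matrix).
#' @export
simulate_annotations <- function(spec, genomes, group_labels) {
  stopifnot(inherits(spec, "simulation_spec"))
  .with_seed(spec$rng_seed + 404L, {
    n <- nrow(genomes)
    gids <- genomes$genome_id
    groups <- LETTERS[seq_len(spec$n_groups)]
    stopifnot(length(group_labels) == n)

    base_f <- sprintf("OG_%04d", seq_len(spec$n_functions))
    marker_f <- lapply(seq_len(spec$n_groups), function(g)
      sprintf("OG_MK%s_%02d", groups[g], seq_len(spec$markers_per_group)))
    names(marker_f) <- groups
    retro_f <- if (spec$n_retro_functions > 0) {
      sprintf("OG_RT_%02d", seq_len(spec$n_retro_functions))
    } else character(0)
    all_f <- c(base_f, unlist(marker_f, use.names = FALSE), retro_f)

    # half of the base functions and of each marker set are unknown-function
    unknown_f <- c(base_f[seq_len(spec$n_functions) %% 2 == 0],
                   unlist(lapply(marker_f, function(f)
                     f[seq_along(f) %% 2 == 0]), use.names = FALSE))

    lam <- matrix(spec$lambda_base, n, length(all_f),
                  dimnames = list(gids, all_f))
    for (g in groups) {
      lam[group_labels == g, marker_f[[g]]] <-
        spec$lambda_base + spec$group_effect_size
    }
    counts <- matrix(stats::rpois(length(lam), lam), n, length(all_f),
                     dimnames = dimnames(lam))
    if (length(retro_f)) {
      biggest <- gids[which.max(genomes$length)]
      counts[biggest, retro_f] <- spec$retro_count
    }

    # materialize genes
    idx <- which(counts > 0, arr.ind = TRUE)
    ann <- data.frame(
      genome_id = rep(gids[idx[, 1]], counts[idx]),
      og_id = rep(all_f[idx[, 2]], counts[idx]),
      stringsAsFactors = FALSE)
    # plus unannotated genes (no orthologous group)
    n_unann <- stats::rpois(n, spec$lambda_base * spec$n_functions * 0.3)
    ann <- rbind(ann,
                 data.frame(genome_id = rep(gids, n_unann), og_id = "",
                            stringsAsFactors = FALSE))
    ann <- ann[order(ann$genome_id), , drop = FALSE]
    ann$gene_id <- sprintf("gene_%07d", seq_len(nrow(ann)))
    ann$og_known <- nzchar(ann$og_id) & !(ann$og_id %in% unknown_f)

    # remote-homology gene clusters: one per function, with label noise,
    # plus clusters over unannotated genes
    ann$agnostos_cluster <- ""
    annotated <- which(nzchar(ann$og_id))
    cl_of_f <- stats::setNames(sprintf("CL_%05d", seq_along(all_f)), all_f)
    ann$agnostos_cluster[annotated] <- cl_of_f[ann$og_id[annotated]]
    n_noise <- floor(spec$label_noise * length(annotated))
    if (n_noise > 0) {
      noisy <- sample(annotated, n_noise)
      ann$agnostos_cluster[noisy] <- sample(cl_of_f, n_noise, replace = TRUE)
    }
    unann <- which(!nzchar(ann$og_id))
    n_ucl <- max(1L, floor(spec$unknown_cluster_fraction * length(all_f)))
    if (length(unann)) {
      ann$agnostos_cluster[unann] <-
        sample(sprintf("CLU_%05d", seq_len(n_ucl)), length(unann),
               replace = TRUE)
    }

    ann <- ann[c("gene_id", "genome_id", "og_id", "og_known",
                 "agnostos_cluster")]
    rownames(ann) <- NULL
    fmeta <- data.frame(og_id = all_f,
                        is_retrotransposon = all_f %in% retro_f,
                        stringsAsFactors = FALSE)
    list(annotations = ann, function_meta = fmeta,
         truth = list(group_labels = stats::setNames(group_labels, gids),
                      marker_functions = marker_f,
                      unknown_functions = unknown_f,
                      retro_functions = retro_f,
                      counts = counts))
  })
}

#' Simulate RNA polymerase marker best-hit identities
#'
#' Each genome receives 1 to 6 of the six marker genes with best-hit
#' identities drawn uniformly in [40, 100], giving novelty scores across
#' the full displayed range.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @param genomes genomes table.
#' @return data.frame, \code{markers} schema.
#' @export
simulate_marker_hits <- function(spec, genomes) {
  stopifnot(inherits(spec, "simulation_spec"))
  .with_seed(spec$rng_seed + 505L, {
    all_markers <- as.vector(outer(c("RNAP-a", "RNAP-b"),
                                   c("polI", "polII", "polIII"),
                                   paste, sep = "-"))
    rows <- lapply(genomes$genome_id, function(g) {
      k <- sample(1:6, 1)
      data.frame(genome_id = g, marker_id = sample(all_markers, k),
                 best_hit_identity = stats::runif(k, 40, 100),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate the full input bundle
#'
#' Chains all generators under one seed and returns every pipeline input
#' plus the truth object.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @return list: \code{genomes}, \code{pairs}, \code{metagenomes},
#'   \code{recruitment}, \code{annotations}, \code{function_meta},
#'   \code{markers}, \code{stations}, \code{grid1}, \code{grid2},
#'   \code{truth}.
#' @export
simulate_bundle <- function(spec = simulation_spec()) {
  g <- simulate_genomes(spec)
  e <- simulate_environment(spec)
  r <- simulate_recruitment(spec, g$genomes, e$stations)
  a <- simulate_annotations(spec, g$genomes, g$truth$group_label)
  mk <- simulate_marker_hits(spec, g$genomes)
  list(genomes = g$genomes, pairs = g$pairs,
       metagenomes = r$metagenomes, recruitment = r$recruitment,
       annotations = a$annotations, function_meta = a$function_meta,
       markers = mk, stations = e$stations,
       grid1 = e$grid1, grid2 = e$grid2,
       truth = list(components = g$truth,
                    detection = r$truth$detection,
                    niches = r$truth$niches,
                    group_labels = a$truth$group_labels,
                    marker_functions = a$truth$marker_functions,
                    unknown_functions = a$truth$unknown_functions,
                    retro_functions = a$truth$retro_functions,
                    counts = a$truth$counts))
}

#' Write a simulated bundle to a directory of TSVs
#'
#' Input tables go to \code{dir/} under their schema names; truth labels
#' go to \code{dir/truth/} as plain TSVs.
#'
#' @param bundle result of \code{\link{simulate_bundle}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  write_table(bundle$genomes, file.path(dir, "genomes.tsv"), "genomes")
  write_table(bundle$pairs, file.path(dir, "pairs.tsv"), "pairs")
  write_table(bundle$metagenomes, file.path(dir, "metagenomes.tsv"),
              "metagenomes")
  write_table(bundle$recruitment, file.path(dir, "recruitment.tsv"),
              "recruitment")
  write_table(bundle$annotations, file.path(dir, "annotations.tsv"),
              "annotations")
  write_table(bundle$function_meta, file.path(dir, "function_meta.tsv"),
              "function_meta")
  write_table(bundle$markers, file.path(dir, "markers.tsv"), "markers")
  write_table(bundle$stations, file.path(dir, "stations.tsv"), "station_env")
  write_table(bundle$grid1, file.path(dir, "grid_period1.tsv"), "grid")
  write_table(bundle$grid2, file.path(dir, "grid_period2.tsv"), "grid")
  utils::write.table(bundle$truth$components,
                     file.path(dir, "truth", "components.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  det <- data.frame(genome_id = rownames(bundle$truth$detection),
                    bundle$truth$detection, check.names = FALSE)
  utils::write.table(det, file.path(dir, "truth", "detection.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
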