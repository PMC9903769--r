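#' Pipeline configuration
#'
#' Bundles every threshold used across the pipeline stages into a single
#' validated object. Defaults reproduce the published analysis rules:
#' genomes are redundant when ANI > 98\% with > 25\% of the smaller genome
#' aligned; a genome is detected in a sample when > 25\% of its length is
#' covered; read counts are projected to completeness except below a 10\%
#' completion floor; differential occurrence uses a raw p < 1e-5 cut across
#' 4 functional groups; functions occurring more than 500 times in the
#' reference giga-scale genome (and flagged as retrotransposon-linked) are
#' removed; consensus gene groups present in less than 2\% of genomes are
#' excluded; niches are fitted for genomes detected in at least 5 stations;
#' distribution shifts are flagged where |deltaP| > 0.1 and presence calls
#' use the P > 0.5 midpoint.
#'
#' @param ani_threshold percent ANI above which a pair may be redundant.
#' @param align_fraction_threshold minimum aligned fraction of the smaller
#'   genome (strict) for redundancy.
#' @param detection_breadth_threshold fraction of genome length that must be
#'   covered (strict) to call detection in one metagenome.
#' @param completion_floor percent completion below which recruited read
#'   counts are preserved rather than projected.
#' @param mapping_identity_note percent read-mapping identity used upstream;
#'   carried as metadata only, never recomputed.
#' @param anova_p_threshold significance cut for the per-function Welch
#'   ANOVA.
#' @param group_count number of functional groups cut from the dendrogram.
#' @param occurrence_cap occurrence count in the reference genome above
#'   which (strictly) a flagged function is removed.
#' @param min_group_prevalence minimum fraction of genomes a consensus gene
#'   group must occur in to be retained.
#' @param min_stations_for_niche minimum number of detection stations
#'   required to fit a niche model.
#' @param delta_p_threshold |deltaP| above which (strictly) a grid cell is
#'   flagged as expansion/reduction and receives a driver label.
#' @param presence_threshold probability above which (strictly) a cell
#'   counts toward the presence surface.
#' @param rng_seed integer seed recorded in provenance logs.
#' @return An object of class \code{pipeline_config} (a named list).
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$ani_threshold
pipeline_config <- function(ani_threshold = 98,
                            align_fraction_threshold = 0.25,
                            detection_breadth_threshold = 0.25,
                            completion_floor = 10,
                            mapping_identity_note = 90,
                            anova_p_threshold = 1e-5,
                            group_count = 4L,
                            occurrence_cap = 500,
                            min_group_prevalence = 0.02,
                            min_stations_for_niche = 5L,
                            delta_p_threshold = 0.1,
                            presence_threshold = 0.5,
                            rng_seed = 1L) {
  cfg <- list(
    ani_threshold = as.numeric(ani_threshold),
    align_fraction_threshold = as.numeric(align_fraction_threshold),
    detection_breadth_threshold = as.numeric(detection_breadth_threshold),
    completion_floor = as.numeric(completion_floor),
    mapping_identity_note = as.numeric(mapping_identity_note),
    anova_p_threshold = as.numeric(anova_p_threshold),
    group_count = as.integer(group_count),
    occurrence_cap = as.numeric(occurrence_cap),
    min_group_prevalence = as.numeric(min_group_prevalence),
    min_stations_for_niche = as.integer(min_stations_for_niche),
    delta_p_threshold = as.numeric(delta_p_threshold),
    presence_threshold = as.numeric(presence_threshold),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks that every threshold lies in its natural range (percents in
#' [0, 100], fractions and probabilities in [0, 1], counts positive).
#'
#' @param cfg a \code{pipeline_config}.
#' @return \code{cfg}, invisibly, if valid; otherwise an error.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  chk <- function(ok, what) {
    if (!isTRUE(ok)) stop("invalid configuration: ", what, call. = FALSE)
  }
  pct <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 100
  frac <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1
  chk(pct(cfg$ani_threshold), "ani_threshold must be a percent in [0,100]")
  chk(frac(cfg$align_fraction_threshold),
      "align_fraction_threshold must be a fraction in [0,1]")
  chk(frac(cfg$detection_breadth_threshold),
      "detection_breadth_threshold must be a fraction in [0,1]")
  chk(pct(cfg$completion_floor), "completion_floor must be a percent in [0,100]")
  chk(pct(cfg$mapping_identity_note),
      "mapping_identity_note must be a percent in [0,100]")
  chk(frac(cfg$anova_p_threshold), "anova_p_threshold must be in [0,1]")
  chk(is.integer(cfg$group_count) && cfg$group_count >= 2L,
      "group_count must be an integer >= 2")
  chk(is.numeric(cfg$occurrence_cap) && cfg$occurrence_cap >= 0,
      "occurrence_cap must be non-negative")
  chk(frac(cfg$min_group_prevalence), "min_group_prevalence must be in [0,1]")
  chk(is.integer(cfg$min_stations_for_niche) && cfg$min_stations_for_niche >= 1L,
      "min_stations_for_niche must be a positive integer")
  chk(frac(cfg$delta_p_threshold), "delta_p_threshold must be in [0,1]")
  chk(frac(cfg$presence_threshold), "presence_threshold must be in [0,1]")
  chk(is.integer(cfg$rng_seed) && !is.na(cfg$rng_seed), "rng_seed must be an integer")
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Write a configuration to a flat key=value file
#'
#' @param cfg a \code{pipeline_config}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  lines <- vapply(names(cfg), function(nm) {
    paste0(nm, "=", format(cfg[[nm]], scientific = FALSE, digits = 15))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a configuration from a flat key=value file
#'
#' Unknown keys are rejected; missing keys fall back to defaults.
#'
#' @param path file written by \code{\link{write_config}} (or by hand).
#' @return a validated \code{pipeline_config}.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) {
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- trimws(vapply(kv, `[`, character(1), 2L))
  defaults <- pipeline_config()
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  args <- as.list(as.numeric(vals))
  names(args) <- keys
  do.call(pipeline_config, args)
}

#' Hash a configuration for provenance logs
#'
#' @param cfg a \code{pipeline_config}.
#' @return an md5 hex string over the canonical key=value serialization.
#' @export
config_hash <- function(cfg) {
  validate_config(cfg)
  tmp <- tempfile(fileext = ".cfg")
  on.exit(unlink(tmp))
  write_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}
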