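#' @name biogeography
#' @title Detection, corrected abundance and cosmopolitan scores
#'
#' @description
#' Recruitment profiles (recruited reads, breadth of coverage and mean
#' vertical coverage per genome x metagenome) are converted into detection
#' calls (breadth strictly above 0.25 of the genome length), filtered read
#' counts (reads in non-detected samples set to 0), completion-projected
#' read counts (reads scaled by 100/completion, preserved unchanged below
#' the 10\% completion floor), per-genome cosmopolitan scores over a station
#' subset, and the overall fraction of the sequencing effort recruited.
NULL

#' Call detection from breadth of coverage
#'
#' @param breadth fraction of genome length covered by at least one read.
#' @param config a \code{\link{pipeline_config}}.
#' @return logical, TRUE iff \code{breadth > detection_breadth_threshold}
#'   (strict). Vectorized.
#' @export
call_detection <- function(breadth, config = pipeline_config()) {
  validate_config(config)
  if (any(breadth < 0 | breadth > 1, na.rm = TRUE)) {
    stop("breadth must be a fraction in [0,1]", call. = FALSE)
  }
  breadth > config$detection_breadth_threshold
}

#' Zero out read counts from non-detected samples
#'
#' @param recruited_reads raw recruited read counts.
#' @param breadth matching breadth values.
#' @param config a \code{\link{pipeline_config}}.
#' @return \code{recruited_reads} where detected, 0 elsewhere. Vectorized.
#' @export
filter_reads <- function(recruited_reads, breadth, config = pipeline_config()) {
  stopifnot(length(recruited_reads) == length(breadth))
  if (any(recruited_reads < 0, na.rm = TRUE)) {
    stop("recruited_reads must be non-negative", call. = FALSE)
  }
  ifelse(call_detection(breadth, config), recruited_reads, 0)
}

#' Project filtered reads to genome completeness
#'
#' Scales filtered read counts by 100/completion so that an incomplete
#' genome is credited the reads its complete version would have recruited.
#' Genomes below the completion floor keep their actual counts, avoiding
#' explosive corrections from unreliable completion estimates. Results are
#' rounded half-up to whole reads.
#'
#' @param filtered_reads filtered read counts (post detection zeroing).
#' @param completion BUSCO-style completion percent of the genome.
#' @param config a \code{\link{pipeline_config}}.
#' @return projected integer read counts. Vectorized (completion recycled).
#' @export
#' @examples
#' cfg <- pipeline_config()
#' project_reads(1000, 50, cfg)  # 2000
#' project_reads(1000, 8, cfg)   # 1000: below the 10% floor, preserved
project_reads <- function(filtered_reads, completion, config = pipeline_config()) {
  validate_config(config)
  if (any(completion < 0 | completion > 100, na.rm = TRUE)) {
    stop("completion must be a percent in [0,100]", call. = FALSE)
  }
  if (any(filtered_reads < 0, na.rm = TRUE)) {
    stop("filtered_reads must be non-negative", call. = FALSE)
  }
  n <- max(length(filtered_reads), length(completion))
  filtered_reads <- rep_len(filtered_reads, n)
  completion <- rep_len(completion, n)
  scale <- ifelse(completion >= config$completion_floor, 100 / completion, 1)
  floor(filtered_reads * scale + 0.5)  # round half-up: reads are integral
}

#' Per-genome biogeography summary
#'
#' Applies detection, filtering and projection to a full recruitment table
#' and summarizes each genome: detected metagenomes and stations, total
#' filtered and projected reads, station count and cosmopolitan score over
#' a chosen metagenome subset.
#'
#' @param recruitment data.frame, \code{recruitment} schema.
#' @param metagenomes data.frame, \code{metagenomes} schema;
#'   \code{subset_labels} is a comma-separated label set.
#' @param genomes data.frame, \code{genomes} schema (for completion).
#' @param subset subset label defining the station panel for the
#'   cosmopolitan score, or NULL to use all metagenomes.
#' @param config a \code{\link{pipeline_config}}.
#' @return list with \code{profiles} (recruitment plus \code{detected},
#'   \code{filtered_reads}, \code{projected_reads} columns) and
#'   \code{summary} (one row per genome: \code{n_detected_metagenomes},
#'   \code{n_detected_stations}, \code{filtered_reads},
#'   \code{projected_reads}, \code{n_subset_stations_detected},
#'   \code{cosmopolitan_score}).
#' @export
biogeography_summary <- function(recruitment, metagenomes, genomes,
                                 subset = NULL, config = pipeline_config()) {
  validate_config(config)
  unknown <- setdiff(recruitment$metagenome_id, metagenomes$metagenome_id)
  if (length(unknown)) {
    stop("recruitment references unknown metagenome(s): ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(recruitment$genome_id, genomes$genome_id)
  if (length(unknown)) {
    stop("recruitment references unknown genome(s): ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  prof <- recruitment
  prof$detected <- call_detection(prof$breadth, config)
  prof$filtered_reads <- filter_reads(prof$recruited_reads, prof$breadth, config)
  completion <- stats::setNames(genomes$completion, genomes$genome_id)
  prof$projected_reads <- project_reads(prof$filtered_reads,
                                        completion[prof$genome_id], config)
  station <- stats::setNames(metagenomes$station_id, metagenomes$metagenome_id)
  prof$station_id <- unname(station[prof$metagenome_id])

  per_genome <- split(prof, prof$genome_id)
  gids <- names(per_genome)
  summary <- data.frame(
    genome_id = gids,
    n_detected_metagenomes = vapply(per_genome, function(d) sum(d$detected), integer(1)),
    n_detected_stations = vapply(per_genome, function(d)
      length(unique(d$station_id[d$detected])), integer(1)),
    filtered_reads = vapply(per_genome, function(d) sum(d$filtered_reads), numeric(1)),
    projected_reads = vapply(per_genome, function(d) sum(d$projected_reads), numeric(1)),
    stringsAsFactors = FALSE
  )
  cosmo <- vapply(gids, function(g)
    cosmopolitan_score(g, prof, metagenomes, subset, config, .checked = TRUE),
    numeric(2))
  summary$n_subset_stations_detected <- as.integer(cosmo[1, ])
  summary$cosmopolitan_score <- cosmo[2, ]
  rownames(summary) <- NULL
  list(profiles = prof, summary = summary)
}

.subset_metagenomes <- function(metagenomes, subset) {
  if (is.null(subset)) return(metagenomes)
  labels <- strsplit(metagenomes$subset_labels, ",", fixed = TRUE)
  hit <- vapply(labels, function(l) subset %in% trimws(l), logical(1))
  if (!any(hit)) stop("unknown subset label: ", subset, call. = FALSE)
  metagenomes[hit, , drop = FALSE]
}

#' Cosmopolitan score of one genome
#'
#' Fraction of the subset's stations at which the genome is detected in at
#' least one metagenome. Detection at the station level is the OR over that
#' station's metagenomes within the subset. The raw detected-station count
#' is returned alongside, as both scales are in use.
#'
#' @param genome_id genome to score.
#' @param profiles recruitment table, or the annotated profile table from
#'   \code{\link{biogeography_summary}}.
#' @param metagenomes data.frame, \code{metagenomes} schema.
#' @param subset subset label (for example \code{"station_subset_1"}) or
#'   NULL for all metagenomes.
#' @param config a \code{\link{pipeline_config}}.
#' @param .checked internal: skip re-derivation of detection columns.
#' @return named numeric vector \code{c(n_stations, score)} where
#'   \code{score} is in [0, 1].
#' @export
cosmopolitan_score <- function(genome_id, profiles, metagenomes, subset = NULL,
                               config = pipeline_config(), .checked = FALSE) {
  sub <- .subset_metagenomes(metagenomes, subset)
  stations <- unique(sub$station_id)
  if (!length(stations)) stop("subset contains no stations", call. = FALSE)
  p <- profiles[profiles$genome_id == genome_id &
                  profiles$metagenome_id %in% sub$metagenome_id, , drop = FALSE]
  if (!.checked) {
    p$detected <- call_detection(p$breadth, config)
    station <- stats::setNames(metagenomes$station_id, metagenomes$metagenome_id)
    p$station_id <- unname(station[p$metagenome_id])
  }
  n_det <- length(unique(p$station_id[p$detected]))
  c(n_stations = n_det, score = n_det / length(stations))
}

#' Fraction of the sequencing effort recruited
#'
#' Ratio of detection-filtered recruited reads (summed over all genomes and
#' metagenomes) to the total read count of the metagenome collection. The
#' per-metagenome breakdown is also returned, as the pooled and per-sample
#' views answer different questions.
#'
#' @param profiles annotated profile table from
#'   \code{\link{biogeography_summary}} (needs \code{filtered_reads}).
#' @param metagenomes data.frame, \code{metagenomes} schema.
#' @return list with \code{pooled} (scalar fraction) and
#'   \code{per_metagenome} (data.frame \code{metagenome_id},
#'   \code{fraction}).
#' @export
fraction_recruited <- function(profiles, metagenomes) {
  total <- sum(metagenomes$total_reads)
  if (total <= 0) stop("total read count is zero", call. = FALSE)
  pooled <- sum(profiles$filtered_reads) / total
  per <- vapply(metagenomes$metagenome_id, function(m) {
    tot <- metagenomes$total_reads[metagenomes$metagenome_id == m]
    sum(profiles$filtered_reads[profiles$metagenome_id == m]) / tot
  }, numeric(1))
  list(pooled = pooled,
       per_metagenome = data.frame(metagenome_id = metagenomes$metagenome_id,
                                   fraction = unname(per),
                                   stringsAsFactors = FALSE))
}
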