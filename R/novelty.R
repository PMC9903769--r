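#' @name marker_novelty
#' @title Novelty score from RNA polymerase marker genes
#'
#' @description
#' Each genome carries up to six marker genes: the two largest subunits of
#' the three DNA-dependent RNA polymerases. The best-hit percent identity
#' of each marker against a reference protein database summarizes how close
#' the genome is to anything already sequenced; the novelty score is 100
#' minus the unweighted mean of these identities, so a genome averaging 64\%
#' identity scores 36. For display, scores are clipped to the [30, 60]
#' window used in figure layers.
NULL

#' Novelty score for one genome
#'
#' @param identities numeric vector of best-hit percent identities, one per
#'   marker gene (1 to 6 values).
#' @return list: \code{n_markers}, \code{mean_identity},
#'   \code{novelty_score} (= 100 - mean identity).
#' @export
#' @examples
#' novelty_score(c(64, 64, 64))$novelty_score  # 36
novelty_score <- function(identities) {
  identities <- identities[!is.na(identities)]
  if (length(identities) < 1) {
    stop("novelty score undefined without marker hits", call. = FALSE)
  }
  if (length(identities) > 6) {
    stop("at most six RNA polymerase markers per genome", call. = FALSE)
  }
  if (any(identities < 0 | identities > 100)) {
    stop("identities must be percents in [0,100]", call. = FALSE)
  }
  m <- mean(identities)
  list(n_markers = length(identities), mean_identity = m,
       novelty_score = 100 - m)
}

#' Novelty table for a genome collection
#'
#' Computes one novelty score per genome with at least one marker hit.
#' When a genome carries several curated copies of the same marker, the
#' copies are averaged within the marker first, then across markers, and
#' the case is reported in \code{multi_copy}. Genomes in \code{genome_ids}
#' that have no marker hit are listed in \code{excluded}.
#'
#' @param hits data.frame, \code{markers} schema (\code{genome_id},
#'   \code{marker_id}, \code{best_hit_identity}).
#' @param genome_ids optional full genome id set used to report exclusions.
#' @param clip_range display clipping bounds, default \code{c(30, 60)}.
#' @return list with \code{results} (data.frame \code{genome_id},
#'   \code{n_markers}, \code{mean_identity}, \code{novelty_score},
#'   \code{novelty_display}), \code{excluded} (character) and
#'   \code{multi_copy} (data.frame \code{genome_id}, \code{marker_id},
#'   \code{n_copies}).
#' @export
novelty_table <- function(hits, genome_ids = NULL, clip_range = c(30, 60)) {
  stopifnot(length(clip_range) == 2, clip_range[1] <= clip_range[2])
  valid_markers <- as.vector(outer(c("RNAP-a", "RNAP-b"),
                                   c("polI", "polII", "polIII"), paste, sep = "-"))
  bad <- setdiff(unique(hits$marker_id), valid_markers)
  if (length(bad)) {
    stop("unknown marker id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!nrow(hits)) {
    return(list(results = data.frame(genome_id = character(0),
                                     n_markers = integer(0),
                                     mean_identity = numeric(0),
                                     novelty_score = numeric(0),
                                     novelty_display = numeric(0)),
                excluded = sort(unique(genome_ids)),
                multi_copy = data.frame(genome_id = character(0),
                                        marker_id = character(0),
                                        n_copies = integer(0))))
  }
  copies <- stats::aggregate(best_hit_identity ~ genome_id + marker_id,
                             data = hits, FUN = length)
  multi <- copies[copies$best_hit_identity > 1, c("genome_id", "marker_id",
                                                  "best_hit_identity")]
  names(multi)[3] <- "n_copies"
  # within-marker average first, then across markers
  per_marker <- stats::aggregate(best_hit_identity ~ genome_id + marker_id,
                                 data = hits, FUN = mean)
  res_list <- lapply(split(per_marker, per_marker$genome_id), function(d) {
    r <- novelty_score(d$best_hit_identity)
    data.frame(genome_id = d$genome_id[[1]], n_markers = r$n_markers,
               mean_identity = r$mean_identity,
               novelty_score = r$novelty_score, stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, res_list)
  rownames(results) <- NULL
  results <- results[order(results$genome_id), , drop = FALSE]
  results$novelty_display <- pmin(pmax(results$novelty_score, clip_range[1]),
                                  clip_range[2])
  excluded <- if (is.null(genome_ids)) character(0) else
    sort(setdiff(genome_ids, results$genome_id))
  rownames(results) <- NULL
  rownames(multi) <- NULL
  list(results = results, excluded = excluded, multi_copy = multi)
}
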