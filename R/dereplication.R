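#' @name dereplication
#' @title Genome dereplication by average nucleotide identity
#'
#' @description
#' A pair of genomes is redundant when its ANI exceeds 98\% with more than
#' 25\% of the smaller genome aligned (both inequalities strict). Redundant
#' pairs define a graph whose connected components are groups of redundant
#' genomes; the longest member of each group represents it, so the
#' representative set is the non-redundant database.
NULL

#' Decide whether one genome pair is redundant
#'
#' @param ani percent average nucleotide identity of the pair.
#' @param aligned_fraction_smaller aligned fraction of the smaller genome.
#' @param config a \code{\link{pipeline_config}}.
#' @return logical: \code{ani > ani_threshold} and
#'   \code{aligned_fraction_smaller > align_fraction_threshold},
#'   both strict. Vectorized over pairs.
#' @export
#' @examples
#' cfg <- pipeline_config()
#' is_redundant_pair(98.5, 0.30, cfg)  # TRUE
#' is_redundant_pair(98.0, 0.30, cfg)  # FALSE: boundary is exclusive
is_redundant_pair <- function(ani, aligned_fraction_smaller, config = pipeline_config()) {
  validate_config(config)
  stopifnot(is.numeric(ani), is.numeric(aligned_fraction_smaller))
  if (any(ani < 0 | ani > 100, na.rm = TRUE)) {
    stop("ani must be a percent in [0,100]", call. = FALSE)
  }
  if (any(aligned_fraction_smaller < 0 | aligned_fraction_smaller > 1, na.rm = TRUE)) {
    stop("aligned_fraction_smaller must be a fraction in [0,1]", call. = FALSE)
  }
  ani > config$ani_threshold &
    aligned_fraction_smaller > config$align_fraction_threshold
}

#' Dereplicate a genome set
#'
#' Builds the redundant-pair graph, extracts its connected components
#' (singleton genomes form their own component), and selects the longest
#' member of each component as representative. Length ties are broken by
#' the lexicographically smallest genome id.
#'
#' In \code{mode = "pairwise"} the transitive closure is not taken: genomes
#' are visited in decreasing length order and each genome is kept unless it
#' is redundant with an already-kept (longer) genome — a greedy variant in
#' which chains A-B, B-C with A-C non-redundant keep both A and C.
#'
#' @param genomes data.frame with the \code{genomes} schema
#'   (\code{genome_id}, \code{length}, ...).
#' @param pairs data.frame with the \code{pairs} schema; pairs absent from
#'   the table are treated as non-redundant.
#' @param config a \code{\link{pipeline_config}}.
#' @param mode \code{"components"} (default, transitive grouping) or
#'   \code{"pairwise"} (greedy longest-first removal).
#' @return list with elements \code{components} (data.frame
#'   \code{genome_id}, \code{component_id}, \code{representative_id},
#'   \code{is_representative}) and \code{representatives} (character vector
#'   of non-redundant genome ids, sorted).
#' @export
dereplicate <- function(genomes, pairs, config = pipeline_config(),
                        mode = c("components", "pairwise")) {
  mode <- match.arg(mode)
  validate_config(config)
  ids <- genomes$genome_id
  if (anyDuplicated(ids)) stop("duplicate genome ids", call. = FALSE)
  unknown <- setdiff(c(pairs$genome_a, pairs$genome_b), ids)
  if (length(unknown)) {
    stop("integrity error: pair references unknown genome id(s): ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  redundant <- pairs[is_redundant_pair(pairs$ani, pairs$aligned_fraction_smaller,
                                       config), , drop = FALSE]
  len <- stats::setNames(genomes$length, ids)

  if (mode == "components") {
    g <- igraph::graph_from_data_frame(
      redundant[c("genome_a", "genome_b")], directed = FALSE,
      vertices = data.frame(name = ids))
    comp <- igraph::components(g)$membership[ids]
  } else {
    # greedy: longest first; drop a genome redundant with any kept genome
    ord <- ids[order(-len[ids], ids)]
    pairkey <- c(paste(redundant$genome_a, redundant$genome_b, sep = "\r"),
                 paste(redundant$genome_b, redundant$genome_a, sep = "\r"))
    kept <- character(0)
    owner <- stats::setNames(ids, ids)
    for (id in ord) {
      hit <- kept[paste(id, kept, sep = "\r") %in% pairkey]
      if (length(hit)) {
        owner[id] <- hit[[1]]
      } else {
        kept <- c(kept, id)
      }
    }
    comp <- match(owner[ids], unique(owner[ids]))
    names(comp) <- ids
  }

  rep_of <- vapply(split(ids, comp[ids]), function(members) {
    mx <- members[len[members] == max(len[members])]
    sort(mx)[[1]]
  }, character(1))
  components <- data.frame(
    genome_id = ids,
    component_id = as.integer(comp[ids]),
    representative_id = unname(rep_of[as.character(comp[ids])]),
    stringsAsFactors = FALSE
  )
  components$is_representative <-
    components$genome_id == components$representative_id
  list(components = components,
       representatives = sort(unique(components$representative_id)))
}
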