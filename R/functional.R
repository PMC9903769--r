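#' @name functional_landscape
#' @title Function occurrence matrices, clustering and differential tests
#'
#' @description
#' Gene annotations (gene -> genome, orthologous group) are tallied into a
#' genome x function occurrence matrix. Genomes are classified by
#' agglomerative clustering of their occurrence profiles (Euclidean
#' distance, Ward linkage) after removing problem genomes and functions
#' that occur more than 500 times in the giga-scale reference genome while
#' being retrotransposon-linked (such repeat-driven functions connect
#' otherwise unrelated genomes). Per-function differences between the
#' resulting groups are tested with Welch's heteroscedastic ANOVA at a raw
#' p < 1e-5 cut, followed by Games-Howell pairwise comparisons for the
#' significant functions. Remote-homology gene clusters receive a
#' majority-vote consensus annotation, clusters with the same resolved
#' consensus are merged, and rare groups (< 2\% of genomes) are excluded.
NULL

#' Build a genome x function occurrence matrix
#'
#' @param annotations data.frame, \code{annotations} schema. Genes with no
#'   orthologous-group assignment (\code{og_id} empty or NA) are ignored.
#' @param genomes data.frame, \code{genomes} schema; defines the row set so
#'   genomes without annotated genes appear as all-zero rows.
#' @return integer matrix, rows = genome ids, columns = function ids;
#'   attribute \code{unannotated_genomes} lists all-zero rows.
#' @export
build_occurrence_matrix <- function(annotations, genomes) {
  unknown <- setdiff(annotations$genome_id, genomes$genome_id)
  if (length(unknown)) {
    stop("annotations reference unknown genome(s): ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  ann <- annotations[!is.na(annotations$og_id) & nzchar(annotations$og_id), ,
                     drop = FALSE]
  gids <- sort(genomes$genome_id)
  fids <- sort(unique(ann$og_id))
  mat <- matrix(0L, nrow = length(gids), ncol = length(fids),
                dimnames = list(gids, fids))
  if (nrow(ann)) {
    tab <- table(factor(ann$genome_id, levels = gids),
                 factor(ann$og_id, levels = fids))
    mat[] <- as.integer(tab)
  }
  attr(mat, "unannotated_genomes") <- gids[rowSums(mat) == 0]
  mat
}

#' Functional redundancy of one genome
#'
#' Fraction of a genome's annotated genes whose function occurs more than
#' once in that genome: the summed occurrence over functions with count >= 2
#' divided by the total annotated gene count.
#'
#' @param matrix occurrence matrix from \code{\link{build_occurrence_matrix}}.
#' @param genome_id row to evaluate; omit to get the full named vector
#'   (NA for genomes without annotated genes).
#' @return fraction in [0, 1], or a named vector over all genomes.
#' @export
#' @examples
#' m <- matrix(c(3, 1), 1, dimnames = list("g1", c("f1", "f2")))
#' functional_redundancy(m, "g1")  # 3/4
functional_redundancy <- function(matrix, genome_id = NULL) {
  one <- function(row) {
    tot <- sum(row)
    if (tot == 0) return(NA_real_)
    sum(row[row >= 2]) / tot
  }
  if (!is.null(genome_id)) {
    if (!genome_id %in% rownames(matrix)) {
      stop("unknown genome id: ", genome_id, call. = FALSE)
    }
    r <- one(matrix[genome_id, ])
    if (is.na(r)) stop("genome has no annotated genes: ", genome_id, call. = FALSE)
    return(r)
  }
  apply(matrix, 1, one)
}

#' Filter the occurrence matrix before clustering
#'
#' Drops excluded genome rows (e.g. lineages with unreliable gene calling,
#' low-completion outliers) and function columns whose occurrence in the
#' designated reference genome exceeds the cap (strictly) while also being
#' flagged as retrotransposon-linked in the function metadata. Both
#' conditions must hold for a column to be dropped.
#'
#' @param matrix occurrence matrix.
#' @param exclusions genome ids to drop (may be empty).
#' @param cap_reference_genome genome whose occurrence counts the cap is
#'   applied to (the giga-scale assembly in the original analysis).
#' @param function_meta data.frame, \code{function_meta} schema
#'   (\code{og_id}, \code{is_retrotransposon}); functions absent from the
#'   table are treated as unflagged.
#' @param config a \code{\link{pipeline_config}}.
#' @return filtered matrix with attributes \code{dropped_genomes} and
#'   \code{dropped_functions}.
#' @export
filter_functions <- function(matrix, exclusions = character(0),
                             cap_reference_genome, function_meta = NULL,
                             config = pipeline_config()) {
  validate_config(config)
  if (!cap_reference_genome %in% rownames(matrix)) {
    stop("cap reference genome not in matrix: ", cap_reference_genome,
         call. = FALSE)
  }
  flagged <- character(0)
  if (!is.null(function_meta)) {
    flagged <- function_meta$og_id[isTRUE_vec(function_meta$is_retrotransposon)]
  }
  refcounts <- matrix[cap_reference_genome, ]
  drop_f <- colnames(matrix)[refcounts > config$occurrence_cap &
                               colnames(matrix) %in% flagged]
  keep_g <- setdiff(rownames(matrix), exclusions)
  out <- matrix[keep_g, setdiff(colnames(matrix), drop_f), drop = FALSE]
  attr(out, "dropped_genomes") <- intersect(exclusions, rownames(matrix))
  attr(out, "dropped_functions") <- drop_f
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Cluster genomes by functional profile
#'
#' Agglomerative clustering of occurrence rows with Euclidean distance and
#' Ward linkage. Outgroup genomes (e.g. small animals used to root the
#' dendrogram) take part in the clustering for display, but functional
#' groups are extracted by cutting a dendrogram rebuilt on the non-outgroup
#' genomes only into \code{group_count} groups. Group labels A, B, C, ...
#' are assigned in order of first appearance along the dendrogram leaf
#' ordering, which makes labels deterministic and invariant to genome input
#' order.
#'
#' @param matrix (filtered) occurrence matrix.
#' @param outgroup genome ids clustered but excluded from group extraction.
#' @param config a \code{\link{pipeline_config}} (\code{group_count}).
#' @param transform \code{"none"} (default) to cluster raw counts or
#'   \code{"log10"} for log10(x + 1).
#' @return list with \code{assignments} (data.frame \code{genome_id},
#'   \code{group_label}, \code{outgroup_flag}), \code{hclust_full} and
#'   \code{hclust_groups} (stats::hclust objects over all and non-outgroup
#'   genomes).
#' @export
cluster_genomes <- function(matrix, outgroup = character(0),
                            config = pipeline_config(),
                            transform = c("none", "log10")) {
  validate_config(config)
  transform <- match.arg(transform)
  x <- matrix[sort(rownames(matrix)), , drop = FALSE]  # order invariance
  if (transform == "log10") x <- log10(x + 1)
  core <- setdiff(rownames(x), outgroup)
  k <- config$group_count
  if (length(core) < k + 1) {
    stop("need at least group_count + 1 non-outgroup genomes", call. = FALSE)
  }
  hc_full <- stats::hclust(stats::dist(x, method = "euclidean"),
                           method = "ward.D2")
  hc_core <- stats::hclust(stats::dist(x[core, , drop = FALSE],
                                       method = "euclidean"),
                           method = "ward.D2")
  cut <- stats::cutree(hc_core, k = k)
  # label groups by first appearance along the dendrogram leaf order
  leaf_order <- hc_core$labels[hc_core$order]
  first_seen <- unique(cut[leaf_order])
  relabel <- stats::setNames(LETTERS[seq_len(k)], first_seen)
  assignments <- data.frame(
    genome_id = rownames(x),
    group_label = ifelse(rownames(x) %in% core,
                         unname(relabel[as.character(cut[rownames(x)])]),
                         NA_character_),
    outgroup_flag = rownames(x) %in% outgroup,
    stringsAsFactors = FALSE
  )
  rownames(assignments) <- NULL
  list(assignments = assignments, hclust_full = hc_full,
       hclust_groups = hc_core)
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' With group weights \eqn{w_i = n_i / s_i^2} and weighted grand mean
#' \eqn{\bar{x}_w = \sum w_i \bar{x}_i / \sum w_i}, the statistic is
#' \deqn{F = \frac{\sum w_i (\bar{x}_i - \bar{x}_w)^2 / (k - 1)}
#'   {1 + \frac{2(k-2)}{k^2-1} \sum \frac{(1 - w_i/\sum w)^2}{n_i - 1}}}
#' with \eqn{df_1 = k - 1} and
#' \eqn{df_2 = (k^2 - 1) / (3 \sum (1 - w_i/\sum w)^2 / (n_i - 1))};
#' the p value is the upper tail of the F distribution. Unlike the
#' classical ANOVA the group variances are not pooled, which suits
#' occurrence counts whose spread differs strongly between groups.
#'
#' @param values list of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 observations and nonzero variance).
#' @return list: \code{F}, \code{df1}, \code{df2}, \code{p_value}.
#' @export
welch_anova <- function(values) {
  k <- length(values)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  n <- vapply(values, length, numeric(1))
  if (any(n < 2)) stop("each group needs at least two observations", call. = FALSE)
  s2 <- vapply(values, stats::var, numeric(1))
  if (any(s2 <= 0)) stop("a group has zero variance", call. = FALSE)
  m <- vapply(values, mean, numeric(1))
  w <- n / s2
  sw <- sum(w)
  mw <- sum(w * m) / sw
  a <- sum((1 - w / sw)^2 / (n - 1))
  num <- sum(w * (m - mw)^2) / (k - 1)
  den <- 1 + 2 * (k - 2) / (k^2 - 1) * a
  f <- num / den
  df2 <- (k^2 - 1) / (3 * a)
  list(F = f, df1 = k - 1, df2 = df2,
       p_value = stats::pf(f, k - 1, df2, lower.tail = FALSE))
}

# Vectorized Welch ANOVA over the columns of a matrix, given a group factor
# on the rows. Returns a data.frame; columns with a zero-variance group get
# NA statistics and a skip reason.
.welch_anova_matrix <- function(mat, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  n <- as.numeric(table(groups))
  idx <- split(seq_along(groups), groups)
  means <- vapply(idx, function(i) colMeans(mat[i, , drop = FALSE]),
                  numeric(ncol(mat)))
  means <- matrix(means, nrow = ncol(mat))
  vars <- vapply(seq_along(idx), function(j) {
    i <- idx[[j]]
    colSums((mat[i, , drop = FALSE] -
               matrix(means[, j], length(i), ncol(mat), byrow = TRUE))^2) /
      (n[j] - 1)
  }, numeric(ncol(mat)))
  vars <- matrix(vars, nrow = ncol(mat))
  bad <- rowSums(vars <= 0) > 0            # per function: any zero-variance group
  w <- sweep(1 / vars, 2, n, "*")          # n_i / s_i^2, per function x group
  sw <- rowSums(w)
  mw <- rowSums(w * means) / sw
  a <- rowSums(sweep((1 - w / sw)^2, 2, n - 1, "/"))
  num <- rowSums(w * (means - mw)^2) / (k - 1)
  den <- 1 + 2 * (k - 2) / (k^2 - 1) * a
  f <- num / den
  df2 <- (k^2 - 1) / (3 * a)
  p <- stats::pf(f, k - 1, df2, lower.tail = FALSE)
  f[bad] <- NA_real_; df2[bad] <- NA_real_; p[bad] <- NA_real_
  data.frame(function_id = colnames(mat), welch_F = f, df1 = k - 1,
             df2 = df2, p_value = p,
             skipped = bad,
             skip_reason = ifelse(bad, "zero variance in a group", ""),
             stringsAsFactors = FALSE)
}

#' Games-Howell pairwise comparison
#'
#' For groups i, j the statistic is
#' \eqn{t = (\bar{x}_i - \bar{x}_j) / \sqrt{s_i^2/n_i + s_j^2/n_j}} with
#' Welch-Satterthwaite degrees of freedom; the p value comes from the
#' studentized-range distribution with \eqn{q = |t| \sqrt{2}} and the total
#' number of groups, which keeps the familywise error of the all-pairs
#' comparison controlled without assuming equal variances.
#'
#' @param values list of per-group numeric vectors (all groups, for the
#'   studentized-range span).
#' @param pair integer or character vector of length 2 naming the two
#'   groups compared; default compares all pairs.
#' @return data.frame: \code{group_i}, \code{group_j},
#'   \code{mean_difference}, \code{t}, \code{df}, \code{p_value}.
#' @export
games_howell <- function(values, pair = NULL) {
  k <- length(values)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  if (is.null(names(values))) names(values) <- as.character(seq_len(k))
  n <- vapply(values, length, numeric(1))
  if (any(n < 2)) stop("each group needs at least two observations", call. = FALSE)
  m <- vapply(values, mean, numeric(1))
  s2 <- vapply(values, stats::var, numeric(1))
  pairs <- if (is.null(pair)) {
    utils::combn(names(values), 2, simplify = FALSE)
  } else {
    list(as.character(if (is.numeric(pair)) names(values)[pair] else pair))
  }
  rows <- lapply(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    se2 <- s2[i] / n[i] + s2[j] / n[j]
    if (se2 <= 0) stop("zero pooled variance for pair ", i, "-", j, call. = FALSE)
    t <- (m[i] - m[j]) / sqrt(se2)
    df <- se2^2 / ((s2[i] / n[i])^2 / (n[i] - 1) + (s2[j] / n[j])^2 / (n[j] - 1))
    p <- stats::ptukey(abs(t) * sqrt(2), nmeans = k, df = df, lower.tail = FALSE)
    data.frame(group_i = i, group_j = j, mean_difference = unname(m[i] - m[j]),
               t = unname(t), df = unname(df), p_value = unname(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Differential occurrence of functions between groups
#'
#' Runs a Welch ANOVA per function across the functional groups; functions
#' with p below the configured threshold are marked significant and receive
#' Games-Howell pairwise results. Functions with a zero-variance group are
#' skipped with a recorded reason. No multiple-testing correction is
#' applied to the significance call (the raw p < 1e-5 rule); Benjamini-
#' Hochberg q-values are reported alongside for transparency.
#'
#' @param matrix (filtered) occurrence matrix.
#' @param groups assignment data.frame from \code{\link{cluster_genomes}}
#'   (\code{genome_id}, \code{group_label}; outgroup/NA rows are ignored).
#' @param config a \code{\link{pipeline_config}}.
#' @param top_n size of the lowest-p display list (default 100).
#' @return list with \code{results} (per-function data.frame sorted by p:
#'   \code{function_id}, group means, \code{welch_F}, \code{df1},
#'   \code{df2}, \code{p_value}, \code{q_value}, \code{significant},
#'   \code{skipped}, \code{skip_reason}), \code{games_howell} (data.frame
#'   over significant functions only) and \code{top} (the \code{top_n}
#'   lowest-p function ids).
#' @export
differential_functions <- function(matrix, groups, config = pipeline_config(),
                                   top_n = 100L) {
  validate_config(config)
  g <- groups[!is.na(groups$group_label), , drop = FALSE]
  g <- g[g$genome_id %in% rownames(matrix), , drop = FALSE]
  mat <- matrix[g$genome_id, , drop = FALSE]
  fac <- factor(g$group_label)
  res <- .welch_anova_matrix(mat, fac)
  for (lev in levels(fac)) {
    res[[paste0("mean_", lev)]] <-
      colMeans(mat[fac == lev, , drop = FALSE])[res$function_id]
  }
  res$q_value <- NA_real_
  ok <- !res$skipped
  res$q_value[ok] <- stats::p.adjust(res$p_value[ok], method = "BH")
  res$significant <- ok & res$p_value < config$anova_p_threshold
  res <- res[order(res$p_value, res$function_id), , drop = FALSE]
  rownames(res) <- NULL

  gh <- lapply(res$function_id[res$significant], function(f) {
    vals <- split(mat[, f], fac)
    out <- tryCatch(games_howell(vals), error = function(e) NULL)
    if (is.null(out)) return(NULL)
    cbind(function_id = f, out, stringsAsFactors = FALSE)
  })
  gh <- do.call(rbind, gh)
  if (is.null(gh)) {
    gh <- data.frame(function_id = character(0), group_i = character(0),
                     group_j = character(0), mean_difference = numeric(0),
                     t = numeric(0), df = numeric(0), p_value = numeric(0))
  }
  rownames(gh) <- NULL
  list(results = res, games_howell = gh,
       top = utils::head(res$function_id[!res$skipped], top_n))
}

#' Consensus annotation of remote-homology gene clusters
#'
#' Each gene cluster inherits the orthologous-group label carried by a
#' strict majority (> 1/2) of its annotated member genes; clusters without
#' such a majority are "unresolved" and treated as unknown-function.
#' Clusters sharing an identical resolved consensus are merged into one
#' group; unknown-function clusters pass through unmerged.
#'
#' @param annotations data.frame, \code{annotations} schema, with
#'   \code{agnostos_cluster} set for clustered genes.
#' @return data.frame: \code{group_id}, \code{consensus_og} ("unknown" for
#'   unresolved/unannotated), \code{member_clusters} (comma-separated
#'   source cluster ids), \code{n_genes}.
#' @export
consensus_annotation <- function(annotations) {
  ann <- annotations[!is.na(annotations$agnostos_cluster) &
                       nzchar(annotations$agnostos_cluster), , drop = FALSE]
  if (!nrow(ann)) {
    return(data.frame(group_id = character(0), consensus_og = character(0),
                      member_clusters = character(0), n_genes = integer(0)))
  }
  per_cluster <- split(ann, ann$agnostos_cluster)
  cons <- vapply(per_cluster, function(d) {
    labs <- d$og_id[isTRUE_vec(d$og_known) & !is.na(d$og_id) & nzchar(d$og_id)]
    if (!length(labs)) return("unknown")
    tab <- sort(table(labs), decreasing = TRUE)
    if (tab[[1]] * 2 > length(labs)) names(tab)[[1]] else "unknown"
  }, character(1))
  n_genes <- vapply(per_cluster, nrow, integer(1))
  cl_ids <- names(per_cluster)
  merged_key <- ifelse(cons == "unknown", paste0("cluster:", cl_ids),
                       paste0("og:", cons))
  rows <- lapply(split(seq_along(cl_ids), merged_key), function(i) {
    data.frame(
      group_id = if (startsWith(merged_key[i[[1]]], "og:")) {
        paste0("CG_", sub("^og:", "", merged_key[i[[1]]]))
      } else cl_ids[i[[1]]],
      consensus_og = if (startsWith(merged_key[i[[1]]], "og:")) {
        sub("^og:", "", merged_key[i[[1]]])
      } else "unknown",
      member_clusters = paste(sort(cl_ids[i]), collapse = ","),
      n_genes = sum(n_genes[i]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$group_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Prevalence filter for consensus gene groups
#'
#' Retains groups occurring in at least the configured fraction of the
#' analyzed genomes (groups in strictly less than 2\% of genomes, by
#' default, are excluded).
#'
#' @param groups consensus groups from \code{\link{consensus_annotation}}.
#' @param annotations data.frame, \code{annotations} schema (to locate the
#'   genomes carrying each member cluster).
#' @param genome_ids the analyzed genome set (prevalence denominator).
#' @param config a \code{\link{pipeline_config}}.
#' @return \code{groups} with a \code{prevalence} column, rows failing the
#'   filter removed; attribute \code{excluded} holds the removed group ids.
#' @export
prevalence_filter <- function(groups, annotations, genome_ids,
                              config = pipeline_config()) {
  validate_config(config)
  cl2g <- split(annotations$genome_id, annotations$agnostos_cluster)
  prev <- vapply(groups$member_clusters, function(mc) {
    cls <- strsplit(mc, ",", fixed = TRUE)[[1]]
    g <- unique(unlist(cl2g[cls], use.names = FALSE))
    length(intersect(g, genome_ids)) / length(genome_ids)
  }, numeric(1))
  groups$prevalence <- unname(prev)
  keep <- groups$prevalence >= config$min_group_prevalence
  out <- groups[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- groups$group_id[!keep]
  out
}
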