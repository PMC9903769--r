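cfg <- pipeline_config()

mk_ann <- function(genome, og, known = TRUE, cluster = "") {
  n <- max(length(genome), length(og))
  data.frame(gene_id = sprintf("gene%04d", sample.int(1e4, n)),
             genome_id = rep_len(genome, n), og_id = rep_len(og, n),
             og_known = rep_len(known, n),
             agnostos_cluster = rep_len(cluster, n), stringsAsFactors = FALSE)
}

test_that("occurrence matrix counts genes per genome and function", {
  genomes <- make_genomes(c("g1", "g2"), c(2e7, 3e7))
  ann <- mk_ann("g1", c("f1", "f1", "f2"))
  m <- build_occurrence_matrix(ann, genomes)
  expect_equal(m["g1", c("f1", "f2")], c(f1 = 2L, f2 = 1L))
  expect_equal(sum(m["g2", ]), 0L)
  expect_equal(attr(m, "unannotated_genomes"), "g2")
  # unannotated genes are ignored
  ann2 <- rbind(ann, mk_ann("g1", ""))
  expect_equal(build_occurrence_matrix(ann2, genomes)["g1", ],
               m["g1", ])
  expect_error(build_occurrence_matrix(mk_ann("gX", "f1"), genomes),
               "unknown genome")
})

test_that("matrix row sums equal annotated gene counts on synthetic data", {
  spec <- simulation_spec(n_genomes = 20, rng_seed = 9)
  gen <- simulate_genomes(spec)
  sim <- simulate_annotations(spec, gen$genomes, gen$truth$group_label)
  m <- build_occurrence_matrix(sim$annotations, gen$genomes)
  tally <- table(sim$annotations$genome_id[nzchar(sim$annotations$og_id)])
  expect_equal(rowSums(m)[names(tally)], unclass(c(tally)),
               ignore_attr = TRUE)
  expect_equal(m[rownames(sim$truth$counts), colnames(sim$truth$counts)],
               sim$truth$counts, ignore_attr = TRUE)
})

test_that("functional redundancy follows its definition", {
  m <- matrix(c(3, 1, 0,
                1, 1, 1,
                0, 0, 4), 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"), c("f1", "f2", "f3")))
  expect_equal(functional_redundancy(m, "gA"), 3 / 4)
  expect_equal(functional_redundancy(m, "gB"), 0)   # all singletons
  expect_equal(functional_redundancy(m, "gC"), 1)   # one function, all genes
  # duplicating every gene sends redundancy to 1
  expect_true(all(functional_redundancy(m * 2) == 1))
  m0 <- rbind(m, gD = c(0, 0, 0))
  expect_error(functional_redundancy(m0, "gD"), "no annotated genes")
  expect_true(is.na(functional_redundancy(m0)["gD"]))
})

test_that("function filter requires both the cap excess and the flag", {
  m <- matrix(c(600, 600, 500, 10), 1,
              dimnames = list("big", c("fA", "fB", "fC", "fD")))
  m <- rbind(m, other = c(1, 1, 1, 1))
  meta <- data.frame(og_id = c("fA", "fC"), is_retrotransposon = TRUE)
  out <- filter_functions(m, exclusions = "other",
                          cap_reference_genome = "big",
                          function_meta = meta, config = cfg)
  expect_equal(attr(out, "dropped_functions"), "fA")  # 600 & flagged
  expect_true("fB" %in% colnames(out))  # 600, unflagged
  expect_true("fC" %in% colnames(out))  # flagged but exactly 500: strict cap
  expect_equal(rownames(out), "big")
  expect_equal(attr(out, "dropped_genomes"), "other")
  expect_error(filter_functions(m, cap_reference_genome = "nope"),
               "reference genome")
})

test_that("clustering is deterministic, order-invariant and metric-sane", {
  set.seed(4)
  m <- matrix(rpois(60 * 30, 2), 60, 30,
              dimnames = list(sprintf("g%02d", 1:60), sprintf("f%02d", 1:30)))
  m["g02", ] <- m["g01", ]  # identical profiles
  cl <- cluster_genomes(m, config = cfg)
  h <- cl$hclust_groups
  pair_height <- h$height[[which.max(
    apply(h$merge, 1, function(r) all(r < 0) &&
            setequal(h$labels[-r], c("g01", "g02"))))]]
  expect_equal(pair_height, 0)
  # permuting input rows changes nothing
  cl2 <- cluster_genomes(m[sample(rownames(m)), ], config = cfg)
  expect_equal(cl$assignments, cl2$assignments)
  expect_error(cluster_genomes(m[1:4, ], config = cfg), "group_count")
})

test_that("outgroup genomes are clustered but excluded from groups", {
  spec <- simulation_spec(n_genomes = 40, n_functions = 200, rng_seed = 12)
  gen <- simulate_genomes(spec)
  sim <- simulate_annotations(spec, gen$genomes, gen$truth$group_label)
  m <- build_occurrence_matrix(sim$annotations, gen$genomes)
  og <- rownames(m)[1:3]
  cl <- cluster_genomes(m, outgroup = og, config = cfg)
  a <- cl$assignments
  expect_true(all(is.na(a$group_label[a$outgroup_flag])))
  expect_true(all(!is.na(a$group_label[!a$outgroup_flag])))
  expect_setequal(unique(na.omit(a$group_label)), LETTERS[1:4])
})

test_that("Welch ANOVA matches a direct transcription of its formula", {
  set.seed(21)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j)
      rnorm(sample(5:30, 1), mean = runif(1, 0, 3), sd = runif(1, 0.5, 3)))
    got <- welch_anova(groups)
    want <- welch_oracle(groups)
    expect_equal(got$F, want$F)
    expect_equal(got$df2, want$df2)
    expect_equal(got$p_value, want$p)
    # and agrees with the stock heteroscedastic one-way test
    dat <- data.frame(y = unlist(groups),
                      g = factor(rep(seq_len(k), lengths(groups))))
    ref <- oneway.test(y ~ g, dat, var.equal = FALSE)
    expect_equal(got$F, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Welch ANOVA handles balanced no-signal and degenerate groups", {
  g1 <- c(1, 2, 3, 4)
  res <- welch_anova(list(g1, g1, g1))  # identical groups
  expect_equal(res$F, 0)
  expect_equal(res$p_value, 1)
  expect_error(welch_anova(list(g1)), "two groups")
  expect_error(welch_anova(list(g1, c(2, 2, 2))), "zero variance")
  expect_error(welch_anova(list(g1, 5)), "two observations")
})

test_that("the vectorized per-function Welch scan agrees with the scalar path", {
  set.seed(31)
  mat <- matrix(rnorm(40 * 25, mean = 2), 40, 25,
                dimnames = list(NULL, sprintf("f%02d", 1:25)))
  groups <- factor(rep(LETTERS[1:4], each = 10))
  scan <- magscape:::.welch_anova_matrix(mat, groups)
  for (j in c(1, 7, 25)) {
    ref <- welch_anova(split(mat[, j], groups))
    expect_equal(scan$welch_F[j], ref$F)
    expect_equal(scan$p_value[j], ref$p_value)
    expect_equal(scan$df2[j], ref$df2)
  }
})

test_that("Games-Howell behaves on identical, separated and symmetric input", {
  set.seed(41)
  same <- list(A = c(5, 6, 7, 8, 9), B = c(5, 6, 7, 8, 9),
               C = rnorm(5, 7))
  gh <- games_howell(same, pair = c("A", "B"))
  expect_equal(gh$mean_difference, 0)
  expect_gt(gh$p_value, 0.999)
  # large separation at n = 50 is detected far below 1e-5
  far <- list(A = rnorm(50, 0), B = rnorm(50, 10), C = rnorm(50, 0.2))
  expect_lt(games_howell(far, pair = c("A", "B"))$p_value, 1e-5)
  # antisymmetry of the difference, symmetry of p
  ab <- games_howell(far, pair = c("A", "C"))
  ba <- games_howell(far, pair = c("C", "A"))
  expect_equal(ab$mean_difference, -ba$mean_difference)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("differential scan flags planted markers and skips constants", {
  spec <- simulation_spec(n_genomes = 80, n_functions = 100,
                          group_effect_size = 6, rng_seed = 17)
  gen <- simulate_genomes(spec)
  sim <- simulate_annotations(spec, gen$genomes, gen$truth$group_label)
  m <- build_occurrence_matrix(sim$annotations, gen$genomes)
  m <- cbind(m, CONST = 5L)  # constant everywhere -> zero variance
  groups <- data.frame(genome_id = names(sim$truth$group_labels),
                       group_label = unname(sim$truth$group_labels))
  d <- differential_functions(m, groups, cfg)
  markers <- unlist(sim$truth$marker_functions, use.names = FALSE)
  res <- d$results
  expect_true(all(res$significant[res$function_id %in% markers]))
  expect_true(res$skipped[res$function_id == "CONST"])
  expect_match(res$skip_reason[res$function_id == "CONST"], "zero variance")
  # Games-Howell emitted only for significant functions
  expect_setequal(unique(d$games_howell$function_id),
                  res$function_id[res$significant])
  # results sorted by p; top list excludes skipped functions
  expect_false(is.unsorted(res$p_value[!res$skipped]))
  expect_false("CONST" %in% d$top)
})

test_that("consensus annotation is strict-majority with merging", {
  ann <- rbind(
    mk_ann("g1", c("K1", "K1", "K2"), known = TRUE, cluster = "c1"),
    mk_ann("g1", c("K1", "K2"), known = TRUE, cluster = "c2"),
    mk_ann("g2", c("K7", "K7"), known = TRUE, cluster = "c3"),
    mk_ann("g3", c("K7", "K7", "K8"), known = TRUE, cluster = "c4"),
    mk_ann("g3", "", known = FALSE, cluster = "c5"))
  cons <- consensus_annotation(ann)
  expect_equal(cons$consensus_og[cons$member_clusters == "c1"], "K1")
  expect_equal(cons$consensus_og[cons$member_clusters == "c2"], "unknown")
  # c3 and c4 share consensus K7 -> merged
  merged <- cons[cons$consensus_og == "K7", ]
  expect_equal(nrow(merged), 1)
  expect_equal(merged$member_clusters, "c3,c4")
  expect_equal(merged$n_genes, 5L)
  # unresolved and unannotated clusters pass through unmerged
  expect_equal(sum(cons$consensus_og == "unknown"), 2)
  expect_setequal(cons$member_clusters[cons$consensus_og == "unknown"],
                  c("c2", "c5"))
})

test_that("prevalence filter excludes groups below the 2% floor, boundary inclusive", {
  genomes <- sprintf("g%03d", 1:100)
  ann <- rbind(
    mk_ann("g001", "K1", cluster = "rare"),
    mk_ann(c("g001", "g002"), "K2", cluster = "edge"),
    mk_ann(genomes, "K3", cluster = "everywhere"))
  cons <- consensus_annotation(ann)
  kept <- prevalence_filter(cons, ann, genomes, cfg)
  kept_clusters <- kept$member_clusters
  expect_false(any(grepl("rare", kept_clusters)))        # 1/100 < 0.02
  expect_true(any(grepl("edge", kept_clusters)))         # 2/100 retained
  expect_true(any(grepl("everywhere", kept_clusters)))
  expect_equal(kept$prevalence[grepl("edge", kept$member_clusters)], 0.02)
})
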