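# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths.

# Brute-force transitive closure of a redundancy relation: boolean adjacency
# matrix powered to a fixed point; components read off the closure rows.
closure_components <- function(ids, red_a, red_b) {
  n <- length(ids)
  adj <- diag(TRUE, n)
  dimnames(adj) <- list(ids, ids)
  for (k in seq_along(red_a)) {
    adj[red_a[k], red_b[k]] <- TRUE
    adj[red_b[k], red_a[k]] <- TRUE
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (all(nxt == adj)) break
    adj <- nxt
  }
  # component label = smallest reachable id
  vapply(ids, function(i) min(ids[adj[i, ]]), character(1))
}

# partition equality up to relabeling
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  key_a <- as.integer(factor(a, levels = unique(a)))
  key_b <- as.integer(factor(b, levels = unique(b)))
  all(tapply(key_b, key_a, function(x) length(unique(x))) == 1) &&
    all(tapply(key_a, key_b, function(x) length(unique(x))) == 1)
}

# minimal genome table
make_genomes <- function(ids, lengths, completion = 50) {
  n <- length(ids)
  data.frame(genome_id = ids, length = lengths,
             completion = rep_len(completion, n),
             redundancy = rep_len(0, n),
             lineage = rep_len("Stramenopiles", n),
             source = rep_len("MAG", n),
             is_phytoplankton = rep_len(FALSE, n), stringsAsFactors = FALSE)
}

make_pairs <- function(a, b, ani, frac) {
  data.frame(genome_a = a, genome_b = b, ani = ani,
             aligned_fraction_smaller = frac, stringsAsFactors = FALSE)
}

# direct transcription of the Welch heteroscedastic F formula, computed
# step by step on scalars (oracle for welch_anova)
welch_oracle <- function(groups) {
  k <- length(groups)
  n <- sapply(groups, length)
  m <- sapply(groups, mean)
  s2 <- sapply(groups, var)
  w <- n / s2
  mw <- sum(w * m) / sum(w)
  a <- sum((1 - w / sum(w))^2 / (n - 1))
  f <- (sum(w * (m - mw)^2) / (k - 1)) / (1 + 2 * (k - 2) / (k^2 - 1) * a)
  df2 <- (k^2 - 1) / (3 * a)
  list(F = f, df1 = k - 1, df2 = df2,
       p = pf(f, k - 1, df2, lower.tail = FALSE))
}

# Gaussian-envelope probability computed independently from a fitted model
envelope_prob <- function(model, env_row) {
  z <- (unlist(env_row[magscape:::ENV_PARAMS]) - model$standardization$mean) /
    model$standardization$sd
  d2 <- mean(((z - model$parameter_means) / model$parameter_spreads)^2)
  exp(-0.5 * model$kappa * d2)
}

# station environments with independent scatter in all seven parameters
make_stations_acc <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(station_id = sprintf("S%03d", seq_len(n)),
             sst = runif(n, -2, 30), salinity = runif(n, 32, 37),
             silicate = runif(n, 0, 50), nitrate = runif(n, 0, 30),
             phosphate = runif(n, 0, 2), iron = runif(n, 0, 0.6),
             si_no3 = runif(n), stringsAsFactors = FALSE)
}

# a small all-ocean grid with arbitrary environments
make_grid <- function(lat, lon, env) {
  g <- data.frame(lat = lat, lon = lon, ocean = TRUE)
  for (p in magscape:::ENV_PARAMS) g[[p]] <- env[[p]]
  g
}
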