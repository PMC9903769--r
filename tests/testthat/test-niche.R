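cfg <- pipeline_config()

make_stations <- make_stations_acc

test_that("niche fitting enforces the five-station minimum", {
  st <- make_stations(30)
  expect_error(fit_niche(st$station_id[1:4], st, cfg), "at least 5")
  model <- fit_niche(st$station_id[1:5], st, cfg)
  expect_s3_class(model, "niche_model")
  expect_equal(model$n_presence_stations, 5)
  expect_true(all(model$parameter_spreads > 0))
  expect_error(fit_niche(c(st$station_id[1:5], "NOPE"), st, cfg),
               "without environments")
})

test_that("degenerate presence scatter hits the spread floor", {
  st <- make_stations(30)
  st$sst <- c(rep(20, 10), runif(20, 0, 30))  # first ten identical SST
  model <- fit_niche(st$station_id[1:10], st, cfg)
  expect_equal(unname(model$parameter_spreads["sst"]), 0.5)
  opt <- niche_optima(model)
  expect_equal(unname(opt["sst"]), 20)
})

test_that("presence probability is 1 at the optimum and decays to 0", {
  st <- make_stations(40)
  model <- fit_niche(st$station_id[1:12], st, cfg)
  opt <- niche_optima(model)
  g_opt <- make_grid(0, 0, as.list(opt))
  expect_equal(project_presence(model, g_opt), 1, ignore_attr = TRUE)
  far <- as.list(opt); far$sst <- 1e6
  expect_lt(project_presence(model, make_grid(0, 0, far))[1], 1e-10)
  # probabilities bounded in [0,1] on arbitrary cells
  g <- make_grid(seq(-60, 60, length.out = 50), 0,
                 lapply(make_stations(50, seed = 9)[magscape:::ENV_PARAMS],
                        identity))
  p <- project_presence(model, g)
  expect_true(all(p >= 0 & p <= 1))
  # land cells carry no values
  g$ocean[1] <- FALSE
  expect_true(is.na(project_presence(model, g)[1]))
})

test_that("the calibration pins the average presence station near P = 0.5", {
  st <- make_stations(60)
  pres <- st$station_id[1:20]
  model <- fit_niche(pres, st, cfg)
  g <- make_grid(rep(0, 20), seq_len(20),
                 lapply(st[st$station_id %in% pres, magscape:::ENV_PARAMS],
                        identity))
  p <- project_presence(model, g)
  # mean squared standardized distance maps to exactly 0.5 by construction
  d2 <- sapply(seq_len(20), function(i) -2 * log(p[i]) / model$kappa)
  expect_equal(exp(-0.5 * model$kappa * mean(d2)), 0.5, tolerance = 1e-12)
  # and matches the independent envelope formula per station
  for (i in c(1, 7, 20)) {
    expect_equal(p[i], envelope_prob(model, g[i, ]), ignore_attr = TRUE)
  }
})

test_that("fitted optima recover a planted Gaussian niche", {
  set.seed(33)
  truth_mean <- c(sst = 18, salinity = 35, silicate = 12, nitrate = 8,
                  phosphate = 0.6, iron = 0.3, si_no3 = 0.4)
  truth_sd <- c(sst = 2, salinity = 0.5, silicate = 3, nitrate = 2,
                phosphate = 0.15, iron = 0.05, si_no3 = 0.1)
  for (n_pres in c(50, 200)) {
    pres <- as.data.frame(lapply(names(truth_mean), function(p)
      rnorm(n_pres, truth_mean[[p]], truth_sd[[p]])))
    names(pres) <- names(truth_mean)
    bg <- make_stations(150, seed = 44)[names(truth_mean)]
    env <- rbind(pres, bg)
    env <- cbind(station_id = sprintf("S%03d", seq_len(nrow(env))), env)
    model <- fit_niche(env$station_id[seq_len(n_pres)], env, cfg)
    opt <- niche_optima(model)
    # within half a planted spread per parameter
    expect_true(all(abs(opt - truth_mean) < 0.5 * truth_sd))
  }
})

test_that("spherical cell areas match the closed form and sum over a hemisphere", {
  # full 1x1 degree cell at the equator, from R = 6371 km:
  # R^2 * (pi/180) * (sin(0.5 deg) - sin(-0.5 deg)) = 12364.15 km^2
  expect_equal(cell_area_km2(0), 12364.15, tolerance = 1e-6)
  r <- 6371
  closed <- r^2 * (pi / 180) * (sin(0.5 * pi / 180) - sin(-0.5 * pi / 180))
  expect_equal(cell_area_km2(0), closed)
  # an all-ocean northern hemisphere integrates to 2 pi R^2
  lat <- seq(0.5, 89.5, by = 1)
  lon <- seq(-179.5, 179.5, by = 1)
  cells <- expand.grid(lat = lat, lon = lon)
  expect_equal(sum(cell_area_km2(cells$lat)), 2 * pi * r^2,
               tolerance = 1e-12)
})

test_that("presence area integrates flagged ocean cells and is threshold-monotone", {
  st <- make_stations(40)
  model <- fit_niche(st$station_id[1:10], st, cfg)
  set.seed(55)
  g <- make_grid(runif(200, -80, 80), runif(200, -180, 180),
                 lapply(make_stations(200, seed = 66)[magscape:::ENV_PARAMS],
                        identity))
  p <- project_presence(model, g)
  expect_equal(presence_area(rep(0, 200), g, cfg), 0)
  areas <- sapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(th)
    presence_area(p, g, pipeline_config(presence_threshold = th)))
  expect_true(all(diff(areas) <= 0))
  # manual check at the default threshold
  sel <- !is.na(p) & p > 0.5
  expect_equal(presence_area(p, g, cfg), sum(cell_area_km2(g$lat[sel])))
})

test_that("delta-P maps flag strictly beyond the threshold", {
  p1 <- c(0.2, 0.5, 0.4, 0.8, NA)
  d0 <- delta_p_map(p1, p1, cfg)
  expect_true(all(d0$delta_p == 0, na.rm = TRUE))
  expect_false(any(d0$expansion | d0$reduction))
  d <- delta_p_map(p1, p1 + 0.2, cfg)
  expect_true(all(d$expansion[!is.na(p1)]))
  dx <- delta_p_map(c(0.1, 0.1), c(0.2, 0.25), cfg)  # +0.1 exactly, +0.15
  expect_equal(dx$expansion, c(FALSE, TRUE))
  expect_error(delta_p_map(p1, p1[1:3], cfg), "mismatch")
})

test_that("driver attribution explains single-parameter scenarios completely", {
  st <- make_stations(40)
  model <- fit_niche(st$station_id[1:10], st, cfg)
  set.seed(77)
  g1 <- make_grid(runif(300, -80, 80), runif(300, -180, 180),
                  lapply(make_stations(300, seed = 88)[magscape:::ENV_PARAMS],
                         identity))
  g2 <- g1
  g2$sst <- g1$sst + 6
  res <- attribute_drivers(model, g1, g2, cfg)
  expect_gt(nrow(res$cells), 0)
  expect_true(all(res$cells$driver == "sst"))
  expect_true(all(res$shares$share_percent == 100))
  # shares sum to 100 within each regime
  sums <- tapply(res$shares$share_percent, res$shares$regime, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  # unchanged grids flag nothing
  res0 <- attribute_drivers(model, g1, g1, cfg)
  expect_equal(nrow(res0$cells), 0)
})

test_that("two disjoint regional changes attribute to their own parameters", {
  st <- make_stations(50)
  model <- fit_niche(st$station_id[1:12], st, cfg)
  opt <- niche_optima(model)
  # 10 cells near the optimum so P responds to perturbations
  set.seed(99)
  env <- lapply(names(opt), function(p) opt[[p]] + rnorm(10, 0, 0.02))
  names(env) <- names(opt)
  g1 <- make_grid(seq(-45, 45, length.out = 10), seq(0, 90, length.out = 10),
                  env)
  g2 <- g1
  g2$sst[1:5] <- g1$sst[1:5] + 8          # region 1: temperature change
  g2$silicate[6:10] <- g1$silicate[6:10] + 40  # region 2: silicate change
  res <- attribute_drivers(model, g1, g2, cfg)
  got <- setNames(res$cells$driver, paste(res$cells$lat, res$cells$lon))
  # one-at-a-time substitution oracle, computed independently per cell
  p1 <- sapply(seq_len(10), function(i) envelope_prob(model, g1[i, ]))
  p2 <- sapply(seq_len(10), function(i) envelope_prob(model, g2[i, ]))
  flagged <- which(abs(p2 - p1) > cfg$delta_p_threshold)
  expect_gt(length(flagged), 0)
  oracle <- sapply(flagged, function(i) {
    dpj <- sapply(magscape:::ENV_PARAMS, function(j) {
      mix <- g1[i, ]; mix[[j]] <- g2[i, ][[j]]
      envelope_prob(model, mix) - p1[i]
    })
    names(which.max(abs(dpj)))
  })
  key <- paste(g1$lat[flagged], g1$lon[flagged])
  expect_equal(unname(got[key]), unname(oracle))
  r1 <- intersect(flagged, 1:5)
  r2 <- intersect(flagged, 6:10)
  expect_true(all(got[paste(g1$lat[r1], g1$lon[r1])] == "sst"))
  expect_true(all(got[paste(g1$lat[r2], g1$lon[r2])] == "silicate"))
})
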