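#' @name niche_projection
#' @title Environmental niche models and distribution projections
#'
#' @description
#' A genome's realized niche is summarized from the environments of the
#' stations where it is detected, over seven physicochemical parameters:
#' sea surface temperature, salinity, silicate, nitrate, phosphate, iron
#' and a seasonality index of nitrate. Parameters are standardized with the
#' training-station mean and standard deviation; the niche is a Gaussian
#' envelope centered on the presence-station mean with per-parameter
#' spreads floored to avoid degenerate widths. The envelope is projected
#' onto gridded climatologies for two periods as a probability of presence
#' P in [0, 1], calibrated so the average presence station sits at
#' P = 0.5 (the figure-legend midpoint). Presence surfaces integrate
#' spherical cell areas where P exceeds 0.5; per-cell changes deltaP with
#' |deltaP| > 0.1 define expansion/reduction regions, and each flagged cell
#' is attributed to the environmental parameter whose period-to-period
#' change alone moves P the most.
NULL

ENV_PARAMS <- c("sst", "salinity", "silicate", "nitrate", "phosphate",
                "iron", "si_no3")

EARTH_RADIUS_KM <- 6371

#' Fit a Gaussian-envelope niche model
#'
#' @param detections station ids where the genome is detected.
#' @param environments data.frame, \code{station_env} schema, covering the
#'   training stations (all sampled stations).
#' @param config a \code{\link{pipeline_config}}
#'   (\code{min_stations_for_niche}).
#' @param spread_floor minimum per-parameter spread in standardized units
#'   (default 0.5), guarding against presence sets with no environmental
#'   scatter.
#' @return object of class \code{niche_model}: \code{parameter_means} and
#'   \code{parameter_spreads} (standardized 7-vectors),
#'   \code{standardization} (per-parameter mean/sd of training stations),
#'   \code{kappa} (probability calibration constant),
#'   \code{n_presence_stations}.
#' @export
fit_niche <- function(detections, environments, config = pipeline_config(),
                      spread_floor = 0.5) {
  validate_config(config)
  detections <- unique(detections)
  unknown <- setdiff(detections, environments$station_id)
  if (length(unknown)) {
    stop("detections at station(s) without environments: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(detections) < config$min_stations_for_niche) {
    stop("genome detected at ", length(detections), " stations; at least ",
         config$min_stations_for_niche, " required to fit a niche",
         call. = FALSE)
  }
  train <- as.matrix(environments[ENV_PARAMS])
  std_mean <- colMeans(train)
  std_sd <- apply(train, 2, stats::sd)
  std_sd[std_sd <= 0] <- 1  # constant parameter across all stations
  z <- sweep(sweep(train, 2, std_mean), 2, std_sd, "/")
  rownames(z) <- environments$station_id
  zp <- z[detections, , drop = FALSE]
  m <- colMeans(zp)
  s <- apply(zp, 2, stats::sd)
  s[is.na(s) | s < spread_floor] <- spread_floor
  # calibrate kappa so the mean presence-station squared distance maps to 0.5
  d2 <- rowSums(sweep(sweep(zp, 2, m), 2, s, "/")^2) / length(ENV_PARAMS)
  mean_d2 <- mean(d2)
  kappa <- if (mean_d2 > .Machine$double.eps) 2 * log(2) / mean_d2 else 1
  model <- list(parameter_means = m, parameter_spreads = s,
                standardization = list(mean = std_mean, sd = std_sd),
                kappa = kappa,
                n_presence_stations = length(detections))
  class(model) <- "niche_model"
  model
}

#' Niche optima on the raw parameter scales
#'
#' Back-transforms the standardized niche center to original units
#' (degrees C, PSU, umol/L, ...).
#'
#' @param model a \code{niche_model}.
#' @return named 7-vector of raw-scale optima.
#' @export
niche_optima <- function(model) {
  stopifnot(inherits(model, "niche_model"))
  model$standardization$mean +
    model$parameter_means * model$standardization$sd
}

#' @export
print.niche_model <- function(x, ...) {
  cat("Gaussian-envelope niche model (", x$n_presence_stations,
      " presence stations, kappa = ", signif(x$kappa, 4), ")\n", sep = "")
  print(round(rbind(mean = x$parameter_means, spread = x$parameter_spreads), 3))
  invisible(x)
}

.standardize_grid <- function(model, grid) {
  g <- as.matrix(grid[ENV_PARAMS])
  sweep(sweep(g, 2, model$standardization$mean), 2, model$standardization$sd, "/")
}

#' Project a niche model onto an environmental grid
#'
#' \deqn{P(cell) = \exp(-\tfrac{1}{2} \kappa \cdot \tfrac{1}{7}
#'   \sum_j ((z_j - m_j)/s_j)^2)}
#' so P = 1 exactly at the niche optimum and P = 0.5 at the calibrated
#' mean presence-station distance. Land cells get NA; ocean cells with a
#' missing parameter are skipped (NA) and counted.
#'
#' @param model a \code{niche_model}.
#' @param grid data.frame, \code{grid} schema.
#' @return numeric vector of per-cell probabilities aligned with
#'   \code{grid} rows; attribute \code{n_skipped} counts ocean cells with
#'   missing parameters.
#' @export
project_presence <- function(model, grid) {
  stopifnot(inherits(model, "niche_model"))
  z <- .standardize_grid(model, grid)
  d2 <- rowSums(sweep(sweep(z, 2, model$parameter_means), 2,
                      model$parameter_spreads, "/")^2) / length(ENV_PARAMS)
  p <- exp(-0.5 * model$kappa * d2)
  p[!grid$ocean] <- NA_real_
  skipped <- sum(grid$ocean & is.na(d2))
  attr(p, "n_skipped") <- skipped
  p
}

#' Spherical area of grid cells
#'
#' Area of a lat/lon cell of the given resolution centered at \code{lat}:
#' \eqn{R^2 \Delta\lambda (\sin\phi_{top} - \sin\phi_{bottom})} with
#' R = 6371 km.
#'
#' @param lat cell-center latitudes in decimal degrees.
#' @param resolution cell size in degrees (default 1).
#' @return areas in square kilometres.
#' @export
#' @examples
#' cell_area_km2(0)  # ~ 12364 km2 for a 1x1 degree equatorial cell
cell_area_km2 <- function(lat, resolution = 1) {
  half <- resolution / 2
  top <- pmin(lat + half, 90) * pi / 180
  bot <- pmax(lat - half, -90) * pi / 180
  EARTH_RADIUS_KM^2 * (resolution * pi / 180) * (sin(top) - sin(bot))
}

#' Presence surface of a projection
#'
#' Sums spherical cell areas over ocean cells whose probability of
#' presence strictly exceeds the presence threshold.
#'
#' @param p per-cell probabilities from \code{\link{project_presence}}.
#' @param grid data.frame, \code{grid} schema.
#' @param config a \code{\link{pipeline_config}} (\code{presence_threshold}).
#' @param resolution grid resolution in degrees (default 1).
#' @return area in square kilometres.
#' @export
presence_area <- function(p, grid, config = pipeline_config(), resolution = 1) {
  validate_config(config)
  stopifnot(length(p) == nrow(grid))
  sel <- !is.na(p) & grid$ocean & p > config$presence_threshold
  sum(cell_area_km2(grid$lat[sel], resolution))
}

#' Per-cell change in probability of presence
#'
#' @param p1,p2 probabilities for periods 1 and 2 on the same grid.
#' @param config a \code{\link{pipeline_config}} (\code{delta_p_threshold}).
#' @return data.frame: \code{delta_p} (= p2 - p1), \code{expansion}
#'   (delta_p strictly above the threshold), \code{reduction} (strictly
#'   below its negative).
#' @export
delta_p_map <- function(p1, p2, config = pipeline_config()) {
  validate_config(config)
  if (length(p1) != length(p2)) stop("grid mismatch", call. = FALSE)
  if (any(is.na(p1) != is.na(p2))) stop("grid mismatch: ocean masks differ",
                                        call. = FALSE)
  d <- p2 - p1
  data.frame(delta_p = d,
             expansion = !is.na(d) & d > config$delta_p_threshold,
             reduction = !is.na(d) & d < -config$delta_p_threshold)
}

#' Attribute distribution shifts to environmental drivers
#'
#' For each flagged cell (|deltaP| above the threshold) the period-2 value
#' of one parameter at a time is substituted into the period-1 environment
#' and the probability recomputed; the parameter whose substitution moves P
#' the most (largest |deltaP_j|) is the cell's first-rank driver, with ties
#' broken lexicographically (and logged). Region-level shares report, for
#' expansion and reduction cells separately, the percentage of flagged
#' cells attributed to each driver; an optional |deltaP|-magnitude
#' weighting is available.
#'
#' @param model a \code{niche_model}.
#' @param grid1,grid2 \code{grid}-schema data.frames for the two periods
#'   (same cells, same order).
#' @param config a \code{\link{pipeline_config}}.
#' @param weight \code{"cells"} (default, flagged-cell counts) or
#'   \code{"magnitude"} (|deltaP|-weighted shares).
#' @return list with \code{cells} (data.frame \code{lat}, \code{lon},
#'   \code{delta_p}, \code{driver}, \code{regime}), \code{shares}
#'   (data.frame \code{regime}, \code{driver}, \code{share_percent}) and
#'   \code{ties} (count of lexicographically broken ties).
#' @export
attribute_drivers <- function(model, grid1, grid2, config = pipeline_config(),
                              weight = c("cells", "magnitude")) {
  validate_config(config)
  weight <- match.arg(weight)
  if (nrow(grid1) != nrow(grid2) ||
      any(grid1$lat != grid2$lat) || any(grid1$lon != grid2$lon)) {
    stop("grid mismatch between periods", call. = FALSE)
  }
  p1 <- project_presence(model, grid1)
  p2 <- project_presence(model, grid2)
  dp <- delta_p_map(p1, p2, config)
  flagged <- which(dp$expansion | dp$reduction)
  empty <- list(
    cells = data.frame(lat = numeric(0), lon = numeric(0),
                       delta_p = numeric(0), driver = character(0),
                       regime = character(0)),
    shares = data.frame(regime = character(0), driver = character(0),
                        share_percent = numeric(0)),
    ties = 0L)
  if (!length(flagged)) return(empty)

  # one-at-a-time substitution: deltaP_j per parameter, flagged cells only
  dpj <- matrix(NA_real_, length(flagged), length(ENV_PARAMS),
                dimnames = list(NULL, ENV_PARAMS))
  g1 <- grid1[flagged, , drop = FALSE]
  for (j in ENV_PARAMS) {
    gmix <- g1
    gmix[[j]] <- grid2[[j]][flagged]
    dpj[, j] <- project_presence(model, gmix) - p1[flagged]
  }
  best <- apply(abs(dpj), 1, function(r) which(r == max(r))[1])
  ties <- sum(apply(abs(dpj), 1, function(r) sum(r == max(r)) > 1))
  driver <- ENV_PARAMS[best]
  regime <- ifelse(dp$expansion[flagged], "expansion", "reduction")
  cells <- data.frame(lat = grid1$lat[flagged], lon = grid1$lon[flagged],
                      delta_p = dp$delta_p[flagged], driver = driver,
                      regime = regime, stringsAsFactors = FALSE)
  shares <- do.call(rbind, lapply(unique(regime), function(rg) {
    sel <- regime == rg
    w <- if (weight == "cells") rep(1, sum(sel)) else abs(dp$delta_p[flagged][sel])
    tot <- sum(w)
    agg <- tapply(w, driver[sel], sum)
    data.frame(regime = rg, driver = names(agg),
               share_percent = 100 * as.numeric(agg) / tot,
               stringsAsFactors = FALSE)
  }))
  rownames(shares) <- NULL
  list(cells = cells, shares = shares, ties = as.integer(ties))
}
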