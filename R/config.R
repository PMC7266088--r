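#' Default plot table for the synthetic stand
#'
#' Returns the per-plot demography and geometry the generator emulates: three
#' Norway spruce plots along an altitudinal transect, with plot centres,
#' elevation, area, and the observed min--max ranges of tree height, cambial
#' age and stem diameter (DBH).  `spatial_range` is the range (metres) of the
#' Gaussian-kernel spatial autocorrelation of individual random effects; it is
#' non-zero only in the dense high-elevation plot, where micro-environmental
#' heterogeneity plausibly correlates neighbouring trees.
#'
#' @param n_plots number of plots to keep (first `n_plots` rows; at most 3
#'   without a user-supplied table).
#' @return a `data.frame` with one row per plot.
#' @export
default_plot_table <- function(n_plots = 3) {
  tab <- data.frame(
    code          = c("CAM-H", "CAM-E", "CAM-L"),
    latitude      = c(44.11000, 44.11306, 44.11861),
    longitude     = c(10.66222, 10.66306, 10.67167),
    elevation     = c(1730, 1615, 1475),
    area_ha       = c(0.25, 0.83, 1.95),
    height_min    = c(10.5, 11, 13),
    height_max    = c(18, 27, 33),
    age_min       = c(34, 35, 39),
    age_max       = c(71, 151, 155),
    dbh_min       = c(22, 20, 28),
    dbh_max       = c(56, 67, 122),
    spatial_range = c(20, 0, 0),
    stringsAsFactors = FALSE
  )
  if (n_plots > nrow(tab)) {
    stop("n_plots: more than ", nrow(tab),
         " plots requires a user-supplied `plots` table", call. = FALSE)
  }
  tab[seq_len(n_plots), , drop = FALSE]
}

#' Configuration of the synthetic stand generator
#'
#' Bundles and validates every tunable of the tracheidogram generator.  The
#' defaults are the study conditions the package is exercised under: 3 plots of
#' 10 trees, the five outermost rings (2008--2012), height/age/DBH ranges as in
#' [default_plot_table()], a wide earlywood plateau with a near-constant
#' latewood cell count, individual random effects dominating year effects, and
#' linear height effects on tangential (larger) and radial (smaller) lumen
#' diameter plus linear age effects on wall thickness and latewood share.
#'
#' Variance components are log-scale standard deviations for the strictly
#' positive parameters they perturb: `count` (earlywood cells per radial file),
#' `dtan` (tangential lumen diameter), `drad` (radial lumen diameter) and `cwt`
#' (wall thickness).  `sd_individual` applies once per tree, `sd_year` once per
#' calendar year (shared by all trees), `sd_cell` per cell within a ring
#' (its `count` entry is the per-file jitter of the earlywood cell count,
#' as a fraction of the ring mean).
#'
#' @param n_plots,trees_per_plot stand layout; `trees_per_plot >= 2`.
#' @param years calendar years simulated (one ring each).
#' @param plots per-plot table as in [default_plot_table()].
#' @param dtan_per_height,drad_per_height linear height effects on the
#'   earlywood tangential / radial lumen diameter (um per m of tree height);
#'   the tangential effect must exceed the radial one.
#' @param cwt_per_age linear age effect on wall thickness (um per year).
#' @param lwpct_per_age linear age effect on latewood percentage (percentage
#'   points per year); converted internally to a latewood-cell-count slope
#'   using the configured mean cell geometry.
#' @param sd_individual,sd_year,sd_cell named numeric vectors of log-scale
#'   standard deviations (see Details); every `sd_individual` entry should be
#'   at least twice its `sd_year` counterpart (warned otherwise).
#' @param ew_cell_count_mean mean earlywood cells per radial file.
#' @param lw_cell_count_mean,lw_cell_count_sd latewood cells per radial file
#'   (normal, truncated at 3).
#' @param ew_drad_mean mean earlywood radial lumen diameter (um).
#' @param ew_drad_ring_cv declared cap on the between-ring coefficient of
#'   variation of the mean radial lumen diameter; the individual + year
#'   variance components for `drad` must respect it.
#' @param lw_drad_frac latewood radial lumen diameter as a fraction of the
#'   earlywood one.
#' @param dtan_mean mean tangential lumen diameter (um).
#' @param cwt_ew_mean,cwt_lw_mean single-wall thickness (um) in earlywood and
#'   latewood.
#' @param height_ref,age_ref reference height (m) and age (years) at which the
#'   linear effects vanish.
#' @param height_age_mix mixing weight in (0, 1) tying the within-plot age
#'   draw to the height draw; the default targets a within-plot height--age
#'   Pearson correlation of roughly 0.4--0.7.
#' @param logistic_scale_cells scale (in cells) of the logistic earlywood to
#'   latewood transition at the ring end.
#' @param conduit_model `"ellipse"` (lumen area and conductivity from the two
#'   measured axes) or `"circle"` (lumen-area-equivalent circles).
#' @param rng_seed master seed; all randomness is reproducible from it.
#' @return an object of class `xylo_config` (a validated list).
#' @seealso [sample_stand()], [simulate_dataset()], [read_generator_config()]
#' @export
generator_config <- function(n_plots = 3,
                             trees_per_plot = 10,
                             years = 2008:2012,
                             plots = default_plot_table(n_plots),
                             dtan_per_height = 0.32,
                             drad_per_height = 0.11,
                             cwt_per_age = 0.010,
                             lwpct_per_age = 0.03,
                             sd_individual = c(count = 0.45, dtan = 0.06,
                                               drad = 0.025, cwt = 0.08),
                             sd_year = c(count = 0.12, dtan = 0.02,
                                         drad = 0.012, cwt = 0.03),
                             sd_cell = c(count = 0.03, drad = 0.05, dtan = 0.04,
                                         cwt = 0.06),
                             ew_cell_count_mean = 45,
                             lw_cell_count_mean = 8,
                             lw_cell_count_sd = 1.5,
                             ew_drad_mean = 32,
                             ew_drad_ring_cv = 0.05,
                             lw_drad_frac = 0.19,
                             dtan_mean = 28,
                             cwt_ew_mean = 2.0,
                             cwt_lw_mean = 4.5,
                             height_ref = 20,
                             age_ref = 80,
                             height_age_mix = 0.4,
                             logistic_scale_cells = 1.2,
                             conduit_model = c("ellipse", "circle"),
                             rng_seed = 1L) {
  cfg <- list(
    n_plots = as.integer(n_plots), trees_per_plot = as.integer(trees_per_plot),
    years = as.integer(years), plots = plots,
    dtan_per_height = dtan_per_height, drad_per_height = drad_per_height,
    cwt_per_age = cwt_per_age, lwpct_per_age = lwpct_per_age,
    sd_individual = sd_individual, sd_year = sd_year, sd_cell = sd_cell,
    ew_cell_count_mean = ew_cell_count_mean,
    lw_cell_count_mean = lw_cell_count_mean,
    lw_cell_count_sd = lw_cell_count_sd,
    ew_drad_mean = ew_drad_mean, ew_drad_ring_cv = ew_drad_ring_cv,
    lw_drad_frac = lw_drad_frac, dtan_mean = dtan_mean,
    cwt_ew_mean = cwt_ew_mean, cwt_lw_mean = cwt_lw_mean,
    height_ref = height_ref, age_ref = age_ref,
    height_age_mix = height_age_mix,
    logistic_scale_cells = logistic_scale_cells,
    conduit_model = match.arg(conduit_model),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "xylo_config"
  validate_config(cfg)
  cfg
}

config_error <- function(field, msg) {
  stop(sprintf("invalid generator configuration: `%s` %s", field, msg),
       call. = FALSE)
}

validate_config <- function(cfg) {
  if (is.na(cfg$n_plots) || cfg$n_plots < 1)
    config_error("n_plots", "must be a positive integer")
  if (is.na(cfg$trees_per_plot) || cfg$trees_per_plot < 2)
    config_error("trees_per_plot", "must be >= 2")
  if (length(cfg$years) < 1 || anyNA(cfg$years))
    config_error("years", "must be a non-empty vector of calendar years")
  if (anyDuplicated(cfg$years))
    config_error("years", "must not contain duplicates")
  p <- cfg$plots
  need <- c("code", "latitude", "longitude", "elevation", "area_ha",
            "height_min", "height_max", "age_min", "age_max",
            "dbh_min", "dbh_max", "spatial_range")
  miss <- setdiff(need, names(p))
  if (length(miss))
    config_error("plots", paste("is missing column(s):",
                                paste(miss, collapse = ", ")))
  if (nrow(p) != cfg$n_plots)
    config_error("plots", "must have exactly n_plots rows")
  if (any(!nzchar(p$code)) || anyDuplicated(p$code))
    config_error("plots$code", "must be non-empty and unique")
  for (rng in c("height", "age", "dbh")) {
    lo <- p[[paste0(rng, "_min")]]; hi <- p[[paste0(rng, "_max")]]
    if (any(!(lo < hi)))
      config_error(paste0("plots$", rng, "_min/_max"),
                   "must satisfy min < max in every plot")
    if (any(lo <= 0))
      config_error(paste0("plots$", rng, "_min"), "must be positive")
  }
  if (any(p$area_ha <= 0)) config_error("plots$area_ha", "must be positive")
  if (any(p$spatial_range < 0))
    config_error("plots$spatial_range", "must be >= 0")
  for (eff in c("dtan_per_height", "drad_per_height", "cwt_per_age",
                "lwpct_per_age")) {
    if (cfg[[eff]] < 0) config_error(eff, "must be >= 0")
  }
  if (cfg$drad_per_height > cfg$dtan_per_height)
    config_error("drad_per_height", "must not exceed dtan_per_height")
  for (nm in c("sd_individual", "sd_year", "sd_cell")) {
    v <- cfg[[nm]]
    if (anyNA(v) || any(v < 0)) config_error(nm, "entries must be >= 0")
  }
  need_sd <- c("count", "dtan", "drad", "cwt")
  if (!all(need_sd %in% names(cfg$sd_individual)))
    config_error("sd_individual",
                 "must name components count, dtan, drad, cwt")
  if (!all(need_sd %in% names(cfg$sd_year)))
    config_error("sd_year", "must name components count, dtan, drad, cwt")
  if (!all(c("count", "drad", "dtan", "cwt") %in% names(cfg$sd_cell)))
    config_error("sd_cell", "must name components count, drad, dtan, cwt")
  weak <- cfg$sd_individual[need_sd] < 2 * cfg$sd_year[need_sd]
  if (any(weak & cfg$sd_year[need_sd] > 0))
    warning("sd_individual < 2 * sd_year for: ",
            paste(need_sd[weak], collapse = ", "),
            " -- individual effects are intended to dominate year effects",
            call. = FALSE)
  for (pos in c("ew_cell_count_mean", "lw_cell_count_mean", "ew_drad_mean",
                "dtan_mean", "cwt_ew_mean", "cwt_lw_mean", "height_ref",
                "age_ref", "logistic_scale_cells")) {
    if (cfg[[pos]] <= 0) config_error(pos, "must be positive")
  }
  if (cfg$lw_cell_count_sd < 0) config_error("lw_cell_count_sd", "must be >= 0")
  if (cfg$lw_drad_frac <= 0 || cfg$lw_drad_frac >= 1)
    config_error("lw_drad_frac", "must be in (0, 1)")
  if (cfg$ew_drad_ring_cv <= 0 || cfg$ew_drad_ring_cv > 0.5)
    config_error("ew_drad_ring_cv", "must be in (0, 0.5]")
  implied_cv <- sqrt(cfg$sd_individual[["drad"]]^2 + cfg$sd_year[["drad"]]^2)
  if (implied_cv > cfg$ew_drad_ring_cv)
    config_error("ew_drad_ring_cv",
                 sprintf(paste("is exceeded by the drad variance components",
                               "(implied between-ring CV %.3f)"), implied_cv))
  if (cfg$height_age_mix <= 0 || cfg$height_age_mix >= 1)
    config_error("height_age_mix", "must be in (0, 1)")
  if (is.na(cfg$rng_seed)) config_error("rng_seed", "must be an integer")
  invisible(cfg)
}

#' @export
print.xylo_config <- function(x, ...) {
  cat("Synthetic stand configuration\n")
  cat(sprintf("  %d plot(s) x %d trees, years %s-%s (%d rings/tree)\n",
              x$n_plots, x$trees_per_plot, min(x$years), max(x$years),
              length(x$years)))
  cat(sprintf("  height effects (um/m): Dtan %.3f, Drad %.3f; age effects: CWT %.3f um/yr, LW%% %.3f pp/yr\n",
              x$dtan_per_height, x$drad_per_height, x$cwt_per_age,
              x$lwpct_per_age))
  cat(sprintf("  EW cells/file %.0f, LW cells/file %.1f (sd %.1f); EW Drad %.1f um, Dtan %.1f um\n",
              x$ew_cell_count_mean, x$lw_cell_count_mean, x$lw_cell_count_sd,
              x$ew_drad_mean, x$dtan_mean))
  cat(sprintf("  conduit model: %s; master seed %d\n", x$conduit_model,
              x$rng_seed))
  invisible(x)
}

# Latewood percentage per year of age -> latewood cells per year of age,
# linearised at the configured mean geometry.
lw_count_per_age <- function(cfg) {
  e_ew <- cfg$ew_drad_mean + 2 * cfg$cwt_ew_mean
  e_lw <- cfg$lw_drad_frac * cfg$ew_drad_mean + 2 * cfg$cwt_lw_mean
  eww <- cfg$ew_cell_count_mean * e_ew
  trw <- eww + cfg$lw_cell_count_mean * e_lw
  dlw_dn <- 100 * e_lw * eww / trw^2   # d(LW%) / d(n_lw) at the means
  cfg$lwpct_per_age / dlw_dn
}

#' Read a generator configuration from YAML
#'
#' The YAML file holds any subset of [generator_config()] arguments by name;
#' unnamed fields keep their defaults.  The `plots` field, if given, is a list
#' of per-plot records.
#'
#' @param path path to a YAML file.
#' @return an `xylo_config`.
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(generator_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    warning("ignoring unknown config field(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  raw <- raw[intersect(names(raw), known)]
  if (!is.null(raw$plots) && !is.data.frame(raw$plots))
    raw$plots <- do.call(rbind, lapply(raw$plots, as.data.frame))
  for (nm in c("sd_individual", "sd_year", "sd_cell"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  if (!is.null(raw$plots) && is.null(raw$n_plots))
    raw$n_plots <- nrow(raw$plots)
  do.call(generator_config, raw)
}
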