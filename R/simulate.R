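# Synthetic stand and tracheidogram generator.
#
# Randomness layout: one master seed (config$rng_seed).  Stand-level draws
# (positions, heights, ages, individual random effects) use the master seed
# directly; per-year effects and per-ring cell noise run in sub-streams whose
# seeds are derived deterministically from (master seed, tree index, year), so
# any single ring is reproducible without regenerating the whole stand.

M31 <- 2147483647

year_seed <- function(master, year) {
  (abs(master) %% 100000L * 31 + (year - 1900) * 104729) %% M31
}

ring_seed <- function(master, tree_index, year) {
  (abs(master) %% 100000L * 1000003 + tree_index * 2039 +
     (year - 1900) * 7919) %% M31
}

# stratified uniform quantiles in (0,1): one draw per equal-width stratum,
# in random order -- spreads trees over the whole plot range
strat_unif <- function(n) {
  u <- (seq_len(n) - stats::runif(n)) / n
  sample(u)
}

eff_params <- c("count", "dtan", "drad", "cwt")

# spatially correlated standard-normal individual effects via a Gaussian
# kernel on within-plot tree coordinates (range 0 -> independent)
spatial_normal <- function(n, x, y, range_m) {
  z <- stats::rnorm(n)
  if (range_m <= 0 || n == 1) return(z)
  d <- as.matrix(stats::dist(cbind(x, y)))
  K <- exp(-d^2 / (2 * range_m^2)) + diag(1e-6, n)
  drop(t(chol(K)) %*% z)
}

#' Sample a stand of trees
#'
#' Draws tree positions, heights, ages and DBH within each plot's configured
#' ranges (stratified, to maximise within-plot variation), plus the individual
#' and year random effects that drive ring simulation.  Height and age are
#' positively tied within a plot through a shared stratified draw (target
#' Pearson correlation about 0.4--0.7) without being collinear.  In plots with
#' `spatial_range > 0` the individual effects of neighbouring trees are
#' positively correlated through a Gaussian kernel on distance.
#'
#' @param config an [generator_config()] object.
#' @return a list with `meta` (the tree metadata table: `tree_id`, `plot`,
#'   `latitude`, `longitude`, `elevation`, `height`, `age`, `dbh`) and
#'   `truth`, an `xylo_truth` ground-truth ledger holding the realised
#'   individual effects, year effects and within-plot coordinates.
#' @export
sample_stand <- function(config) {
  validate_config(config)
  cfg <- config
  set.seed(cfg$rng_seed)
  metas <- list(); xs <- list(); inds <- list()
  for (k in seq_len(cfg$n_plots)) {
    pl <- cfg$plots[k, ]
    n <- cfg$trees_per_plot
    side <- sqrt(pl$area_ha * 10000)          # plot modelled as a square, m
    x_m <- stats::runif(n, 0, side)
    y_m <- stats::runif(n, 0, side)
    u_h <- strat_unif(n)
    u_mix <- strat_unif(n)
    w <- cfg$height_age_mix
    u_a <- w * u_h + (1 - w) * u_mix
    u_d <- 0.6 * u_h + 0.4 * stats::runif(n)
    height <- pl$height_min + u_h * (pl$height_max - pl$height_min)
    age <- pl$age_min + u_a * (pl$age_max - pl$age_min)
    dbh <- pl$dbh_min + u_d * (pl$dbh_max - pl$dbh_min)
    ind <- sapply(eff_params, function(pp)
      cfg$sd_individual[[pp]] *
        spatial_normal(n, x_m, y_m, pl$spatial_range))
    ind <- matrix(ind, nrow = n,
                  dimnames = list(NULL, eff_params))
    tree_id <- sprintf("%s_%02d", pl$code, seq_len(n))
    metas[[k]] <- data.frame(
      tree_id = tree_id, plot = pl$code,
      latitude = pl$latitude + y_m / 111320,
      longitude = pl$longitude + x_m / (111320 * cos(pl$latitude * pi / 180)),
      elevation = pl$elevation,
      height = height, age = round(age), dbh = dbh,
      stringsAsFactors = FALSE
    )
    xs[[k]] <- data.frame(tree_id = tree_id, plot = pl$code,
                          x_m = x_m, y_m = y_m, stringsAsFactors = FALSE)
    rownames(ind) <- tree_id
    inds[[k]] <- ind
  }
  meta <- do.call(rbind, metas)
  rownames(meta) <- NULL
  ind_effects <- do.call(rbind, inds)
  # common per-year effects, one sub-stream per calendar year
  year_effects <- t(vapply(cfg$years, function(yr) {
    set.seed(year_seed(cfg$rng_seed, yr))
    stats::rnorm(length(eff_params)) * cfg$sd_year[eff_params]
  }, numeric(length(eff_params))))
  dimnames(year_effects) <- list(as.character(cfg$years), eff_params)
  truth <- structure(
    list(config = cfg, meta = meta,
         positions = do.call(rbind, xs),
         ind_effects = ind_effects,
         year_effects = year_effects),
    class = "xylo_truth")
  list(meta = meta, truth = truth)
}

#' @export
print.xylo_truth <- function(x, ...) {
  cat(sprintf("Ground truth for %d trees x %d years (seed %d)\n",
              nrow(x$meta), length(x$config$years), x$config$rng_seed))
  cat("  individual effect SD (realised):\n")
  print(round(apply(x$ind_effects, 2, stats::sd), 4))
  invisible(x)
}

#' Deterministic ring parameters for one tree and year
#'
#' Combines the configured means, the tree's height/age effects and the
#' realised individual and year random effects into the parameter set that
#' fully determines one simulated ring (given its noise sub-stream).
#'
#' @param truth ground truth from [sample_stand()].
#' @param tree_id a tree identifier present in the stand.
#' @param year a simulated calendar year.
#' @return a list of ring-level parameters, including the derived number of
#'   tangential files and the per-ring noise seed.
#' @export
ring_params <- function(truth, tree_id, year) {
  cfg <- truth$config
  i <- match(tree_id, truth$meta$tree_id)
  if (is.na(i)) stop("tree not present in truth: ", tree_id, call. = FALSE)
  if (!year %in% cfg$years)
    stop("year not simulated: ", year, call. = FALSE)
  ind <- truth$ind_effects[tree_id, ]
  yr <- truth$year_effects[as.character(year), ]
  h <- truth$meta$height[i]; age <- truth$meta$age[i]
  ew_drad <- cfg$ew_drad_mean * exp(ind[["drad"]] + yr[["drad"]]) +
    cfg$drad_per_height * (h - cfg$height_ref)
  dtan <- cfg$dtan_mean * exp(ind[["dtan"]] + yr[["dtan"]]) +
    cfg$dtan_per_height * (h - cfg$height_ref)
  cwt_ew <- cfg$cwt_ew_mean * exp(ind[["cwt"]] + yr[["cwt"]]) +
    cfg$cwt_per_age * (age - cfg$age_ref)
  cwt_lw <- cfg$cwt_lw_mean * cwt_ew / cfg$cwt_ew_mean
  lw_drad <- cfg$lw_drad_frac * ew_drad
  n_ew <- cfg$ew_cell_count_mean * exp(ind[["count"]] + yr[["count"]])
  lw_mean <- cfg$lw_cell_count_mean + lw_count_per_age(cfg) *
    (age - cfg$age_ref)
  if (min(ew_drad, dtan, cwt_ew, cwt_lw, lw_drad, n_ew, lw_mean) <= 0)
    stop(sprintf(paste("ring generation failed for %s year %d:",
                       "parameter combination infeasible",
                       "(non-positive geometry)"), tree_id, year),
         call. = FALSE)
  n_files <- floor(1000 / (dtan + 2 * cwt_ew))
  if (n_files < 1)
    stop(sprintf(paste("ring generation failed for %s year %d: tangential",
                       "cell pitch exceeds the 1-mm strip"), tree_id, year),
         call. = FALSE)
  list(tree_id = tree_id, year = year, height = h, age = age,
       ew_drad = ew_drad, lw_drad = lw_drad, dtan = dtan,
       cwt_ew = cwt_ew, cwt_lw = cwt_lw,
       n_ew = n_ew, lw_mean = lw_mean, n_files = n_files,
       seed = ring_seed(cfg$rng_seed, i, year))
}

#' Simulate the cell table of one ring
#'
#' Builds a 1-mm tangential strip of radial files.  Each file is a
#' tracheidogram: an earlywood plateau of wide, thin-walled cells followed by
#' a logistic decline of lumen diameter (and rise of wall thickness) over the
#' last cells of the ring, centred so that Mork's index crosses 1 at a
#' roughly constant latewood cell count per file.  Lumen areas are elliptical
#' (`pi/4 * Drad * Dtan`); the cell wall area is the rectangular cell
#' footprint minus the lumen ellipse.
#'
#' @param tree a `tree_id` or a one-row slice of the metadata table.
#' @param year simulated calendar year.
#' @param truth ground truth from [sample_stand()].
#' @param config optional override; defaults to `truth$config`.
#' @return a cell table (one row per tracheid) with the canonical columns
#'   `tree_id`, `year`, `file_index`, `cell_index`, `rel_pos`, `drad_lumen`,
#'   `dtan_lumen`, `lumen_area`, `cwt_pi`, `cwt_ba`, `cwt_le`, `cwt_ri`,
#'   `cwa`.  Cell index 1 is the pith side.
#' @export
simulate_ring <- function(tree, year, truth, config = truth$config) {
  if (is.data.frame(tree)) tree <- tree$tree_id[1]
  cfg <- config
  pr <- ring_params(truth, tree, year)
  set.seed(pr$seed)
  f <- pr$n_files
  n_lw_f <- pmax(3L, as.integer(round(
    stats::rnorm(f, pr$lw_mean, cfg$lw_cell_count_sd))))
  n_ew_f <- pmax(5L, as.integer(round(
    stats::rnorm(f, pr$n_ew, cfg$sd_cell[["count"]] * pr$n_ew))))
  n_f <- n_ew_f + n_lw_f
  total <- sum(n_f)
  file_index <- rep.int(seq_len(f), n_f)
  cell_index <- sequence(n_f)
  # cells counted from the bark end of each file; the logistic transition is
  # centred so that ~n_lw_f cells sit beyond the Mork = 1 crossing
  j <- rep.int(n_f, n_f) - cell_index
  s <- cfg$logistic_scale_cells
  j0 <- rep.int(n_lw_f, n_f) + log(2) * s
  L <- stats::plogis((j - j0) / s)
  drad <- (pr$lw_drad + (pr$ew_drad - pr$lw_drad) * L) *
    exp(stats::rnorm(total, 0, cfg$sd_cell[["drad"]]))
  cwt_prof <- pr$cwt_ew + (pr$cwt_lw - pr$cwt_ew) * (1 - L)
  wall_noise <- function()
    exp(stats::rnorm(total, 0, cfg$sd_cell[["cwt"]]))
  cwt_le <- cwt_prof * wall_noise()
  cwt_ri <- cwt_prof * wall_noise()
  cwt_pi <- cwt_prof * wall_noise()
  cwt_ba <- cwt_prof * wall_noise()
  dtan <- pr$dtan * exp(stats::rnorm(total, 0, cfg$sd_cell[["dtan"]]))
  lumen_area <- pi / 4 * drad * dtan
  ext_rad <- drad + cwt_le + cwt_ri
  footprint <- ext_rad * (dtan + cwt_pi + cwt_ba)
  cwa <- footprint - lumen_area
  rel_pos <- unlist(lapply(split(ext_rad, file_index), function(e)
    (cumsum(e) - e / 2) / sum(e)), use.names = FALSE)
  data.frame(
    tree_id = pr$tree_id, year = pr$year,
    file_index = file_index, cell_index = cell_index, rel_pos = rel_pos,
    drad_lumen = drad, dtan_lumen = dtan, lumen_area = lumen_area,
    cwt_pi = cwt_pi, cwt_ba = cwt_ba, cwt_le = cwt_le, cwt_ri = cwt_ri,
    cwa = cwa, stringsAsFactors = FALSE
  )
}

#' Simulate a full dataset (all trees, all years)
#'
#' @param config an [generator_config()] object.
#' @return a list with `cells` (one combined cell table covering every
#'   tree-year ring), `meta` (tree metadata) and `truth` (ground-truth
#'   ledger).  Total rings = trees x years.
#' @export
simulate_dataset <- function(config) {
  st <- sample_stand(config)
  rings <- vector("list", nrow(st$meta) * length(config$years))
  k <- 0
  for (tid in st$meta$tree_id) {
    for (yr in config$years) {
      k <- k + 1
      rings[[k]] <- simulate_ring(tid, yr, st$truth)
    }
  }
  cells <- do.call(rbind, rings)
  rownames(cells) <- NULL
  list(cells = cells, meta = st$meta, truth = st$truth)
}
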