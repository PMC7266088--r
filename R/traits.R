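# Ring-level wood anatomical traits from per-cell measurements.
#
# Conventions fixed here and documented in the vignette:
#  * single-wall thicknesses are averaged per axis before use
#    (CWTrad = (cwt_le + cwt_ri)/2, CWTtan = (cwt_pi + cwt_ba)/2); the
#    "double wall" t is twice the averaged single wall;
#  * percentiles use linear interpolation between order statistics
#    (stats::quantile type 7);
#  * traits over an empty earlywood or latewood subset are NA, never 0;
#  * the analysed ring area is TRW x strip width (1 tangential mm default).

pctl <- c(1, 25, 50, 75, 99) / 100
pctl_suffix <- c("_01", "_25", "_50", "_75", "_99")

#' The canonical ring-trait catalogue
#'
#' Column names (and order) of the wide trait table: ring growth (TRW, BAI,
#' `EW%`, `LW%`, `LW%/EW%`), cell growth (counts, widths, lumen diameters and
#' areas with percentiles, cell density), mechanical traits (wall
#' thicknesses, Mork's index rTSR and relative wood density RWD, each with
#' earlywood/latewood and percentile variants), and hydraulic traits (Dh, Ks,
#' Kh, the cell wall reinforcement index `tb2` with its 5th percentile, and
#' hydraulic carbon-use efficiency HCUE).
#'
#' @return character vector of trait column names.
#' @export
xylo_trait_names <- function() {
  wp <- function(base) c(base, paste0(base, "_EW"), paste0(base, "_LW"),
                         paste0(base, pctl_suffix))
  c("TRW", "BAI", "EW%", "LW%", "LW%/EW%",
    "NoCells_tang", "NoCells_rad", "EW_Nocells", "LW_Nocells", "EWW", "LWW",
    "Drad", "Dtan", "Drad_EW", "Dtan_LW",
    "CWA", "CWA_EW", "CWA_LW",
    "LA", paste0("LA", pctl_suffix),
    "CD", "CNO", "CNO_EW", "CNO_LW",
    wp("CWTall"), wp("CWTtan"), wp("CWTrad"), wp("rTSR"), wp("RWD"),
    "Dh", "Ks", "Kh", "tb2", "tb2_05", "HCUE")
}

#' Physical constants for hydraulic traits
#'
#' @param eta dynamic viscosity of water (MPa s; default at 20 C).
#' @param water_density density of water (kg m-3).
#' @param tube_length_m tube length convention for conductivity (m).
#' @return a validated list of class `hydraulic_constants`.
#' @export
hydraulic_constants <- function(eta = 1.002e-9, water_density = 998.2,
                                tube_length_m = 1) {
  if (eta <= 0 || water_density <= 0 || tube_length_m <= 0)
    stop("hydraulic constants must all be positive", call. = FALSE)
  structure(list(eta = eta, water_density = water_density,
                 tube_length_m = tube_length_m),
            class = "hydraulic_constants")
}

#' Mork's index of one or more cells
#'
#' Ratio of four times the single radial wall thickness (the two radial walls
#' averaged) to the radial lumen diameter.  Values >= 1 mark latewood-shaped
#' tracheids.
#'
#' @param cells cell table (rows are tracheids).
#' @return numeric vector, one value per cell.
#' @export
mork_index <- function(cells) {
  if (any(cells$drad_lumen <= 0))
    stop("mork_index: non-positive radial lumen diameter", call. = FALSE)
  4 * (cells$cwt_le + cells$cwt_ri) / 2 / cells$drad_lumen
}

#' Classify cells into earlywood and latewood
#'
#' `method = "mork"` labels a cell latewood iff its Mork index is >= 1;
#' `method = "shape"` iff its radial/tangential lumen diameter ratio is < 1.
#' The ring-level boundary is, per radial file, the relative radial position
#' of the first cell from the pith side whose label and all successors'
#' labels are latewood (1 if the file has none), averaged over files.
#'
#' @param cells cell table of one ring.
#' @param method `"mork"` or `"shape"`.
#' @return a list with `labels` (factor `EW`/`LW` per cell), `boundary`
#'   (mean relative position of the earlywood--latewood transition) and
#'   `flag` (`TRUE` when the ring lacks one of the two classes entirely,
#'   in which case the boundary is reported as 0 or 1 with a warning).
#' @export
classify_ew_lw <- function(cells, method = c("mork", "shape")) {
  method <- match.arg(method)
  if (nrow(cells) == 0) stop("classify_ew_lw: empty ring", call. = FALSE)
  lw <- if (method == "mork") {
    mork_index(cells) >= 1
  } else {
    cells$drad_lumen / cells$dtan_lumen < 1
  }
  labels <- factor(ifelse(lw, "LW", "EW"), levels = c("EW", "LW"))
  ord <- order(cells$file_index, cells$cell_index)
  flag <- FALSE
  if (all(lw)) {
    boundary <- 0; flag <- TRUE
    warning("ring contains no earlywood cells; boundary reported as 0",
            call. = FALSE)
  } else if (!any(lw)) {
    boundary <- 1; flag <- TRUE
    warning("ring contains no latewood cells; boundary reported as 1",
            call. = FALSE)
  } else {
    per_file <- vapply(split(ord, cells$file_index[ord]), function(idx) {
      lwf <- lw[idx]
      n <- length(lwf)
      # first index of the terminal all-LW run
      run <- rev(cumprod(rev(lwf)))   # 1 while the tail is all LW
      k <- which(run == 1)
      if (length(k) == 0) 1 else cells$rel_pos[idx[k[1]]]
    }, numeric(1))
    boundary <- mean(per_file)
  }
  list(labels = labels, boundary = boundary, flag = flag)
}

file_sums <- function(x, file_index, files) {
  s <- vapply(split(x, factor(file_index, levels = files)), sum, numeric(1))
  s[is.na(s)] <- 0
  s
}

#' Ring, earlywood and latewood widths
#'
#' The radial extent of a cell is its lumen diameter plus both radial single
#' walls.  TRW is the mean over radial files of the summed cell extents; EWW
#' and LWW sum the extents of the correspondingly labelled cells, so
#' `TRW = EWW + LWW` by construction.  Percentages are of TRW.
#'
#' @param cells cell table of one ring.
#' @param labels factor of `EW`/`LW` labels, as from [classify_ew_lw()].
#' @return named list: `TRW`, `EWW`, `LWW` (um), `EW%`, `LW%` and `LW%/EW%`.
#' @export
ring_geometry <- function(cells, labels) {
  if (nrow(cells) == 0) stop("ring_geometry: empty ring", call. = FALSE)
  stopifnot(length(labels) == nrow(cells))
  ext <- cells$drad_lumen + cells$cwt_le + cells$cwt_ri
  files <- sort(unique(cells$file_index))
  trw <- mean(file_sums(ext, cells$file_index, files))
  eww <- mean(file_sums(ifelse(labels == "EW", ext, 0),
                        cells$file_index, files))
  lww <- trw - eww
  ewp <- 100 * eww / trw
  lwp <- 100 - ewp
  list(TRW = trw, EWW = eww, LWW = lww, `EW%` = ewp, `LW%` = lwp,
       `LW%/EW%` = if (ewp > 0) lwp / ewp else NA_real_)
}

#' Basal area increment from a ring-width series
#'
#' With cumulative radius `r_i = inner_radius + sum(widths[1:i])`, the basal
#' area increment of ring i is `pi * (r_i^2 - r_{i-1}^2)`, converted from
#' um2 to mm2.
#'
#' @param ring_widths ring widths (um), oldest first.
#' @param inner_radius stem radius at the inner edge of the first ring (um).
#' @return numeric vector of BAI (mm2 per year), one per ring.
#' @export
bai_series <- function(ring_widths, inner_radius) {
  if (any(ring_widths < 0))
    stop("bai_series: negative ring width", call. = FALSE)
  if (inner_radius < 0)
    stop("bai_series: negative inner radius", call. = FALSE)
  r <- inner_radius + cumsum(ring_widths)
  r0 <- c(inner_radius, r[-length(r)])
  pi * (r^2 - r0^2) / 1e6
}

#' Cell counts and density of one ring
#'
#' `CNO` is the total cell count of the 1-mm strip, split into `CNO_EW` and
#' `CNO_LW` by the labels.  `NoCells_tang` counts the radial files containing
#' latewood (per mm of strip); `NoCells_rad = CNO / NoCells_tang` is the mean
#' number of cells per radial file, `EW_Nocells`/`LW_Nocells` its earlywood/
#' latewood analogues.  `CD = CNO / (TRW * strip width)` in cells per mm2.
#'
#' @param cells cell table of one ring.
#' @param labels `EW`/`LW` factor.
#' @param trw ring width (um), as from [ring_geometry()].
#' @param strip_mm analysed tangential strip width (mm).
#' @return named list of counts and density.
#' @export
cell_counts <- function(cells, labels, trw, strip_mm = 1) {
  cno <- nrow(cells)
  cno_lw <- sum(labels == "LW")
  cno_ew <- cno - cno_lw
  lw_files <- unique(cells$file_index[labels == "LW"])
  n_tang <- length(lw_files) / strip_mm
  if (n_tang == 0)
    stop("cell_counts: no latewood-bearing radial files (tangential count 0)",
         call. = FALSE)
  list(CNO = cno, CNO_EW = cno_ew, CNO_LW = cno_lw,
       NoCells_tang = n_tang,
       NoCells_rad = cno / n_tang,
       EW_Nocells = cno_ew / n_tang,
       LW_Nocells = cno_lw / n_tang,
       CD = cno / ((trw / 1000) * strip_mm))
}

subset_mean <- function(x, keep) if (any(keep)) mean(x[keep]) else NA_real_

with_portions <- function(x, labels, base) {
  out <- c(mean(x), subset_mean(x, labels == "EW"),
           subset_mean(x, labels == "LW"),
           unname(stats::quantile(x, pctl, type = 7)))
  names(out) <- c(base, paste0(base, "_EW"), paste0(base, "_LW"),
                  paste0(base, pctl_suffix))
  out
}

#' Wall thickness, density and reinforcement metrics of one ring
#'
#' Per cell: `CWTtan = (cwt_pi + cwt_ba)/2`, `CWTrad = (cwt_le + cwt_ri)/2`,
#' `CWTall = (CWTtan + CWTrad)/2`; `rTSR` is Mork's index; `RWD = cwa /
#' (cwa + lumen area)`; the reinforcement index `(t/b)^2` uses the double
#' wall `t = 2 x single wall` over the lumen span of the same axis, taking
#' the smaller of the radial and tangential ratios before squaring.  Ring
#' values are unweighted means; percentile variants are per-cell percentiles
#' (type 7); `tb2_05` is the 5th percentile of per-cell `(t/b)^2`.
#'
#' @param cells cell table of one ring.
#' @param labels `EW`/`LW` factor.
#' @return named numeric vector covering the mechanical and safety traits
#'   plus the CWA and LA aggregates.
#' @export
wall_metrics <- function(cells, labels) {
  cwttan <- (cells$cwt_pi + cells$cwt_ba) / 2
  cwtrad <- (cells$cwt_le + cells$cwt_ri) / 2
  cwtall <- (cwttan + cwtrad) / 2
  rtsr <- 4 * cwtrad / cells$drad_lumen
  rwd <- cells$cwa / (cells$cwa + cells$lumen_area)
  tb2 <- pmin(2 * cwtrad / cells$drad_lumen,
              2 * cwttan / cells$dtan_lumen)^2
  la <- cells$lumen_area
  out <- c(
    with_portions(cwtall, labels, "CWTall"),
    with_portions(cwttan, labels, "CWTtan"),
    with_portions(cwtrad, labels, "CWTrad"),
    with_portions(rtsr, labels, "rTSR"),
    with_portions(rwd, labels, "RWD"),
    CWA = mean(cells$cwa),
    CWA_EW = subset_mean(cells$cwa, labels == "EW"),
    CWA_LW = subset_mean(cells$cwa, labels == "LW"),
    LA = mean(la),
    stats::setNames(unname(stats::quantile(la, pctl, type = 7)),
                    paste0("LA", pctl_suffix)),
    Drad = mean(cells$drad_lumen),
    Dtan = mean(cells$dtan_lumen),
    Drad_EW = subset_mean(cells$drad_lumen, labels == "EW"),
    Dtan_LW = subset_mean(cells$dtan_lumen, labels == "LW"),
    tb2 = mean(tb2),
    tb2_05 = unname(stats::quantile(tb2, 0.05, type = 7))
  )
  out
}

#' Hydraulic traits of one ring
#'
#' Lumen-area-equivalent diameters `d_i = 2 sqrt(LA_i / pi)` give the
#' hydraulic diameter `Dh = sum(d^5) / sum(d^4)`.  Theoretical conductivity
#' sums per-conduit Poiseuille terms over the configured tube length; for
#' elliptical conduits with semi-axes a (radial) and b (tangential),
#' `k = pi a^3 b^3 / (4 eta (a^2 + b^2) L)`, which reduces to the
#' Hagen-Poiseuille `pi r^4 / (8 eta L)` when a = b.  `Ks` divides `Kh` by
#' the analysed xylem area (TRW x strip width, in m2) and `HCUE` expresses
#' the mass-flow conductivity (`Kh` x water density) per unit cell wall area
#' invested (um2).
#'
#' @param cells cell table of one ring.
#' @param trw ring width (um).
#' @param strip_mm analysed tangential strip width (mm).
#' @param constants a [hydraulic_constants()] object.
#' @param conduit_model `"ellipse"` (measured axes) or `"circle"`
#'   (lumen-area-equivalent circles).
#' @return named list: `Dh` (um), `Kh` (m3 MPa-1 s-1), `Ks` (m2 MPa-1 s-1),
#'   `HCUE` (kg m-1 MPa-1 s-1 um-2).
#' @export
hydraulic_traits <- function(cells, trw, strip_mm = 1,
                             constants = hydraulic_constants(),
                             conduit_model = c("ellipse", "circle")) {
  conduit_model <- match.arg(conduit_model)
  if (any(cells$lumen_area <= 0))
    stop("hydraulic_traits: non-positive lumen area", call. = FALSE)
  d_um <- 2 * sqrt(cells$lumen_area / pi)
  dh <- sum(d_um^5) / sum(d_um^4)
  eta <- constants$eta; L <- constants$tube_length_m
  if (conduit_model == "ellipse") {
    a <- cells$drad_lumen / 2 * 1e-6
    b <- cells$dtan_lumen / 2 * 1e-6
    k <- pi * a^3 * b^3 / (4 * eta * (a^2 + b^2) * L)
  } else {
    r <- d_um / 2 * 1e-6
    k <- pi * r^4 / (8 * eta * L)
  }
  kh <- sum(k)
  xylem_area_m2 <- (trw * 1e-6) * (strip_mm * 1e-3)
  ks <- kh / xylem_area_m2
  hcue <- kh * constants$water_density / sum(cells$cwa)
  list(Dh = dh, Kh = kh, Ks = ks, HCUE = hcue)
}

#' Derive the full trait vector of one ring
#'
#' Dispatches to [classify_ew_lw()], [ring_geometry()], [cell_counts()],
#' [wall_metrics()] and [hydraulic_traits()] and assembles the canonical
#' trait catalogue for one tree-ring.  BAI needs the stem radius at the
#' ring's inner edge; when `inner_radius` is `NULL` the BAI column is `NA`
#' (it is filled in by [derive_traits()], which reconstructs radii from DBH).
#'
#' @param cells cell table of one ring (a single tree and year).
#' @param tree_id,year ring identity; defaulted from the cell table.
#' @param inner_radius stem radius at the ring's inner edge (um), or `NULL`.
#' @param method earlywood/latewood rule, see [classify_ew_lw()].
#' @param strip_mm analysed tangential strip width (mm).
#' @param constants a [hydraulic_constants()] object.
#' @param conduit_model see [hydraulic_traits()].
#' @return a one-row `data.frame`: `tree_id`, `year`, then the catalogue of
#'   [xylo_trait_names()].
#' @export
aggregate_ring <- function(cells, tree_id = cells$tree_id[1],
                           year = cells$year[1], inner_radius = NULL,
                           method = "mork", strip_mm = 1,
                           constants = hydraulic_constants(),
                           conduit_model = c("ellipse", "circle")) {
  if (nrow(cells) == 0) stop("aggregate_ring: empty ring", call. = FALSE)
  conduit_model <- match.arg(conduit_model)
  cl <- classify_ew_lw(cells, method)
  geom <- ring_geometry(cells, cl$labels)
  counts <- tryCatch(
    cell_counts(cells, cl$labels, geom$TRW, strip_mm),
    error = function(e) {
      warning(conditionMessage(e), call. = FALSE)
      list(CNO = nrow(cells), CNO_EW = sum(cl$labels == "EW"),
           CNO_LW = sum(cl$labels == "LW"), NoCells_tang = NA_real_,
           NoCells_rad = NA_real_, EW_Nocells = NA_real_,
           LW_Nocells = NA_real_,
           CD = nrow(cells) / ((geom$TRW / 1000) * strip_mm))
    })
  walls <- wall_metrics(cells, cl$labels)
  hyd <- hydraulic_traits(cells, geom$TRW, strip_mm, constants,
                          conduit_model)
  bai <- if (is.null(inner_radius)) NA_real_ else
    bai_series(geom$TRW, inner_radius)
  vals <- c(geom[c("TRW")], BAI = bai,
            geom[c("EW%", "LW%", "LW%/EW%")],
            counts[c("NoCells_tang", "NoCells_rad", "EW_Nocells",
                     "LW_Nocells")],
            geom[c("EWW", "LWW")],
            as.list(walls[c("Drad", "Dtan", "Drad_EW", "Dtan_LW",
                            "CWA", "CWA_EW", "CWA_LW",
                            "LA", paste0("LA", pctl_suffix))]),
            counts[c("CD", "CNO", "CNO_EW", "CNO_LW")],
            as.list(walls[grep("^(CWTall|CWTtan|CWTrad|rTSR|RWD)",
                               names(walls))]),
            hyd[c("Dh", "Ks", "Kh")],
            as.list(walls[c("tb2", "tb2_05")]),
            hyd["HCUE"])
  out <- data.frame(tree_id = tree_id, year = year,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out[xylo_trait_names()] <- vals[xylo_trait_names()]
  out
}

#' Derive traits for every ring of a dataset
#'
#' Splits a combined cell table by (tree, year), derives each ring's traits
#' and reconstructs the BAI series per tree: the stem radius at the inner
#' edge of the oldest sampled ring is taken as DBH/2 minus the summed
#' sampled ring widths (bark ignored).
#'
#' @param cells combined cell table (all rings).
#' @param meta tree metadata (needed for DBH; `NULL` leaves BAI as `NA`).
#' @inheritParams aggregate_ring
#' @return trait table, one row per (tree, year), ordered by tree then year.
#' @export
derive_traits <- function(cells, meta = NULL, method = "mork", strip_mm = 1,
                          constants = hydraulic_constants(),
                          conduit_model = c("ellipse", "circle")) {
  conduit_model <- match.arg(conduit_model)
  key <- interaction(cells$tree_id, cells$year, drop = TRUE)
  rows <- lapply(split(cells, key), aggregate_ring, method = method,
                 strip_mm = strip_mm, constants = constants,
                 conduit_model = conduit_model)
  traits <- do.call(rbind, rows)
  traits <- traits[order(traits$tree_id, traits$year), ]
  rownames(traits) <- NULL
  if (!is.null(meta)) {
    for (tid in unique(traits$tree_id)) {
      i <- which(traits$tree_id == tid)
      m <- match(tid, meta$tree_id)
      if (is.na(m)) next
      widths <- traits$TRW[i]
      r_bark <- meta$dbh[m] / 2 * 1e4          # cm -> um
      r0 <- max(r_bark - sum(widths), 0)
      traits$BAI[i] <- bai_series(widths, r0)
    }
  }
  traits
}
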