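test_that("Mork's index follows the 4 x single radial wall / Drad definition", {
  mk <- function(le, ri, drad) {
    cells <- hand_ring(n_ew = 1, n_lw = 0, drad_ew = drad)
    cells$cwt_le <- le; cells$cwt_ri <- ri
    mork_index(cells)
  }
  expect_equal(mk(1.5, 1.5, 6), 1.0)
  expect_equal(mk(0.5, 0.5, 30), 4 * 0.5 / 30)
  expect_equal(mk(2, 4, 6), 2.0)     # walls averaged before the ratio
  bad <- hand_ring(n_ew = 1, n_lw = 0)
  bad$drad_lumen <- 0
  expect_error(mork_index(bad), "non-positive")
})

test_that("earlywood/latewood classification and boundary follow the terminal-run rule", {
  ring <- hand_ring(n_ew = 7, n_lw = 3)
  cl <- classify_ew_lw(ring, "mork")
  expect_equal(as.character(cl$labels),
               c(rep("EW", 7), rep("LW", 3)))
  expect_equal(cl$boundary, ring$rel_pos[8])
  expect_false(cl$flag)

  # all earlywood: boundary 1 with a warning flag
  ew_only <- uniform_ring(n = 5)
  expect_warning(cl2 <- classify_ew_lw(ew_only, "mork"), "no latewood")
  expect_true(all(cl2$labels == "EW"))
  expect_equal(cl2$boundary, 1)
  expect_true(cl2$flag)

  # shape rule: latewood iff Drad/Dtan < 1
  ring$drad_lumen[9:10] <- 10; ring$dtan_lumen[9:10] <- 20
  ring$drad_lumen[1:8] <- 30
  ring$lumen_area <- pi / 4 * ring$drad_lumen * ring$dtan_lumen
  cl3 <- classify_ew_lw(ring, "shape")
  expect_equal(which(cl3$labels == "LW"), c(9L, 10L))
})

test_that("ring geometry partitions TRW into EWW and LWW", {
  # one file, 4 identical cells (drad 20, walls 2.5): extents 25 each
  ring <- hand_ring(n_ew = 3, n_lw = 1, drad_ew = 20, drad_lw = 20,
                    cwt_ew = 2.5, cwt_lw = 2.5)
  labels <- factor(c("EW", "EW", "EW", "LW"), levels = c("EW", "LW"))
  g <- ring_geometry(ring, labels)
  expect_equal(g$TRW, 100)
  expect_equal(g$EWW, 75)
  expect_equal(g$`EW%`, 75)
  expect_equal(g$`LW%/EW%`, 1 / 3)

  all_ew <- ring_geometry(ring, factor(rep("EW", 4), levels = c("EW", "LW")))
  expect_equal(all_ew$`LW%`, 0)
  expect_equal(all_ew$`LW%/EW%`, 0)

  # two files of different widths average to the ring width
  two <- rbind(hand_ring(n_ew = 3, n_lw = 0, drad_ew = 26, cwt_ew = 2),
               within(hand_ring(n_ew = 3, n_lw = 0, drad_ew = 110 / 3 - 4,
                                cwt_ew = 2), file_index <- 2L))
  g2 <- ring_geometry(two, factor(rep("EW", 6), levels = c("EW", "LW")))
  expect_equal(g2$TRW, 100)   # mean of file widths 90 and 110
  expect_error(ring_geometry(two[0, ], factor(character())), "empty")
})

test_that("basal area increment matches its closed form", {
  # inner radius 10 mm, ring 2 mm -> pi (12^2 - 10^2) mm2
  expect_equal(bai_series(2000, 10000), pi * 44, tolerance = 1e-12)
  expect_equal(bai_series(c(1000, 0, 500), 5000)[2], 0)
  # equal widths on a growing radius give strictly increasing BAI
  b <- bai_series(rep(800, 5), 20000)
  expect_true(all(diff(b) > 0))
  expect_error(bai_series(c(100, -5), 1000), "negative")
})

test_that("cell counts and density follow the 1-mm strip conventions", {
  rings <- lapply(1:20, function(f)
    within(hand_ring(n_ew = 45, n_lw = 5), file_index <- as.integer(f)))
  cells <- do.call(rbind, rings)
  labels <- classify_ew_lw(cells)$labels
  cc <- cell_counts(cells, labels, trw = 1000, strip_mm = 1)
  expect_equal(cc$CNO, 1000)
  expect_equal(cc$NoCells_tang, 20)
  expect_equal(cc$NoCells_rad, 50)
  expect_equal(cc$CD, 1000)      # 1000 cells over 1 mm x 1 mm
  expect_equal(cc$CNO_EW + cc$CNO_LW, cc$CNO)

  # unequal files: mean cells per radial file
  uneq <- rbind(hand_ring(n_ew = 5, n_lw = 5),
                within(hand_ring(n_ew = 25, n_lw = 5),
                       file_index <- 2L))
  lab2 <- classify_ew_lw(uneq)$labels
  expect_equal(cell_counts(uneq, lab2, trw = 1000)$NoCells_rad, 20)

  ew_only <- uniform_ring(n = 4)
  lab3 <- factor(rep("EW", 4), levels = c("EW", "LW"))
  expect_error(cell_counts(ew_only, lab3, trw = 100), "tangential")
})

test_that("wall metrics follow the averaged-wall and min-axis conventions", {
  ring <- hand_ring(n_ew = 1, n_lw = 0, drad_ew = 20, cwt_ew = 2, dtan = 20)
  lab <- factor("EW", levels = c("EW", "LW"))
  w <- wall_metrics(ring, lab)
  expect_equal(unname(w["CWTall"]), 2)
  expect_equal(unname(w["tb2"]), (4 / 20)^2)

  # square cell with wall area equal to lumen area has RWD 1/2
  sq <- ring; sq$cwa <- sq$lumen_area
  expect_equal(unname(wall_metrics(sq, lab)["RWD"]), 0.5)

  # min rule: the less reinforced axis governs (t/b)^2
  m <- ring
  m$cwt_le <- m$cwt_ri <- 3; m$drad_lumen <- 10    # single-wall ratio 0.3
  m$cwt_pi <- m$cwt_ba <- 1; m$dtan_lumen <- 10    # single-wall ratio 0.1
  m$lumen_area <- pi / 4 * m$drad_lumen * m$dtan_lumen
  expect_equal(unname(wall_metrics(m, lab)["tb2"]), 0.2^2)

  # empty latewood subset reports NA, never 0
  expect_true(is.na(w["CWTall_LW"]))
})

test_that("hydraulic traits reduce to their closed forms", {
  consts <- hydraulic_constants()
  # uniform ring: Dh equals the common diameter
  u <- uniform_ring(n = 6, drad = 10, dtan = 10)
  h <- hydraulic_traits(u, trw = 100, constants = consts)
  expect_equal(h$Dh, 10, tolerance = 1e-12)
  # two circular cells 10 and 20 um
  two <- uniform_ring(n = 2)
  two$drad_lumen <- two$dtan_lumen <- c(10, 20)
  two$lumen_area <- pi / 4 * two$drad_lumen * two$dtan_lumen
  h2 <- hydraulic_traits(two, trw = 50, constants = consts)
  expect_equal(h2$Dh, (10^5 + 20^5) / (10^4 + 20^4), tolerance = 1e-12)
  # circular conduit: elliptical formula collapses to pi r^4 / (8 eta)
  one <- uniform_ring(n = 1, drad = 20, dtan = 20)
  h3 <- hydraulic_traits(one, trw = 25, constants = consts)
  r <- 10e-6
  expect_equal(h3$Kh, pi * r^4 / (8 * consts$eta), tolerance = 1e-12)
  expect_equal(h3$Kh, 3.919e-12, tolerance = 1e-3)
  # circle model agrees with ellipse model on circular cells
  h4 <- hydraulic_traits(one, trw = 25, constants = consts,
                         conduit_model = "circle")
  expect_equal(h4$Kh, h3$Kh, tolerance = 1e-9)
})

test_that("hydraulic diameter is a hydraulically weighted mean", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    ring <- uniform_ring(n = n)
    d <- runif(n, 5, 40)
    ring$drad_lumen <- ring$dtan_lumen <- d
    ring$lumen_area <- pi / 4 * d^2
    h <- hydraulic_traits(ring, trw = sum(d))
    expect_gte(h$Dh, mean(d))
    expect_gte(h$Dh, min(d)); expect_lte(h$Dh, max(d))
    # adding a cell wider than Dh strictly increases Dh
    wide <- ring[1, ]
    wide$drad_lumen <- wide$dtan_lumen <- h$Dh * 1.5
    wide$lumen_area <- pi / 4 * wide$drad_lumen^2
    wide$cell_index <- n + 1L
    h2 <- hydraulic_traits(rbind(ring, wide), trw = sum(d))
    expect_gt(h2$Dh, h$Dh)
  }
})

test_that("aggregate_ring matches the brute-force oracle and scales correctly", {
  ds <- simulate_dataset(tiny_config(seed = 33, trees = 2))
  key <- interaction(ds$cells$tree_id, ds$cells$year, drop = TRUE)
  rings <- split(ds$cells, key)
  for (ring in rings[1:4]) {
    got <- aggregate_ring(ring)
    want <- oracle_ring_traits(ring)
    for (nm in names(want)) {
      expect_equal(got[[nm]], unname(want[nm]), tolerance = 1e-9, label = nm)
    }
  }
  # a single-cell ring: TRW is that cell's extent, percentiles degenerate
  suppressWarnings({
    one <- aggregate_ring(uniform_ring(n = 1, drad = 20, cwt = 2.5))
  })
  expect_equal(one$TRW, 25)
  expect_equal(one$LA_01, one$LA_99)
  # doubling linear dimensions doubles Dh, leaves tb2 and RWD unchanged
  ring <- rings[[1]]
  dbl <- ring
  for (cc in c("drad_lumen", "dtan_lumen", "cwt_pi", "cwt_ba", "cwt_le",
               "cwt_ri")) dbl[[cc]] <- 2 * dbl[[cc]]
  dbl$lumen_area <- 4 * ring$lumen_area
  dbl$cwa <- 4 * ring$cwa
  a <- aggregate_ring(ring); b <- aggregate_ring(dbl)
  expect_equal(b$Dh / a$Dh, 2, tolerance = 1e-9)
  expect_equal(b$tb2, a$tb2, tolerance = 1e-9)
  expect_equal(b$RWD, a$RWD, tolerance = 1e-9)
})

test_that("derived trait tables satisfy the partition and ordering invariants", {
  ds <- simulate_dataset(tiny_config(seed = 34))
  tr <- derive_traits(ds$cells, ds$meta)
  expect_equal(tr$`EW%` + tr$`LW%`, rep(100, nrow(tr)), tolerance = 1e-9)
  expect_equal(tr$EWW + tr$LWW, tr$TRW, tolerance = 1e-6)
  expect_equal(tr$CNO_EW + tr$CNO_LW, tr$CNO)
  expect_true(all(tr$LA_01 <= tr$LA_25 & tr$LA_25 <= tr$LA_50 &
                  tr$LA_50 <= tr$LA_75 & tr$LA_75 <= tr$LA_99))
  expect_true(all(tr$RWD > 0 & tr$RWD < 1))
  expect_true(all(tr$BAI > 0))
  # thickening walls weakly increases RWD, CWT means and tb2
  ring <- ds$cells[ds$cells$tree_id == tr$tree_id[1] &
                   ds$cells$year == tr$year[1], ]
  thick <- ring
  for (cc in c("cwt_pi", "cwt_ba", "cwt_le", "cwt_ri"))
    thick[[cc]] <- thick[[cc]] * 1.3
  thick$cwa <- (thick$drad_lumen + thick$cwt_le + thick$cwt_ri) *
    (thick$dtan_lumen + thick$cwt_pi + thick$cwt_ba) - thick$lumen_area
  a <- aggregate_ring(ring); b <- aggregate_ring(thick)
  expect_gte(b$RWD, a$RWD)
  expect_gte(b$CWTall, a$CWTall)
  expect_gte(b$tb2, a$tb2)
})
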