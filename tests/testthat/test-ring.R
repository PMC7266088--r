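test_that("zero-variance configuration makes equal trees produce identical rings", {
  plots <- default_plot_table(1)
  cfg <- generator_config(
    n_plots = 1, trees_per_plot = 2, years = 2012, plots = plots,
    sd_individual = c(count = 0, dtan = 0, drad = 0, cwt = 0),
    sd_year = c(count = 0, dtan = 0, drad = 0, cwt = 0),
    sd_cell = c(count = 0, drad = 0, dtan = 0, cwt = 0),
    lw_cell_count_sd = 0, rng_seed = 3)
  st <- sample_stand(cfg)
  # force identical covariates
  st$meta$height[] <- 15; st$meta$age[] <- 50
  st$truth$meta <- st$meta
  r1 <- simulate_ring(st$meta$tree_id[1], 2012, st$truth)
  r2 <- simulate_ring(st$meta$tree_id[2], 2012, st$truth)
  expect_equal(r1[setdiff(names(r1), "tree_id")],
               r2[setdiff(names(r2), "tree_id")])
})

test_that("taller trees get wider tangential lumina and fewer files (all else equal)", {
  plots <- default_plot_table(1)
  cfg <- generator_config(
    n_plots = 1, trees_per_plot = 2, years = 2012, plots = plots,
    sd_individual = c(count = 0, dtan = 0, drad = 0, cwt = 0),
    sd_year = c(count = 0, dtan = 0, drad = 0, cwt = 0),
    sd_cell = c(count = 0, drad = 0, dtan = 0, cwt = 0),
    lw_cell_count_sd = 0, rng_seed = 4)
  st <- sample_stand(cfg)
  st$meta$height <- c(11, 27); st$meta$age[] <- 60
  st$truth$meta <- st$meta
  short <- simulate_ring(st$meta$tree_id[1], 2012, st$truth)
  tall <- simulate_ring(st$meta$tree_id[2], 2012, st$truth)
  lab_s <- classify_ew_lw(short)$labels
  lab_t <- classify_ew_lw(tall)$labels
  expect_gt(mean(tall$dtan_lumen[lab_t == "EW"]),
            mean(short$dtan_lumen[lab_s == "EW"]))
  expect_gt(mean(tall$drad_lumen[lab_t == "EW"]),
            mean(short$drad_lumen[lab_s == "EW"]))
  expect_lt(max(tall$file_index), max(short$file_index))
})

test_that("older trees get thicker walls and more latewood (all else equal)", {
  plots <- default_plot_table(1)
  cfg <- generator_config(
    n_plots = 1, trees_per_plot = 2, years = 2012, plots = plots,
    sd_individual = c(count = 0, dtan = 0, drad = 0, cwt = 0),
    sd_year = c(count = 0, dtan = 0, drad = 0, cwt = 0),
    sd_cell = c(count = 0, drad = 0, dtan = 0, cwt = 0),
    lw_cell_count_sd = 0, rng_seed = 5)
  st <- sample_stand(cfg)
  st$meta$height[] <- 15; st$meta$age <- c(40, 150)
  st$truth$meta <- st$meta
  young <- aggregate_ring(simulate_ring(st$meta$tree_id[1], 2012, st$truth))
  old <- aggregate_ring(simulate_ring(st$meta$tree_id[2], 2012, st$truth))
  expect_gt(old$CWTall, young$CWTall)
  expect_gt(old$`LW%`, young$`LW%`)
})

test_that("every default ring shows a clear earlywood-latewood contrast", {
  ds <- simulate_dataset(generator_config(trees_per_plot = 3, rng_seed = 6))
  key <- interaction(ds$cells$tree_id, ds$cells$year, drop = TRUE)
  for (ring in split(ds$cells, key)) {
    m <- mork_index(ring)
    expect_gte(sum(m >= 1), 3)
    expect_gte(sum(m < 1), 3)
  }
})

test_that("cells constructed as the profile tail are labelled latewood by the Mork rule", {
  cfg <- generator_config(trees_per_plot = 3, rng_seed = 7)
  st <- sample_stand(cfg)
  agree <- total <- 0
  for (tid in st$meta$tree_id) {
    ring <- simulate_ring(tid, 2012, st$truth)
    pr <- ring_params(st$truth, tid, 2012)
    lab <- classify_ew_lw(ring)$labels
    # construction truth: the last lw_mean-ish cells of each file are LW;
    # recover per-file intended LW count from the cell indices
    for (f in split(seq_len(nrow(ring)), ring$file_index)) {
      n <- length(f)
      # intended LW cells sit at the file tail; compare label blocks
      n_lw_lab <- sum(lab[f] == "LW")
      tail_idx <- f[ring$cell_index[f] > n - n_lw_lab]
      agree <- agree + sum(lab[tail_idx] == "LW")
      total <- total + n_lw_lab
    }
  }
  expect_gte(agree / total, 0.95)
})

test_that("simulated datasets are deterministic and have trees x years rings", {
  cfg <- tiny_config(seed = 9)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$cells, b$cells)
  key <- unique(a$cells[c("tree_id", "year")])
  expect_equal(nrow(key), nrow(a$meta) * length(cfg$years))
  # byte-identical CSV under a fixed seed
  f1 <- tempfile(); f2 <- tempfile()
  on.exit(unlink(c(f1, f2)))
  write_cell_table(a$cells, f1)
  write_cell_table(b$cells, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("individual variance dominates year variance in derived traits", {
  ds <- simulate_dataset(generator_config(rng_seed = 10))
  tr <- derive_traits(ds$cells, ds$meta)
  for (trait in c("TRW", "Dtan", "CWTall")) {
    fit <- stats::aov(tr[[trait]] ~ factor(tr$tree_id) + factor(tr$year))
    ms <- summary(fit)[[1]][["Mean Sq"]]
    expect_gt(ms[1], ms[2])   # individual mean square > year mean square
  }
})

test_that("infeasible parameter combinations raise a generation error", {
  cfg <- tiny_config(seed = 2)
  st <- sample_stand(cfg)
  st$truth$ind_effects[1, "drad"] <- -50   # drives ew_drad negative
  expect_error(simulate_ring(st$meta$tree_id[1], cfg$years[1], st$truth),
               "infeasible")
  expect_error(ring_params(st$truth, "nope", cfg$years[1]), "nope")
})
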