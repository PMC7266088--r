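test_that("the default stand respects plot ranges and layout", {
  st <- sample_stand(generator_config(rng_seed = 11))
  expect_equal(nrow(st$meta), 30)
  expect_equal(as.integer(table(st$meta$plot)[c("CAM-H", "CAM-E", "CAM-L")]),
               rep(10L, 3))
  expect_true(all(st$meta$height >= 10.5 & st$meta$height <= 33))
  expect_true(all(st$meta$age >= 34 & st$meta$age <= 155))
  cfg <- generator_config()
  for (k in 1:3) {
    pl <- cfg$plots[k, ]
    m <- st$meta[st$meta$plot == pl$code, ]
    expect_true(all(m$height >= pl$height_min & m$height <= pl$height_max))
    expect_true(all(m$age >= pl$age_min - 0.5 & m$age <= pl$age_max + 0.5))
    expect_true(all(m$dbh >= pl$dbh_min & m$dbh <= pl$dbh_max))
  }
})

test_that("stand sampling is deterministic under a fixed seed", {
  cfg <- generator_config(trees_per_plot = 2, rng_seed = 123)
  a <- sample_stand(cfg)
  b <- sample_stand(cfg)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth$ind_effects, b$truth$ind_effects)
  expect_identical(a$truth$year_effects, b$truth$year_effects)
})

test_that("within-plot height-age correlation hits the 0.4-0.7 target on average", {
  rs <- vapply(1:100, function(s) {
    st <- sample_stand(generator_config(rng_seed = s))
    mean(vapply(unique(st$meta$plot), function(pl) {
      m <- st$meta[st$meta$plot == pl, ]
      cor(m$height, m$age)
    }, numeric(1)))
  }, numeric(1))
  expect_gt(mean(rs), 0.4)
  expect_lt(mean(rs), 0.7)
})

test_that("spatial autocorrelation correlates neighbours' effects only when enabled", {
  moran_like <- function(eff, x, y, range_m) {
    d <- as.matrix(dist(cbind(x, y)))
    w <- exp(-d^2 / (2 * range_m^2)); diag(w) <- 0
    e <- eff - mean(eff)
    sum(w * outer(e, e)) / (sum(w) * var(e))
  }
  on <- off <- numeric(60)
  for (i in seq_len(60)) {
    plots <- default_plot_table(1)
    plots$spatial_range <- 25
    st1 <- sample_stand(generator_config(
      n_plots = 1, trees_per_plot = 15, plots = plots, rng_seed = i))
    plots$spatial_range <- 0
    st0 <- sample_stand(generator_config(
      n_plots = 1, trees_per_plot = 15, plots = plots, rng_seed = i))
    p1 <- st1$truth$positions
    on[i] <- moran_like(st1$truth$ind_effects[, "count"], p1$x_m, p1$y_m, 25)
    p0 <- st0$truth$positions
    off[i] <- moran_like(st0$truth$ind_effects[, "count"], p0$x_m, p0$y_m, 25)
  }
  # the null expectation of a Moran-like statistic is -1/(n-1), not 0
  expect_gt(mean(on), 0)
  expect_gt(unname(t.test(on, off)$statistic), 3)
  expect_lt(abs(mean(off) + 1 / 14), 0.08)
})
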