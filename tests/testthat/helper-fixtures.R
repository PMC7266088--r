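# Shared fixtures: small configurations and hand-built rings.

# a fast stand: 2 plots x 3 trees x 2 years, few cells per file
tiny_config <- function(seed = 1, years = 2010:2011, trees = 3) {
  plots <- default_plot_table(2)
  generator_config(n_plots = 2, trees_per_plot = trees, years = years,
                   plots = plots, ew_cell_count_mean = 12,
                   rng_seed = seed)
}

# a deterministic single-file ring built by hand
# drad/cwt chosen so cells 1..n_ew are earlywood, the rest latewood (Mork)
hand_ring <- function(n_ew = 6, n_lw = 4, drad_ew = 30, drad_lw = 5,
                      cwt_ew = 2, cwt_lw = 4, dtan = 25, files = 1,
                      tree_id = "T1", year = 2012) {
  one_file <- function(fi) {
    n <- n_ew + n_lw
    drad <- c(rep(drad_ew, n_ew), rep(drad_lw, n_lw))
    cwt <- c(rep(cwt_ew, n_ew), rep(cwt_lw, n_lw))
    ext <- drad + 2 * cwt
    la <- pi / 4 * drad * dtan
    cwa <- ext * (dtan + 2 * cwt) - la
    data.frame(tree_id = tree_id, year = year, file_index = fi,
               cell_index = seq_len(n),
               rel_pos = (cumsum(ext) - ext / 2) / sum(ext),
               drad_lumen = drad, dtan_lumen = dtan, lumen_area = la,
               cwt_pi = cwt, cwt_ba = cwt, cwt_le = cwt, cwt_ri = cwt,
               cwa = cwa, stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(seq_len(files), one_file))
}

# uniform ring of identical circular-ish cells
uniform_ring <- function(n = 8, drad = 20, dtan = 20, cwt = 2.5,
                         files = 1, tree_id = "U1", year = 2012) {
  hand_ring(n_ew = n, n_lw = 0, drad_ew = drad, cwt_ew = cwt,
            dtan = dtan, files = files, tree_id = tree_id, year = year)
}
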