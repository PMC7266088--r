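# Brute-force per-cell oracle: every derived ring trait recomputed with
# explicit loops and hand-coded percentile interpolation, independent of the
# package's vectorized path.

oracle_quantile <- function(x, p) {
  # linear interpolation between order statistics (type 7)
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

oracle_mean <- function(x) if (length(x)) sum(x) / length(x) else NA_real_

oracle_ring_traits <- function(cells, strip_mm = 1, eta = 1.002e-9,
                               rho = 998.2) {
  n <- nrow(cells)
  mork <- cwttan <- cwtrad <- cwtall <- rwd <- tb2 <- ext <- numeric(n)
  for (i in seq_len(n)) {
    cwtrad[i] <- (cells$cwt_le[i] + cells$cwt_ri[i]) / 2
    cwttan[i] <- (cells$cwt_pi[i] + cells$cwt_ba[i]) / 2
    cwtall[i] <- (cwtrad[i] + cwttan[i]) / 2
    mork[i] <- 4 * cwtrad[i] / cells$drad_lumen[i]
    rwd[i] <- cells$cwa[i] / (cells$cwa[i] + cells$lumen_area[i])
    t_rad <- 2 * cwtrad[i] / cells$drad_lumen[i]
    t_tan <- 2 * cwttan[i] / cells$dtan_lumen[i]
    tb2[i] <- (min(t_rad, t_tan))^2
    ext[i] <- cells$drad_lumen[i] + cells$cwt_le[i] + cells$cwt_ri[i]
  }
  lw <- mork >= 1
  files <- sort(unique(cells$file_index))
  trw_f <- eww_f <- numeric(length(files))
  for (k in seq_along(files)) {
    idx <- which(cells$file_index == files[k])
    for (i in idx) {
      trw_f[k] <- trw_f[k] + ext[i]
      if (!lw[i]) eww_f[k] <- eww_f[k] + ext[i]
    }
  }
  trw <- oracle_mean(trw_f)
  eww <- oracle_mean(eww_f)
  lww <- trw - eww
  ewp <- 100 * eww / trw
  lwp <- 100 - ewp
  cno <- n
  cno_lw <- sum(lw)
  cno_ew <- cno - cno_lw
  lw_files <- 0
  for (k in seq_along(files))
    if (any(lw[cells$file_index == files[k]])) lw_files <- lw_files + 1
  n_tang <- lw_files / strip_mm
  d <- numeric(n); k_cond <- numeric(n)
  for (i in seq_len(n)) {
    d[i] <- 2 * sqrt(cells$lumen_area[i] / pi)
    a <- cells$drad_lumen[i] / 2 * 1e-6
    b <- cells$dtan_lumen[i] / 2 * 1e-6
    k_cond[i] <- pi * a^3 * b^3 / (4 * eta * (a^2 + b^2))
  }
  dh <- sum(d^5) / sum(d^4)
  kh <- sum(k_cond)
  ks <- kh / ((trw * 1e-6) * (strip_mm * 1e-3))
  hcue <- kh * rho / sum(cells$cwa)
  pvec <- c(1, 25, 50, 75, 99) / 100
  sfx <- c("_01", "_25", "_50", "_75", "_99")
  wp <- function(x, base) {
    out <- c(oracle_mean(x), oracle_mean(x[!lw]), oracle_mean(x[lw]))
    for (j in seq_along(pvec)) out <- c(out, oracle_quantile(x, pvec[j]))
    names(out) <- c(base, paste0(base, "_EW"), paste0(base, "_LW"),
                    paste0(base, sfx))
    out
  }
  out <- c(
    TRW = trw, `EW%` = ewp, `LW%` = lwp,
    `LW%/EW%` = if (ewp > 0) lwp / ewp else NA_real_,
    NoCells_tang = n_tang, NoCells_rad = cno / n_tang,
    EW_Nocells = cno_ew / n_tang, LW_Nocells = cno_lw / n_tang,
    EWW = eww, LWW = lww,
    Drad = oracle_mean(cells$drad_lumen), Dtan = oracle_mean(cells$dtan_lumen),
    Drad_EW = oracle_mean(cells$drad_lumen[!lw]),
    Dtan_LW = oracle_mean(cells$dtan_lumen[lw]),
    CWA = oracle_mean(cells$cwa), CWA_EW = oracle_mean(cells$cwa[!lw]),
    CWA_LW = oracle_mean(cells$cwa[lw]),
    LA = oracle_mean(cells$lumen_area))
  for (j in seq_along(pvec))
    out[paste0("LA", sfx[j])] <- oracle_quantile(cells$lumen_area, pvec[j])
  out <- c(out,
           CD = cno / ((trw / 1000) * strip_mm),
           CNO = cno, CNO_EW = cno_ew, CNO_LW = cno_lw,
           wp(cwtall, "CWTall"), wp(cwttan, "CWTtan"), wp(cwtrad, "CWTrad"),
           wp(mork, "rTSR"), wp(rwd, "RWD"),
           Dh = dh, Ks = ks, Kh = kh,
           tb2 = oracle_mean(tb2), tb2_05 = oracle_quantile(tb2, 0.05),
           HCUE = hcue)
  out
}

# numerically searched 2-D Procrustes correlation: best rotation/reflection
# angle by grid + golden-section refinement, an independent check of the
# SVD-based statistic
oracle_protest_r_2d <- function(x, y) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- scale(y, center = TRUE, scale = FALSE)
  xc <- xc / sqrt(sum(xc^2)); yc <- yc / sqrt(sum(yc^2))
  fit <- function(theta, reflect) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    if (reflect) R <- R %*% diag(c(1, -1))
    sum(diag(crossprod(xc, yc %*% R)))   # best uniform scaling -> r = trace
  }
  best <- -Inf
  for (reflect in c(FALSE, TRUE)) {
    g <- vapply(seq(-pi, pi, length.out = 721), fit, numeric(1),
                reflect = reflect)
    th0 <- seq(-pi, pi, length.out = 721)[which.max(g)]
    opt <- stats::optimize(fit, c(th0 - 0.02, th0 + 0.02), reflect = reflect,
                           maximum = TRUE, tol = 1e-12)
    best <- max(best, opt$objective)
  }
  best
}
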