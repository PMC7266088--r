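# The statistical chain: best-of-three curve fits, year-wise PCA, backward
# LRT model selection, Mantel and Procrustes permutation tests, CV-based
# trait stability.  The permutation machinery is written out in full; the
# established implementations (vegan) serve only as cross-checks in the
# test suite.

#' Best-fitting curve among linear, exponential and logarithmic
#'
#' Fits `y ~ x` (linear), `log(y) ~ x` (exponential) and `y ~ log(x)`
#' (logarithmic) by least squares and returns the family with the highest
#' R^2, each R^2 computed in its own fitted space (the exponential and
#' logarithmic fits transform the y- and x-axis respectively).  Families
#' whose transform is undefined (non-positive y or x) are skipped.  Note
#' this is an R^2 contest across different response spaces, not a
#' likelihood comparison.
#'
#' @param x,y numeric vectors (pairs with missing values are dropped).
#' @return an object of class `xylo_curvefit`: family, intercept, slope
#'   (in the fitted space), `r_squared`, `p_value` (slope F test), `n`,
#'   and the set of eligible families.
#' @export
fit_best_curve <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3)
    stop("fit_best_curve: insufficient data (n < 3)", call. = FALSE)
  fams <- list(
    linear      = if (stats::var(x) > 0) list(xx = x, yy = y),
    exponential = if (all(y > 0) && stats::var(x) > 0)
      list(xx = x, yy = log(y)),
    logarithmic = if (all(x > 0) && stats::var(log(x)) > 0)
      list(xx = log(x), yy = y)
  )
  fams <- Filter(Negate(is.null), fams)
  if (length(fams) == 0)
    stop("fit_best_curve: no eligible family (non-positive data)",
         call. = FALSE)
  fits <- lapply(fams, function(f) {
    m <- stats::lm(f$yy ~ f$xx)
    sm <- summary(m)
    p <- if (is.null(sm$fstatistic)) NA_real_ else
      stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                lower.tail = FALSE)
    list(coef = stats::coef(m), r2 = sm$r.squared, p = unname(p))
  })
  r2 <- vapply(fits, `[[`, numeric(1), "r2")
  best <- names(which.max(r2))
  f <- fits[[best]]
  structure(list(family = best,
                 intercept = unname(f$coef[1]), slope = unname(f$coef[2]),
                 r_squared = f$r2, p_value = f$p, n = n,
                 eligible = names(fams)),
            class = "xylo_curvefit")
}

#' @export
print.xylo_curvefit <- function(x, ...) {
  cat(sprintf("Best curve: %s (n = %d)\n", x$family, x$n))
  cat(sprintf("  intercept %.6g, slope %.6g (fitted space), R2 = %.4f, p = %.3g\n",
              x$intercept, x$slope, x$r_squared, x$p_value))
  if (length(x$eligible) < 3)
    cat("  eligible families:", paste(x$eligible, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.xylo_curvefit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.xylo_curvefit <- function(object, newdata, ...) {
  x <- if (is.list(newdata)) newdata$x else newdata
  switch(object$family,
         linear      = object$intercept + object$slope * x,
         exponential = exp(object$intercept + object$slope * x),
         logarithmic = object$intercept + object$slope * log(x))
}

#' Year-wise principal component analysis of standardized traits
#'
#' Standardizes every trait column to zero mean and unit (n-1) standard
#' deviation and decomposes the correlation structure with [stats::prcomp()].
#' A deterministic sign convention is applied: within each component the
#' loading of largest magnitude is made positive.
#'
#' @param x individuals x traits matrix or data.frame, rownames = tree ids.
#' @param year calendar year the matrix belongs to (bookkeeping only).
#' @param on_constant `"error"` (default) stops naming the first
#'   zero-variance trait; `"drop"` removes such traits with a warning.
#' @return an object of class `xylo_pca`: `year`, `traits`, `center`,
#'   `scale`, `loadings`, `scores`, `sdev` and `var_share` (percent,
#'   summing to 100).
#' @export
pca_year <- function(x, year = NULL, on_constant = c("error", "drop")) {
  on_constant <- match.arg(on_constant)
  x <- as.matrix(x)
  if (nrow(x) < 3)
    stop("pca_year: need at least 3 individuals", call. = FALSE)
  if (anyNA(x))
    stop("pca_year: missing values; filter trait completeness first",
         call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    cst <- colnames(x)[sds == 0]
    if (on_constant == "error")
      stop("pca_year: constant trait (SD = 0): ", cst[1], call. = FALSE)
    warning("pca_year: dropping constant trait(s): ",
            paste(cst, collapse = ", "), call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  for (k in seq_len(ncol(pc$rotation))) {
    m <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[m, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  structure(list(year = year, traits = colnames(x),
                 center = pc$center, scale = pc$scale,
                 loadings = pc$rotation, scores = pc$x, sdev = pc$sdev,
                 var_share = 100 * pc$sdev^2 / sum(pc$sdev^2)),
            class = "xylo_pca")
}

#' @export
print.xylo_pca <- function(x, n = 3, ...) {
  hdr <- if (is.null(x$year)) "PCA" else sprintf("PCA (year %s)", x$year)
  cat(sprintf("%s: %d individuals x %d traits\n", hdr, nrow(x$scores),
              length(x$traits)))
  k <- min(n, length(x$var_share))
  cat("  variance share (%):",
      paste(sprintf("PC%d %.1f", seq_len(k), x$var_share[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.xylo_pca <- function(x, comps = c(1, 2), ...) {
  s <- x$scores[, comps, drop = FALSE]
  graphics::plot(s, asp = 1,
                 xlab = sprintf("PC%d (%.1f%%)", comps[1],
                                x$var_share[comps[1]]),
                 ylab = sprintf("PC%d (%.1f%%)", comps[2],
                                x$var_share[comps[2]]), ...)
  graphics::abline(h = 0, v = 0, lty = 3, col = "grey60")
  graphics::text(s, labels = rownames(s), pos = 3, cex = 0.6)
  invisible(x)
}

#' Backward model selection by likelihood-ratio tests
#'
#' Starts from `response ~ height + age + plot` (plot a categorical block)
#' and repeatedly removes the term whose deletion gives the largest
#' likelihood-ratio p-value above `alpha`, until every remaining deletion is
#' significant.  The LRT compares nested linear models via their Gaussian
#' log-likelihoods.  A `drop1` F table of the full model (equivalent to
#' Type-II tests for this additive design) is attached for comparison.
#'
#' @param response numeric vector (e.g. a PC score).
#' @param covariates data.frame with columns `height`, `age`, `plot`.
#' @param alpha drop threshold for the LRT p-value.
#' @return an object of class `xylo_selection`: retained terms,
#'   coefficient table of the final model, the drop trail (term, LRT
#'   statistic, df, p per removal), the full-model F table and `alpha`.
#' @export
backward_select <- function(response, covariates, alpha = 0.05) {
  need <- c("height", "age", "plot")
  miss <- setdiff(need, names(covariates))
  if (length(miss))
    stop("backward_select: covariates must contain ",
         paste(miss, collapse = ", "), call. = FALSE)
  dat <- data.frame(.y = response, covariates[need])
  dat$plot <- factor(dat$plot)
  terms_now <- c("height", "age", if (nlevels(dat$plot) > 1) "plot")
  full_formula <- stats::reformulate(terms_now, response = ".y")
  full <- stats::lm(full_formula, data = dat)
  mm <- stats::model.matrix(full)
  if (qr(mm)$rank < ncol(mm))
    stop("backward_select: rank-deficient design (collinear covariates)",
         call. = FALSE)
  if (nrow(dat) <= ncol(mm))
    stop("backward_select: n must exceed the number of model parameters",
         call. = FALSE)
  type2 <- stats::drop1(full, test = "F")
  trail <- data.frame(term = character(), statistic = numeric(),
                      df = numeric(), p = numeric(),
                      stringsAsFactors = FALSE)
  model <- full
  repeat {
    if (length(terms_now) == 0) break
    tests <- lapply(terms_now, function(tt) {
      red_terms <- setdiff(terms_now, tt)
      red_formula <- if (length(red_terms))
        stats::reformulate(red_terms, response = ".y") else .y ~ 1
      red <- stats::lm(red_formula, data = dat)
      stat <- as.numeric(2 * (stats::logLik(model) - stats::logLik(red)))
      df <- attr(stats::logLik(model), "df") - attr(stats::logLik(red), "df")
      list(term = tt, statistic = stat, df = df,
           p = stats::pchisq(stat, df, lower.tail = FALSE), red = red)
    })
    ps <- vapply(tests, `[[`, numeric(1), "p")
    worst <- which.max(ps)
    if (ps[worst] <= alpha) break
    tw <- tests[[worst]]
    trail <- rbind(trail, data.frame(term = tw$term, statistic = tw$statistic,
                                     df = tw$df, p = tw$p,
                                     stringsAsFactors = FALSE))
    terms_now <- setdiff(terms_now, tw$term)
    model <- tw$red
  }
  structure(list(retained = terms_now,
                 coefficients = summary(model)$coefficients,
                 trail = trail, type2_full = type2, alpha = alpha,
                 model = model, n = nrow(dat)),
            class = "xylo_selection")
}

#' @export
print.xylo_selection <- function(x, ...) {
  cat("Backward LRT selection (alpha =", x$alpha, ")\n")
  if (nrow(x$trail)) {
    cat("  dropped:",
        paste(sprintf("%s (p = %.3f)", x$trail$term, x$trail$p),
              collapse = ", "), "\n")
  }
  cat("  retained:",
      if (length(x$retained)) paste(x$retained, collapse = " + ")
      else "(intercept only)", "\n")
  stats::printCoefmat(x$coefficients, digits = 4)
  invisible(x)
}

#' @export
coef.xylo_selection <- function(object, ...) {
  stats::coef(object$model)
}

lower_tri <- function(m) m[lower.tri(m)]

as_dist_matrix <- function(d, arg) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m))
    stop("mantel_test: `", arg, "` is not square", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8)
    stop("mantel_test: `", arg, "` is not symmetric", call. = FALSE)
  if (any(abs(diag(m)) > 1e-12))
    stop("mantel_test: `", arg, "` has a non-zero diagonal", call. = FALSE)
  m
}

#' Mantel test between two distance matrices
#'
#' The statistic is the Pearson correlation over the strict lower triangles.
#' The null distribution permutes the rows and columns of the second matrix
#' simultaneously; the one-tailed (greater) p-value uses the add-one
#' convention `(#{r_perm >= r_obs} + 1) / (n_perm + 1)`, so it is never 0.
#'
#' @param d_geo,d_trait distance matrices (or `dist` objects) of the same
#'   order.
#' @param n_perm number of permutations.
#' @param seed optional RNG seed for the permutations.
#' @return an object of class `xylo_mantel`: `r`, `p`, `n_perm`, `seed`, `n`.
#' @export
mantel_test <- function(d_geo, d_trait, n_perm = 999, seed = NULL) {
  m1 <- as_dist_matrix(d_geo, "d_geo")
  m2 <- as_dist_matrix(d_trait, "d_trait")
  if (nrow(m1) != nrow(m2))
    stop("mantel_test: dimension mismatch", call. = FALSE)
  n <- nrow(m1)
  v1 <- lower_tri(m1)
  r_obs <- stats::cor(v1, lower_tri(m2))
  if (!is.null(seed)) set.seed(seed)
  r_perm <- vapply(seq_len(n_perm), function(b) {
    p <- sample.int(n)
    stats::cor(v1, lower_tri(m2[p, p]))
  }, numeric(1))
  structure(list(r = r_obs,
                 p = (sum(r_perm >= r_obs) + 1) / (n_perm + 1),
                 n_perm = n_perm, seed = seed, n = n),
            class = "xylo_mantel")
}

#' @export
print.xylo_mantel <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%d permutations, n = %d)\n",
              x$r, x$p, x$n_perm, x$n))
  invisible(x)
}

protest_stat <- function(xc, yc) {
  # both configurations centered and Frobenius-normalized beforehand
  sum(La.svd(crossprod(yc, xc), nu = 0, nv = 0)$d)^2
}

#' Procrustes correlation test between two point configurations
#'
#' Both configurations (e.g. PC scores of two years, same individuals in the
#' same row order) are column-centered and scaled to unit sum of squares;
#' the optimal rotation comes from the singular value decomposition of the
#' cross-product.  The fit statistic is `m2 = 1 - (sum of singular values)^2`
#' and the correlation `r = sqrt(1 - m2)`, invariant to translation, uniform
#' scaling and rotation/reflection of either configuration.  Significance is
#' assessed by permuting the rows of the second configuration (one-tailed,
#' add-one convention).
#'
#' @param x,y numeric matrices, individuals x components, same shape.
#' @param n_perm number of permutations.
#' @param seed optional RNG seed for the permutations.
#' @return an object of class `xylo_protest`: `r`, `m2`, `p`, `n_perm`,
#'   `seed`, `n`.
#' @export
procrustes_protest <- function(x, y, n_perm = 999, seed = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == dim(y)))
    stop("procrustes_protest: shape mismatch", call. = FALSE)
  n <- nrow(x)
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- scale(y, center = TRUE, scale = FALSE)
  xc <- xc / sqrt(sum(xc^2))
  yc <- yc / sqrt(sum(yc^2))
  ss <- protest_stat(xc, yc)
  m2 <- 1 - ss
  r_obs <- sqrt(max(ss, 0))
  if (!is.null(seed)) set.seed(seed)
  r_perm <- vapply(seq_len(n_perm), function(b) {
    sqrt(max(protest_stat(xc, yc[sample.int(n), , drop = FALSE]), 0))
  }, numeric(1))
  structure(list(r = r_obs, m2 = m2,
                 p = (sum(r_perm >= r_obs) + 1) / (n_perm + 1),
                 n_perm = n_perm, seed = seed, n = n),
            class = "xylo_protest")
}

#' @export
print.xylo_protest <- function(x, ...) {
  cat(sprintf("Procrustes test: r = %.4f (m2 = %.4f), p = %.4g (%d permutations, n = %d)\n",
              x$r, x$m2, x$p, x$n_perm, x$n))
  invisible(x)
}

#' Inter-annual trait stability (coefficient of variation ranking)
#'
#' For every trait and individual, the coefficient of variation over years
#' (`100 * sd / mean`, n-1 denominator) is computed; individual CVs are then
#' averaged across individuals, and their range (max - min) recorded.
#' Traits are ranked by descending mean CV and flagged at the conventional
#' 10% (mean) and 20% (range) thresholds.  An individual whose trait mean is
#' 0 yields an undefined CV, reported missing with a warning.
#'
#' @param traits trait table over several years ([derive_traits()] layout).
#' @param flag_mean,flag_range flag thresholds (percent).
#' @return an object of class `xylo_stability` wrapping a data.frame with
#'   one row per trait: `trait`, `mean_cv`, `cv_range`, `flag_mean`,
#'   `flag_range`, `flagged`, `rank`.
#' @export
trait_cv <- function(traits, flag_mean = 10, flag_range = 20) {
  trait_cols <- intersect(xylo_trait_names(), names(traits))
  ids <- unique(traits$tree_id)
  yrs_per_id <- vapply(ids, function(i)
    length(unique(traits$year[traits$tree_id == i])), integer(1))
  if (any(yrs_per_id < 2))
    stop("trait_cv: every individual needs at least 2 years", call. = FALSE)
  warned <- FALSE
  rows <- lapply(trait_cols, function(tc) {
    cvs <- vapply(ids, function(i) {
      v <- traits[[tc]][traits$tree_id == i]
      v <- v[is.finite(v)]
      if (length(v) < 2) return(NA_real_)
      m <- mean(v)
      if (m == 0) return(NA_real_)
      100 * stats::sd(v) / abs(m)
    }, numeric(1))
    if (anyNA(cvs) && !warned) {
      warned <<- TRUE
      warning("trait_cv: undefined CV (zero mean or missing years) for some individuals; reported missing",
              call. = FALSE)
    }
    cvs <- cvs[is.finite(cvs)]
    if (length(cvs) == 0)
      return(data.frame(trait = tc, mean_cv = NA_real_, cv_range = NA_real_,
                        stringsAsFactors = FALSE))
    data.frame(trait = tc, mean_cv = mean(cvs),
               cv_range = max(cvs) - min(cvs), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$flag_mean <- out$mean_cv > flag_mean
  out$flag_range <- out$cv_range > flag_range
  out$flagged <- out$flag_mean & out$flag_range
  out$rank <- rank(-out$mean_cv, ties.method = "first", na.last = "keep")
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  structure(list(table = out, flag_mean = flag_mean,
                 flag_range = flag_range),
            class = "xylo_stability")
}

#' @export
print.xylo_stability <- function(x, n = 10, ...) {
  tb <- x$table
  cat(sprintf("Trait stability: %d traits, %d flagged (mean CV > %g%% and range > %g%%)\n",
              nrow(tb), sum(tb$flagged, na.rm = TRUE), x$flag_mean,
              x$flag_range))
  cat("  most variable:\n")
  print(utils::head(tb[c("trait", "mean_cv", "cv_range", "flagged")], n),
        digits = 4)
  invisible(x)
}

#' Pairwise best-curve scan over trait pairs
#'
#' Applies [fit_best_curve()] to each requested pair and attaches a
#' Benjamini-Hochberg adjusted p-value column for reference; no correction
#' is applied to the family selection itself.
#'
#' @param data data.frame holding the variables.
#' @param pairs two-column character matrix or data.frame of (x, y) names.
#' @return data.frame with one row per pair: family, intercept, slope,
#'   `r_squared`, `p_value`, `p_bh`, `n`.
#' @export
pairwise_trait_scan <- function(data, pairs) {
  pairs <- as.matrix(pairs)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    fit <- fit_best_curve(data[[pairs[i, 1]]], data[[pairs[i, 2]]])
    data.frame(x = pairs[i, 1], y = pairs[i, 2], family = fit$family,
               intercept = fit$intercept, slope = fit$slope,
               r_squared = fit$r_squared, p_value = fit$p_value, n = fit$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out
}
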