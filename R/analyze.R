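# Whole-dataset analysis: year-wise PCA, backward selection of the outermost
# year's PC scores on height/age/plot, within-plot Mantel tests, pairwise
# inter-annual Procrustes tests, and the CV stability ranking.

#' Trait matrix of one year, individuals in rows
#'
#' @param traits trait table ([derive_traits()] layout).
#' @param year calendar year to extract.
#' @param trait_cols trait columns to keep (default: full catalogue).
#' @return numeric matrix with tree ids as rownames, ordered by tree id.
#' @export
trait_matrix <- function(traits, year, trait_cols = xylo_trait_names()) {
  sub <- traits[traits$year == year, , drop = FALSE]
  sub <- sub[order(sub$tree_id), , drop = FALSE]
  m <- as.matrix(sub[intersect(trait_cols, names(sub))])
  rownames(m) <- sub$tree_id
  m
}

# traits usable in every year: finite everywhere and non-constant per year
complete_trait_set <- function(traits, years) {
  keep <- xylo_trait_names()
  for (yr in years) {
    m <- trait_matrix(traits, yr, keep)
    ok <- apply(m, 2, function(v) all(is.finite(v)) && stats::sd(v) > 0)
    keep <- colnames(m)[ok]
  }
  keep
}

#' Run the full statistical chain on a trait table
#'
#' Performs, per calendar year, a PCA on the standardized complete-trait
#' matrix; regresses the first `n_pcs_regression` PC scores of the outermost
#' year on tree height, age and plot with backward LRT selection; runs
#' within-plot Mantel tests between geographic distance and Euclidean
#' distance over the outermost year's leading PC scores; tests the
#' inter-annual stability of score configurations with pairwise Procrustes
#' tests; and ranks traits by their inter-annual coefficient of variation.
#'
#' Traits that are incomplete or constant in any year are removed first
#' (with a warning) so that every year's PCA sees the same trait set.
#'
#' @param traits trait table ([derive_traits()] layout), >= 3 individuals.
#' @param meta tree metadata table.
#' @param alpha LRT drop threshold for [backward_select()].
#' @param n_perm permutations for the Mantel and Procrustes tests.
#' @param seed RNG seed for the permutation tests.
#' @param n_pcs_regression number of leading PCs regressed on covariates.
#' @param n_pcs_procrustes number of PCs entering the Procrustes tests.
#' @param n_pcs_mantel number of PCs behind the Mantel trait distances.
#' @return an object of class `xylo_analysis`: `pca` (list by year),
#'   `selection` (list by PC), `mantel` (list by plot), `procrustes`
#'   (data.frame of year pairs plus the test objects), `stability`,
#'   `trait_set`, and the settings used.  Stages needing >= 2 years are
#'   `NULL`, with a message, when only one year is present.
#' @export
analyze_traits <- function(traits, meta, alpha = 0.05, n_perm = 999,
                           seed = NULL, n_pcs_regression = 3,
                           n_pcs_procrustes = 2, n_pcs_mantel = 3) {
  years <- sort(unique(traits$year))
  trait_set <- complete_trait_set(traits, years)
  dropped <- setdiff(xylo_trait_names(), trait_set)
  if (length(dropped))
    warning("analyze_traits: dropping incomplete/constant trait(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  pca <- lapply(years, function(yr)
    pca_year(trait_matrix(traits, yr, trait_set), year = yr))
  names(pca) <- as.character(years)

  ref_year <- as.character(max(years))
  scores_ref <- pca[[ref_year]]$scores
  ids <- rownames(scores_ref)
  mrow <- meta[match(ids, meta$tree_id), ]
  covars <- data.frame(height = mrow$height, age = mrow$age,
                       plot = mrow$plot)
  k_reg <- min(n_pcs_regression, ncol(scores_ref))
  selection <- lapply(seq_len(k_reg), function(k)
    backward_select(scores_ref[, k], covars, alpha = alpha))
  names(selection) <- paste0("PC", seq_len(k_reg))

  k_man <- min(n_pcs_mantel, ncol(scores_ref))
  mantel <- list()
  for (pl in unique(mrow$plot)) {
    sel <- which(mrow$plot == pl)
    if (length(sel) < 4) next
    geo <- geosphere::distm(cbind(mrow$longitude[sel], mrow$latitude[sel]))
    dtr <- as.matrix(stats::dist(scores_ref[sel, seq_len(k_man),
                                            drop = FALSE]))
    mantel[[pl]] <- mantel_test(geo, dtr, n_perm = n_perm, seed = seed)
  }

  procrustes <- NULL
  stability <- NULL
  if (length(years) >= 2) {
    k_pro <- min(n_pcs_procrustes, ncol(scores_ref))
    pairs <- utils::combn(as.character(years), 2)
    tests <- lapply(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      procrustes_protest(pca[[a]]$scores[, seq_len(k_pro), drop = FALSE],
                         pca[[b]]$scores[, seq_len(k_pro), drop = FALSE],
                         n_perm = n_perm, seed = seed)
    })
    procrustes <- data.frame(year_a = pairs[1, ], year_b = pairs[2, ],
                             r = vapply(tests, `[[`, numeric(1), "r"),
                             m2 = vapply(tests, `[[`, numeric(1), "m2"),
                             p = vapply(tests, `[[`, numeric(1), "p"),
                             stringsAsFactors = FALSE)
    attr(procrustes, "tests") <- tests
    stability <- trait_cv(traits[c("tree_id", "year", trait_set)])
  } else {
    message("analyze_traits: single year -- Procrustes and stability stages skipped (need >= 2 years)")
  }

  structure(list(pca = pca, selection = selection, mantel = mantel,
                 procrustes = procrustes, stability = stability,
                 trait_set = trait_set, years = years,
                 ref_year = as.integer(ref_year),
                 settings = list(alpha = alpha, n_perm = n_perm, seed = seed,
                                 n_pcs_regression = n_pcs_regression,
                                 n_pcs_procrustes = n_pcs_procrustes,
                                 n_pcs_mantel = n_pcs_mantel)),
            class = "xylo_analysis")
}

#' @export
print.xylo_analysis <- function(x, ...) {
  cat(sprintf("Wood anatomy analysis: %d year(s), %d traits retained\n",
              length(x$years), length(x$trait_set)))
  ref <- x$pca[[as.character(x$ref_year)]]
  cat(sprintf("  PCA %d: variance shares %s\n", x$ref_year,
              paste(sprintf("%.1f%%", ref$var_share[1:min(3, length(ref$var_share))]),
                    collapse = ", ")))
  for (nm in names(x$selection)) {
    s <- x$selection[[nm]]
    cat(sprintf("  %s ~ %s\n", nm,
                if (length(s$retained)) paste(s$retained, collapse = " + ")
                else "1"))
  }
  for (pl in names(x$mantel)) {
    m <- x$mantel[[pl]]
    cat(sprintf("  Mantel %s: r = %.3f, p = %.3g\n", pl, m$r, m$p))
  }
  if (!is.null(x$procrustes))
    cat(sprintf("  Procrustes r over %d year pairs: min %.3f, max p %.3g\n",
                nrow(x$procrustes), min(x$procrustes$r),
                max(x$procrustes$p)))
  if (!is.null(x$stability))
    cat(sprintf("  stability: %d/%d traits flagged\n",
                sum(x$stability$table$flagged, na.rm = TRUE),
                nrow(x$stability$table)))
  invisible(x)
}

#' @export
summary.xylo_analysis <- function(object, ...) {
  vs <- t(vapply(object$pca, function(p) p$var_share[1:3], numeric(3)))
  colnames(vs) <- paste0("PC", 1:3)
  out <- list(
    variance_shares = vs,
    retained = lapply(object$selection, `[[`, "retained"),
    mantel = if (length(object$mantel))
      data.frame(plot = names(object$mantel),
                 r = vapply(object$mantel, `[[`, numeric(1), "r"),
                 p = vapply(object$mantel, `[[`, numeric(1), "p"),
                 row.names = NULL),
    procrustes = object$procrustes,
    flagged = if (!is.null(object$stability))
      object$stability$table$trait[which(object$stability$table$flagged)]
  )
  class(out) <- "summary.xylo_analysis"
  out
}

#' @export
print.summary.xylo_analysis <- function(x, ...) {
  cat("Per-year PCA variance shares (%):\n")
  print(round(x$variance_shares, 1))
  cat("\nRetained covariates per PC:\n")
  for (nm in names(x$retained))
    cat(" ", nm, "~",
        if (length(x$retained[[nm]])) paste(x$retained[[nm]], collapse = " + ")
        else "1", "\n")
  if (!is.null(x$mantel)) { cat("\nWithin-plot Mantel tests:\n"); print(x$mantel, digits = 3) }
  if (!is.null(x$procrustes)) {
    cat("\nInter-annual Procrustes tests:\n")
    print(x$procrustes, digits = 3)
  }
  if (length(x$flagged))
    cat("\nFlagged unstable traits:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}
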