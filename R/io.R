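# Readers and writers for the canonical CSV dialects (cells, tree metadata,
# ring traits).  All tables are plain RFC-4180 CSV with a dot decimal
# separator; units are fixed by the schema (um, um2, m, years, cm).

cell_columns <- c("tree_id", "year", "file_index", "cell_index", "rel_pos",
                  "drad_lumen", "dtan_lumen", "lumen_area",
                  "cwt_pi", "cwt_ba", "cwt_le", "cwt_ri", "cwa")

cell_numeric <- setdiff(cell_columns, "tree_id")

meta_columns <- c("tree_id", "plot", "latitude", "longitude", "elevation",
                  "height", "age", "dbh")

#' Best-effort alias map for raw ROXAS-style exports
#'
#' Maps common column names of raw image-analysis exports onto the canonical
#' cell-table schema.  The upstream export layout is not standardised, so
#' these aliases are best-effort and explicitly unverified; pass your own
#' named vector to [read_cell_table()] when your dialect differs.
#'
#' @return named character vector, `canonical = alias`.
#' @export
roxas_alias_map <- function() {
  c(year = "YEAR", cell_index = "RADDISTR.RANK", file_index = "ROW",
    drad_lumen = "DRAD", dtan_lumen = "DTAN", lumen_area = "LA",
    cwt_pi = "CWTPI", cwt_ba = "CWTBA", cwt_le = "CWTLE", cwt_ri = "CWTRI",
    cwa = "CWA", rel_pos = "RRADDISTR", tree_id = "ID")
}

apply_aliases <- function(df, aliases) {
  if (is.null(aliases)) return(df)
  for (canon in names(aliases)) {
    a <- aliases[[canon]]
    if (!canon %in% names(df) && a %in% names(df))
      names(df)[names(df) == a] <- canon
  }
  df
}

#' Read a per-cell anatomical table
#'
#' Reads the canonical cell CSV (one row per tracheid), validates types,
#' positivity and key uniqueness, and preserves row order.  Unknown extra
#' columns are dropped with a warning.  An optional alias map renames raw
#' export columns onto the canonical schema first.
#'
#' @param path CSV file path.
#' @param aliases optional named character vector `canonical = alias`
#'   (see [roxas_alias_map()]).
#' @return a `data.frame` with the canonical cell columns.
#' @export
read_cell_table <- function(path, aliases = NULL) {
  if (!file.exists(path)) stop("cell table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  df <- apply_aliases(df, aliases)
  miss <- setdiff(cell_columns, names(df))
  if (length(miss))
    stop("cell table format error: missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(df), cell_columns)
  if (length(extra)) {
    warning("ignoring unknown cell-table column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
    df <- df[cell_columns]
  } else {
    df <- df[cell_columns]
  }
  for (cc in cell_numeric) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v) & !anyNA(df[[cc]]))
      stop("cell table format error: non-numeric values in `", cc, "`",
           call. = FALSE)
    df[[cc]] <- v
  }
  validate_cells(df)
  df
}

validate_cells <- function(df) {
  geom <- c("drad_lumen", "dtan_lumen", "lumen_area",
            "cwt_pi", "cwt_ba", "cwt_le", "cwt_ri", "cwa")
  for (cc in geom) {
    bad <- which(!is.finite(df[[cc]]) | df[[cc]] <= 0)
    if (length(bad))
      stop(sprintf("cell table validation error: non-positive `%s` on row %d",
                   cc, bad[1]), call. = FALSE)
  }
  bad <- which(df$rel_pos < 0 | df$rel_pos > 1)
  if (length(bad))
    stop(sprintf("cell table validation error: rel_pos outside [0,1] on row %d",
                 bad[1]), call. = FALSE)
  # elliptical lumen cannot exceed the bounding box ellipse
  cap <- pi / 4 * df$drad_lumen * df$dtan_lumen * (1 + 1e-6)
  bad <- which(df$lumen_area > cap)
  if (length(bad))
    stop(sprintf(paste("cell table validation error: lumen_area exceeds the",
                       "elliptical bound on row %d"), bad[1]), call. = FALSE)
  key <- paste(df$tree_id, df$year, df$file_index, df$cell_index)
  if (anyDuplicated(key))
    stop("cell table validation error: duplicated (tree_id, year, file_index, cell_index) key",
         call. = FALSE)
  invisible(df)
}

#' Write a per-cell anatomical table
#'
#' @param cells canonical cell table (as from [simulate_ring()] or
#'   [read_cell_table()]).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  miss <- setdiff(cell_columns, names(cells))
  if (length(miss))
    stop("cannot write cell table: missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  utils::write.csv(cells[cell_columns], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read / write tree metadata
#'
#' The metadata table holds one row per tree: `tree_id`, `plot`, `latitude`,
#' `longitude` (decimal degrees), `elevation` (m), `height` (m), `age`
#' (years), `dbh` (cm).
#'
#' @param path CSV file path.
#' @return `read_tree_meta()`: a validated `data.frame`;
#'   `write_tree_meta()`: the path, invisibly.
#' @export
read_tree_meta <- function(path) {
  if (!file.exists(path)) stop("metadata not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(meta_columns, names(df))
  if (length(miss))
    stop("metadata format error: missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df <- df[meta_columns]
  if (any(!nzchar(df$plot)))
    stop("metadata validation error: empty plot code", call. = FALSE)
  if (any(df$height <= 0))
    stop("metadata validation error: height must be > 0", call. = FALSE)
  if (any(df$age < 1))
    stop("metadata validation error: age must be >= 1", call. = FALSE)
  if (anyDuplicated(df$tree_id))
    stop("metadata validation error: duplicated tree_id", call. = FALSE)
  df
}

#' @rdname read_tree_meta
#' @param meta tree metadata table.
#' @export
write_tree_meta <- function(meta, path) {
  miss <- setdiff(meta_columns, names(meta))
  if (length(miss))
    stop("cannot write metadata: missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  utils::write.csv(meta[meta_columns], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read the wide ring-trait table
#'
#' One row per (tree, year); two key columns followed by the full trait
#' catalogue (see [xylo_trait_names()]).  Writing refuses a table whose trait
#' columns are incomplete; numbers survive a round trip to at least 12
#' significant digits.
#'
#' @param traits trait table as returned by [derive_traits()].
#' @param path CSV file path.
#' @return `write_trait_table()`: the path, invisibly;
#'   `read_trait_table()`: a `data.frame`.
#' @export
write_trait_table <- function(traits, path) {
  want <- c("tree_id", "year", xylo_trait_names())
  miss <- setdiff(want, names(traits))
  if (length(miss))
    stop("trait table completeness error: missing trait(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df <- traits[want]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trait_table
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop("trait table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  want <- c("tree_id", "year", xylo_trait_names())
  miss <- setdiff(want, names(df))
  if (length(miss))
    stop("trait table format error: missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (cc in setdiff(want, "tree_id")) df[[cc]] <- as.numeric(df[[cc]])
  df[want]
}
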