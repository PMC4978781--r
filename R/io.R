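#' Path to a packaged example file
#'
#' The package ships the worked example of a 20-common-item linking study as
#' plain CSV: generating and estimated item parameters for two calibrations
#' (`generating_items.csv`, `cal1_items.csv`, `cal2_items.csv`), the per-item
#' estimation covariances (`cal1_cov.csv`, `cal2_cov.csv`), and the published
#' per-item linking estimates (`published_per_item_links.csv`).
#'
#' @param file File name; with no argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
irtlink_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "irtlink")))
  }
  path <- system.file("extdata", file, package = "irtlink")
  if (path == "") {
    abort(paste0("No packaged file named '", file, "'."),
          class = "irtlink_io_error")
  }
  path
}

read_checked_csv <- function(path, schema) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "irtlink_io_error")
  }
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  missing_cols <- setdiff(schema, names(tbl))
  extra <- setdiff(names(tbl), schema)
  if (length(missing_cols) > 0 || length(extra) > 0) {
    abort(paste0("Schema mismatch in ", basename(path),
                 if (length(missing_cols)) paste0("; missing: ",
                   paste(missing_cols, collapse = ", ")),
                 if (length(extra)) paste0("; unexpected: ",
                   paste(extra, collapse = ", "))),
          class = "irtlink_io_error")
  }
  numeric_cols <- setdiff(schema, c("item_id", "person_id"))
  for (col in numeric_cols) {
    vals <- suppressWarnings(as.numeric(tbl[[col]]))
    bad <- which(is.na(vals))
    if (length(bad) > 0) {
      abort(paste0("Non-numeric or missing cells in ", basename(path),
                   ", column ", col, ", data row(s): ",
                   paste(head(bad, 5), collapse = ", ")),
            class = "irtlink_io_error")
    }
    tbl[[col]] <- vals
  }
  tbl$item_id <- as.character(tbl$item_id)
  tbl
}

#' Read and write the package's CSV formats
#'
#' Item tables use columns `item_id,a,b,c`; covariance tables
#' `item_id,var_a,var_b,var_c,cov_ab,cov_ac,cov_bc`; response matrices have a
#' `person_id` first column followed by one 0/1 column per item. Schema
#' violations raise an error naming the offending columns or rows. Writing
#' uses full double precision, so a write/read round trip is lossless.
#'
#' @param path File path.
#' @return A validated tibble (items, covariances) or an integer matrix with
#'   person ids as row names (responses).
#' @export
read_item_table <- function(path) {
  validate_items(read_checked_csv(path, c("item_id", "a", "b", "c")),
                 require_id = TRUE)
}

#' @rdname read_item_table
#' @export
read_cov_table <- function(path) {
  check_cov_table(read_checked_csv(path, c("item_id", "var_a", "var_b",
                                           "var_c", "cov_ab", "cov_ac",
                                           "cov_bc")), basename(path))
}

#' @rdname read_item_table
#' @export
read_response_matrix <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  if (names(tbl)[1] != "person_id") {
    abort("Response CSV must have `person_id` as its first column.",
          class = "irtlink_io_error")
  }
  u <- as.matrix(tbl[-1])
  if (!all(u %in% c(0, 1, NA))) {
    abort("Response entries must be 0/1.", class = "irtlink_io_error")
  }
  storage.mode(u) <- "integer"
  rownames(u) <- as.character(tbl$person_id)
  u
}

#' @rdname read_item_table
#' @param items Item tibble to write.
#' @export
write_item_table <- function(items, path) {
  items <- validate_items(items, require_id = TRUE)
  readr::write_csv(items[c("item_id", "a", "b", "c")], path)
  invisible(path)
}

#' Assemble and serialize a linking report
#'
#' Collects pooled estimates and the per-item block into a single report
#' mirroring the layout of a linking-study summary: one row per method with
#' `(u, se_u, v, se_v)`, the per-item table, and provenance (inputs, seed,
#' package version, timestamp, linking direction).
#'
#' @param pooled A list of `pooled_link` objects.
#' @param per_item Per-item estimate tibble.
#' @param inputs Named character vector or list describing input paths.
#' @param seed Seed used, if any.
#' @return An object of class `link_report`.
#' @export
link_report <- function(pooled, per_item = NULL, inputs = NULL, seed = NULL) {
  methods_tbl <- bind_rows(lapply(pooled, glance))
  warnings <- character(0)
  if (any(is.na(methods_tbl$se_u))) {
    warnings <- c(warnings,
                  "some methods report no standard errors (no covariances)")
  }
  structure(list(methods = methods_tbl, per_item = per_item,
                 provenance = list(
                   inputs = inputs, seed = seed,
                   direction = "cal1_to_cal2 (theta* = u theta + v)",
                   package = "irtlink",
                   version = as.character(utils::packageVersion("irtlink")),
                   timestamp = format(Sys.time(), tz = "UTC",
                                      usetz = TRUE)),
                 warnings = warnings),
            class = "link_report")
}

#' @rdname link_report
#' @param report A `link_report`.
#' @param path Output JSON path.
#' @export
write_link_report <- function(report, path) {
  jsonlite::write_json(
    list(methods = report$methods, per_item = report$per_item,
         provenance = report$provenance, warnings = report$warnings),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE,
    null = "null")
  invisible(path)
}

#' @export
print.link_report <- function(x, ...) {
  cat("<link_report>", x$provenance$direction, "\n")
  print(x$methods)
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "),
                              "\n")
  invisible(x)
}
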