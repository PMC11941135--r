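#' Read / write a TSS snapshot as CSV
#'
#' Snapshots are plain comma-separated files (UTF-8, '.' decimal, header of
#' species names, one row per cell). Provenance -- time stamp, scenario,
#' seed, and any other metadata -- travels in a JSON sidecar named
#' `<file>.meta.json`, so the CSV itself stays tool-friendly.
#'
#' @param data Cells-by-species data frame.
#' @param path CSV path.
#' @param meta Named list of metadata to store in the sidecar. `time` is
#'   filled from the data's `time` attribute when present.
#' @param digits Significant digits for abundances (machine outputs keep 17).
#' @return `write_tss_csv()` invisibly returns `path`; `read_tss_csv()`
#'   returns a tibble with attributes restored from the sidecar (if found).
#' @export
write_tss_csv <- function(data, path, meta = list(), digits = 17) {
  df <- as.data.frame(data)
  if (!all(vapply(df, is.numeric, logical(1)))) {
    abort("all snapshot columns must be numeric abundances")
  }
  meta$time <- meta$time %||% attr(data, "time")
  out <- df
  out[] <- lapply(df, function(x) signif(x, digits))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (length(meta) > 0) {
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_tss_csv
#' @param species Optional expected species columns; a mismatch is an error
#'   naming the offending column.
#' @export
read_tss_csv <- function(path, species = NULL) {
  df <- read.csv(path, check.names = FALSE)
  if (!is.null(species)) {
    missing <- setdiff(species, names(df))
    extra <- setdiff(names(df), species)
    if (length(missing) > 0 || length(extra) > 0) {
      abort(sprintf(
        "snapshot header mismatch: missing (%s), unexpected (%s)",
        paste(missing, collapse = ", "), paste(extra, collapse = ", ")))
    }
    df <- df[species]
  }
  bad <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(sprintf("non-numeric snapshot column: %s", bad[[1]]))
  }
  out <- as_tibble(df)
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$time)) attr(out, "time") <- meta$time
    attr(out, "meta") <- meta
  }
  out
}
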