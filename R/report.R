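#' Write result tables as deterministic TSV plus a JSON manifest
#'
#' Every table is written tab-separated with a header row and the column order
#' it arrived with; rows are written as-is (producers are responsible for a
#' stable sort). A \code{manifest.json} records per-table row counts and a hash
#' of the configuration used, so two runs with identical inputs and config can
#' be compared byte-for-byte. Coordinates in all exported tables are 1-based
#' inclusive; gene ranks are 0-based.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory, created if missing.
#' @param config optional list describing the run; hashed into the manifest.
#' @return (invisibly) the manifest as a list.
#' @export
exportReport <- function(tables, out_dir, config = list()) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  cfg_hash <- unname(tools::md5sum(tf)); unlink(tf)
  counts <- integer(0)
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    stopifnot(is.data.frame(tab))
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    con <- file(path, open = "wb")  # binary mode: identical bytes on all platforms
    write.table(format_tsv_frame(tab), con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE, eol = "\n")
    close(con)
    counts[nm] <- nrow(tab)
  }
  manifest <- list(tables = as.list(counts), config_hash = cfg_hash,
                   coordinate_system = "1-based inclusive; ranks 0-based")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Format numerics with full precision and no scientific notation drift.
format_tsv_frame <- function(tab) {
  for (j in seq_along(tab)) {
    if (is.double(tab[[j]]))
      tab[[j]] <- vapply(tab[[j]], function(v)
        if (is.na(v)) "NA" else format(v, digits = 15, scientific = FALSE,
                                       trim = TRUE), character(1))
    if (is.logical(tab[[j]])) tab[[j]] <- ifelse(tab[[j]], "TRUE", "FALSE")
  }
  tab
}
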