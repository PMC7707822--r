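# Result tables: one CSV per result kind, fixed column order, numbers at
# 17 significant digits so write -> read is the identity on doubles.

.table_schemas <- list(
  resp_cycles   = c(onset = "numeric", Ti = "numeric", Te = "numeric",
                    f_inst = "numeric", peak_amp = "numeric"),
  stride_cycles = c(limb = "character", footfall_prev = "numeric",
                    liftoff = "numeric", footfall_next = "numeric"),
  phases        = c(ref_limb = "character", cycle_index = "integer",
                    insp_onset = "numeric", phi = "numeric"),
  circular_stats = c(ref_limb = "character", mean_phase = "numeric",
                     R = "numeric", n = "integer"),
  condition_summary = c(condition = "character", parameter = "character",
                        animal = "character", value = "numeric"),
  epochs        = c(start = "numeric", end = "numeric", label = "character")
)

.format_cell <- function(col) {
  if (is.double(col)) sprintf("%.17g", col) else as.character(col)
}

#' Write result tables
#'
#' Writes each supplied record set as `<kind>.csv` under `outdir` with the
#' documented fixed column order. Supported kinds: `resp_cycles`,
#' `stride_cycles`, `phases`, `circular_stats`, `condition_summary`,
#' `epochs`. Re-reading with [read_result_tables()] reproduces the records
#' exactly (doubles are written with 17 significant digits).
#'
#' @param results named list of data frames, names drawn from the supported
#'   kinds; missing columns are an error, extra columns are dropped.
#' @param outdir output directory, created if absent.
#' @return invisible character vector of the files written.
#' @export
write_result_tables <- function(results, outdir) {
  stopifnot(is.list(results), length(names(results)) == length(results))
  unknown <- setdiff(names(results), names(.table_schemas))
  if (length(unknown))
    stop_parameter("unknown result kind(s): %s", paste(unknown, collapse = ", "))
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE))
    stop_io("cannot create %s", outdir)
  out <- character(0)
  for (kind in names(results)) {
    schema <- .table_schemas[[kind]]
    df <- results[[kind]]
    miss <- setdiff(names(schema), names(df))
    if (length(miss))
      stop_validation("%s table lacks column(s): %s", kind, paste(miss, collapse = ", "))
    path <- file.path(outdir, paste0(kind, ".csv"))
    header <- paste(names(schema), collapse = ",")
    if (nrow(df) == 0L) {
      lines <- header
    } else {
      cells <- lapply(names(schema), function(cn) .format_cell(df[[cn]]))
      lines <- c(header, do.call(paste, c(cells, sep = ",")))
    }
    ok <- tryCatch({ writeLines(lines, path); TRUE }, error = function(e) FALSE)
    if (!ok) stop_io("cannot write %s", path)
    out <- c(out, path)
  }
  invisible(out)
}

#' Read result tables written by [write_result_tables()]
#'
#' @param indir directory containing `<kind>.csv` files.
#' @param kinds which kinds to read; defaults to every supported kind
#'   present in `indir`.
#' @return named list of data frames with schema-typed columns.
#' @export
read_result_tables <- function(indir, kinds = NULL) {
  if (!dir.exists(indir)) stop_io("no such directory: %s", indir)
  if (is.null(kinds)) {
    present <- sub("\\.csv$", "", list.files(indir, pattern = "\\.csv$"))
    kinds <- intersect(names(.table_schemas), present)
  }
  out <- list()
  for (kind in kinds) {
    schema <- .table_schemas[[kind]]
    path <- file.path(indir, paste0(kind, ".csv"))
    if (!file.exists(path)) stop_io("no such file: %s", path)
    df <- utils::read.csv(path, colClasses = unname(schema),
                          col.names = names(schema), check.names = FALSE)
    out[[kind]] <- df
  }
  out
}
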