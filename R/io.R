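#' Read and write the spike-event exchange format
#'
#' A dataset directory holds three plain-text files: \code{events.tsv}
#' (columns \code{trial}, \code{electrode}, \code{time_ms}),
#' \code{stim_log.tsv} (\code{trial}, \code{abs_time_s}, \code{source},
#' \code{condition}) and a \code{grid.json} sidecar (\code{n_rows},
#' \code{n_cols}, \code{pitch_um}). Spike times are written with 17
#' significant digits so a write/read cycle reproduces the dataset exactly.
#'
#' @param path directory containing (or to receive) the three files.
#' @param dataset a \code{\link{spike_dataset}}.
#' @return \code{read_dataset} returns a \code{\link{spike_dataset}};
#'   \code{write_dataset} returns \code{path} invisibly.
#' @name dataset_io
NULL

#' @rdname dataset_io
#' @export
read_dataset <- function(path) {
  f_ev <- file.path(path, "events.tsv")
  f_st <- file.path(path, "stim_log.tsv")
  f_gr <- file.path(path, "grid.json")
  for (f in c(f_ev, f_st, f_gr))
    if (!file.exists(f)) stop("missing file: ", f)
  gj <- jsonlite::read_json(f_gr, simplifyVector = TRUE)
  grid <- grid_geometry(gj$n_rows, gj$n_cols, gj$pitch_um)

  ev <- utils::read.delim(f_ev, colClasses = "character")
  ev <- parse_columns(ev, c(trial = "integer", electrode = "integer",
                            time_ms = "numeric"), f_ev)
  st <- utils::read.delim(f_st, colClasses = "character")
  st <- parse_columns(st, c(trial = "integer", abs_time_s = "numeric",
                            source = "integer", condition = "character"),
                      f_st)
  spike_dataset(ev, st, grid)
}

# convert character columns to their declared types; a field that fails to
# parse is a malformed row, reported by line (the header is line 1, so data
# row i is line i + 1)
parse_columns <- function(df, types, file) {
  bad <- rep(FALSE, nrow(df))
  for (col in names(types)) {
    if (is.null(df[[col]]))
      stop("missing column '", col, "' in ", file)
    if (types[[col]] == "character") next
    parsed <- suppressWarnings(
      if (types[[col]] == "integer") as.integer(df[[col]])
      else as.numeric(df[[col]]))
    bad <- bad | (is.na(parsed) & !is.na(df[[col]]))
    df[[col]] <- parsed
  }
  if (any(bad))
    stop("malformed row(s) in ", file, " at line(s): ",
         paste(utils::head(which(bad) + 1L, 5L), collapse = ", "))
  df
}

#' @rdname dataset_io
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "spike_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  ev <- dataset$events
  ev$time_ms <- sprintf("%.17g", ev$time_ms)
  utils::write.table(ev, file.path(path, "events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  st <- dataset$stim_log
  st$abs_time_s <- sprintf("%.17g", st$abs_time_s)
  utils::write.table(st, file.path(path, "stim_log.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n_rows = dataset$grid$n_rows, n_cols = dataset$grid$n_cols,
         pitch_um = dataset$grid$pitch_um,
         electrode_ids = dataset$grid$electrode_ids),
    file.path(path, "grid.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
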