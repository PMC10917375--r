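#' Write a region time series to TSV with a JSON sidecar
#'
#' The TSV has a `time_s` column plus one column per node; the sidecar
#' (same path with `.json` extension) records TR, run structure, units and
#' any provenance metadata.
#'
#' @param ts A [region_ts()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_region_ts <- function(ts, path) {
  stopifnot(inherits(ts, "region_ts"))
  time_s <- (stats::ave(seq_along(ts$run), ts$run, FUN = seq_along) - 1) * ts$TR
  df <- data.frame(time_s = time_s, ts$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- sub("\\.tsv$", ".json", path)
  jsonlite::write_json(
    list(TR = ts$TR, run = ts$run, nodes = ts$nodes, units = ts$units,
         meta = ts$meta),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Read a region time series written by [write_region_ts()]
#'
#' @param path TSV path (sidecar JSON expected alongside).
#' @return A [region_ts()].
#' @export
read_region_ts <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  side <- jsonlite::read_json(sub("\\.tsv$", ".json", path),
                              simplifyVector = TRUE)
  vals <- as.matrix(df[, setdiff(names(df), "time_s"), drop = FALSE])
  region_ts(vals, TR = side$TR, run = side$run, nodes = side$nodes,
            units = side$units,
            meta = if (is.null(side$meta)) list() else as.list(side$meta))
}

#' Serialize DCM parameters to JSON
#'
#' Matrices are written with explicit row (target) and column (source) node
#' labels so the file is self-describing.
#'
#' @param params A [dcm_params()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dcm_params <- function(params, path) {
  stopifnot(inherits(params, "dcm_params"))
  mat_json <- function(m) {
    list(rows = rownames(m), cols = colnames(m),
         values = unname(apply(m, 1, as.numeric, simplify = FALSE)))
  }
  obj <- list(
    nodes = params$nodes,
    A = mat_json(params$A),
    B = lapply(params$B, mat_json),
    C = mat_json(params$C),
    hemo = params$hemo,
    noise_log_precision = as.list(params$noise_log_precision)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read DCM parameters written by [write_dcm_params()]
#'
#' @param path JSON path.
#' @return A [dcm_params()].
#' @export
read_dcm_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mat_from <- function(mj) {
    m <- if (is.matrix(mj$values)) mj$values else
      do.call(rbind, lapply(mj$values, unlist))
    dimnames(m) <- list(unlist(mj$rows), unlist(mj$cols))
    m
  }
  B <- lapply(obj$B, mat_from)
  dcm_params(mat_from(obj$A), B, mat_from(obj$C),
             hemo = as.data.frame(obj$hemo),
             noise_log_precision = unlist(obj$noise_log_precision),
             nodes = obj$nodes)
}

#' Write a trial table as a BIDS-style events TSV
#'
#' Columns: `onset`, `duration`, `trial_type` plus any behavioral columns
#' present (`response`, `correct`, `rt_ms`, `run`, `block`).
#'
#' @param trials Trial table from [generate_paradigm()] or
#'   [generate_behavior()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(trials, path) {
  lead <- intersect(c("onset", "duration", "trial_type"), names(trials))
  rest <- setdiff(names(trials), lead)
  write.table(trials[, c(lead, rest)], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "n/a")
  invisible(path)
}

#' Read an events TSV written by [write_events()]
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_events <- function(path) {
  read.delim(path, na.strings = "n/a")
}
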