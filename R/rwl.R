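#' Read a Tucson (RWL) ring-width file
#'
#' Parses the decadal Tucson interchange format: each line carries a series
#' id (columns 1-8), the decade's first year, and up to ten ring widths.
#' The precision dialect is taken from the stop marker unless given:
#' marker 999 means values are hundredths of a millimetre, marker -9999
#' thousandths. A stored value of 0 denotes a missing (locally absent)
#' ring and is returned as an NA gap, not a zero width.
#'
#' @param path file path.
#' @param precision `"auto"` (default, from the stop marker), `"0.01"` or
#'   `"0.001"` (mm per unit).
#' @param plot_ids optional named character vector mapping series id to
#'   plot id; unmatched series get plot_id NA.
#' @return named list of [ring_width_series()] objects.
#' @export
read_rwl <- function(path, precision = c("auto", "0.01", "0.001"),
                     plot_ids = NULL) {
  precision <- match.arg(precision)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  recs <- list()
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    id <- trimws(substr(line, 1, 8))
    rest <- strsplit(trimws(substr(line, 9, nchar(line))), "\\s+")[[1]]
    if (length(rest) < 2) {
      stop("malformed RWL line ", ln, ": fewer than two fields after the id")
    }
    vals <- suppressWarnings(as.numeric(rest))
    if (anyNA(vals)) {
      stop("non-numeric field in RWL file at line ", ln, ": '",
           rest[which(is.na(vals))[1]], "'")
    }
    recs[[length(recs) + 1L]] <- list(id = id, year = vals[1], vals = vals[-1])
  }
  ids <- vapply(recs, `[[`, "", "id")
  out <- list()
  for (id in unique(ids)) {
    rr <- recs[ids == id]
    yrs <- integer(0)
    raw <- numeric(0)
    for (r in rr) {
      v <- r$vals
      yrs <- c(yrs, seq(r$year, length.out = length(v)))
      raw <- c(raw, v)
    }
    stopifnot(length(yrs) == length(raw))
    # stop marker terminates the series
    stop_i <- which(raw == 999 | raw == -9999)
    marker <- NA_real_
    if (length(stop_i) > 0) {
      marker <- raw[stop_i[1]]
      yrs <- yrs[seq_len(stop_i[1] - 1)]
      raw <- raw[seq_len(stop_i[1] - 1)]
    }
    if (anyDuplicated(yrs)) {
      stop("duplicate years for series id '", id,
           "': overlapping duplicate series ids?")
    }
    unit <- switch(precision,
                   "0.01" = 0.01, "0.001" = 0.001,
                   auto = if (!is.na(marker) && marker == -9999) 0.001 else 0.01)
    widths <- ifelse(raw == 0, NA_real_, raw * unit)
    pid <- if (!is.null(plot_ids) && id %in% names(plot_ids)) plot_ids[[id]] else NA_character_
    out[[id]] <- ring_width_series(id, pid, yrs[1], widths)
  }
  out
}

#' Write ring-width series to a Tucson (RWL) file
#'
#' @param collection list of [ring_width_series()] objects.
#' @param path output path.
#' @param precision `"0.01"` (stop marker 999, default) or `"0.001"`
#'   (stop marker -9999), mm per stored unit.
#' @return invisibly, `path`.
#' @export
write_rwl <- function(collection, path, precision = c("0.01", "0.001")) {
  precision <- match.arg(precision)
  unit <- as.numeric(precision)
  marker <- if (precision == "0.01") 999 else -9999
  ids <- vapply(collection, `[[`, "", "tree_id")
  if (anyDuplicated(ids)) stop("duplicate series ids: ", ids[duplicated(ids)][1])
  con <- file(path, "w")
  on.exit(close(con))
  for (s in collection) {
    id <- substr(s$tree_id, 1, 8)
    vals <- ifelse(is.na(s$widths), 0, round(s$widths / unit))
    yrs <- s$years
    stream <- c(vals, marker)
    syrs <- c(yrs, yrs[length(yrs)] + 1L)
    while (length(stream) > 0) {
      y0 <- syrs[1]
      n_in_dec <- 10 - (y0 %% 10)
      take <- min(n_in_dec, length(stream))
      chunk <- stream[seq_len(take)]
      writeLines(sprintf("%-8s%4d%s", id, y0,
                         paste(sprintf("%6d", chunk), collapse = "")), con)
      stream <- stream[-seq_len(take)]
      syrs <- syrs[-seq_len(take)]
    }
  }
  invisible(path)
}
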