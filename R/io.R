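#' Write / read a signal matrix as delimited text
#'
#' One row per site, tab-delimited, preceded by a metadata comment line
#' `# fs=<Hz> t0=<ms> units=<units>` and a header of site ids.
#'
#' @param x a [signal_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_signal_matrix <- function(x, path) {
  stopifnot(inherits(x, "signal_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g t0=%g units=%s", x$fs, x$t0, x$units), con)
  writeLines(paste(c("site_id", sprintf("s%d", seq_len(ncol(x$samples)))),
                   collapse = "\t"), con)
  utils::write.table(cbind(x$site_id, x$samples), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_signal_matrix
#' @param path input file written by [write_signal_matrix()].
#' @export
read_signal_matrix <- function(path) {
  meta <- readLines(path, n = 1)
  kv <- strsplit(sub("^#\\s*", "", meta), "\\s+")[[1]]
  kv <- strsplit(kv, "=")
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  d <- utils::read.table(path, sep = "\t", skip = 1, header = TRUE,
                         check.names = FALSE)
  signal_matrix(as.matrix(d[, -1]), fs = as.numeric(vals[["fs"]]),
                t0 = as.numeric(vals[["t0"]]), units = vals[["units"]],
                site_id = d[[1]])
}

#' Write / read a marker map as CSV
#'
#' Columns: `site_id, AT_ms, RT_ms, ARI_ms, valid, reason`.
#'
#' @param markers a `marker_map` from [mark_all()].
#' @param path file path.
#' @return `path` (write) or a `marker_map` (read).
#' @export
write_marker_map <- function(markers, path) {
  utils::write.csv(as.data.frame(markers), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_map
#' @export
read_marker_map <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "AT_ms", "RT_ms", "ARI_ms", "valid", "reason")
  if (!all(need %in% names(d))) stop("not a marker map CSV")
  d$reason[is.na(d$reason)] <- ""
  class(d) <- c("marker_map", "data.frame")
  d
}

#' Export a sock dataset to plain-text files
#'
#' Writes geometry, ground-truth timing, stimulus times, the generator
#' configuration (flat key=value) and the raw signal matrix into a
#' directory.
#'
#' @param dataset a `sock_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sock_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sock_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset$geometry, file.path(dir, "geometry.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$truth, file.path(dir, "truth_markers.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(stim_ms = dataset$stim_times),
                   file.path(dir, "stim_times.csv"), row.names = FALSE)
  cfg <- dataset$config
  writeLines(c(sprintf("%s=%s", names(cfg),
                       vapply(cfg, function(v)
                         if (is.null(v)) "" else as.character(v), "")),
               sprintf("seed=%d", dataset$seed)),
             file.path(dir, "generator_config.txt"))
  write_signal_matrix(dataset$raw, file.path(dir, "raw_signals.tsv"))
  invisible(dir)
}
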