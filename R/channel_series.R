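#' Multichannel time series
#'
#' The universal currency between pipeline stages: a T x K real-valued matrix
#' of per-frame channel values (e.g. inter-residue distances), channel labels,
#' the frame stride in nanoseconds, and optional segment breaks marking frames
#' after which temporal continuity is lost (concatenated trajectories,
#' split-half pieces, shuffled-null surrogates).
#'
#' @param values numeric matrix, one row per frame, one column per channel.
#' @param labels character vector of channel names; defaults to column names
#'   or `ch1..chK`.
#' @param dt frame stride in nanoseconds (must be > 0).
#' @param segment_breaks integer vector of frame indices `i` such that frame
#'   `i + 1` does not temporally follow frame `i`; strictly increasing, each
#'   in `[1, T - 1]`. Empty for a single continuous trajectory.
#' @return An object of class `channel_series`.
#' @export
channel_series <- function(values, labels = NULL, dt = 1,
                           segment_breaks = integer(0)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values))
    stop("channel values must not contain missing values")
  K <- ncol(values)
  if (is.null(labels)) labels <- colnames(values)
  if (is.null(labels)) labels <- paste0("ch", seq_len(K))
  labels <- as.character(labels)
  if (length(labels) != K)
    stop("length(labels) must equal the number of channels (", K, ")")
  dt <- as.numeric(dt)
  if (length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number (frame stride in ns)")
  segment_breaks <- as.integer(segment_breaks)
  Tn <- nrow(values)
  if (length(segment_breaks)) {
    if (any(diff(segment_breaks) <= 0))
      stop("segment_breaks must be strictly increasing")
    if (any(segment_breaks < 1L) || any(segment_breaks > Tn - 1L))
      stop("segment_breaks must lie in [1, T - 1]")
  }
  colnames(values) <- labels
  structure(list(values = values, labels = labels, dt = dt,
                 segment_breaks = segment_breaks),
            class = "channel_series")
}

#' @export
print.channel_series <- function(x, ...) {
  cat(sprintf("channel_series: %d frames x %d channels, dt = %g ns, %d segment break(s)\n",
              nrow(x$values), ncol(x$values), x$dt, length(x$segment_breaks)))
  cat("  channels:", paste(utils::head(x$labels, 8), collapse = ", "),
      if (length(x$labels) > 8) "..." else "", "\n")
  invisible(x)
}

n_frames <- function(series) nrow(series$values)
n_channels <- function(series) ncol(series$values)

# Contiguous segments as a list of index vectors.
series_segments <- function(series) {
  Tn <- n_frames(series)
  bounds <- c(0L, series$segment_breaks, Tn)
  lapply(seq_len(length(bounds) - 1L),
         function(i) seq.int(bounds[i] + 1L, bounds[i + 1L]))
}

#' Normalize channels to zero mean and unit variance
#'
#' Centers and scales every channel so that its mean is 0 and its variance
#' (computed with denominator T, i.e. the population convention) is 1 over
#' the frames provided. Channels whose variance falls below `1e-12` are
#' rejected by name: such channels carry no usable signal and would blow up
#' under scaling (the gate exists for pathological synthetic inputs; real
#' minimum-distance channels between covalent neighbours still fluctuate
#' enough to pass).
#'
#' @param series a [channel_series].
#' @return A normalized `channel_series` with the same labels, dt and breaks.
#' @export
normalize_channels <- function(series) {
  stopifnot(inherits(series, "channel_series"))
  x <- series$values
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu, "-")
  v <- colMeans(xc^2)
  bad <- v <= 1e-12
  if (any(bad))
    stop("constant channel(s) cannot be normalized: ",
         paste(series$labels[bad], collapse = ", "))
  xs <- sweep(xc, 2L, sqrt(v), "/")
  channel_series(xs, series$labels, series$dt, series$segment_breaks)
}

#' Write / read a channel matrix as delimited text
#'
#' One row per frame, one tab-separated column per channel, header row with
#' channel labels. `dt` is recorded in a `# dt_ns:` comment line.
#'
#' @param series a [channel_series].
#' @param path output file path.
#' @export
write_channels <- function(series, path) {
  stopifnot(inherits(series, "channel_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt_ns: %.17g", series$dt), con)
  if (length(series$segment_breaks))
    writeLines(paste0("# segment_breaks: ",
                      paste(series$segment_breaks, collapse = ",")), con)
  utils::write.table(series$values, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_channels
#' @export
read_channels <- function(path) {
  hdr <- readLines(path, n = 5L)
  dt <- 1
  breaks <- integer(0)
  for (ln in hdr[startsWith(hdr, "#")]) {
    if (grepl("^# dt_ns:", ln))
      dt <- as.numeric(sub("^# dt_ns:\\s*", "", ln))
    if (grepl("^# segment_breaks:", ln))
      breaks <- as.integer(strsplit(sub("^# segment_breaks:\\s*", "", ln),
                                    ",")[[1]])
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", check.names = FALSE)
  channel_series(as.matrix(tab), colnames(tab), dt, breaks)
}
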