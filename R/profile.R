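#' Binned profile with uncertainty
#'
#' Common container for statistics binned along a coordinate: free-energy
#' profiles (PMF), committor functions (CF), transition-path probability
#' p(TP|xi), and the native-ensemble overlap Omega(xi). Holds bin centers,
#' values (NA for undefined/empty bins), a lower and upper uncertainty, and
#' a kind tag.
#'
#' @param center numeric bin centers.
#' @param value numeric values per bin (NA where undefined).
#' @param err_lo,err_hi lower/upper uncertainty per bin.
#' @param kind one of `"PMF"`, `"CF"`, `"pTP"`, `"overlap"`.
#' @return An object of class `fold_profile` (a data.frame).
#' @export
fold_profile <- function(center, value, err_lo = NA_real_, err_hi = NA_real_,
                         kind = c("PMF", "CF", "pTP", "overlap")) {
  kind <- match.arg(kind)
  out <- data.frame(center = center, value = value,
                    err_lo = rep_len(err_lo, length(center)),
                    err_hi = rep_len(err_hi, length(center)))
  ok <- !is.na(out$value)
  if (kind != "PMF" && any(out$value[ok] < -1e-9 | out$value[ok] > 1 + 1e-9))
    stop(kind, " profile values must lie in [0, 1]")
  class(out) <- c("fold_profile", "data.frame")
  attr(out, "kind") <- kind
  out
}

#' @export
print.fold_profile <- function(x, ...) {
  ok <- !is.na(x$value)
  cat(sprintf("fold_profile [%s]: %d bins (%d defined), value range [%.4g, %.4g]\n",
              attr(x, "kind"), nrow(x), sum(ok),
              if (any(ok)) min(x$value[ok]) else NA,
              if (any(ok)) max(x$value[ok]) else NA))
  invisible(x)
}

#' Write a profile as four-column delimited text
#'
#' Columns: bin center, value, lower error, upper error.
#'
#' @param profile a [fold_profile].
#' @param path output path.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "fold_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind: %s", attr(profile, "kind")), con)
  utils::write.table(as.data.frame(profile), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
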