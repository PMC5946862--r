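#' Per-position profiles
#'
#' All per-nucleotide signals in the package share one representation: a
#' data frame with integer `position` (1-based forward-strand coordinate)
#' and numeric `value`, carrying a subclass that records what the value
#' means. Missing positions are simply absent rows, never zeros.
#'
#' * `cleavage_profile` - median-normalized hydroxyl radical cleavage for
#'   one strand (dimensionless, values >= 0), attribute `strand`.
#' * `orchid2_profile` - cross-strand averaged minor-groove proxy,
#'   attribute `smoothed` (logical).
#' * `groove_width_profile` - minor groove width in Angstroms.
#'
#' @param positions Integer vector of distinct 1-based positions.
#' @param values Numeric vector, same length.
#' @param strand `"forward"` or `"reverse"` (cleavage profiles).
#' @param smoothed Logical flag (ORChID2 profiles).
#' @name profiles
NULL

new_profile <- function(positions, values, subclass, ...) {
  positions <- as.integer(positions)
  values <- as.numeric(values)
  if (length(positions) != length(values))
    stop("positions and values must have the same length")
  if (anyNA(positions) || any(positions < 1L))
    stop("positions must be positive integers")
  if (anyDuplicated(positions))
    stop("duplicate positions: ",
         paste(unique(positions[duplicated(positions)]), collapse = ", "))
  if (any(!is.finite(values)))
    stop("profile values must be finite")
  ord <- order(positions)
  out <- data.frame(position = positions[ord], value = values[ord])
  class(out) <- c(subclass, "gp_profile", "data.frame")
  extra <- list(...)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  out
}

#' @rdname profiles
#' @export
cleavage_profile <- function(positions, values,
                             strand = c("forward", "reverse")) {
  strand <- match.arg(strand)
  if (any(values < 0)) stop("cleavage values must be >= 0")
  new_profile(positions, values, "cleavage_profile", strand = strand)
}

#' @rdname profiles
#' @export
orchid2_profile <- function(positions, values, smoothed = FALSE) {
  new_profile(positions, values, "orchid2_profile", smoothed = smoothed)
}

#' @rdname profiles
#' @export
groove_width_profile <- function(positions, values) {
  if (any(values < 0)) stop("groove widths must be >= 0")
  new_profile(positions, values, "groove_width_profile")
}

#' @export
print.gp_profile <- function(x, ...) {
  cat(sprintf("<%s> %d positions", class(x)[1L], nrow(x)))
  if (nrow(x))
    cat(sprintf(" [%d..%d]", min(x$position), max(x$position)))
  st <- attr(x, "strand"); if (!is.null(st)) cat(", strand:", st)
  sm <- attr(x, "smoothed"); if (isTRUE(sm)) cat(", smoothed")
  cat("\n")
  NextMethod()
}

#' Look up profile values at given positions
#'
#' @param profile A profile (see [profiles]).
#' @param positions Integer positions.
#' @return Numeric vector with `NA` where a position is absent.
#' @export
profile_values <- function(profile, positions) {
  profile$value[match(as.integer(positions), profile$position)]
}

#' Read / write a profile as two-column TSV
#'
#' The on-disk dialect is tab-separated text with a header line
#' `position<TAB>value`. Round-tripping reproduces values at full printed
#' precision (values are written with 15 significant digits).
#'
#' @param path File path.
#' @param profile A profile object.
#' @param type Subclass to construct on read: one of `"cleavage"`,
#'   `"orchid2"`, `"groove"`.
#' @param strand,smoothed Passed to the relevant constructor on read.
#' @return `read_profile` returns a profile; `write_profile` returns
#'   `path` invisibly.
#' @export
read_profile <- function(path, type = c("cleavage", "orchid2", "groove"),
                         strand = "forward", smoothed = FALSE) {
  type <- match.arg(type)
  df <- utils::read.delim(path, header = TRUE,
                          colClasses = c("integer", "numeric"))
  if (ncol(df) < 2L) stop("expected two columns (position, value) in ", path)
  if (anyNA(df[[1L]]) || anyNA(df[[2L]]))
    stop("non-numeric or missing entries in ", path)
  switch(type,
    cleavage = cleavage_profile(df[[1L]], df[[2L]], strand = strand),
    orchid2  = orchid2_profile(df[[1L]], df[[2L]], smoothed = smoothed),
    groove   = groove_width_profile(df[[1L]], df[[2L]]))
}

#' @rdname read_profile
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(position = profile$position,
                   value = formatC(profile$value, digits = 15,
                                   format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("position", "value"))
  invisible(path)
}

#' Restrict a profile to a binding-site window
#'
#' Returns exactly those positions of `profile` that fall inside the
#' site's 1-based inclusive interval and exist in the input; positions
#' absent from the input stay absent.
#'
#' @param profile A profile object.
#' @param site A [site_annotation()].
#' @param seq_length Optional sequence length for bounds checking.
#' @return A profile of the same subclass.
#' @export
extract_site <- function(profile, site, seq_length = NULL) {
  stopifnot(inherits(site, "site_annotation"))
  if (!is.null(seq_length) && site$end > seq_length)
    stop(sprintf("site '%s' [%d,%d] exceeds sequence length %d",
                 site$name, site$start, site$end, seq_length))
  keep <- profile$position >= site$start & profile$position <= site$end
  out <- profile[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
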