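#' Binding-site annotation
#'
#' An interval on the forward strand, 1-based and inclusive at both ends,
#' named after the bound protein or site.
#'
#' @param name Site name.
#' @param start,end 1-based inclusive interval, `1 <= start <= end`.
#' @param protein Free-text protein label (defaults to `name`).
#' @return An object of class `site_annotation`.
#' @export
site_annotation <- function(name, start, end, protein = name) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start)
    stop(sprintf("invalid site interval [%s, %s] for '%s'",
                 start, end, name))
  structure(list(name = as.character(name), start = start, end = end,
                 protein = as.character(protein)),
            class = "site_annotation")
}

#' @export
print.site_annotation <- function(x, ...) {
  cat(sprintf("<site> %s [%d..%d] (%s)\n", x$name, x$start, x$end,
              x$protein))
  invisible(x)
}

#' Read binding-site annotations
#'
#' Two dialects are supported. The native format is a 1-based inclusive
#' TSV with header `name start end protein` (protein optional). Files
#' ending in `.bed` are read as BED (0-based, half-open) and converted to
#' the package's 1-based inclusive convention (`start + 1`, `end`); the
#' conversion is reported via [message()].
#'
#' @param path Path to a TSV or BED file.
#' @param seq_length Optional sequence length; sites beyond it are
#'   rejected.
#' @return A list of [site_annotation()] objects.
#' @export
read_sites <- function(path, seq_length = NULL) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 3L) stop("BED file needs at least 3 columns: ", path)
    nm <- if (ncol(df) >= 4L) as.character(df[[4L]])
          else sprintf("site%d", seq_len(nrow(df)))
    message(sprintf(
      "read_sites: converted %d BED intervals (0-based half-open) to 1-based inclusive",
      nrow(df)))
    starts <- df[[2L]] + 1L
    ends <- df[[3L]]
  } else {
    df <- utils::read.delim(path, header = TRUE,
                            stringsAsFactors = FALSE)
    need <- c("name", "start", "end")
    if (!all(need %in% names(df)))
      stop("site TSV needs columns name, start, end: ", path)
    nm <- as.character(df$name)
    starts <- df$start
    ends <- df$end
  }
  prot <- if ("protein" %in% names(df)) as.character(df$protein) else nm
  sites <- Map(site_annotation, nm, starts, ends, prot)
  names(sites) <- nm
  if (!is.null(seq_length)) {
    for (s in sites)
      if (s$end > seq_length)
        stop(sprintf("site '%s' end %d exceeds sequence length %d",
                     s$name, s$end, seq_length))
  }
  sites
}

#' Write sites in the native 1-based TSV dialect
#'
#' @param sites List of [site_annotation()].
#' @param path Output path.
#' @export
write_sites <- function(sites, path) {
  df <- data.frame(name = vapply(sites, `[[`, "", "name"),
                   start = vapply(sites, `[[`, 1L, "start"),
                   end = vapply(sites, `[[`, 1L, "end"),
                   protein = vapply(sites, `[[`, "", "protein"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
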