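#' Experimental ORChID2: cross-strand averaging
#'
#' In B-form DNA the nucleotide directly across the minor groove from
#' position `i` of one strand is the other strand's nucleotide staggered
#' three positions toward its 3' end. The experimental ORChID2 value at
#' `i` is the mean of the two strands' normalized cleavage values for
#' that cross-groove pair:
#' `value(i) = (fwd(i) + rev(i + offset)) / 2`.
#' Both profiles are keyed by forward coordinates; the reverse strand's
#' 3' direction runs toward decreasing forward coordinates, so the
#' default offset is -3. Positions where either partner is missing are
#' absent from the output.
#'
#' @param fwd,rev [cleavage_profile()]s for the two strands, both keyed
#'   by forward coordinates.
#' @param offset Signed cross-strand stagger in forward coordinates.
#' @return An unsmoothed [orchid2_profile()].
#' @export
exp_orchid2 <- function(fwd, rev, offset = -3L) {
  offset <- as.integer(offset)
  partner <- fwd$position + offset
  m <- match(partner, rev$position)
  ok <- !is.na(m)
  if (!any(ok))
    stop("no positions where both strands have a cross-groove partner")
  orchid2_profile(fwd$position[ok],
                  (fwd$value[ok] + rev$value[m[ok]]) / 2,
                  smoothed = FALSE)
}

#' Loess-smooth an ORChID2 profile
#'
#' Minimal local-linear smoothing of a per-position profile, as with
#' `loess.smooth` in R: tricube-weighted local linear regression over
#' the nearest `span` fraction of points, evaluated on an equally spaced
#' grid of `evaluation` points over the position range, then mapped back
#' to the integer positions by linear interpolation. The defaults
#' (`span = 0.015`, `evaluation = 300`) give minimal smoothing of a
#' ~300-nt profile.
#'
#' @param profile A profile object (typically an [orchid2_profile()]).
#' @param span Smoothing span as a fraction of the points.
#' @param evaluation Number of grid points at which the local fit is
#'   evaluated.
#' @return A profile of the same subclass, `smoothed = TRUE` for
#'   ORChID2 profiles.
#' @export
loess_smooth_profile <- function(profile, span = 0.015,
                                 evaluation = 300) {
  n <- nrow(profile)
  k <- max(ceiling(span * n), 2)
  if (n < max(4, k))
    stop(sprintf("need at least %d points for span %.4g; got %d",
                 max(4, k), span, n))
  sm <- suppressWarnings(stats::loess.smooth(
    profile$position, profile$value, span = span,
    evaluation = evaluation, degree = 1, family = "gaussian"))
  vals <- stats::approx(sm$x, sm$y, xout = profile$position,
                        rule = 2)$y
  if (inherits(profile, "orchid2_profile"))
    orchid2_profile(profile$position, vals, smoothed = TRUE)
  else
    new_profile(profile$position, vals, class(profile)[1L])
}

#' Pentamer minor-groove-width lookup table
#'
#' A pluggable sequence-to-shape model: a map from each 5-mer over
#' `{A,C,G,T}` to a minor groove width (Angstroms). Tables may be
#' strand-symmetric (a pentamer and its reverse complement share a
#' value); [read_pentamer_table()] can close a half table under that
#' symmetry.
#'
#' @param pentamers Character vector of 5-mers.
#' @param widths Numeric widths (Angstroms).
#' @param symmetric Close the table under reverse complementation.
#' @return Named numeric vector of class `pentamer_table`.
#' @export
pentamer_table <- function(pentamers, widths, symmetric = FALSE) {
  pentamers <- toupper(pentamers)
  if (any(nchar(pentamers) != 5L) || any(grepl("[^ACGT]", pentamers)))
    stop("pentamer keys must be length-5 strings over ACGT")
  if (any(!is.finite(widths))) stop("pentamer widths must be finite")
  tab <- stats::setNames(as.numeric(widths), pentamers)
  if (symmetric) {
    rc <- vapply(names(tab), reverse_complement, "")
    add <- !(rc %in% names(tab))
    tab <- c(tab, stats::setNames(tab[add], rc[add]))
  }
  if (anyDuplicated(names(tab))) stop("duplicate pentamer keys")
  class(tab) <- "pentamer_table"
  tab
}

#' @rdname pentamer_table
#' @param path Two-column TSV (pentamer, width) with header.
#' @export
read_pentamer_table <- function(path, symmetric = FALSE) {
  df <- utils::read.delim(path, header = TRUE,
                          stringsAsFactors = FALSE)
  pentamer_table(df[[1L]], df[[2L]], symmetric = symmetric)
}

#' @rdname pentamer_table
#' @param table A `pentamer_table`.
#' @export
write_pentamer_table <- function(table, path) {
  utils::write.table(data.frame(pentamer = names(table),
                                width = as.numeric(table)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' A synthetic toy pentamer table
#'
#' A deterministic, strand-symmetric stand-in for a real pentamer shape
#' table, for examples and tests: width narrows with A/T content and
#' with ApT steps, echoing the narrow minor groove of A-tracts. Not
#' derived from simulation or experiment.
#'
#' @return A [pentamer_table()] covering all 1024 pentamers.
#' @export
toy_pentamer_table <- function() {
  bases <- c("A", "C", "G", "T")
  g <- expand.grid(b1 = bases, b2 = bases, b3 = bases, b4 = bases,
                   b5 = bases, stringsAsFactors = FALSE)
  pent <- do.call(paste0, g)
  at <- vapply(pent, function(p)
    sum(strsplit(p, "")[[1L]] %in% c("A", "T")), numeric(1))
  apt <- vapply(pent, function(p)
    lengths(regmatches(p, gregexpr("AT", p))), numeric(1))
  width <- 5.8 - 0.35 * at - 0.3 * apt
  # symmetrize: average each pentamer with its reverse complement
  rc <- vapply(pent, reverse_complement, "")
  width <- (width + width[match(rc, pent)]) / 2
  pentamer_table(pent, pmax(width, 2.5))
}

#' Predict minor groove width by sliding-pentamer lookup
#'
#' Slides a 5-nt window along the forward strand; the table value of
#' each pentamer is assigned to the pentamer's central position, so the
#' output covers positions `3..L-2`.
#'
#' @param seq A [duplex_sequence()] of length >= 5.
#' @param table A [pentamer_table()] covering every pentamer in `seq`.
#' @return A [groove_width_profile()] over positions `3..L-2`.
#' @export
predict_pentamer_mgw <- function(seq, table) {
  L <- seq$length
  if (L < 5L) stop("sequence must be at least 5 nt")
  starts <- seq_len(L - 4L)
  pents <- substring(seq$forward, starts, starts + 4L)
  miss <- !(pents %in% names(table))
  if (any(miss))
    stop("pentamer(s) missing from table: ",
         paste(unique(pents[miss]), collapse = ", "))
  groove_width_profile(starts + 2L,
                       as.numeric(unclass(table)[pents]))
}
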