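#' Spearman's rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks),
#' computed via [stats::cor()].
#'
#' @param x,y Equal-length numeric vectors (n >= 2) paired on common
#'   positions.
#' @return Spearman's rho in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 paired values")
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0)
    stop("zero rank variance")
  stats::cor(x, y, method = "spearman")
}

stars_for_p <- function(p) {
  if (p <= 0.001) 4L else if (p <= 0.01) 3L else if (p <= 0.05) 2L
  else if (p <= 0.1) 1L else 0L
}

render_stars <- function(stars) strrep("*", stars)

#' Significance of a Spearman correlation
#'
#' The standard t approximation: `t = rho * sqrt((n-2)/(1-rho^2))`
#' referred to a t distribution with `n - 2` degrees of freedom
#' (two-sided by default). Stars follow the alpha ladder 0.1 (*),
#' 0.05 (**), 0.01 (***), 0.001 (****), with significance declared at
#' `P <= alpha`.
#'
#' @param rho Spearman's rho.
#' @param n Number of paired observations (>= 3).
#' @param two_sided Two-sided p-value (default) or one-sided upper
#'   tail.
#' @return List `t`, `P`, `stars` (0-4), `degenerate` (TRUE when
#'   `|rho| = 1`, for which P underflows the machine floor).
#' @export
rho_significance <- function(rho, n, two_sided = TRUE) {
  if (n < 3L) stop("need n >= 3 for significance")
  if (abs(rho) > 1) stop("|rho| must be <= 1")
  if (abs(rho) == 1) {
    return(list(t = sign(rho) * Inf, P = .Machine$double.xmin,
                stars = 4L, degenerate = TRUE))
  }
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  P <- if (two_sided) 2 * stats::pt(-abs(t), df = n - 2)
       else stats::pt(t, df = n - 2, lower.tail = FALSE)
  list(t = t, P = P, stars = stars_for_p(P), degenerate = FALSE)
}

#' Compare two profiles over binding-site windows
#'
#' For each site, Spearman's rho between the two profiles on the
#' intersection of their defined positions inside the site, with the
#' t-approximation significance; sites with fewer than 3 common
#' positions are excluded with a warning. The summary is the unweighted
#' arithmetic mean of the per-site rho values.
#'
#' @param a,b Profile objects sharing the forward coordinate axis.
#' @param sites List of [site_annotation()]s.
#' @return An object of class `comparison_table`: data frame `site`,
#'   `n`, `rho`, `t`, `P`, `stars`, with attribute `mean_rho`.
#' @export
compare_sites <- function(a, b, sites) {
  rows <- list()
  for (s in sites) {
    pa <- extract_site(a, s)
    common <- intersect(pa$position, b$position)
    if (length(common) < 3L) {
      warning(sprintf("site '%s': only %d common positions, excluded",
                      s$name, length(common)))
      next
    }
    x <- profile_values(a, common)
    y <- profile_values(b, common)
    rho <- spearman_rho(x, y)
    sig <- rho_significance(rho, length(common))
    rows[[length(rows) + 1L]] <- data.frame(
      site = s$name, n = length(common), rho = rho, t = sig$t,
      P = sig$P, stars = render_stars(sig$stars))
  }
  if (length(rows) == 0L) stop("no site had >= 3 common positions")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("comparison_table", "data.frame")
  attr(out, "mean_rho") <- mean(out$rho)
  out
}

#' @export
print.comparison_table <- function(x, ...) {
  NextMethod()
  cat(sprintf("mean rho over %d sites: %.3f\n", nrow(x),
              attr(x, "mean_rho")))
  invisible(x)
}

#' Write a comparison table as TSV
#' @param table A `comparison_table`.
#' @param path Output path.
#' @export
write_comparison <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Calibrate ORChID2 units to Angstroms
#'
#' Least-squares affine map `width ~ slope * orchid + intercept` over a
#' reference window (in practice a naked-DNA reference duplex such as
#' the Drew-Dickerson dodecamer, whose crystallographic groove widths
#' anchor the y-axis scale). The map only rescales the overlay; rank
#' correlations are unchanged by it.
#'
#' @param orchid_vals,groove_vals Paired values over the reference
#'   window (>= 2 points, `orchid_vals` with nonzero variance).
#' @return An object of class `scale_calibration`: list `slope`,
#'   `intercept`, `residual_rms`, `n`.
#' @export
calibrate_scale <- function(orchid_vals, groove_vals) {
  if (length(orchid_vals) != length(groove_vals))
    stop("inputs must have equal length")
  if (length(orchid_vals) < 2L) stop("need at least 2 paired points")
  if (stats::var(orchid_vals) == 0)
    stop("zero variance in ORChID2 values")
  fit <- stats::lm(groove_vals ~ orchid_vals)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 residual_rms = sqrt(mean(stats::residuals(fit)^2)),
                 n = length(orchid_vals)),
            class = "scale_calibration")
}

#' Apply a scale calibration to a profile
#'
#' Pure transform: `slope * value + intercept`, returned as a
#' [groove_width_profile()] (negative mapped values clamp to zero).
#'
#' @param profile A profile object.
#' @param calibration A [calibrate_scale()] result.
#' @export
apply_calibration <- function(profile, calibration) {
  v <- calibration$slope * profile$value + calibration$intercept
  groove_width_profile(profile$position, pmax(v, 0))
}
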