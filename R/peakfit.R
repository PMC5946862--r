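#' A set of Gaussian peaks
#'
#' Holds the parameters of the fitted (or initial) Gaussian mixture: one
#' row per peak with amplitude `a >= 0`, center `c` (data points,
#' strictly increasing), width `w > 0`, the assigned fragment length
#' (nt, or `NA`), the trapezoidal `area`, and the median-window
#' `normalized_area`.
#'
#' @param amplitude,center,width Numeric vectors of equal length.
#' @param fragment_length Integer fragment lengths or `NA`.
#' @return An object of class `peak_set` (a data frame).
#' @export
peak_set <- function(amplitude, center, width, fragment_length = NA) {
  n <- length(amplitude)
  stopifnot(length(center) == n, length(width) == n)
  if (any(amplitude < 0)) stop("amplitudes must be >= 0")
  if (any(width <= 0)) stop("widths must be > 0")
  ord <- order(center)
  out <- data.frame(fragment_length =
                      as.integer(rep_len(fragment_length, n))[ord],
                    amplitude = amplitude[ord], center = center[ord],
                    width = width[ord], area = NA_real_,
                    normalized_area = NA_real_,
                    edge_flagged = FALSE)
  if (n > 1L && any(diff(out$center) <= 0))
    stop("peak centers must be strictly increasing")
  class(out) <- c("peak_set", "data.frame")
  out
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peaks\n", nrow(x)))
  NextMethod()
}

#' Read / write a peak set TSV
#' @param path File path.
#' @param peaks A `peak_set`.
#' @export
write_peak_set <- function(peaks, path) {
  utils::write.table(as.data.frame(peaks), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_set
#' @export
read_peak_set <- function(path) {
  df <- utils::read.delim(path, header = TRUE)
  ps <- peak_set(df$amplitude, df$center, df$width, df$fragment_length)
  for (col in intersect(c("area", "normalized_area", "base"), names(df)))
    ps[[col]] <- df[[col]]
  ps
}

#' Fitting configuration
#'
#' Parameters of the three-pass sliding-window fit. Defaults follow the
#' scheme of 600-point windows (roughly 40-60 peaks each) stepped by 300
#' points, discarding the five first and last peaks of each window, and
#' 50-nt normalization blocks.
#'
#' @param window Window size in data points.
#' @param shift Window step in data points (must be <= `window`).
#' @param edge_discard Peaks discarded at each window edge.
#' @param norm_window Nucleotides per normalization block.
#' @param ladder_sensitivity Fraction of the global maximum a ladder
#'   local maximum must exceed.
#' @param tol Convergence tolerance on the cost.
#' @param max_iter Maximum optimizer iterations per window.
#' @param width_level Level of the width-regression prediction interval
#'   used to bound widths in pass 2.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(window = 600, shift = 300, edge_discard = 5,
                       norm_window = 50, ladder_sensitivity = 0.1,
                       tol = 1e-8, max_iter = 200, width_level = 0.95) {
  if (shift > window) stop("shift must be <= window")
  structure(list(window = window, shift = shift,
                 edge_discard = edge_discard, norm_window = norm_window,
                 ladder_sensitivity = ladder_sensitivity, tol = tol,
                 max_iter = max_iter, width_level = width_level),
            class = "fit_config")
}

#' Subtract the global baseline from a trace
#'
#' Subtracts the global minimum intensity from every sample, so the
#' output minimum is exactly zero and the shape is preserved.
#'
#' @param trace A `ce_trace`.
#' @return The baseline-subtracted trace.
#' @export
subtract_baseline <- function(trace) {
  if (nrow(trace) == 0L) stop("empty trace")
  trace$intensity <- trace$intensity - min(trace$intensity)
  trace
}

#' Detect ladder peak maxima
#'
#' Simple local-maximum detection: the trace is lightly smoothed with a
#' centered moving average (`smooth_pts` samples) and re-zeroed, then a
#' sample is a peak if it exceeds both neighbors (plateaus report their
#' leftmost sample) and its intensity exceeds `sensitivity` times the
#' global maximum. Candidates closer than `min_sep` data points to a
#' taller candidate are suppressed, so noise ripples on a peak flank do
#' not register as extra peaks.
#'
#' @param trace Baseline-subtracted `ce_trace`.
#' @param sensitivity Fraction of the global maximum (default 0.1).
#' @param min_sep Minimum separation between reported peaks (data
#'   points).
#' @param smooth_pts Odd moving-average length; 1 disables smoothing.
#' @return Numeric vector of peak centers (data points), ordered.
#' @export
detect_ladder_peaks <- function(trace, sensitivity = 0.1,
                                min_sep = 10, smooth_pts = 5) {
  y <- trace$intensity
  if (smooth_pts > 1L && length(y) > smooth_pts) {
    y <- as.numeric(stats::filter(y, rep(1 / smooth_pts, smooth_pts),
                                  sides = 2))
    half <- smooth_pts %/% 2L
    y[seq_len(half)] <- y[half + 1L]
    y[length(y) - seq_len(half) + 1L] <- y[length(y) - half]
    y <- y - min(y)
  }
  n <- length(y)
  if (n < 3L) return(numeric(0))
  thr <- sensitivity * max(y)
  # strictly rises before, does not rise after; ties resolve leftmost
  d <- diff(y)
  rising <- c(FALSE, d > 0)
  falling_next <- c(d < 0, FALSE)
  flat_next <- c(d == 0, FALSE)
  is_max <- logical(n)
  i <- 2L
  while (i <= n - 1L) {
    if (rising[i]) {
      if (falling_next[i]) { is_max[i] <- TRUE; i <- i + 1L; next }
      if (flat_next[i]) {
        j <- i
        while (j < n && y[j + 1L] == y[i]) j <- j + 1L
        if (j < n && y[j + 1L] < y[i]) is_max[i] <- TRUE
        i <- j + 1L; next
      }
    }
    i <- i + 1L
  }
  cand <- which(is_max & y > thr)
  if (length(cand) == 0L) return(numeric(0))
  # greedy non-maximum suppression within min_sep
  cand <- cand[order(-y[cand])]
  kept <- integer(0)
  for (i in cand)
    if (all(abs(trace$data_point[i] - trace$data_point[kept]) >= min_sep))
      kept <- c(kept, i)
  sort(trace$data_point[kept])
}

#' Assign ladder fragment lengths to detected centers
#'
#' Pairs the i-th smallest detected center with the i-th smallest known
#' ladder fragment length; refuses a count mismatch.
#'
#' @param centers Detected peak centers.
#' @param ladder Known ladder fragment lengths (nt).
#' @return Data frame `fragment_length`, `center`.
#' @export
assign_ladder <- function(centers, ladder) {
  if (length(centers) != length(ladder))
    stop(sprintf("detected %d ladder peaks but ladder defines %d lengths",
                 length(centers), length(ladder)))
  data.frame(fragment_length = as.integer(sort(ladder)),
             center = sort(centers))
}

# residuals and analytic jacobian of the Gaussian-sum model
#   G(x) = b + sum_i a_i exp(-0.5 ((x - c_i)/w_i)^2)
gauss_sum <- function(x, a, cc, w, b = 0) {
  y <- rep(b, length(x))
  for (i in seq_along(a))
    y <- y + a[i] * exp(-0.5 * ((x - cc[i]) / w[i])^2)
  y
}

# Bounded Levenberg-Marquardt fit of a sum of Gaussians.
# free_w: "free" (a,c,w), "bounded" (a,c,w with per-peak w box), "fixed"
# (a,c only). Returns list(a, c, w, info, deviance).
fit_gauss_window <- function(x, y, a0, c0, w0, c_lo, c_hi,
                             w_lo = NULL, w_hi = NULL,
                             free_w = c("free", "bounded", "fixed"),
                             tol = 1e-8, max_iter = 200) {
  free_w <- match.arg(free_w)
  np <- length(a0)
  with_w <- free_w != "fixed"
  pack <- function(a, cc, w) if (with_w) c(a, cc, w) else c(a, cc)
  unpack <- function(p) {
    a <- p[seq_len(np)]; cc <- p[np + seq_len(np)]
    w <- if (with_w) p[2L * np + seq_len(np)] else w0
    list(a = a, cc = cc, w = w)
  }
  resid_fn <- function(p) {
    q <- unpack(p)
    gauss_sum(x, q$a, q$cc, q$w) - y
  }
  jac_fn <- function(p) {
    q <- unpack(p)
    J <- matrix(0, length(x), length(p))
    for (i in seq_len(np)) {
      z <- (x - q$cc[i]) / q$w[i]
      E <- exp(-0.5 * z^2)
      J[, i] <- E
      J[, np + i] <- q$a[i] * E * z / q$w[i]
      if (with_w) J[, 2L * np + i] <- q$a[i] * E * z^2 / q$w[i]
    }
    J
  }
  if (is.null(w_lo)) w_lo <- rep(1e-6, np)
  if (is.null(w_hi)) w_hi <- rep(Inf, np)
  lower <- pack(rep(0, np), c_lo, pmax(w_lo, 1e-6))
  upper <- pack(rep(Inf, np), c_hi, w_hi)
  p0 <- pmin(pmax(pack(a0, c0, w0), lower), upper)
  fit <- minpack.lm::nls.lm(
    par = p0, lower = lower, upper = upper,
    fn = resid_fn, jac = jac_fn,
    control = minpack.lm::nls.lm.control(
      ftol = tol, ptol = tol, maxiter = max_iter))
  q <- unpack(fit$par)
  list(a = q$a, c = q$cc, w = q$w, info = fit$info,
       deviance = fit$deviance)
}

#' Fit the size-standard ladder
#'
#' Jointly fits one Gaussian per assigned ladder peak by bounded
#' nonlinear least squares, then regresses fitted width on fitted center
#' to give the width model (with prediction intervals) used to
#' initialize and constrain the cleavage-channel fit.
#'
#' @param trace Baseline-subtracted ladder `ce_trace`.
#' @param assignment Data frame from [assign_ladder()].
#' @param cfg A [fit_config()].
#' @return List with `peaks` (data frame `fragment_length`, `amplitude`,
#'   `center`, `width`) and `width_fit` (an [stats::lm()] of width on
#'   center).
#' @export
fit_ladder <- function(trace, assignment, cfg = fit_config()) {
  x <- trace$data_point; y <- trace$intensity
  c0 <- assignment$center
  n <- length(c0)
  a0 <- y[pmax(1L, round(c0 - x[1L] + 1))]
  spacing <- if (n > 1L) min(diff(c0)) else diff(range(x))
  # width init from the half-maximum crossing around each apex
  w0 <- vapply(seq_len(n), function(i) {
    ci <- round(c0[i] - x[1L] + 1)
    half <- a0[i] / 2
    r <- ci
    while (r < length(y) && y[r] > half && x[r] - c0[i] < spacing / 2)
      r <- r + 1L
    hwhm <- max(x[r] - c0[i], 1)
    hwhm / sqrt(2 * log(2))
  }, numeric(1))
  fit <- fit_gauss_window(x, y, a0, c0, w0,
                          c_lo = c0 - spacing / 2, c_hi = c0 + spacing / 2,
                          free_w = "free",
                          tol = cfg$tol, max_iter = cfg$max_iter)
  if (!fit$info %in% 1:3)
    stop("ladder fit did not converge (residual norm ",
         signif(sqrt(fit$deviance), 4), ")")
  peaks <- data.frame(fragment_length = assignment$fragment_length,
                      amplitude = fit$a, center = fit$c, width = fit$w)
  if (n < 3L)
    stop("ladder width regression needs at least 3 peaks; got ", n)
  width_fit <- stats::lm(width ~ center, data = peaks)
  list(peaks = peaks, width_fit = width_fit)
}

width_interval <- function(width_fit, centers, level = 0.95) {
  pr <- stats::predict(width_fit,
                       newdata = data.frame(center = centers),
                       interval = "prediction", level = level)
  pr[, "lwr"] <- pmax(pr[, "lwr"], 1e-6)
  pr
}

#' Initialize cleavage peaks from the ladder
#'
#' One initial Gaussian per expected fragment: centers linearly
#' interpolated in fragment length between bracketing ladder peaks,
#' amplitude equal to the trace intensity at the (rounded) center, width
#' from the ladder width regression evaluated at the center. Fragments
#' outside the ladder span are refused (no extrapolation).
#'
#' @param trace Baseline-subtracted cleavage `ce_trace`.
#' @param ladder_fit Result of [fit_ladder()].
#' @param fragments Integer fragment lengths expected in the trace.
#' @return An initial [peak_set()].
#' @export
initialize_peaks <- function(trace, ladder_fit, fragments) {
  lp <- ladder_fit$peaks
  fragments <- sort(as.integer(fragments))
  if (min(fragments) < min(lp$fragment_length) ||
      max(fragments) > max(lp$fragment_length))
    stop(sprintf(
      "fragments %d..%d outside ladder span %d..%d (no extrapolation)",
      min(fragments), max(fragments),
      min(lp$fragment_length), max(lp$fragment_length)))
  centers <- stats::approx(lp$fragment_length, lp$center,
                           xout = fragments)$y
  idx <- round(centers) - trace$data_point[1L] + 1
  idx <- pmin(pmax(idx, 1L), nrow(trace))
  amp <- pmax(trace$intensity[idx], 0)
  width <- as.numeric(stats::predict(
    ladder_fit$width_fit, newdata = data.frame(center = centers)))
  if (any(width <= 0)) stop("ladder width regression predicts w <= 0")
  peak_set(amplitude = amp, center = centers, width = width,
           fragment_length = fragments)
}

window_starts <- function(x, window, shift) {
  lo <- min(x); hi <- max(x)
  if (hi - lo + 1 <= window) return(lo)
  st <- seq(lo, hi - window + 1, by = shift)
  if (st[length(st)] + window - 1 < hi) st <- c(st, hi - window + 1)
  st
}

# run one sliding-window pass; returns updated peaks + edge flags
run_pass <- function(trace, peaks, cfg, free_w, width_fit = NULL) {
  x_all <- trace$data_point; y_all <- trace$intensity
  starts <- window_starts(x_all, cfg$window, cfg$shift)
  n <- nrow(peaks)
  best_score <- rep(Inf, n)       # distance of peak from window center
  got_nonedge <- rep(FALSE, n)
  res <- peaks
  spacing <- if (n > 1L) stats::median(diff(peaks$center)) else
    diff(range(x_all))
  for (s in starts) {
    in_win <- which(peaks$center >= s & peaks$center < s + cfg$window)
    if (length(in_win) == 0L) {
      message(sprintf("fit window [%g, %g): no peaks, skipped",
                      s, s + cfg$window))
      next
    }
    sel <- x_all >= s & x_all < s + cfg$window
    x <- x_all[sel]; y <- y_all[sel]
    a0 <- peaks$amplitude[in_win]
    c0 <- peaks$center[in_win]
    w0 <- peaks$width[in_win]
    w_lo <- NULL; w_hi <- NULL
    if (identical(free_w, "bounded")) {
      pr <- width_interval(width_fit, c0, cfg$width_level)
      w_lo <- pr[, "lwr"]; w_hi <- pr[, "upr"]
      w0 <- pmin(pmax(w0, w_lo), w_hi)
    }
    fit <- fit_gauss_window(x, y, a0, c0, w0,
                            c_lo = c0 - spacing / 2,
                            c_hi = c0 + spacing / 2,
                            w_lo = w_lo, w_hi = w_hi, free_w = free_w,
                            tol = cfg$tol, max_iter = cfg$max_iter)
    if (!fit$info %in% 1:3)
      stop(sprintf("fit did not converge in window [%g, %g) (info %d)",
                   s, s + cfg$window, fit$info))
    m <- length(in_win)
    edge <- rep(FALSE, m)
    if (m > 2L * cfg$edge_discard) {
      edge[seq_len(cfg$edge_discard)] <- TRUE
      edge[m - seq_len(cfg$edge_discard) + 1L] <- TRUE
    }
    score <- abs(c0 - (s + cfg$window / 2))
    for (k in seq_len(m)) {
      j <- in_win[k]
      accept <- if (edge[k]) !got_nonedge[j] && score[k] < best_score[j]
                else !got_nonedge[j] || score[k] < best_score[j]
      if (accept) {
        res$amplitude[j] <- fit$a[k]
        res$center[j] <- fit$c[k]
        res$width[j] <- fit$w[k]
        res$edge_flagged[j] <- edge[k]
        best_score[j] <- score[k]
        if (!edge[k]) got_nonedge[j] <- TRUE
      }
    }
  }
  res
}

#' Three-pass sliding-window Gaussian fit
#'
#' Fits the cleavage trace to a sum of Gaussians in three passes over
#' sliding windows of `cfg$window` data points stepped by `cfg$shift`:
#' pass 1 optimizes amplitude, center and width jointly and refreshes
#' the global width-versus-center regression; pass 2 re-optimizes with
#' each width constrained inside that regression's prediction interval;
#' pass 3 optimizes amplitude and center with widths held fixed.
#' Within each window the first and last `cfg$edge_discard` peaks are
#' discarded and retained from the overlapping window; peaks near the
#' trace ends that are only ever edge peaks keep the only available
#' estimate and are flagged.
#'
#' @param trace Baseline-subtracted cleavage `ce_trace`.
#' @param init Initial [peak_set()] from [initialize_peaks()].
#' @param cfg A [fit_config()].
#' @return The fitted `peak_set` (attribute `width_fit` holds the pass-1
#'   width regression).
#' @export
fit_peaks <- function(trace, init, cfg = fit_config()) {
  stopifnot(inherits(init, "peak_set"))
  p1 <- run_pass(trace, init, cfg, free_w = "free")
  if (nrow(p1) >= 3L) {
    wf <- stats::lm(width ~ center,
                    data = data.frame(width = p1$width,
                                      center = p1$center))
    p2 <- run_pass(trace, p1, cfg, free_w = "bounded", width_fit = wf)
  } else {
    # too few peaks for a width trend: leave widths free in pass 2
    wf <- NULL
    p2 <- run_pass(trace, p1, cfg, free_w = "free")
  }
  p3 <- run_pass(trace, p2, cfg, free_w = "fixed")
  out <- p3[order(p3$center), ]
  rownames(out) <- NULL
  class(out) <- class(init)
  attr(out, "width_fit") <- wf
  out
}

#' Integrate fitted peaks
#'
#' Trapezoidal integration of each single-peak model
#' `a*exp(-0.5((x-c)/w)^2)` at unit grid step over `c +/- 6w`, truncated
#' to the fitted trace range.
#'
#' @param peaks A fitted `peak_set`.
#' @param range Numeric length-2: the fitted data-point range.
#' @return `peaks` with the `area` column filled.
#' @export
integrate_peaks <- function(peaks, range) {
  lo_all <- range[1L]; hi_all <- range[2L]
  peaks$area <- vapply(seq_len(nrow(peaks)), function(i) {
    a <- peaks$amplitude[i]; cc <- peaks$center[i]; w <- peaks$width[i]
    if (a == 0) return(0)
    lo <- max(lo_all, floor(cc - 6 * w))
    hi <- min(hi_all, ceiling(cc + 6 * w))
    x <- seq(lo, hi, by = 1)
    pracma::trapz(x, a * exp(-0.5 * ((x - cc) / w)^2))
  }, numeric(1))
  peaks
}

#' Median-window normalization of peak areas
#'
#' Partitions peaks (by assigned fragment length) into consecutive
#' non-overlapping blocks of `norm_window` nucleotides (the last block
#' may be short) and divides each area by its block median, so the
#' median normalized area within every block is exactly 1.000 while the
#' dynamic range of individual peaks is preserved.
#'
#' @param peaks A `peak_set` with areas and fragment lengths.
#' @param norm_window Block size in nucleotides.
#' @return `peaks` with `normalized_area` filled.
#' @export
normalize_areas <- function(peaks, norm_window = 50) {
  if (anyNA(peaks$fragment_length))
    stop("all peaks must have assigned fragment lengths")
  if (anyNA(peaks$area)) stop("areas must be computed first")
  block <- (peaks$fragment_length - min(peaks$fragment_length)) %/%
    norm_window
  med <- stats::ave(peaks$area, block, FUN = stats::median)
  if (any(med == 0)) stop("normalization block with zero median area")
  peaks$normalized_area <- peaks$area / med
  peaks
}

#' Convert a peak set to a per-position cleavage profile
#'
#' With a 5' label, a fragment of length `k` reports cleavage at
#' position `k` of the labeled strand. Forward-strand fragments map to
#' forward coordinate `k`; reverse-strand fragments map to forward
#' coordinate `L - k + 1`, so both strands share the forward axis.
#'
#' @param peaks A normalized `peak_set`.
#' @param strand Which strand was labeled.
#' @param seq A [duplex_sequence()].
#' @return A [cleavage_profile()].
#' @export
peaks_to_profile <- function(peaks, strand = c("forward", "reverse"),
                             seq) {
  strand <- match.arg(strand)
  if (anyNA(peaks$normalized_area))
    stop("normalized areas must be computed first")
  k <- peaks$fragment_length
  pos <- if (strand == "forward") k else seq$length - k + 1L
  if (anyDuplicated(pos))
    stop("duplicate profile positions from fragment lengths")
  cleavage_profile(pos, peaks$normalized_area, strand = strand)
}

#' Fit one cleavage channel end to end
#'
#' Convenience wrapper: baseline-subtract both channels, detect and fit
#' the ladder, initialize, run the three-pass fit, integrate and
#' normalize.
#'
#' @param cleavage_trace,ladder_trace Raw `ce_trace` objects.
#' @param ladder Known ladder fragment lengths.
#' @param fragments Expected cleavage fragment lengths.
#' @param cfg A [fit_config()].
#' @return A normalized `peak_set`.
#' @export
fit_channel <- function(cleavage_trace, ladder_trace, ladder, fragments,
                        cfg = fit_config()) {
  lt <- subtract_baseline(ladder_trace)
  ct <- subtract_baseline(cleavage_trace)
  centers <- detect_ladder_peaks(lt, cfg$ladder_sensitivity)
  lad <- fit_ladder(lt, assign_ladder(centers, ladder), cfg)
  init <- initialize_peaks(ct, lad, fragments)
  fitted <- fit_peaks(ct, init, cfg)
  fitted <- integrate_peaks(fitted, range(ct$data_point))
  normalize_areas(fitted, cfg$norm_window)
}
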