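#' Electrophoretic migration model
#'
#' Maps fragment length (nt) to data-point index on the electropherogram.
#' The default is affine-plus-quadratic,
#' `c(len) = p0 + p1*len + p2*len^2`, with a small positive quadratic
#' term mimicking the slowly stretching peak spacing of capillary
#' electrophoresis. The model must be strictly increasing over the
#' simulated length range.
#'
#' @param p0,p1,p2 Coefficients (data points; data points per nt; per
#'   nt^2).
#' @return An object of class `migration_model`; call it with
#'   [migrate()].
#' @export
migration_model <- function(p0 = 50, p1 = 11, p2 = 2e-4) {
  structure(list(p0 = p0, p1 = p1, p2 = p2), class = "migration_model")
}

#' Evaluate a migration model
#' @param model A [migration_model()].
#' @param len Fragment lengths (nt).
#' @return Data-point indices (numeric).
#' @export
migrate <- function(model, len) {
  model$p0 + model$p1 * len + model$p2 * len^2
}

check_monotone_migration <- function(model, lens) {
  lens <- sort(unique(lens))
  if (length(lens) > 1L && any(diff(migrate(model, lens)) <= 0))
    stop("migration model is not strictly increasing over the simulated range")
  invisible(TRUE)
}

#' Simulation specification
#'
#' Describes one synthetic electropherogram experiment: the labeled
#' strand of a duplex, the true per-position cleavage intensity, peak
#' width and migration models, baseline and noise, and the size-standard
#' ladder. One cleavage fragment of length `k` is produced per cleaved
#' position `k` of the labeled strand (5' label), so intensities are
#' keyed by the labeled strand's own 5'->3' positions `1..L-1`.
#'
#' Noise has two parts: additive Gaussian noise of standard deviation
#' `noise_add` (fluorescence units) on every sample, and independent
#' per-peak multiplicative amplitude jitter with standard deviation
#' `noise_mult`. Both default to the small values (1 fluorescence unit
#' against amplitudes of ~100, i.e. ~1%, and 5%) typical of a clean CE
#' run. The deuteration factor `f_D` scales adenine peak amplitudes in
#' the deuterated sample; its default 0.5 reflects the roughly two-fold
#' reduction in hydroxyl radical cleavage caused by 5',5''-deuteration.
#'
#' @param sequence A [duplex_sequence()].
#' @param strand Which strand carries the fluorescent label.
#' @param intensity Positive numeric vector of true cleavage intensities
#'   for labeled-strand positions `1..L-1` (recycled if scalar).
#' @param fragments Integer vector of fragment lengths actually observed
#'   (default all of `1..L-1`); lets a run restrict to the ladder span.
#' @param baseline Baseline fluorescence `b`.
#' @param noise_add Additive Gaussian sd per sample.
#' @param noise_mult Per-peak multiplicative amplitude jitter sd.
#' @param width0,width1 Peak width model `w(c) = width0 + width1*c`
#'   (data points), linear in data-point index.
#' @param migration A [migration_model()].
#' @param f_D Deuteration amplitude factor in (0, 1].
#' @param ladder Ladder fragment lengths (nt).
#' @param ladder_amplitude Amplitude of ladder peaks.
#' @param seed Integer random seed (required; fixed seed gives
#'   bit-reproducible traces).
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(sequence, strand = c("forward", "reverse"),
                     intensity = 100, fragments = NULL,
                     baseline = 20, noise_add = 1, noise_mult = 0.05,
                     width0 = 3, width1 = 3e-4,
                     migration = migration_model(),
                     f_D = 0.5,
                     ladder = seq(60, 440, by = 20),
                     ladder_amplitude = 100,
                     seed) {
  strand <- match.arg(strand)
  if (missing(seed)) stop("`seed` is required")
  L <- sequence$length
  npos <- L - 1L
  intensity <- rep_len(as.numeric(intensity), npos)
  if (any(intensity <= 0)) stop("intensities must be > 0")
  if (is.null(fragments)) fragments <- seq_len(npos)
  fragments <- sort(as.integer(fragments))
  if (any(fragments < 1L | fragments > npos))
    stop("fragments must lie in 1..L-1")
  if (f_D <= 0 || f_D > 1) stop("f_D must be in (0, 1]")
  spec <- structure(list(
    sequence = sequence, strand = strand, intensity = intensity,
    fragments = fragments, baseline = baseline,
    noise_add = noise_add, noise_mult = noise_mult,
    width0 = width0, width1 = width1, migration = migration,
    f_D = f_D, ladder = as.integer(ladder),
    ladder_amplitude = ladder_amplitude, seed = as.integer(seed)),
    class = "sim_spec")
  check_monotone_migration(migration, c(spec$fragments, spec$ladder))
  wmin <- width0 + width1 * migrate(migration, min(spec$fragments))
  if (wmin <= 0) stop("peak width model must be positive over the range")
  spec
}

#' Read a simulation spec from a YAML config
#'
#' Keys mirror the arguments of [sim_spec()]; `sequence` is a FASTA path
#' and `migration` a mapping `p0/p1/p2`.
#'
#' @param path YAML file.
#' @return A `sim_spec`.
#' @export
read_sim_spec <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$sequence)) stop("config must name a `sequence` FASTA path")
  seqd <- read_fasta_duplex(y$sequence)
  mig <- if (is.null(y$migration)) migration_model()
         else do.call(migration_model, y$migration)
  args <- y[setdiff(names(y), c("sequence", "migration"))]
  do.call(sim_spec, c(list(sequence = seqd, migration = mig), args))
}

sim_truth <- function(spec, channel, deuterated = FALSE) {
  if (channel == "ladder") {
    frag <- spec$ladder
    amp0 <- rep(spec$ladder_amplitude, length(frag))
  } else {
    frag <- spec$fragments
    amp0 <- spec$intensity[frag]
    if (deuterated) {
      bases <- strand_bases(spec$sequence, spec$strand)
      amp0 <- amp0 * ifelse(bases[frag] == "A", spec$f_D, 1)
    }
  }
  centers <- migrate(spec$migration, frag)
  widths <- spec$width0 + spec$width1 * centers
  # per-peak amplitude jitter first, then sample noise: both streams are
  # reproduced exactly for the same seed
  jitter <- stats::rnorm(length(frag), 0, spec$noise_mult)
  amp <- amp0 * (1 + jitter)
  amp[amp < 0] <- 0
  data.frame(fragment_length = frag, amplitude = amp, center = centers,
             width = widths, area = amp * widths * sqrt(2 * pi))
}

#' Simulate an electropherogram trace
#'
#' Generates `trace(x) = b + sum_i a_i exp(-0.5 ((x - c_i)/w_i)^2) +
#' noise` on an integer data-point grid covering all peaks plus a 6-width
#' margin, together with the per-fragment ground truth (realized
#' amplitude after jitter, center, width, and the analytic area
#' `a*w*sqrt(2*pi)`).
#'
#' @param spec A [sim_spec()].
#' @param channel `"cleavage"` or `"ladder"`.
#' @param deuterated Internal; use [simulate_deuterated()].
#' @return A list with `trace` (class `ce_trace`: data frame
#'   `data_point`, `intensity`) and `truth` (data frame, one row per
#'   fragment).
#' @export
simulate_trace <- function(spec, channel = c("cleavage", "ladder"),
                           deuterated = FALSE) {
  channel <- match.arg(channel)
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  truth <- sim_truth(spec, channel, deuterated = deuterated)
  margin <- 6 * max(truth$width)
  x <- seq.int(max(1L, floor(min(truth$center) - margin)),
               ceiling(max(truth$center) + margin))
  y <- rep(spec$baseline, length(x))
  for (i in seq_len(nrow(truth)))
    y <- y + truth$amplitude[i] *
      exp(-0.5 * ((x - truth$center[i]) / truth$width[i])^2)
  if (spec$noise_add > 0)
    y <- y + stats::rnorm(length(x), 0, spec$noise_add)
  trace <- new_trace(x, y, channel = channel)
  list(trace = trace, truth = truth)
}

#' Simulate the adenine-deuterated sample
#'
#' Identical to [simulate_trace()] for the cleavage channel except that
#' the amplitude of every peak whose labeled-strand base is adenine is
#' multiplied by `spec$f_D`. With the same seed and `f_D = 1` the output
#' is identical to the normal trace; a normal/deuterated pair from
#' separate reactions should use different seeds.
#'
#' @param spec A [sim_spec()].
#' @return As [simulate_trace()].
#' @export
simulate_deuterated <- function(spec) {
  simulate_trace(spec, "cleavage", deuterated = TRUE)
}

new_trace <- function(data_point, intensity, channel = "cleavage") {
  out <- data.frame(data_point = as.numeric(data_point),
                    intensity = as.numeric(intensity))
  class(out) <- c("ce_trace", "data.frame")
  attr(out, "channel") <- channel
  out
}

#' @export
print.ce_trace <- function(x, ...) {
  cat(sprintf("<ce_trace> %d samples [%g..%g], channel: %s\n",
              nrow(x), min(x$data_point), max(x$data_point),
              attr(x, "channel")))
  invisible(x)
}

#' Read / write a trace TSV
#'
#' Two tab-separated columns `data_point`, `intensity` with a header.
#'
#' @param path File path.
#' @param trace A `ce_trace`.
#' @param channel Channel label to attach on read.
#' @export
read_trace <- function(path, channel = "cleavage") {
  df <- utils::read.delim(path, header = TRUE,
                          colClasses = c("numeric", "numeric"))
  new_trace(df[[1L]], df[[2L]], channel = channel)
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(data_point = trace$data_point,
                   intensity = formatC(trace$intensity, digits = 15,
                                       format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE,
                     col.names = c("data_point", "intensity"))
  invisible(path)
}

#' PeakSet from simulator ground truth
#'
#' Converts a ground-truth table into a fitted-look [peak_set()] using
#' the analytic areas, for studies that isolate downstream stages
#' (normalization, adenine calling) from the curve-fitting stage.
#'
#' @param truth Ground-truth data frame from [simulate_trace()].
#' @return A `peak_set` with areas set to the analytic values.
#' @export
peakset_from_truth <- function(truth) {
  ps <- peak_set(amplitude = truth$amplitude, center = truth$center,
                 width = truth$width,
                 fragment_length = truth$fragment_length)
  ps$area <- truth$area
  ps
}
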