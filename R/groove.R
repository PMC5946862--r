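#' Backbone phosphate model of a duplex
#'
#' The minimal geometry needed for minor groove width: one phosphate
#' (P atom) coordinate per residue on each strand, each strand ordered
#' 5' to 3'. Strands are paired antiparallel by order: residue `j` of
#' the second strand pairs with forward coordinate `n_bp - j + 1`.
#'
#' @param forward,reverse Data frames with columns `res` (strictly
#'   increasing residue index) and `x`, `y`, `z` (Angstroms).
#' @param n_bp Duplex length in bp (defaults to the larger strand
#'   residue count).
#' @return An object of class `backbone_model`.
#' @export
backbone_model <- function(forward, reverse, n_bp = NULL) {
  for (df in list(forward, reverse)) {
    if (!all(c("res", "x", "y", "z") %in% names(df)))
      stop("strand data frames need columns res, x, y, z")
    if (any(diff(df$res) <= 0))
      stop("residue indices must be strictly increasing within a strand")
    if (any(!is.finite(as.matrix(df[c("x", "y", "z")]))))
      stop("coordinates must be finite")
  }
  if (is.null(n_bp)) n_bp <- max(nrow(forward), nrow(reverse))
  structure(list(forward = forward, reverse = reverse,
                 n_bp = as.integer(n_bp)),
            class = "backbone_model")
}

#' Parse a duplex backbone from a PDB file
#'
#' Reads the phosphate (P) atoms of two named chains via
#' [bio3d::read.pdb()]. Only blank or 'A' altloc records are used.
#' Residues without a P atom (typically 5' termini) are omitted.
#'
#' @param path PDB file.
#' @param chainA,chainB Chain identifiers of the two strands (A strand
#'   is taken as the forward strand, 5'->3' in residue order).
#' @return A [backbone_model()].
#' @export
parse_structure <- function(path, chainA, chainB) {
  pdb <- tryCatch(bio3d::read.pdb(path),
                  error = function(e)
                    stop("failed to parse PDB file ", path, ": ",
                         conditionMessage(e)))
  atoms <- pdb$atom
  atoms <- atoms[atoms$alt %in% c("", "A", NA), , drop = FALSE]
  strand <- function(ch) {
    sel <- atoms$chain == ch & atoms$elety == "P"
    if (!any(atoms$chain == ch, na.rm = TRUE))
      stop("chain '", ch, "' not found in ", path)
    sub <- atoms[which(sel), , drop = FALSE]
    if (nrow(sub) == 0L)
      stop("no P atoms on chain '", ch, "' in ", path)
    sub <- sub[order(sub$resno), , drop = FALSE]
    data.frame(res = sub$resno, x = sub$x, y = sub$y, z = sub$z)
  }
  fa <- strand(chainA)
  fb <- strand(chainB)
  nbp <- max(diff(range(fa$res)), diff(range(fb$res))) + 2L
  backbone_model(fa, fb, n_bp = nbp)
}

#' Groove-calculation parameters
#'
#' @param vdw_offset Angstroms subtracted from the raw phosphate
#'   distance: the summed van der Waals extent of the two phosphate
#'   groups (default 5.8).
#' @param stagger Cross-strand search range in bp around each position.
#' @param clamp_at_zero Clamp negative raw widths at zero.
#' @return An object of class `groove_params`.
#' @export
groove_params <- function(vdw_offset = 5.8, stagger = 5,
                          clamp_at_zero = TRUE) {
  if (vdw_offset <= 0) stop("vdw_offset must be > 0")
  structure(list(vdw_offset = vdw_offset, stagger = as.integer(stagger),
                 clamp_at_zero = isTRUE(clamp_at_zero)),
            class = "groove_params")
}

#' Minor groove width from backbone coordinates
#'
#' A geometric minor-groove measure: for each forward-strand phosphate
#' the minimum Euclidean distance to an opposite-strand phosphate whose
#' paired forward coordinate lies within `stagger` bp, minus the 5.8-A
#' van der Waals extent of the two phosphate groups (negative values
#' clamp to zero). Each minimum-distance pair contributes its width to
#' the midpoint nucleotide position (rounding half down); contributions
#' landing on the same position are averaged. This is a deliberately
#' simple stand-in for a full curvilinear-helical-axis groove
#' calculation; the stagger cap suppresses spurious minima at duplex
#' ends.
#'
#' @param model A [backbone_model()].
#' @param params A [groove_params()].
#' @return A [groove_width_profile()] keyed by forward coordinates.
#' @export
minor_groove_width <- function(model, params = groove_params()) {
  fwd <- model$forward; rev <- model$reverse
  if (nrow(fwd) < 2L || nrow(rev) < 2L)
    stop("need at least 2 phosphates per strand")
  nbp <- model$n_bp
  # forward coordinate of each phosphate
  f_res <- fwd$res - min(fwd$res) + 1L
  r_order <- seq_len(nrow(rev))
  r_fwd_coord <- nbp - (rev$res - min(rev$res) + 1L) + 1L
  fx <- as.matrix(fwd[c("x", "y", "z")])
  rx <- as.matrix(rev[c("x", "y", "z")])
  pos_acc <- integer(0); w_acc <- numeric(0)
  for (i in seq_len(nrow(fwd))) {
    cand <- which(abs(r_fwd_coord - f_res[i]) <= params$stagger)
    if (length(cand) == 0L) next
    d2 <- colSums((t(rx[cand, , drop = FALSE]) - fx[i, ])^2)
    j <- cand[which.min(d2)]
    d <- sqrt(min(d2))
    w <- d - params$vdw_offset
    if (params$clamp_at_zero) w <- max(w, 0)
    mid <- floor((f_res[i] + r_fwd_coord[j]) / 2)
    pos_acc <- c(pos_acc, mid)
    w_acc <- c(w_acc, w)
  }
  if (length(pos_acc) == 0L)
    stop("no cross-strand pairs within the stagger range")
  agg <- tapply(w_acc, pos_acc, mean)
  if (params$clamp_at_zero)
    groove_width_profile(as.integer(names(agg)), as.numeric(agg))
  else  # raw widths may be negative when vdW shells interpenetrate
    new_profile(as.integer(names(agg)), as.numeric(agg),
                "groove_width_profile")
}

#' Idealized B-DNA phosphate backbone coordinates
#'
#' Generates synthetic phosphate positions for an ideal straight B-form
#' double helix: two antiparallel strands on a cylinder of radius
#' `radius`, 10.5 bp per turn, 3.38 A rise, with the strands' azimuthal
#' separation set so the minor groove faces between them. Intended for
#' tests and demonstrations, not as a substitute for real coordinates.
#'
#' @param n Number of base pairs.
#' @param radius Helix radius to the phosphates (Angstroms).
#' @param rise Rise per bp (Angstroms).
#' @param twist Twist per bp (degrees).
#' @param groove_phase Azimuthal offset between the strands (degrees);
#'   the default 138 gives an interior minor groove width near the
#'   canonical B-DNA value of ~5.8 Angstroms.
#' @return A [backbone_model()] with `n` phosphates per strand.
#' @export
ideal_backbone <- function(n = 20, radius = 9.4, rise = 3.38,
                           twist = 34.3, groove_phase = 138) {
  i <- seq_len(n)
  th <- (i - 1) * twist * pi / 180
  ph <- groove_phase * pi / 180
  fwd <- data.frame(res = i,
                    x = radius * cos(th),
                    y = radius * sin(th),
                    z = (i - 1) * rise)
  # antiparallel partner strand, listed 5'->3' in its own order
  j <- seq_len(n)
  thr <- (n - j) * twist * pi / 180 + ph
  rev <- data.frame(res = j,
                    x = radius * cos(thr),
                    y = radius * sin(thr),
                    z = (n - j) * rise)
  backbone_model(fwd, rev, n_bp = n)
}
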