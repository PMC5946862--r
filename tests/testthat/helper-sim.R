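# shared fixtures, built in code

random_duplex <- function(n, seed = 1) {
  set.seed(seed)
  duplex_sequence(paste(sample(c("A", "C", "G", "T"), n, TRUE),
                        collapse = ""))
}

# a small standard simulation: duplex, intensities, ladder spanning the
# fragment range
make_sim <- function(seq_len = 80, frag_min = 10, frag_max = 70,
                     ladder_step = 10, noise_add = 0, noise_mult = 0,
                     strand = "forward", seed = 42, seq_seed = 7, ...) {
  seqd <- random_duplex(seq_len, seq_seed)
  set.seed(seq_seed + 1)
  inten <- exp(rnorm(seq_len - 1, log(100), 0.4))
  ladder <- seq(frag_min, frag_max, by = ladder_step)
  if (max(ladder) < frag_max) ladder <- c(ladder, frag_max)
  spec <- sim_spec(seqd, strand = strand, intensity = inten,
                   fragments = frag_min:frag_max, ladder = ladder,
                   noise_add = noise_add, noise_mult = noise_mult,
                   seed = seed, ...)
  list(seq = seqd, spec = spec)
}

# toy straight-strand duplex: two parallel backbones `gap` Angstroms
# apart, residues far apart along z so the cross-strand gap is the
# unique minimum
toy_backbone <- function(n = 8, gap = 11, rise = 7) {
  fwd <- data.frame(res = 1:n, x = 0, y = 0, z = (1:n) * rise)
  rev <- data.frame(res = 1:n, x = gap, y = 0, z = (n:1) * rise)
  backbone_model(fwd, rev, n_bp = n)
}

# write a minimal PDB with P atoms for two chains
write_toy_pdb <- function(model, path, drop_first_P = FALSE) {
  lines <- character(0)
  serial <- 0L
  emit <- function(df, chain, skip_first) {
    for (i in seq_len(nrow(df))) {
      if (skip_first && i == 1L) next
      serial <<- serial + 1L
      lines <<- c(lines, sprintf(
        "ATOM  %5d  P    DA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           P",
        serial, chain, df$res[i], df$x[i], df$y[i], df$z[i]))
    }
  }
  emit(model$forward, "A", drop_first_P)
  emit(model$reverse, "B", FALSE)
  writeLines(c(lines, "END"), path)
  path
}

# brute-force Spearman for untied vectors: 1 - 6*sum(d^2)/(n(n^2-1))
spearman_bruteforce <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}
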