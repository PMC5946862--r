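#' Pipeline configuration
#'
#' Collects the file paths and stage parameters for an end-to-end run.
#' All paths are interpreted at run time; `sites`, `deuterated` traces,
#' a `pdb` structure and a `pentamer_table` are optional stages.
#'
#' @param sequence FASTA path of the duplex.
#' @param forward_trace,reverse_trace Cleavage trace TSVs (one labeled
#'   strand each).
#' @param forward_ladder,reverse_ladder Ladder trace TSVs.
#' @param ladder Numeric vector of ladder fragment lengths.
#' @param fragments Integer vector of expected cleavage fragment
#'   lengths (defaults to the part of `1..L-1` inside the ladder span).
#' @param forward_deuterated,reverse_deuterated Optional deuterated
#'   trace TSVs for adenine calling.
#' @param sites Optional site annotation file (TSV or BED).
#' @param pdb,chains Optional PDB path and length-2 chain IDs for the
#'   groove stage.
#' @param pentamer_table Optional pentamer table TSV for the predicted
#'   groove profile.
#' @param fit A [fit_config()].
#' @param orchid2_offset,orchid2_span,orchid2_evaluation ORChID2 stage
#'   parameters.
#' @param smooth Apply loess smoothing to the ORChID2 profile.
#' @param groove A [groove_params()].
#' @param adenine_threshold Ratio threshold for [call_adenines()].
#' @param seed Integer seed recorded in the manifest.
#' @param out_dir Output directory for the run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sequence, forward_trace, reverse_trace,
                            forward_ladder, reverse_ladder, ladder,
                            fragments = NULL,
                            forward_deuterated = NULL,
                            reverse_deuterated = NULL,
                            sites = NULL, pdb = NULL, chains = c("A", "B"),
                            pentamer_table = NULL,
                            fit = fit_config(),
                            orchid2_offset = -3L, orchid2_span = 0.015,
                            orchid2_evaluation = 300, smooth = TRUE,
                            groove = groove_params(),
                            adenine_threshold = 0.75,
                            seed = 1L, out_dir) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline config from YAML
#'
#' Scalar keys mirror [pipeline_config()] arguments; `fit` and `groove`
#' are nested mappings passed to [fit_config()] and [groove_params()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$fit)) y$fit <- do.call(fit_config, y$fit)
  if (!is.null(y$groove)) y$groove <- do.call(groove_params, y$groove)
  do.call(pipeline_config, y)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full pipeline
#'
#' Executes the stages in order - fit forward, fit reverse, adenine
#' assignment (when deuterated traces are given), ORChID2 averaging and
#' smoothing, groove computation (when a structure or pentamer table is
#' given), and site comparison - writing every intermediate as TSV under
#' `out_dir` plus a JSON manifest recording the config hash, seed and
#' package version. A stage error aborts the run naming the stage;
#' intermediates finished before the failure remain on disk.
#'
#' @param cfg A [pipeline_config()] or path to its YAML file.
#' @return Invisibly, a list of the main in-memory results.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  set.seed(cfg$seed)

  seqd <- run_stage("sequence", read_fasta_duplex(cfg$sequence))
  if (is.null(cfg$fragments)) {
    lad <- sort(cfg$ladder)
    cfg$fragments <- seq.int(max(1L, min(lad)),
                             min(seqd$length - 1L, max(lad)))
  }

  fit_one <- function(strand) {
    trace_path <- cfg[[paste0(strand, "_trace")]]
    ladder_path <- cfg[[paste0(strand, "_ladder")]]
    if (is.null(trace_path) || is.null(ladder_path))
      stop("missing ", strand, " trace/ladder input")
    ps <- fit_channel(read_trace(trace_path),
                      read_trace(ladder_path, channel = "ladder"),
                      cfg$ladder, cfg$fragments, cfg$fit)
    write_peak_set(ps, out(paste0("peaks_", strand, ".tsv")))
    ps
  }
  ps_fwd <- run_stage("fit_forward", fit_one("forward"))
  ps_rev <- run_stage("fit_reverse", fit_one("reverse"))

  for (strand in c("forward", "reverse")) {
    dpath <- cfg[[paste0(strand, "_deuterated")]]
    if (is.null(dpath)) next
    run_stage(paste0("assign_", strand), {
      ps <- if (strand == "forward") ps_fwd else ps_rev
      dtrace <- read_trace(dpath)
      lpath <- cfg[[paste0(strand, "_ladder")]]
      dps <- fit_channel(dtrace, read_trace(lpath, channel = "ladder"),
                         cfg$ladder, cfg$fragments, cfg$fit)
      calls <- call_adenines(ps, dps, cfg$adenine_threshold)
      lab <- map_sequence(calls, seqd, strand)
      utils::write.table(lab, out(paste0("assign_", strand, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }

  orch <- run_stage("orchid2", {
    pf <- peaks_to_profile(ps_fwd, "forward", seqd)
    pr <- peaks_to_profile(ps_rev, "reverse", seqd)
    write_profile(pf, out("cleavage_forward.tsv"))
    write_profile(pr, out("cleavage_reverse.tsv"))
    o <- exp_orchid2(pf, pr, cfg$orchid2_offset)
    write_profile(o, out("orchid2_raw.tsv"))
    if (isTRUE(cfg$smooth)) {
      o <- loess_smooth_profile(o, cfg$orchid2_span,
                                cfg$orchid2_evaluation)
      write_profile(o, out("orchid2_smoothed.tsv"))
    }
    o
  })

  groove_prof <- NULL
  if (!is.null(cfg$pdb)) {
    groove_prof <- run_stage("groove", {
      model <- parse_structure(cfg$pdb, cfg$chains[1L], cfg$chains[2L])
      g <- minor_groove_width(model, cfg$groove)
      write_profile(g, out("groove_xray.tsv"))
      g
    })
  }
  pred_prof <- NULL
  if (!is.null(cfg$pentamer_table)) {
    pred_prof <- run_stage("pentamer", {
      tab <- read_pentamer_table(cfg$pentamer_table)
      g <- predict_pentamer_mgw(seqd, tab)
      write_profile(g, out("groove_pentamer.tsv"))
      g
    })
  }

  comparison <- NULL
  ref <- if (!is.null(groove_prof)) groove_prof else pred_prof
  if (!is.null(cfg$sites) && !is.null(ref)) {
    comparison <- run_stage("compare", {
      sites <- read_sites(cfg$sites, seqd$length)
      tab <- compare_sites(orch, ref, sites)
      write_comparison(tab, out("comparison.tsv"))
      tab
    })
  }

  manifest <- list(
    package = "grooveprint",
    version = as.character(utils::packageVersion("grooveprint")),
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(write_manifest_config(cfg))),
    outputs = list.files(cfg$out_dir))
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(peaks_forward = ps_fwd, peaks_reverse = ps_rev,
                 orchid2 = orch, groove = groove_prof,
                 predicted = pred_prof, comparison = comparison))
}

# serialize the config deterministically for hashing, next to outputs
write_manifest_config <- function(cfg) {
  p <- file.path(cfg$out_dir, "config_used.yaml")
  flat <- lapply(unclass(cfg), function(v)
    if (inherits(v, c("fit_config", "groove_params"))) unclass(v) else v)
  yaml::write_yaml(flat[order(names(flat))], p)
  p
}
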