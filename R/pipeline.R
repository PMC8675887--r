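#' Pipeline configuration
#'
#' Exactly one input source must be given: a simulation [design_spec()],
#' or paths to a transient table and a metadata table.
#'
#' @param out_dir Output directory (created if needed).
#' @param design Optional [design_spec()] for simulated input.
#' @param transients_path,metadata_path Optional input file paths.
#' @param layout,time_unit Passed to [read_transients()] for file input.
#' @param conventions A [jip_conventions()].
#' @param contrasts Contrast data frame or `NULL` for [default_contrasts()].
#' @param adjust_family `"per_parameter"` or `"global"` BH scope.
#' @param cap A [cap_config()]; its seed is overridden by `seed`.
#' @param seed Integer master seed, recorded in every artifact.
#' @param make_plot Write a CAP ordination PNG (default `FALSE`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, design = NULL, transients_path = NULL,
                            metadata_path = NULL, layout = "long",
                            time_unit = "s",
                            conventions = jip_conventions(),
                            contrasts = NULL,
                            adjust_family = "per_parameter",
                            cap = cap_config(), seed = 1L,
                            make_plot = FALSE) {
  has_files <- !is.null(transients_path) || !is.null(metadata_path)
  if (!is.null(design) && has_files)
    stop("config must set exactly one of: design, input paths (both given)")
  if (is.null(design) && !(is.character(transients_path) && is.character(metadata_path)))
    stop("config must set exactly one of: design, input paths (neither given)")
  structure(list(out_dir = out_dir, design = design,
                 transients_path = transients_path,
                 metadata_path = metadata_path, layout = layout,
                 time_unit = time_unit, conventions = conventions,
                 contrasts = contrasts, adjust_family = adjust_family,
                 cap = cap, seed = as.integer(seed), make_plot = make_plot),
            class = "pipeline_config")
}

#' Run the full OJIP analysis pipeline
#'
#' Executes ingest (or simulation), batch JIP parameter derivation,
#' pairwise rank-sum statistics with BH correction, and CAP
#' classification, writing `parameters.tsv`, `stats.tsv`,
#' `cap_scores.tsv`, `cap_confusion.tsv`, `cap_summary.json` and a
#' `manifest.json` (seed, config echo, rejects and skipped contrasts)
#' under `cfg$out_dir`. Degenerate samples and skipped contrasts are
#' warnings recorded in the manifest, never silent drops; stage failures
#' abort with the stage named.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a run summary list.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(cfg$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  sim <- NULL
  if (!is.null(cfg$design)) {
    design <- cfg$design
    design$seed <- cfg$seed
    sim <- stage("simulate", simulate_experiment(design))
    transients <- sim$transients
    metadata <- sim$metadata
    stage("simulate", {
      write_transients(transients, path("transients.tsv"))
      write_table(metadata, path("metadata.tsv"))
      write_table(sim$truth, path("truth.tsv"))
    })
  } else {
    transients <- stage("ingest",
                        read_transients(cfg$transients_path, layout = cfg$layout,
                                        time_unit = cfg$time_unit))
    metadata <- stage("ingest", read_metadata(cfg$metadata_path))
  }
  unmatched <- setdiff(names(transients), metadata$sample_id)
  if (length(unmatched))
    warning(sprintf("transients without metadata: %s",
                    paste(unmatched, collapse = ", ")))

  jip <- stage("analyze", analyze_transients(transients, cfg$conventions))
  if (nrow(jip$rejects))
    warning(sprintf("%d sample(s) rejected during JIP analysis", nrow(jip$rejects)))
  stage("analyze", write_table(jip$parameters, path("parameters.tsv")))

  tests <- stage("stats",
                 pairwise_parameter_tests(jip$parameters, metadata,
                                          contrasts = cfg$contrasts,
                                          family = cfg$adjust_family))
  if (nrow(tests$skipped))
    warning(sprintf("%d contrast(s) skipped", nrow(tests$skipped)))
  stage("stats", write_table(tests$results, path("stats.tsv")))

  cap_res <- stage("cap", {
    merged <- merge(jip$parameters, metadata, by = "sample_id")
    X <- as.matrix(merged[jip_parameter_names()])
    rownames(X) <- merged$sample_id
    groups <- .group_key(merged$population, merged$season, merged$period)
    cap_cfg <- cfg$cap
    cap_cfg$seed <- cfg$seed
    cap_fit(X, groups, cap_cfg)
  })
  stage("cap", {
    scores <- data.frame(sample_id = rownames(cap_res$canonical_scores),
                         cap_res$canonical_scores, stringsAsFactors = FALSE)
    write_table(scores, path("cap_scores.tsv"))
    conf <- as.data.frame(cap_res$allocation, stringsAsFactors = FALSE)
    write_table(conf, path("cap_confusion.tsv"))
    jsonlite::write_json(list(
      m_used = cap_res$m_used,
      n_correct = cap_res$n_correct,
      n_samples = length(cap_res$groups),
      trace_statistic = cap_res$trace_statistic,
      p_perm = cap_res$p_perm,
      n_permutations = cap_res$cfg$n_permutations,
      seed = cfg$seed),
      path("cap_summary.json"), auto_unbox = TRUE, digits = NA)
    if (cfg$make_plot) plot_cap(cap_res, path("cap_ordination.png"))
  })

  manifest <- list(
    package = "ojipcap",
    version = as.character(utils::packageVersion("ojipcap")),
    seed = cfg$seed,
    input = if (is.null(cfg$design)) list(mode = "files",
                                          transients = cfg$transients_path,
                                          metadata = cfg$metadata_path)
            else list(mode = "simulation",
                      n_cells = length(cfg$design$cells),
                      noise_sd = cfg$design$noise_sd,
                      sampling = cfg$design$sampling[c("t_min", "t_max", "points")]),
    conventions = unclass(cfg$conventions),
    adjust_family = cfg$adjust_family,
    cap = unclass(cfg$cap),
    n_samples = length(transients),
    rejects = jip$rejects,
    skipped_contrasts = tests$skipped)
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")

  invisible(list(parameters = jip$parameters, rejects = jip$rejects,
                 stats = tests$results, skipped = tests$skipped,
                 cap = cap_res, manifest = manifest,
                 out_dir = cfg$out_dir))
}
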