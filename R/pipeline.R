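#' Configuration of the end-to-end analysis pipeline
#'
#' Collects everything one reproducible run needs: the master seed, the
#' track analysis window and binning, the genotype classes to simulate,
#' and the test settings.  The whole object is serializable; a run echoes
#' its config into the output directory so the run can be re-executed to
#' identical outputs.
#'
#' @param seed Master integer seed; every generator seed is derived from
#'   it.
#' @param window_min Length-2 numeric, analysis window in minutes for the
#'   complete-track filter (default `c(0, 360)`, the 6 h window).
#' @param n_bins Angular bins for the deviation-angle histograms.
#' @param track_classes List of [simulation_config()] argument lists (the
#'   `seed` entry is filled in from the master seed).  The default pair
#'   emulates the wild-type vs fgf8a contrast: equal speeds, directional
#'   bias present only in the wild type.
#' @param n_cells Cells per track class (used by the default classes).
#' @param phenotype_classes Character vector of shipped genotype classes
#'   to simulate and score.
#' @param n_embryos Embryos per phenotype class.
#' @param timeline_classes Timeline classes to tabulate.
#' @param timeline_start_hpf,timeline_window_h Timeline observation
#'   window (default 26 hpf + 10 h, the span of the recordings).
#' @param welch_tail Tail for the velocity/persistence Welch tests, with
#'   the first-listed track class as `sample_a`.  The default
#'   `one_tailed_less` encodes the directional hypothesis that the mutant
#'   class (listed second) exceeds... the first class is the mutant; see
#'   Details.
#' @param alpha Significance level echoed into the report.
#' @details In the default class list the mutant-like class
#'   (`fgf8a_mut`, zero bias) is listed first, so `one_tailed_less` tests
#'   mutant < wild type for velocity and persistence.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            window_min = c(0, 360),
                            n_bins = 8L,
                            track_classes = NULL,
                            n_cells = 30L,
                            phenotype_classes = c("wild_type", "tbx1",
                                                  "single_mutant",
                                                  "double_mutant"),
                            n_embryos = 25L,
                            timeline_classes = c("wild_type", "tbx1"),
                            timeline_start_hpf = 26,
                            timeline_window_h = 10,
                            welch_tail = "one_tailed_less",
                            alpha = 0.05) {
  check_scalar_number(seed, "seed")
  if (length(window_min) != 2L || window_min[2] <= window_min[1]) {
    config_error("window_min", "must be an increasing pair of minutes")
  }
  check_scalar_number(n_bins, "n_bins", lower = 2)
  check_scalar_number(n_embryos, "n_embryos", lower = 1)
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  welch_tail <- match_tail(welch_tail)
  if (is.null(track_classes)) {
    track_classes <- list(
      list(class_name = "fgf8a_mut", n_cells = n_cells, kappa_bias = 0,
           kappa_persist = 1, dropout_prob = 0.2),
      list(class_name = "wild_type", n_cells = n_cells, kappa_bias = 5,
           kappa_persist = 1, dropout_prob = 0.2)
    )
  }
  structure(
    list(seed = as.integer(seed), window_min = window_min,
         n_bins = as.integer(n_bins), track_classes = track_classes,
         phenotype_classes = phenotype_classes,
         n_embryos = as.integer(n_embryos),
         timeline_classes = timeline_classes,
         timeline_start_hpf = timeline_start_hpf,
         timeline_window_h = timeline_window_h,
         welch_tail = welch_tail, alpha = alpha),
    class = "pipeline_config"
  )
}

#' Run the full generation -> metrics -> statistics -> scoring pipeline
#'
#' Simulates tracks and phenotype records for the configured genotype
#' classes, applies the complete-track filter and computes per-track
#' metrics, compares the first two track classes (Welch tests on velocity
#' and persistence, chi-square on the pooled angle histograms), scores
#' the phenotype records and runs Tukey-Kramer across genotypes, draws a
#' marker-contribution table and tests it with Fisher's exact test, and
#' tabulates pouch-formation timelines.  All outputs plus a manifest
#' (config echo, file hashes, package version) are written under
#' `output_dir`; runs are idempotent under a fixed seed.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Directory to create/write into.
#' @return The run report, invisibly (also written as `report.json`).
#' @export
run_pipeline <- function(config, output_dir) {
  if (!inherits(config, "pipeline_config")) {
    config_error("config", "must be created by pipeline_config()")
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir)) {
    input_error(sprintf("cannot create output directory '%s'", output_dir))
  }
  probe <- file.path(output_dir, ".write_probe")
  ok <- tryCatch({ file.create(probe, showWarnings = FALSE) }, error = function(e) FALSE)
  if (!isTRUE(ok)) input_error(sprintf("output directory '%s' is not writable", output_dir))
  unlink(probe)

  # --- tracks ---------------------------------------------------------
  tracks <- do.call(rbind, lapply(seq_along(config$track_classes), function(i) {
    args <- config$track_classes[[i]]
    args$seed <- config$seed * 101L + i
    simulate_tracks(do.call(simulation_config, args))
  }))
  kept <- filter_complete_tracks(tracks, config$window_min[1],
                                 config$window_min[2])
  metrics <- track_metrics(kept)
  group_summary <- summarize_group_metrics(metrics)
  angle_tab <- deviation_angle_table(kept)
  groups <- vapply(config$track_classes, function(x) x$class_name, character(1))
  hists <- lapply(groups, function(g) {
    bin_angles(angle_tab$angle_deg[angle_tab$group == g], config$n_bins,
               group = g)
  })
  names(hists) <- groups
  metric_tests <- list(
    velocity = welch_t_one_tailed(
      metrics$velocity_um_per_min[metrics$group == groups[1]],
      metrics$velocity_um_per_min[metrics$group == groups[2]],
      config$welch_tail),
    persistence = welch_t_one_tailed(
      stats::na.omit(metrics$persistence[metrics$group == groups[1]]),
      stats::na.omit(metrics$persistence[metrics$group == groups[2]]),
      config$welch_tail),
    angle_distribution = compare_angle_distributions(hists[[1]], hists[[2]])
  )

  # --- phenotypes -----------------------------------------------------
  phenos <- do.call(rbind, lapply(seq_along(config$phenotype_classes), function(i) {
    cls <- phenotype_class(config$phenotype_classes[i],
                           seed = config$seed * 211L + i)
    simulate_phenotypes(cls, config$n_embryos, sides = c("left", "right"))
  }))
  scores <- score_phenotypes(phenos)
  score_summary <- summarize_scores(phenos)
  per_embryo <- stats::aggregate(
    cbind(pouch_score, cb_score) ~ embryo_id + genotype, data = scores,
    FUN = mean)
  tukey <- list(
    pouch_score = tukey_kramer(split(per_embryo$pouch_score, per_embryo$genotype)),
    cb_score = tukey_kramer(split(per_embryo$cb_score, per_embryo$genotype))
  )

  # --- contribution table ---------------------------------------------
  contrib <- simulate_contribution_table(60, 60, 0.7, 0.3,
                                         seed = config$seed * 307L + 1L)
  fisher <- fisher_exact(contrib, "two_tailed")

  # --- timelines ------------------------------------------------------
  timelines <- lapply(config$timeline_classes, function(cls) {
    simulate_pouch_timeline(cls, config$timeline_start_hpf,
                            config$timeline_window_h)
  })
  names(timelines) <- config$timeline_classes
  timeline_df <- do.call(rbind, lapply(config$timeline_classes, function(cls) {
    tl <- timelines[[cls]]
    if (nrow(tl) == 0) return(NULL)
    cbind(class_name = cls, tl)
  }))
  if (is.null(timeline_df)) {
    timeline_df <- data.frame(class_name = character(0),
                              pouch_index = integer(0),
                              formation_time_hpf = numeric(0))
  }

  # --- write ----------------------------------------------------------
  write_tracks(tracks, file.path(output_dir, "tracks.csv"))
  metrics_flat <- metrics[, setdiff(names(metrics), "deviation_angles_deg")]
  utils::write.csv(metrics_flat, file.path(output_dir, "track_metrics.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(group_summary, file.path(output_dir, "group_metric_summary.csv"),
                   row.names = FALSE)
  write_phenotypes(phenos, file.path(output_dir, "phenotypes.csv"))
  utils::write.csv(scores, file.path(output_dir, "phenotype_scores.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(score_summary, file.path(output_dir, "score_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(timeline_df, file.path(output_dir, "timelines.csv"),
                   row.names = FALSE, quote = FALSE)

  report <- list(
    seed = config$seed,
    n_tracks = list(generated = length(unique(tracks$track_id)),
                    analyzed = length(unique(kept$track_id)),
                    dropped_by_filter = attr(kept, "n_dropped")),
    group_metric_summary = group_summary,
    metric_tests = lapply(metric_tests, unclass),
    angle_histograms = lapply(hists, unclass),
    tukey_kramer = lapply(tukey, function(x) as.data.frame(x)),
    score_summary = score_summary,
    contribution_table = list(counts = unname(contrib),
                              fisher = unclass(fisher)),
    timeline_event_counts = vapply(timelines, nrow, integer(1)),
    alpha = config$alpha
  )
  jsonlite::write_json(report, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  jsonlite::write_json(unclass(config), file.path(output_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  files <- setdiff(list.files(output_dir), "manifest.json")
  manifest <- list(
    package = "pouchtrack",
    version = as.character(utils::packageVersion("pouchtrack")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(file.path(output_dir, "config.json"))),
    files = lapply(stats::setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(file.path(output_dir, f))))
    })
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}
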