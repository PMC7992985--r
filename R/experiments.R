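#' Run all replications of one scenario
#'
#' Runs `replications` independent replications (seeds `base_seed`,
#' `base_seed + 1`, ...) and returns the per-replication indicator table.
#' Different scenarios run with the same `base_seed` share seeds and hence
#' demand streams (common random numbers), which sharpens paired policy
#' contrasts.
#'
#' @param scenario a [scenario_config()].
#' @param calib a [calibration()].
#' @param mss an MSS.
#' @param replications,horizon_weeks,warmup_weeks,base_seed overrides of the
#'   scenario's experiment sizes.
#' @return data.frame of [compute_kpis()] rows with `scenario`, `rep` and
#'   `seed` columns.
#' @export
run_scenario <- function(scenario, calib = default_calibration(),
                         mss = default_mss(),
                         replications = scenario$replications,
                         horizon_weeks = scenario$horizon_weeks,
                         warmup_weeks = scenario$warmup_weeks,
                         base_seed = scenario$base_seed) {
  rows <- lapply(seq_len(replications), function(i) {
    rep_ <- run_replication(scenario, calib, mss,
                            horizon_weeks = horizon_weeks,
                            warmup_weeks = warmup_weeks,
                            seed = base_seed + i - 1L)
    k <- compute_kpis(rep_)
    k$scenario <- scenario$label
    k$rep <- i
    k$seed <- base_seed + i - 1L
    k
  })
  do.call(rbind, rows)
}

#' Run a batch of scenario experiments
#'
#' End-to-end batch runner: validates a configuration, runs every scenario
#' with seeded replications under common random numbers, and writes
#' machine-readable result tables - per-replication indicators, 95%
#' confidence intervals per scenario, pairwise interval-overlap flags
#' against the first scenario, and a run manifest.
#'
#' @param config either a path to a YAML/JSON configuration file or a named
#'   list. Recognized top-level fields: `scenarios` (list of
#'   [scenario_config()] argument lists, or the string `"presets"`),
#'   `replications`, `horizon_weeks`, `warmup_weeks`, `base_seed`, and
#'   `mss_file` (CSV path).
#' @param out_dir output directory, created when missing.
#' @param calib a [calibration()].
#' @return invisibly, a list with `kpis`, `ci`, `overlap`, `manifest`.
#' @export
run_experiments <- function(config = list(scenarios = "presets"),
                            out_dir = "orsim-results",
                            calib = default_calibration()) {
  if (is.character(config) && length(config) == 1) {
    config <- read_config(config)
  }
  stopifnot(is.list(config))
  common <- config[intersect(names(config),
                             c("replications", "horizon_weeks",
                               "warmup_weeks", "base_seed"))]
  mss <- if (!is.null(config$mss_file)) read_mss(config$mss_file)
         else default_mss()
  scen_spec <- config$scenarios %||% "presets"
  scenarios <- if (identical(scen_spec, "presets")) {
    do.call(preset_experiments, common)
  } else {
    lapply(scen_spec, function(s) do.call(scenario_config,
                                          modifyList(common, s)))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  kpis <- do.call(rbind, lapply(scenarios, run_scenario,
                                calib = calib, mss = mss))
  ci <- do.call(rbind, lapply(split(kpis, kpis$scenario), function(df) {
    out <- aggregate_replications(df)
    out$scenario <- df$scenario[1]
    out
  }))
  rownames(ci) <- NULL

  # interval-overlap flags of every scenario against the first (reference)
  ref_label <- scenarios[[1]]$label
  overlap <- do.call(rbind, lapply(unique(ci$scenario), function(sc) {
    if (sc == ref_label) return(NULL)
    a <- ci[ci$scenario == sc, ]
    b <- ci[ci$scenario == ref_label, ]
    data.frame(scenario = sc, reference = ref_label, kpi = a$kpi,
               overlap = mapply(function(i, j) ci_overlap(a[i, ], b[j, ]),
                                seq_len(nrow(a)), match(a$kpi, b$kpi)))
  }))

  manifest <- list(
    package_version = as.character(utils::packageVersion("orsim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    scenarios = lapply(scenarios, function(s) unclass(s)),
    seeds = lapply(scenarios, function(s)
      s$base_seed + seq_len(s$replications) - 1L))

  write.csv(kpis, file.path(out_dir, "replication_kpis.csv"),
            row.names = FALSE)
  write.csv(ci, file.path(out_dir, "scenario_ci.csv"), row.names = FALSE)
  if (!is.null(overlap)) {
    write.csv(overlap, file.path(out_dir, "ci_overlap.csv"),
              row.names = FALSE)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(
    split(ci[c("kpi", "mean", "half_width", "lower", "upper")], ci$scenario),
    file.path(out_dir, "scenario_ci.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(kpis = kpis, ci = ci, overlap = overlap,
                 manifest = manifest))
}

read_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}
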