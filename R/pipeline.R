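#' Read a pipeline configuration file
#'
#' YAML with sections `paths` (catalog, children, visits, reports,
#' out_dir), `episode_params`, `rates` (bin_months, split_febrile),
#' `model` (factors) and `sim` (passed to [sim_config()]).  Missing
#' entries fall back to package defaults; an annotated example ships in
#' `inst/extdata/example_config.yaml`.
#'
#' @param path YAML file path.
#' @return Named list of configuration sections.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop_input("config file not found: ", path, class = "usage_error")
  }
  cfg <- yaml::read_yaml(path)
  cfg$paths <- cfg$paths %||% list()
  cfg$paths$out_dir <- cfg$paths$out_dir %||% "episodizer-out"
  cfg$episode_params <- cfg$episode_params %||% list()
  cfg$rates <- cfg$rates %||% list()
  cfg$model <- cfg$model %||% list()
  cfg$sim <- cfg$sim %||% list()
  cfg
}

pipeline_params <- function(cfg) {
  do.call(episode_params, cfg$episode_params)
}

pipeline_catalog <- function(cfg) {
  load_catalog(cfg$paths$catalog)
}

write_manifest <- function(out_dir, cfg_path, seed, counts) {
  manifest <- list(
    package_version = as.character(utils::packageVersion("episodizer")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_file = cfg_path,
    config_md5 = if (!is.null(cfg_path) && file.exists(cfg_path)) {
      unname(tools::md5sum(cfg_path))
    } else NA,
    seed = seed,
    row_counts = counts,
    written_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the report-to-rates pipeline
#'
#' Commands: `simulate` writes a synthetic cohort (children.csv,
#' visits.csv, reports.csv, truth.csv); `episodes` reads roster + reports,
#' applies the eligibility filter, builds episodes and writes episodes.csv
#' and summary.csv; `rates` writes rates.csv (age, season) and
#' percent_reporting.csv; `model` writes model_result.csv with the
#' all / febrile / nonfebrile panels; `all` chains everything.  A
#' manifest.json (package version, config hash, seed, row counts) is
#' always written, and every filtering step is logged with its count.
#'
#' @param command One of `"simulate"`, `"episodes"`, `"rates"`, `"model"`,
#'   `"all"`.
#' @param config Path to a YAML config file or a list from
#'   [read_pipeline_config()].
#' @param seed Optional integer overriding the config's sim seed.
#' @param out_dir Optional output directory override.
#' @param quiet Suppress progress logging?
#' @return Invisible named list of written file paths.
#' @export
run_pipeline <- function(command = c("all", "simulate", "episodes",
                                     "rates", "model"),
                         config, seed = NULL, out_dir = NULL,
                         quiet = FALSE) {
  command <- match.arg(command)
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    config <- read_pipeline_config(config)
  }
  out_dir <- out_dir %||% config$paths$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) if (!quiet) message("[episodizer] ", ...)
  written <- list()
  counts <- list()

  path_of <- function(name, default) {
    config$paths[[name]] %||% file.path(out_dir, default)
  }

  if (command %in% c("simulate", "all")) {
    sim_args <- config$sim
    if (!is.null(seed)) sim_args$seed <- seed
    if (is.null(sim_args$seed)) {
      stop_input("simulate: a seed is required (config sim.seed or --seed)",
                 class = "usage_error")
    }
    scfg <- do.call(sim_config, sim_args)
    sim <- simulate_cohort(scfg, pipeline_catalog(config))
    for (nm in c("children", "visits", "reports", "truth")) {
      f <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(sim[[nm]], f, row.names = FALSE)
      written[[nm]] <- f
      counts[[nm]] <- nrow(sim[[nm]])
    }
    log_msg("simulated ", nrow(sim$children), " children, ",
            nrow(sim$reports), " reports, ", nrow(sim$truth),
            " true episodes")
    config$paths$children <- written$children
    config$paths$visits <- written$visits
    config$paths$reports <- written$reports
  }

  if (command %in% c("episodes", "all")) {
    for (nm in c("children", "reports")) {
      if (is.null(config$paths[[nm]])) {
        stop_input("episodes: config paths.", nm, " is required",
                   class = "usage_error")
      }
    }
    children <- read_children(config$paths$children)
    if (!is.null(config$paths$visits)) {
      visits <- read_visits(config$paths$visits)
      filt <- apply_cohort_filter(children, visits)
      log_msg("eligibility filter: ", nrow(filt$children), " of ",
              nrow(children), " children retained (",
              nrow(filt$exclusions), " excluded)")
      children <- filt$children
      counts$excluded_children <- nrow(filt$exclusions)
    }
    reports <- read_reports(config$paths$reports)
    catalog <- pipeline_catalog(config)
    ext <- extract_infection_reports(reports, catalog)
    log_msg("dropped ", ext$n_dropped_chronic, " chronic and ",
            ext$n_dropped_noninfectious, " non-infectious reports; ",
            nrow(ext$classified), " infection reports retained")
    built <- build_episodes(ext$classified, children,
                            pipeline_params(config))
    log_msg(built$summary$n_code_reports, " code reports reduced to ",
            built$summary$n_episodes, " episodes (",
            built$n_dropped_fevers, " unattachable fevers dropped)")
    f <- file.path(out_dir, "episodes.csv")
    write_episodes(built$episodes, f)
    written$episodes <- f
    counts$episodes <- nrow(built$episodes)
    counts$dropped_chronic <- ext$n_dropped_chronic
    counts$dropped_noninfectious <- ext$n_dropped_noninfectious
    counts$dropped_fevers <- built$n_dropped_fevers
    s <- built$summary$per_class
    s$codes_per_episode <- built$summary$codes_per_episode
    f <- file.path(out_dir, "summary.csv")
    utils::write.csv(s, f, row.names = FALSE)
    written$summary <- f
    config$paths$episodes <- written$episodes
  }

  if (command %in% c("rates", "model", "all")) {
    # a prior `episodes` run in the same out_dir is the default source
    default_eps <- file.path(out_dir, "episodes.csv")
    if (is.null(config$paths$episodes) && file.exists(default_eps)) {
      config$paths$episodes <- default_eps
    }
    for (nm in c("children", "episodes")) {
      if (is.null(config$paths[[nm]])) {
        stop_input(command, ": config paths.", nm, " is required",
                   class = "usage_error")
      }
    }
    children <- read_children(config$paths$children)
    episodes <- read_episodes(config$paths$episodes)
  }

  if (command %in% c("rates", "all")) {
    bin <- config$rates$bin_months %||% 3L
    split_feb <- isTRUE(config$rates$split_febrile %||% TRUE)
    age <- episode_rates(episodes, children, "age_bin",
                         split_febrile = split_feb, bin_months = bin)
    age$stratification <- "age_bin"
    seas <- episode_rates(episodes, children, "season",
                          split_febrile = split_feb)
    seas$stratification <- "season"
    f <- file.path(out_dir, "rates.csv")
    write_rates(rbind(age, seas), f)
    written$rates <- f
    f <- file.path(out_dir, "percent_reporting.csv")
    utils::write.csv(percent_reporting(episodes, children, bin), f,
                     row.names = FALSE)
    written$percent_reporting <- f
    log_msg("wrote rate tables for ", nrow(episodes), " episodes")
  }

  if (command %in% c("model", "all")) {
    factors <- config$model$factors %||% c("site", "sex", "fdr",
                                           "hla_group")
    panels <- lapply(c("all", "febrile", "nonfebrile"), function(flt) {
      frame <- aggregate_model_frame(episodes, children, flt)
      tab <- rate_model_table(fit_poisson_rate_model(frame, factors))
      cbind(panel = flt, tab)
    })
    f <- file.path(out_dir, "model_result.csv")
    out <- do.call(rbind, panels)
    for (col in c("rate_ratio", "ci_low", "ci_high", "wald_chi_square",
                  "p_value")) {
      out[[col]] <- signif(out[[col]], 6)
    }
    utils::write.csv(out, f, row.names = FALSE)
    written$model_result <- f
    log_msg("wrote rate-ratio panels for factors: ",
            paste(factors, collapse = ", "))
  }

  write_manifest(out_dir, cfg_path, seed, counts)
  written$manifest <- file.path(out_dir, "manifest.json")
  invisible(written)
}
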