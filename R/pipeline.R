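# Pipeline plumbing: a structured run configuration (YAML), stage execution
# (simulate / metrics / pathways / abundances / network) and a reproducible
# machine-readable report.

PIPELINE_STAGES <- c("simulate", "metrics", "pathways", "simulate-abundances",
                     "network")

read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config),
                                   call. = FALSE)
    cfg <- yaml::read_yaml(config)
    cfg$config_hash <- unname(tools::md5sum(config))
  } else if (is.list(config)) {
    cfg <- config
    tmp <- tempfile(fileext = ".yaml")
    yaml::write_yaml(cfg, tmp)
    cfg$config_hash <- unname(tools::md5sum(tmp))
    unlink(tmp)
  } else {
    stop("config must be a file path or a list", call. = FALSE)
  }
  if (is.null(cfg$stages) || !length(cfg$stages)) {
    stop("config must select at least one stage", call. = FALSE)
  }
  bad <- setdiff(cfg$stages, PIPELINE_STAGES)
  if (length(bad)) {
    stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$out_dir)) cfg$out_dir <- "pcbdechlor-out"
  cfg
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in order and writes their outputs plus a
#' machine-readable JSON report into `out_dir`. Stages:
#' \describe{
#'   \item{simulate}{kinetic congener time course ([simulate_dechlor()]);
#'     writes `timecourse.csv`.}
#'   \item{metrics}{dechlorination metrics per window
#'     ([dechlor_metrics()]) on the simulated or an input time course;
#'     writes `metrics.csv`.}
#'   \item{pathways}{reachability of target congeners from parent congeners
#'     over the allowed positions ([reachable()]); writes `reachability.csv`
#'     and the reaction network edge list.}
#'   \item{simulate-abundances}{synthetic abundance table
#'     ([simulate_abundances()]); writes `abundances.csv`.}
#'   \item{network}{co-occurrence network ([build_cooccurrence()]); writes
#'     edge list, GraphML and topology metrics.}
#' }
#' All randomness flows from the single top-level `seed`. The report carries
#' the package version, seed and a hash of the configuration; a log file
#' records the run.
#'
#' @param config path to a YAML configuration file, or an equivalent list.
#'   Top-level keys: `stages` (required), `seed`, `out_dir`, and one optional
#'   section per stage (`simulate`, `metrics`, `pathways`, `abundances`,
#'   `network`).
#' @return The run report, invisibly (also written as `report.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package = "pcbdechlor",
                 version = as.character(utils::packageVersion("pcbdechlor")),
                 seed = cfg$seed, config_hash = cfg$config_hash,
                 stages = cfg$stages)
  log_lines <- c(sprintf("pcbdechlor %s", report$version),
                 sprintf("seed: %s", cfg$seed),
                 sprintf("config hash: %s", cfg$config_hash))
  tc <- NULL

  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  for (stage in cfg$stages) {
    log_lines <- c(log_lines, sprintf("running stage: %s", stage))
    if (stage == "simulate") {
      run_stage(stage, function() {
        s <- cfg$simulate
        sp <- simulation_spec(
          target_avg_cl = s$target_avg_cl %||% 6.34,
          base_rates = unlist(s$base_rates %||%
                                list(ortho = 0, meta = 0.01, para = 0.002)),
          process_multipliers = unlist(s$process_multipliers),
          lag = s$lag %||% 15,
          times = unlist(s$times %||% c(0, 15, 21, 45, 112)),
          sigma = s$sigma %||% 0,
          detection_limit = s$detection_limit %||% 0.05,
          mass_conc_mg_l = s$mass_conc_mg_l %||% 25,
          seed = cfg$seed)
        tc <<- simulate_dechlor(sp)
        write_congener_csv(tc, file.path(cfg$out_dir, "timecourse.csv"))
        report$simulate <<- list(
          times = tc$times,
          avg_cl = vapply(tc$profiles, average_chlorine, numeric(1)),
          chloride_released = ledger_chloride(tc, max(tc$times)))
      })
    } else if (stage == "metrics") {
      run_stage(stage, function() {
        mcfg <- cfg$metrics
        courses <- if (!is.null(mcfg$input)) {
          read_congener_csv(mcfg$input,
                            mass_conc_mg_l = mcfg$mass_conc_mg_l %||% 25)
        } else if (!is.null(tc)) list(sim = tc) else {
          stop("metrics stage needs an input CSV or a prior simulate stage")
        }
        windows <- lapply(mcfg$windows, unlist)
        if (!length(windows)) windows <- NULL
        met <- do.call(rbind, lapply(courses, dechlor_metrics,
                                     windows = windows))
        rownames(met) <- NULL
        utils::write.csv(met, file.path(cfg$out_dir, "metrics.csv"),
                         row.names = FALSE)
        report$metrics <<- met
      })
    } else if (stage == "pathways") {
      run_stage(stage, function() {
        pcfg <- cfg$pathways
        allowed <- unlist(pcfg$positions %||% c("meta", "para"))
        rules <- if (!is.null(pcfg$rules)) read_process_rules(pcfg$rules) else
          default_process_rules()
        net <- build_network(allowed, rules = rules)
        export_network(net, csv = file.path(cfg$out_dir, "reactions.csv"))
        parents <- unlist(pcfg$parents %||%
                            c(101, 110, 138, 149, 153, 158, 174, 180, 187))
        targets <- unlist(pcfg$targets %||% c(47, 49, 51, 53))
        reach <- do.call(rbind, lapply(parents, reachable, targets = targets,
                                       network = net))
        utils::write.csv(reach, file.path(cfg$out_dir, "reachability.csv"),
                         row.names = FALSE)
        report$pathways <<- reach
      })
    } else if (stage == "simulate-abundances") {
      run_stage(stage, function() {
        acfg <- cfg$abundances
        sp <- abundance_spec(
          n_per_group = acfg$n_per_group %||% 3,
          groups = unlist(acfg$groups %||% c("Bla", "HM", "HA", "AQDS")),
          n_taxa = acfg$n_taxa %||% 50,
          log_mean_sd = acfg$log_mean_sd %||% 1,
          log_sigma = acfg$log_sigma %||% 1,
          blocks = lapply(acfg$blocks %||% list(), function(b) {
            b$taxa <- unlist(b$taxa)
            b
          }),
          seed = cfg$seed)
        tab <- simulate_abundances(sp)
        write_abundance_csv(tab, file.path(cfg$out_dir, "abundances.csv"))
        report$abundances <<- list(samples = nrow(tab), taxa = ncol(tab))
      })
    } else if (stage == "network") {
      run_stage(stage, function() {
        ncfg <- cfg$network
        tab <- if (!is.null(ncfg$input)) read_abundance_csv(ncfg$input) else {
          f <- file.path(cfg$out_dir, "abundances.csv")
          if (!file.exists(f)) {
            stop("network stage needs an input CSV or a prior simulate-abundances stage")
          }
          read_abundance_csv(f)
        }
        nc <- network_config(
          min_abundance = ncfg$min_abundance %||% 1e-4,
          r_threshold = ncfg$r_threshold %||% 0.7,
          p_threshold = ncfg$p_threshold %||% 0.05,
          p_adjust = ncfg$p_adjust %||% "none",
          filter_stat = ncfg$filter_stat %||% "mean")
        net <- build_cooccurrence(tab, nc)
        top <- export_cooccurrence(
          net, csv = file.path(cfg$out_dir, "network_edges.csv"),
          graphml = file.path(cfg$out_dir, "network.graphml"),
          metrics_json = file.path(cfg$out_dir, "network_metrics.json"))
        report$network <<- top
      })
    }
  }
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  writeLines(c(log_lines, format(Sys.time(), "finished: %Y-%m-%d %H:%M:%S")),
             file.path(cfg$out_dir, "run.log"))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
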