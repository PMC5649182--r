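#' Validate a run configuration
#'
#' Schema-checks a raw configuration list (or YAML file) for
#' [run_pipeline()]. All problems are collected and reported together.
#'
#' Recognized keys: `condition` ("WT", "SQT1", "N588K"), `drug`
#' ("disopyramide", "quinidine" or NULL), `concentrations` (numeric,
#' >= 0), `actions` ("all", "ikr", "ina", "ikr+ina"), `cl` (ms),
#' `stages` (subset of "cell", "strand", "erp"), `seed`, plus optional
#' `strand` (list passed to [strand_config()]) and scaled-down numeric
#' controls `n_prepace`, `n_beats`, `n_s1`, `dt`.
#'
#' @param raw named list or path to a YAML file.
#' @return validated config (class `run_config`) with defaults filled, or
#'   an error listing every violation.
#' @export
validate_config <- function(raw) {
  if (is.character(raw) && length(raw) == 1) raw <- yaml::read_yaml(raw)
  if (!is.list(raw)) stop("config must be a list or a YAML file path")
  defaults <- list(condition = "SQT1", drug = NULL, concentrations = numeric(),
                   actions = "all", cl = 1000, stages = c("cell", "strand"),
                   seed = 1, strand = list(), n_prepace = 100, n_beats = 4,
                   n_s1 = 5, dt = 0.005)
  errs <- character()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    errs <- c(errs, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  cfg <- modifyList(defaults, raw[intersect(names(raw), names(defaults))])
  if (!cfg$condition %in% c("WT", "SQT1", "N588K"))
    errs <- c(errs, "condition must be one of WT, SQT1, N588K")
  if (!is.null(cfg$drug) && !cfg$drug %in% c("disopyramide", "quinidine"))
    errs <- c(errs, paste0("unknown drug '", cfg$drug,
                           "'; known drugs: disopyramide, quinidine"))
  if (length(cfg$concentrations) &&
      (!is.numeric(cfg$concentrations) || any(cfg$concentrations < 0)))
    errs <- c(errs, "concentrations must be numeric and >= 0")
  if (!cfg$actions %in% c("all", "ikr", "ina", "ikr+ina"))
    errs <- c(errs, "actions must be one of all, ikr, ina, ikr+ina")
  if (!all(cfg$stages %in% c("cell", "strand", "erp")))
    errs <- c(errs, "stages must be a subset of cell, strand, erp")
  if (!is.numeric(cfg$cl) || cfg$cl < 200)
    errs <- c(errs, "cl must be a pacing cycle length in ms (>= 200)")
  if (length(errs)) stop(paste(errs, collapse = "\n"), call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

#' Run the simulation pipeline for one configuration
#'
#' Executes the requested stages for every concentration (plus the
#' drug-free baseline) and assembles a biomarker report. Deterministic:
#' identical configurations give identical reports.
#'
#' @param config a validated config, raw list, or YAML path
#'   (see [validate_config()]).
#' @return `run_report`: list with `config`, `cell` and/or `strand` data
#'   frames, and a config digest.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  conc <- unique(c(0, config$concentrations))
  scfg <- do.call(strand_config, config$strand)
  cell_rows <- list(); strand_rows <- list()
  for (D in conc) {
    drug <- if (D > 0) drug_spec(config$drug, D, config$actions) else NULL
    label <- if (D > 0) config$drug else "drug-free"
    if ("cell" %in% config$stages) {
      tr <- steady_beat(cell_params("ENDO", config$condition), drug,
                        stimulus_spec(period = config$cl),
                        n_beats = config$n_prepace, dt = config$dt)
      cell_rows[[length(cell_rows) + 1]] <-
        data.frame(condition = config$condition, drug = label,
                   concentration_uM = D,
                   APD90 = as.numeric(measure_apd90(tr)),
                   MUV = as.numeric(measure_muv(tr)))
    }
    if ("strand" %in% config$stages) {
      bm <- strand_biomarkers(scfg, config$condition, drug, cl = config$cl,
                              n_beats = config$n_beats,
                              n_prepace = config$n_prepace, dt = config$dt,
                              erp = "erp" %in% config$stages,
                              n_s1 = config$n_s1)
      row <- data.frame(condition = config$condition, drug = label,
                        concentration_uM = D,
                        QT = as.numeric(bm$QT), CV = as.numeric(bm$CV),
                        TDR = as.numeric(bm$TDR))
      if ("erp" %in% config$stages) {
        row$ERP <- as.numeric(bm$ERP)
        row$WL <- as.numeric(bm$WL)
      }
      strand_rows[[length(strand_rows) + 1]] <- row
    }
  }
  report <- list(config = unclass(config),
                 digest = config_digest(config))
  if (length(cell_rows)) report$cell <- do.call(rbind, cell_rows)
  if (length(strand_rows)) report$strand <- do.call(rbind, strand_rows)
  class(report) <- "run_report"
  report
}

config_digest <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  # tiny polynomial rolling hash (double arithmetic, exact below 2^53);
  # stable across sessions
  h <- 5381
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Named experiment presets
#'
#' Ready-made configurations for the package's main experiments: the
#' single-cell concentration sweep, the four-concentration strand table,
#' and the action-mask decomposition scenarios.
#'
#' @param name one of "cell_sweep", "strand_table", "mask_scenarios".
#' @param drug "disopyramide" or "quinidine".
#' @export
pipeline_preset <- function(name = c("cell_sweep", "strand_table",
                                     "mask_scenarios"),
                            drug = "disopyramide") {
  name <- match.arg(name)
  switch(name,
    cell_sweep = validate_config(list(
      condition = "SQT1", drug = drug, stages = "cell",
      concentrations = exp(seq(log(0.2), log(20), length.out = 15)))),
    strand_table = validate_config(list(
      condition = "SQT1", drug = drug, stages = c("strand", "erp"),
      concentrations = c(1, 2, 5, 10))),
    mask_scenarios = lapply(c("ikr", "ina", "ikr+ina", "all"), function(a)
      validate_config(list(condition = "SQT1", drug = drug,
                           stages = "strand", actions = a,
                           concentrations = c(1, 2, 5, 10)))))
}
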