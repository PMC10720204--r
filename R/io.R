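# Plain-text persistence: cohort/metabolite/outcome tables as CSV, the truth
# record as a JSON sidecar, the configuration as YAML.

#' Write a simulated cohort to a directory
#'
#' Writes `cohort.csv`, `metabolites.csv`, `annotations.csv`, the planted
#' truth record as `truth.json`, and the configuration (seed included) as
#' `config.yaml`.
#'
#' @param sim An `oo_simulation` from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @param outcomes Optional outcome tibble, written as `outcomes.csv`.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, outcomes = NULL) {
  stopifnot(inherits(sim, "oo_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sim$cohort, file.path(dir, "cohort.csv"))
  readr::write_csv(sim$metabolites, file.path(dir, "metabolites.csv"))
  readr::write_csv(sim$annotations, file.path(dir, "annotations.csv"))
  if (!is.null(outcomes)) {
    readr::write_csv(outcomes, file.path(dir, "outcomes.csv"))
  }
  truth <- sim$truth
  for (e in c("voo", "coo", "total_oo")) { # named vectors survive as objects
    truth[[e]]$weights <- as.list(truth[[e]]$weights)
  }
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  yaml::write_yaml(unclass(sim$config), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a simulated cohort back from a directory
#'
#' @param dir Directory written by [write_simulation()].
#' @return An `oo_simulation` (plus `outcomes` when present).
#' @export
read_simulation <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg$missing_mechanism <- cfg$missing_mechanism %||% "MCAR"
  config <- do.call(sim_config, cfg[setdiff(names(cfg), character(0))])
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  for (e in c("voo", "coo", "total_oo")) {
    truth[[e]]$weights <- unlist(truth[[e]]$weights)
    truth[[e]]$active <- as.character(truth[[e]]$active)
  }
  out <- list(
    cohort = readr::read_csv(file.path(dir, "cohort.csv"),
                             show_col_types = FALSE),
    metabolites = readr::read_csv(file.path(dir, "metabolites.csv"),
                                  show_col_types = FALSE),
    annotations = readr::read_csv(file.path(dir, "annotations.csv"),
                                  show_col_types = FALSE),
    truth = truth, config = config)
  op <- file.path(dir, "outcomes.csv")
  if (file.exists(op)) out$outcomes <- readr::read_csv(op, show_col_types = FALSE)
  structure(out, class = "oo_simulation")
}
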