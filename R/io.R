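# Config serialization (YAML) used by the command-line wrapper.

block_ctor <- c(grid = "grid_config", tumor = "tumor_params",
                dosing = "dosing_schedule")
product_ctor <- c(kill = "nk_kill_params", prolif = "nk_prolif_params",
                  exhaustion = "exhaustion_params",
                  rates = "phenotype_rates", motility = "motility_params",
                  genetics = "genetic_effect_params")

#' Read a simulation configuration from YAML
#'
#' Field names mirror [simulation_config()] and its parameter blocks.
#' Products live under `products:` keyed by name; optional
#' `effect_table` and `expression_pool` entries are file paths loaded
#' with [load_effect_table()] / `read.csv`.
#'
#' @param path YAML file path.
#' @return A [simulation_config()].
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  for (nm in names(raw)) {
    val <- raw[[nm]]
    if (nm %in% names(block_ctor)) {
      if (nm == "dosing") {
        args[[nm]] <- do.call(dosing_schedule, val)
      } else {
        args[[nm]] <- do.call(block_ctor[[nm]], val)
      }
    } else if (nm == "products") {
      args[[nm]] <- lapply(names(val), function(pn) {
        pv <- val[[pn]]
        pargs <- list(name = pn)
        for (bn in names(pv)) {
          pargs[[bn]] <- if (bn %in% names(product_ctor))
            do.call(product_ctor[[bn]], pv[[bn]]) else pv[[bn]]
        }
        do.call(nk_product, pargs)
      })
      names(args[[nm]]) <- names(val)
    } else if (nm == "cytokines") {
      args[[nm]] <- lapply(val, function(cv) do.call(cytokine_params, cv))
    } else if (nm == "effect_table") {
      args[[nm]] <- load_effect_table(val)
    } else if (nm == "expression_pool") {
      df <- utils::read.csv(val, check.names = FALSE)
      mat <- as.matrix(df[, -1, drop = FALSE])
      rownames(mat) <- df[[1]]
      args[[nm]] <- mat
    } else {
      args[[nm]] <- val
    }
  }
  do.call(simulation_config, args)
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Write a simulation configuration to YAML
#'
#' Inverse of [read_config_yaml()] for the scalar blocks; in-memory
#' effect tables and expression pools are not serialized.
#'
#' @param config A [simulation_config()].
#' @param path Output path.
#' @export
write_config_yaml <- function(config, path) {
  out <- config
  out$effect_table <- NULL
  out$expression_pool <- NULL
  out$antigen_pool <- NULL
  out$dosing <- as.list(as.data.frame(out$dosing))
  yaml::write_yaml(strip_classes(unclass(out)), path)
}

#' Write run metadata JSON
#'
#' Seed, package version and a config echo, alongside the time-series
#' CSVs of a run.
#'
#' @param config A [simulation_config()].
#' @param seed Seed actually used.
#' @param path Output path.
#' @export
write_run_metadata <- function(config, seed, path) {
  cfg <- unclass(config)
  cfg$effect_table <- NULL
  cfg$expression_pool <- NULL
  cfg$antigen_pool <- NULL
  cfg$dosing <- as.list(as.data.frame(cfg$dosing))
  meta <- list(seed = seed,
               version = as.character(utils::packageVersion("nkabm")),
               config = strip_classes(cfg))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
}
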