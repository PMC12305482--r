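#' Read a wide-format trajectory table
#'
#' Reads a delimited text file with one row per subject and validates it
#' for the backward-recursive fit: every declared column must exist, no
#' declared column may contain missing values (offending rows are listed),
#' and treatment columns must contain only 0/1 (offending rows are named).
#'
#' @param path CSV file path.
#' @param columns Column roles: a list with `covariates` (list of character
#'   vectors, one per stage), `treatment` (character vector, one per
#'   stage), and `outcome` (single name).
#' @param sep Field separator (default comma).
#' @return A validated data frame of class `c("trajectories",
#'   "data.frame")` with the roles stored in attribute `"roles"`.
#' @export
read_trajectories <- function(path, columns, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  validate_trajectories(df, columns)
}

#' @rdname read_trajectories
#' @param data A data frame to validate in place of a file.
#' @export
validate_trajectories <- function(data, columns) {
  need <- c(unlist(columns$covariates), columns$treatment, columns$outcome)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("declared columns not present: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  na_rows <- which(rowSums(is.na(data[need])) > 0)
  if (length(na_rows)) {
    stop("missing values in rows: ",
         paste(utils::head(na_rows, 10L), collapse = ", "),
         if (length(na_rows) > 10L) " ..." else "", call. = FALSE)
  }
  for (a in columns$treatment) {
    bad <- which(!data[[a]] %in% c(0, 1))
    if (length(bad)) {
      stop("treatment column '", a, "' has non-binary values in rows: ",
           paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
    }
  }
  structure(data, roles = columns,
            class = c("trajectories", "data.frame"))
}

#' @rdname read_trajectories
#' @export
write_trajectories <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' Serialize a dwols fit to JSON
#'
#' Writes the per-stage blip and treatment-free coefficients with their
#' term names, the per-stage recommended-action shares, and the positivity
#' diagnostic.  Numbers are written at full precision so a write/read
#' round trip reproduces the coefficients exactly.
#'
#' @param fit A fitted [dwols()] object.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_dwols <- function(fit, path) {
  stages <- lapply(seq_len(fit$n_stages), function(t) {
    s <- fit$stages[[t]]
    list(stage = t,
         psi = as.list(s$psi),
         beta = as.list(s$beta),
         rule = list(treat = mean(s$opt == 1, na.rm = TRUE),
                     withhold = mean(s$opt == 0, na.rm = TRUE),
                     undefined = mean(is.na(s$opt))))
  })
  obj <- list(schema = "dwolsml/fit/1",
              method = fit$method,
              learner = if (is.character(fit$learner)) fit$learner else
                (fit$learner$name %||% "custom"),
              folds = fit$folds, n = fit$n,
              low_weight_share = fit$diagnostics$low_weight_share,
              stages = stages)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dwols
#' @export
read_dwols <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write per-subject recommended actions
#'
#' One row per subject with the recommended action at each stage (1 =
#' treat, 0 = withhold, empty = undefined rule).
#'
#' @param fit A fitted [dwols()] object.
#' @param path Output CSV path.
#' @export
write_actions <- function(fit, path) {
  out <- as.data.frame(lapply(seq_len(fit$n_stages), function(t) {
    as.integer(fit$stages[[t]]$opt)
  }))
  names(out) <- paste0("d_opt_stage", seq_len(fit$n_stages))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a metrics table as CSV
#'
#' One row per method x parameter, as produced by
#' [summarize_replicates()].
#'
#' @param metrics A `dwols_metrics` data frame.
#' @param path Output CSV path.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.csv(as.data.frame(metrics), path, row.names = FALSE)
  invisible(path)
}

#' Serialize an m-out-of-n bootstrap result to JSON
#'
#' Per parameter: selected subsample size, rate exponent, bootstrap
#' variance, interval bounds; plus the grid configuration and dropped
#' replicate counts.
#'
#' @param result An [mn_boot()] object.
#' @param path Output JSON path.
#' @export
write_mn_boot <- function(result, path) {
  obj <- list(schema = "dwolsml/mnboot/1",
              q = result$config$q, K_grid = result$config$K_grid,
              B = result$config$B, level = result$config$level,
              dropped = result$dropped,
              parameters = result$summary)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run manifest for reproducibility
#'
#' Captures everything needed to re-run an analysis bit-for-bit: the
#' configuration snapshot, the master seed, package versions, timestamps,
#' and replicate drop counts.
#'
#' @param config Configuration object or list (serialized as-is).
#' @param seed Master seed.
#' @param drops Named drop/failure counts (optional).
#' @param path Optional path; when given the manifest is written as JSON.
#' @return The manifest list, invisibly when written.
#' @export
run_manifest <- function(config, seed, drops = NULL, path = NULL) {
  man <- list(schema = "dwolsml/manifest/1",
              package_version =
                as.character(utils::packageVersion("dwolsml")),
              r_version = as.character(getRversion()),
              timestamp = format(Sys.time(), tz = "UTC",
                                 "%Y-%m-%dT%H:%M:%SZ"),
              master_seed = seed,
              config = unclass(config),
              drops = drops)
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    return(invisible(man))
  }
  man
}

#' Read a YAML run configuration
#'
#' Scenario/harness configuration files use plain YAML with keys matching
#' [scenario_config()] (`study`, `complexity`, `n`, `seed`, `psi`,
#' `overrides`) plus optional harness keys (`methods`, `R`, `folds`) and an
#' `mn_boot` block matching [mn_boot_config()].
#'
#' @param path YAML file path.
#' @return List with elements `scenario` (a [scenario_config()]),
#'   `methods`, `R`, `folds`, and `mn_boot` (an [mn_boot_config()] or
#'   `NULL`).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sc <- scenario_config(
    study = y$study %||% 1L,
    complexity = y$complexity %||% "simple",
    n = y$n %||% 300L,
    seed = y$seed,
    psi = unlist(y$psi) %||% c(1, -1, 1, -1),
    overrides = y$overrides)
  mb <- if (!is.null(y$mn_boot)) {
    do.call(mn_boot_config, y$mn_boot)
  }
  list(scenario = sc,
       methods = y$methods %||% "logit",
       R = y$R %||% 200L,
       folds = y$folds %||% 2L,
       mn_boot = mb)
}
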