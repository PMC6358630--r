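#' Read an annual production series from CSV
#'
#' Expects a header with columns `year` and `production`. Rows are sorted
#' by year; duplicated years, gaps in the year sequence and non-numeric
#' values are hard errors (no imputation). Values are converted to
#' thousand tonnes, the package's internal production unit.
#'
#' @param path CSV file path.
#' @param unit unit of the `production` column: `"kilotonnes"` (thousand
#'   tonnes, default) or `"tonnes"`.
#' @return A [year_series()] in thousand tonnes.
#' @export
read_production_csv <- function(path, unit = c("kilotonnes", "tonnes")) {
  unit <- match.arg(unit)
  df <- utils::read.csv(path)
  if (!all(c("year", "production") %in% names(df)))
    stop("production CSV must have header columns 'year' and 'production'",
         call. = FALSE)
  yrs <- suppressWarnings(as.integer(df$year))
  val <- suppressWarnings(as.numeric(df$production))
  if (anyNA(yrs) || anyNA(val))
    stop("non-numeric year or production value in ", path, call. = FALSE)
  ord <- order(yrs)
  yrs <- yrs[ord]
  val <- val[ord]
  if (anyDuplicated(yrs))
    stop("duplicate year in ", path, call. = FALSE)
  if (!identical(yrs, yrs[1L] + seq_along(yrs) - 1L))
    stop("missing year(s) in ", path, ": the series must be contiguous",
         call. = FALSE)
  if (unit == "tonnes") val <- val / 1000
  year_series(val, yrs[1L])
}

#' Write an annual production series to CSV
#'
#' @param y a [year_series()] in thousand tonnes.
#' @param path output path.
#' @param unit unit for the written `production` column.
#' @return `path`, invisibly.
#' @export
write_production_csv <- function(y, path,
                                 unit = c("kilotonnes", "tonnes")) {
  unit <- match.arg(unit)
  stopifnot(inherits(y, "year_series"))
  val <- as.numeric(y)
  if (unit == "tonnes") val <- val * 1000
  utils::write.csv(data.frame(year = years(y), production = val), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read the seven environmental covariates from CSV
#'
#' Expects a header with columns `year, R, C, T, W, S, N, Q`, strictly
#' positive values and a contiguous year range. By default each column is
#' divided by its mean over the loaded window, producing the mean-one
#' ratios the model consumes; pass `normalize = FALSE` for data that is
#' already normalized (its column means must then equal 1).
#'
#' @param path CSV file path.
#' @param normalize divide each column by its own mean (default `TRUE`).
#' @return A normalized [covariate_set()].
#' @export
read_covariates_csv <- function(path, normalize = TRUE) {
  df <- utils::read.csv(path)
  cov <- covariate_set(df, normalized = !normalize)
  if (normalize) cov <- normalize_covariates(cov)
  cov
}

#' Write a covariate set to CSV
#'
#' @param cov a [covariate_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_covariates_csv <- function(cov, path) {
  stopifnot(inherits(cov, "covariate_set"))
  utils::write.csv(as.data.frame(cov), path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Describes one end-to-end run: either paths to real production and
#' covariate CSVs, or a [sim_config()] for a synthetic study (exactly one
#' of the two), together with priors, sampler settings, the decline
#' anchors, the trend split year and the output directory.
#'
#' @param production_csv,covariates_csv input paths (real-data mode).
#' @param simulation a [sim_config()] (simulation mode).
#' @param unit unit of the production CSV.
#' @param priors a [psm_priors()].
#' @param control a [psm_control()].
#' @param decline_anchor_years calendar years at which the decline
#'   decomposition is evaluated (posterior-mean suitability at those
#'   years); `NULL` picks four years evenly spanning the window.
#' @param split_year first year of the later period in the disturbance
#'   breakpoint comparison.
#' @param out_dir output directory (created if absent).
#' @param seed integer seed for the whole run.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(production_csv = NULL, covariates_csv = NULL,
                            simulation = NULL,
                            unit = c("kilotonnes", "tonnes"),
                            priors = psm_priors(),
                            control = psm_control(),
                            decline_anchor_years = NULL,
                            split_year = 1998, out_dir = "prodsuit-run",
                            seed = 1L) {
  unit <- match.arg(unit)
  real_mode <- !is.null(production_csv) || !is.null(covariates_csv)
  sim_mode <- !is.null(simulation)
  if (real_mode == sim_mode)
    stop("supply either both CSV paths or a simulation config, not both ",
         "or neither", call. = FALSE)
  if (real_mode && (is.null(production_csv) || is.null(covariates_csv)))
    stop("real-data mode needs both production_csv and covariates_csv",
         call. = FALSE)
  if (sim_mode) stopifnot(inherits(simulation, "sim_config"))
  structure(list(production_csv = production_csv,
                 covariates_csv = covariates_csv, simulation = simulation,
                 unit = unit, priors = priors, control = control,
                 decline_anchor_years = decline_anchor_years,
                 split_year = as.integer(split_year), out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

pipeline_stage <- function(log_path, stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
  cat(sprintf("stage=%s elapsed=%.2fs\n", stage,
              proc.time()[["elapsed"]] - t0),
      file = log_path, append = TRUE)
  res
}

#' Run the full analysis pipeline
#'
#' Chains simulate (or load), fit, summarize, decompose and trend-analyse,
#' writing one CSV per artifact plus a JSON run manifest and a stage log.
#' Outputs: `chain.csv` (retained posterior draws), `summary.csv`
#' (posterior summary table), `suitability.csv` (posterior suitability
#' trajectory), `decline.csv` (decline decomposition at the anchor
#' years), `trends.csv` (production trend and two-period disturbance
#' trends), `manifest.json` and `log.txt`. Runs are deterministic given
#' the seed; input files are never modified.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the fitted [psm()] object, the artifact
#'   paths and the decline/trend tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$out_dir,
                     c(chain = "chain.csv", summary = "summary.csv",
                       suitability = "suitability.csv",
                       decline = "decline.csv", trends = "trends.csv",
                       manifest = "manifest.json", log = "log.txt"))
  names(paths) <- c("chain", "summary", "suitability", "decline", "trends",
                    "manifest", "log")
  cat(sprintf("run start seed=%d\n", config$seed), file = paths[["log"]])

  inputs <- pipeline_stage(paths[["log"]], "load", {
    if (!is.null(config$simulation)) {
      sim <- config$simulation
      sim$seed <- config$seed
      out <- psm_simulate(sim)
      list(y = out$production, cov = out$covariates, truth = out$params)
    } else {
      list(y = read_production_csv(config$production_csv, config$unit),
           cov = read_covariates_csv(config$covariates_csv),
           truth = NULL)
    }
  })

  fit <- pipeline_stage(paths[["log"]], "fit",
    psm(inputs$y, inputs$cov, priors = config$priors,
        control = config$control, seed = config$seed))

  pipeline_stage(paths[["log"]], "summarize", {
    utils::write.csv(as.data.frame(fit$draws), paths[["chain"]],
                     row.names = FALSE)
    utils::write.csv(posterior_summary(fit), paths[["summary"]],
                     row.names = FALSE)
    utils::write.csv(suitability_trajectory(fit), paths[["suitability"]],
                     row.names = FALSE)
  })

  decline <- pipeline_stage(paths[["log"]], "decompose", {
    est <- suitability_trajectory(fit)
    anchor_years <- config$decline_anchor_years
    if (is.null(anchor_years)) {
      idx <- unique(round(seq(1L, nrow(est), length.out = 4L)))
      anchor_years <- est$year[idx]
    }
    cm <- coef(fit)
    tab <- decline_decomposition(
      data.frame(year = anchor_years,
                 es = est$mean[match(anchor_years, est$year)]),
      V = cm[["V"]], K = cm[["K"]])
    utils::write.csv(as.data.frame(tab), paths[["decline"]],
                     row.names = FALSE)
    tab
  })

  trends <- pipeline_stage(paths[["log"]], "trends", {
    hd_mean <- disturbance_trajectory(fit)
    hd_series <- year_series(hd_mean$mean, hd_mean$year[1L])
    bp <- breakpoint_comparison(hd_series, config$split_year)
    tab <- trend_table(production = linear_trend(inputs$y),
                       disturbance = linear_trend(hd_series),
                       disturbance_before = bp$before,
                       disturbance_after = bp$after)
    utils::write.csv(tab, paths[["trends"]], row.names = FALSE)
    list(table = tab, breakpoint = bp)
  })

  pipeline_stage(paths[["log"]], "manifest", {
    manifest <- list(
      seed = config$seed,
      mode = if (is.null(config$simulation)) "real" else "simulation",
      unit = config$unit,
      iterations = config$control$iterations,
      thin = config$control$thin,
      burn_in = config$control$burn_in,
      chains = config$control$chains,
      gamma_convention = config$priors$gamma_convention,
      split_year = config$split_year,
      package_version = as.character(utils::packageVersion("prodsuit")),
      r_version = R.version.string)
    jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                         pretty = TRUE)
  })

  cat("run complete\n", file = paths[["log"]], append = TRUE)
  invisible(list(fit = fit, paths = paths, decline = decline,
                 trends = trends$table,
                 breakpoint = trends$breakpoint))
}
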