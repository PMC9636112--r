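#' Run an analysis described by a YAML configuration
#'
#' Single entry point tying the package together for scripted use.  The
#' configuration (a YAML file or an equivalent named list) selects a mode
#' and its inputs; all artifacts are written under \code{out_dir} and the
#' seed, quadrature size and package version are logged to standard error.
#'
#' Modes:
#' \describe{
#'   \item{simulate}{generate a dataset (defaults to the diary-study
#'     design of [study_truth()]); writes \code{data.csv} and a
#'     \code{truth.json} sidecar.}
#'   \item{fit}{fit the configured model to a CSV dataset; writes
#'     \code{fit.json} and a readable \code{fit.txt} parameter table.}
#'   \item{compare}{fit the configured ladder of models and write an
#'     LRT/AIC/BIC table (\code{compare.csv}, \code{compare.json}).}
#'   \item{eb}{fit, then write empirical Bayes subject summaries and
#'     conditional residuals as CSV.}
#'   \item{invariance}{run the measurement-invariance sequence and write
#'     its table (\code{invariance.csv}).}
#' }
#'
#' @param config path to a YAML file, or a named list with the same
#'   structure.  Unknown keys are rejected.
#' @param out_dir output directory (overrides the config's
#'   \code{out_dir}).
#' @return Invisibly, a list of the artifacts produced (paths and the main
#'   in-memory result).
#' @export
run_config <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML file or a named list")
  allowed <- c("mode", "seed", "out_dir", "data", "model", "models",
               "quadrature", "optimizer", "simulate", "invariance")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
  mode <- config$mode %||% stop("config needs a `mode`")
  if (!mode %in% c("simulate", "fit", "compare", "eb", "invariance"))
    stop("unknown mode `", mode, "`")
  out_dir <- out_dir %||% config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  n_quad <- config$quadrature$n_points %||% 10L
  message(sprintf("lvmelsm %s | mode=%s seed=%d quadrature=%d",
                  as.character(utils::packageVersion("lvmelsm")),
                  mode, as.integer(seed), as.integer(n_quad)))
  set.seed(seed)

  read_data <- function() {
    blk <- config$data %||% stop("mode `", mode, "` needs a `data` block")
    read_diary_csv(blk$path, blk$schema %||% blk)
  }

  artifacts <- switch(mode,
    simulate = {
      blk <- config$simulate %||% list()
      base <- study_truth(blk$mode %||% "latent")
      sim <- simulate_melsm(base$spec, base$truth,
                            n_subjects = blk$n_subjects %||% 435L,
                            n_occasions = blk$n_occasions %||% 8L,
                            stressors = isTRUE(blk$stressors),
                            missing_rate = blk$missing_rate %||% 0,
                            seed = seed)
      data_path <- file.path(out_dir, "data.csv")
      truth_path <- file.path(out_dir, "truth.json")
      write_diary_csv(sim$data, data_path)
      jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE,
                           digits = NA, matrix = "rowmajor")
      list(data = data_path, truth = truth_path)
    },
    fit = {
      data <- read_data()
      spec <- spec_from_config(config$model %||% stop("mode `fit` needs a `model` block"))
      fit <- fit_melsm(data, spec, n_quad = n_quad,
                       control = config$optimizer %||% list())
      write_fit(fit, out_dir, seed)
      list(fit = fit)
    },
    compare = {
      data <- read_data()
      blocks <- config$models %||% stop("mode `compare` needs a `models` block")
      fits <- lapply(blocks, function(b)
        fit_melsm(data, spec_from_config(b), n_quad = n_quad, se = FALSE))
      names(fits) <- names(blocks) %||% paste0("M", seq_along(blocks))
      tab <- compare_melsm(fits)
      utils::write.csv(tab, file.path(out_dir, "compare.csv"), row.names = FALSE)
      jsonlite::write_json(tab, file.path(out_dir, "compare.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      list(table = tab)
    },
    eb = {
      data <- read_data()
      spec <- spec_from_config(config$model %||% stop("mode `eb` needs a `model` block"))
      fit <- fit_melsm(data, spec, n_quad = n_quad, se = FALSE)
      eb <- eb_estimates(fit)
      write_eb_csv(eb, file.path(out_dir, "eb_subjects.csv"),
                   file.path(out_dir, "eb_residuals.csv"))
      list(eb = eb)
    },
    invariance = {
      data <- read_data()
      blk <- config$invariance %||% list()
      tab <- invariance_sequence(
        data,
        free_intercepts_equal = blk$free_intercepts_equal,
        free_intercepts_both = blk$free_intercepts_both)
      utils::write.csv(tab, file.path(out_dir, "invariance.csv"),
                       row.names = FALSE)
      list(table = tab)
    })
  invisible(artifacts)
}

## model spec from a config block
spec_from_config <- function(blk) {
  ok <- c("location", "between", "within", "measurement")
  unknown <- setdiff(names(blk), ok)
  if (length(unknown))
    stop("unknown model keys: ", paste(unknown, collapse = ", "))
  loc <- blk$location %||% list()
  bv <- blk$between %||% list()
  wv <- blk$within %||% list()
  ms <- NULL
  if (!is.null(blk$measurement)) {
    m <- blk$measurement
    ms <- measurement_spec(m$n_items, m$n_occasions,
                           anchor = m$anchor %||% 1L,
                           intercepts = m$intercepts %||% "item",
                           loadings = m$loadings %||% "item",
                           uniquenesses = m$uniquenesses %||% "item")
  }
  melsm_spec(
    location = location_spec(x_terms = unlist(loc$x_terms) %||% character(),
                             w_terms = unlist(loc$w_terms) %||% character(),
                             random = unlist(loc$random) %||% "1"),
    between = between_spec(terms = unlist(bv$terms) %||% character()),
    within = within_spec(x_terms = unlist(wv$x_terms) %||% character(),
                         w_terms = unlist(wv$w_terms) %||% character(),
                         random_scale = wv$random_scale %||% TRUE),
    measurement = ms)
}

write_fit <- function(fit, out_dir, seed) {
  payload <- list(estimates = as.list(fit$estimates),
                  se = as.list(fit$se),
                  loglik = fit$loglik, deviance = fit$deviance,
                  aic = fit$aic, bic = fit$bic,
                  n_params = fit$n_params, n_subjects = fit$N,
                  converged = fit$converged, grad_norm = fit$grad_norm,
                  n_quad = fit$n_quad, seed = seed,
                  package_version = as.character(utils::packageVersion("lvmelsm")))
  jsonlite::write_json(payload, file.path(out_dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA)
  tab <- sprintf("%-24s %12.5f %12.5f", names(fit$estimates),
                 fit$estimates, fit$se)
  writeLines(c(sprintf("%-24s %12s %12s", "parameter", "estimate", "se"), tab,
               "",
               sprintf("deviance %.3f  AIC %.3f  BIC %.3f  (k = %d, N = %d)",
                       fit$deviance, fit$aic, fit$bic, fit$n_params, fit$N)),
             file.path(out_dir, "fit.txt"))
  invisible(NULL)
}
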