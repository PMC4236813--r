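# CSV/JSON input-output for chase datasets, parameter sets and
# trajectories. Plain UTF-8 CSV with header rows; times in minutes as
# decimals; no locale-dependent formatting.

CHASE_COLUMNS <- c("variant", "flux", "replicate", "time_min", "abundance")

#' Read / write chase datasets
#'
#' Chase CSV layout: columns `variant`, `flux`, `replicate`, `time_min`,
#' `abundance`. `read_chase_csv` validates the header and reports the file
#' and any missing columns; the pair round-trips exactly.
#'
#' @param path file path.
#' @return `read_chase_csv`: the chase data.frame.
#' @export
read_chase_csv <- function(path) {
  if (!file.exists(path)) stop("chase CSV not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(CHASE_COLUMNS, names(d))
  if (length(missing) > 0)
    stop(sprintf("malformed chase CSV %s: missing column(s) %s",
                 path, paste(missing, collapse = ", ")))
  d[, CHASE_COLUMNS]
}

#' @rdname read_chase_csv
#' @param data chase data.frame.
#' @export
write_chase_csv <- function(data, path) {
  stopifnot(all(CHASE_COLUMNS %in% names(data)))
  utils::write.csv(data[, CHASE_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read / write kinetic parameter sets as JSON
#'
#' One record per variant: a named object of rate constants matching the
#' [psd_params] fields.
#'
#' @param path file path.
#' @return `read_params_json`: a [psd_params] object (single record) or a
#'   named list of them.
#' @export
read_params_json <- function(path) {
  if (!file.exists(path)) stop("parameter JSON not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  to_params <- function(rec) do.call(psd_params, as.list(rec))
  if (all(vapply(obj, is.numeric, logical(1)))) to_params(obj)
  else lapply(obj, to_params)
}

#' @rdname read_params_json
#' @param params a [psd_params] object or named list of them.
#' @export
write_params_json <- function(params, path) {
  strip <- function(p) unclass(p)
  obj <- if (inherits(params, "psd_params")) strip(params)
         else lapply(params, strip)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a trajectory as tidy CSV
#'
#' Long format: columns `time`, `species`, `count`, `run_id`.
#'
#' @param traj a `psd_traj` object.
#' @param path file path.
#' @param run_id identifier stored with every row.
#' @export
write_trajectory_csv <- function(traj, path, run_id = 1) {
  d <- as.data.frame(traj)
  d$run_id <- run_id
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize an estimation result to JSON
#'
#' Captures estimates, standard deviations, priors, masks and convergence
#' metadata of a [psd_fit] or [gauss_newton_solve] result.
#'
#' @param fit a `psd_fit` or `psd_gn_result` object.
#' @param path file path.
#' @param seed seed to record for provenance (optional).
#' @export
write_fit_json <- function(fit, path, seed = NULL) {
  problem <- fit$problem
  est <- if (inherits(fit, "psd_fit")) fit$coefficients else fit$estimates
  sds <- fit$standard_deviations
  obj <- list(variant = problem$variant,
              estimates = as.list(est),
              standard_deviations = as.list(sds),
              free = as.list(problem$free),
              priors = problem$priors,
              residual_norm = fit$residual_norm,
              constraint_violation = fit$constraint_violation,
              iterations = fit$iterations,
              converged = fit$converged,
              seed = seed,
              package_version = as.character(utils::packageVersion("psdkin")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
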