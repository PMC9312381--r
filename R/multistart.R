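#' Multistart optimization study
#'
#' Runs independent trust-region minimizations from uniformly sampled (or
#' user-supplied) start points and summarizes them with the success count
#' `gamma`, convergence rate `nu` and performance `phi` for each requested
#' threshold `tau`. Failed runs are data: their gradient evaluations count
#' towards the totals and their final values are marked unsuccessful.
#'
#' @param objective a [tr_objective()].
#' @param domain a [search_domain()] with finite bounds (needed for start
#'   sampling unless `startpoints` is given).
#' @param n_starts number of optimization runs.
#' @param options a [tr_options()].
#' @param seed integer seed for start-point sampling.
#' @param startpoints optional matrix of start points (one per row);
#'   overrides sampling.
#' @param tau numeric vector of success thresholds (default 2).
#' @param keep_traces keep the full per-run iteration traces (default
#'   `FALSE`; summaries via [trace_statistics()] are kept either way).
#' @return object of class `"tr_multistart"`: list with `runs` (data frame:
#'   start index, final objective, iterations, status, distance moved),
#'   `metrics` (data frame with one row per `tau`: `tau`, `gamma`, `nu`,
#'   `phi`, `n_grad_total`), `best` (the best run's result), `startpoints`,
#'   `final_thetas` (matrix), and optionally `traces`.
#' @export
tr_multistart <- function(objective, domain, n_starts = 100,
                          options = tr_options(), seed = 1L,
                          startpoints = NULL, tau = 2,
                          keep_traces = FALSE) {
  stopifnot(all(tau > 0), n_starts >= 1)
  if (is.null(startpoints))
    startpoints <- sample_startpoints(domain, n_starts, seed)
  n_starts <- nrow(startpoints)
  results <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    results[[i]] <- tr_minimize(objective, startpoints[i, ], domain,
                                options)
  }
  finals <- vapply(results, `[[`, numeric(1), "f")
  iters <- vapply(results, `[[`, integer(1), "n_grad")
  status <- vapply(results, `[[`, character(1), "status")
  finals[status == "failure"] <- NA_real_
  n_grad_total <- sum(iters)
  metrics <- do.call(rbind, lapply(tau, function(tt) {
    m <- compute_metrics(finals, n_grad_total, tt)
    data.frame(tau = tt, gamma = m$gamma, nu = m$nu, phi = m$phi,
               n_grad_total = n_grad_total)
  }))
  thetas <- do.call(rbind, lapply(results, `[[`, "theta"))
  runs <- data.frame(start = seq_len(n_starts), f_final = finals,
                     iterations = iters, status = status,
                     stringsAsFactors = FALSE)
  best_i <- if (any(is.finite(finals))) which.min(finals) else 1L
  out <- list(runs = runs, metrics = metrics, best = results[[best_i]],
              startpoints = startpoints, final_thetas = thetas,
              scheme = options$scheme, seed = seed)
  if (keep_traces) out$traces <- lapply(results, `[[`, "trace")
  structure(out, class = "tr_multistart")
}

#' @export
print.tr_multistart <- function(x, ...) {
  cat(sprintf("Multistart study: %d runs, scheme %s\n", nrow(x$runs),
              x$scheme))
  ok <- is.finite(x$runs$f_final)
  if (any(ok))
    cat(sprintf("  best objective: %.8g\n", min(x$runs$f_final[ok])))
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Indices of successful runs
#'
#' Start indices whose final objective lies within `tau` of the best final
#' value; input to [startpoint_overlap()].
#'
#' @param ms a `"tr_multistart"`.
#' @param tau success threshold.
#' @return integer vector of start indices.
#' @export
successful_starts <- function(ms, tau = 2) {
  f <- ms$runs$f_final
  ok <- is.finite(f)
  if (!any(ok)) return(integer())
  which(ok & (f - min(f[ok]) < tau))
}

#' Write multistart outputs to disk
#'
#' Writes `runs.csv` (per-run summary), `waterfall.csv` (sorted final
#' objective values), and `metrics.csv` (`gamma`/`nu`/`phi` per `tau`) into
#' `dir`; with `traces = TRUE` also one `trace_<i>.csv` per run (requires
#' the study to have been run with `keep_traces = TRUE`) plus a single
#' hierarchical container `traces.rds`.
#'
#' @param ms a `"tr_multistart"`.
#' @param dir output directory (created if missing).
#' @param traces also write per-run traces.
#' @return invisibly, the directory.
#' @export
write_multistart <- function(ms, dir, traces = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(ms$runs, file.path(dir, "runs.csv"), row.names = FALSE)
  wf <- data.frame(rank = seq_len(nrow(ms$runs)),
                   f_final = sort(ms$runs$f_final, na.last = TRUE))
  utils::write.csv(wf, file.path(dir, "waterfall.csv"), row.names = FALSE)
  utils::write.csv(ms$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  if (traces) {
    if (is.null(ms$traces))
      stop("study was not run with keep_traces = TRUE")
    for (i in seq_along(ms$traces))
      utils::write.csv(ms$traces[[i]],
                       file.path(dir, sprintf("trace_%04d.csv", i)),
                       row.names = FALSE)
    saveRDS(ms$traces, file.path(dir, "traces.rds"))
  }
  invisible(dir)
}
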