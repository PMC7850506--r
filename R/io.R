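#' Write a trajectory to CSV
#'
#' Writes the 12-column observable table (`t, R, N, x, p_F, p_S, p_bar,
#' frac_grouped, n_fast_alone, n_fast_grouped, n_slow_alone,
#' n_slow_grouped`) at 15 significant digits, so a read-back reproduces the
#' printed values exactly.
#'
#' @param traj an `"eco_trajectory"` or an observable data.frame from
#'   [derive_observables()].
#' @param path output file path.
#' @param params needed when `traj` is a bare `t, R, N, x` data.frame.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, params = NULL) {
  obs <- if (is.data.frame(traj) && "frac_grouped" %in% names(traj)) traj
         else derive_observables(traj, params)
  cols <- c("t", "R", "N", "x", "p_F", "p_S", "p_bar", "frac_grouped",
            "n_fast_alone", "n_fast_grouped", "n_slow_alone",
            "n_slow_grouped")
  out <- obs[, cols]
  out[] <- lapply(out, function(v) format(v, digits = 15, trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#'
#' @param path file path.
#' @return a data.frame with the 12 documented columns.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  cols <- c("t", "R", "N", "x", "p_F", "p_S", "p_bar", "frac_grouped",
            "n_fast_alone", "n_fast_grouped", "n_slow_alone",
            "n_slow_grouped")
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop("trajectory CSV is missing columns: ",
         paste(missing, collapse = ", "))
  df[, cols]
}

#' Serialize an analysis report to JSON
#'
#' Writes equilibrium reports (eigenvalues as `[re, im]` pairs),
#' limit-cycle summaries, Hopf curves and evolution traces as plain JSON
#' for downstream consumption.
#'
#' @param x an `equilibrium_report`, `limit_cycle_summary`,
#'   `evolution_trace`, or a data.frame (e.g. a Hopf curve or scan table).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  obj <- if (inherits(x, "equilibrium_report")) {
    list(label = x$label, location = as.list(x$location),
         eigenvalues = lapply(x$eigenvalues,
                              function(z) c(Re(z), Im(z))),
         stability = x$stability,
         leading_real_part = x$leading_real_part,
         exists = x$exists, residual = x$residual)
  } else if (inherits(x, "limit_cycle_summary")) {
    list(period = x$period, extrema = x$extrema,
         means = as.list(x$means), converged = x$converged,
         n_transient_cycles = x$n_transient_cycles,
         net_growth_integral = x$net_growth_integral)
  } else if (inherits(x, "evolution_trace")) {
    list(delta = attr(x, "delta"), steps = as.data.frame(x))
  } else if (is.data.frame(x)) {
    x
  } else {
    stop("unsupported object for JSON report")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
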