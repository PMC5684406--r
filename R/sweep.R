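#' Define a parameter sweep
#'
#' A sweep grid is the Cartesian product of one or more parameter axes
#' (drawn from `tau`, `gamma0`, `phi`, `delta0`) around a base coupling; one
#' solver run per grid cell, with the chosen observable evaluated on a
#' shared output time axis.
#'
#' @param axes Named list of numeric axis vectors; names must be among
#'   `tau`, `gamma0`, `phi`, `delta0`. Use [sweep_axis()] to build an axis
#'   from (min, max, count, spacing).
#' @param coupling Base [feedback_coupling()] supplying the non-swept
#'   parameters.
#' @param t_max Final time in fs for every run.
#' @param dt Solver step in fs, or `NULL` for the per-run default
#'   `min(tau/200, 0.5)`.
#' @param observable `"population"` or `"coherence"` (coherence implies the
#'   dimer mode).
#' @param mode `"scalar"` or `"dimer"`.
#' @param site Site index for populations.
#' @param c_init Initial amplitude(s); defaults per mode.
#' @param n_times Number of shared output times (linearly spaced over
#'   `[0, t_max]`).
#' @param cap Maximum number of grid cells (guard against runaway grids).
#' @return Object of class `"sweep_grid"`.
#' @export
sweep_grid <- function(axes, coupling, t_max, dt = NULL,
                       observable = c("population", "coherence"),
                       mode = c("scalar", "dimer"), site = 1L,
                       c_init = NULL, n_times = 400L, cap = 1e6) {
  observable <- match.arg(observable)
  mode <- match.arg(mode)
  coupling <- as_feedback_coupling(coupling)
  allowed <- c("tau", "gamma0", "phi", "delta0")
  if (length(axes) == 0 || is.null(names(axes)) ||
      !all(names(axes) %in% allowed)) {
    stop("axes must be a named list over {tau, gamma0, phi, delta0}",
         call. = FALSE)
  }
  for (nm in names(axes)) {
    ax <- axes[[nm]]
    if (length(ax) < 2 || any(!is.finite(ax)) || any(diff(ax) <= 0)) {
      stop("axis '", nm, "' must be >= 2 strictly increasing finite values",
           call. = FALSE)
    }
  }
  cells <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  if (nrow(cells) > cap) {
    stop("grid has ", nrow(cells), " cells, above the cap of ", cap,
         call. = FALSE)
  }
  if (observable == "coherence") mode <- "dimer"
  structure(
    list(axes = axes, cells = cells, coupling = coupling, t_max = t_max,
         dt = dt, observable = observable, mode = mode, site = site,
         c_init = c_init, n_times = as.integer(n_times)),
    class = "sweep_grid"
  )
}

#' Build a sweep axis
#'
#' @param min,max Axis range (`min < max`).
#' @param count Number of points (>= 2).
#' @param spacing `"linear"` or `"log"`.
#' @return Numeric axis vector.
#' @export
sweep_axis <- function(min, max, count, spacing = c("linear", "log")) {
  spacing <- match.arg(spacing)
  if (!(count >= 2) || !(min < max)) {
    stop("need count >= 2 and min < max", call. = FALSE)
  }
  if (spacing == "log") {
    if (min <= 0) stop("log spacing needs min > 0", call. = FALSE)
    exp(seq(log(min), log(max), length.out = count))
  } else {
    seq(min, max, length.out = count)
  }
}

#' Run a parameter sweep
#'
#' Runs one solver call per grid cell and evaluates the observable on the
#' shared output time axis (linear interpolation from each run's own grid).
#' Cells are independent; a failing cell is recorded as `NA` and the sweep
#' continues.
#'
#' @param grid A [sweep_grid()].
#' @return Object of class `"sweep_result"`: list with `cells` (data frame
#'   of swept parameters), `times` (shared axis), `values` (cells x times
#'   matrix) and the grid. Convert to long-format rows with
#'   `as.data.frame()`.
#' @export
run_sweep <- function(grid) {
  stopifnot(inherits(grid, "sweep_grid"))
  times_out <- seq(0, grid$t_max, length.out = grid$n_times)
  vals <- matrix(NA_real_, nrow(grid$cells), grid$n_times)
  for (i in seq_len(nrow(grid$cells))) {
    vals[i, ] <- tryCatch(
      sweep_cell(grid, as.list(grid$cells[i, , drop = FALSE]), times_out),
      error = function(e) {
        warning("sweep cell ", i, " failed: ", conditionMessage(e),
                call. = FALSE)
        rep(NA_real_, grid$n_times)
      }
    )
  }
  structure(list(cells = grid$cells, times = times_out, values = vals,
                 grid = grid),
            class = "sweep_result")
}

sweep_cell <- function(grid, params, times_out) {
  cp <- grid$coupling
  for (nm in names(params)) cp[[nm]] <- params[[nm]]
  cp <- feedback_coupling(cp$gamma0, cp$tau, cp$phi, cp$delta0, cp$omega0)
  if (grid$mode == "dimer") {
    init <- if (is.null(grid$c_init)) c(1 + 0i, 0 + 0i) else grid$c_init
    traj <- solve_dimer(cp, c_init = init, t_max = grid$t_max, dt = grid$dt)
  } else {
    init <- if (is.null(grid$c_init)) 1 + 0i else grid$c_init
    traj <- solve_amplitude(cp, c_init = init, t_max = grid$t_max,
                            dt = grid$dt)
  }
  series <- switch(grid$observable,
    population = population(traj, grid$site),
    coherence = coherence(traj)
  )
  stats::approx(series$t, series$value, xout = times_out, rule = 2)$y
}

#' @export
as.data.frame.sweep_result <- function(x, ...) {
  n_cells <- nrow(x$cells)
  n_t <- length(x$times)
  long <- x$cells[rep(seq_len(n_cells), each = n_t), , drop = FALSE]
  long$t <- rep(x$times, times = n_cells)
  long$value <- as.vector(t(x$values))
  rownames(long) <- NULL
  long
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Sweep over {%s}: %d cells x %d times, observable '%s'\n",
              paste(names(x$cells), collapse = ", "), nrow(x$cells),
              length(x$times), x$grid$observable))
  invisible(x)
}

#' Write a sweep result in long format
#'
#' One CSV row per grid cell per output time, plus a JSON metadata sidecar.
#'
#' @param result A `sweep_result`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  g <- result$grid
  jsonlite::write_json(
    list(observable = g$observable, mode = g$mode, t_max = g$t_max,
         dt = g$dt, n_times = g$n_times, axes = g$axes,
         coupling = unclass(g$coupling)),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
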