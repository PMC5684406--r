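#' Amplitude trajectory container
#'
#' Holds a solved excitation-amplitude trajectory: a strictly increasing time
#' grid starting at 0 (fs) and a complex amplitude matrix with one column per
#' site component (1 for the scalar model, 2 for the dimer mode), plus the
#' coupling and solver settings it was produced with.
#'
#' @param times Numeric vector, strictly increasing, starting at 0.
#' @param amplitudes Complex matrix, `length(times)` rows.
#' @param coupling The [feedback_coupling()] used (may be `NULL` for generic
#'   site systems).
#' @param mode Character tag: `"scalar"`, `"dimer"` or `"volterra"`.
#' @param solver Named list of solver settings.
#' @return Object of class `"amplitude_trajectory"`.
#' @export
amplitude_trajectory <- function(times, amplitudes, coupling = NULL,
                                 mode = "scalar", solver = list()) {
  amplitudes <- as.matrix(amplitudes)
  storage.mode(amplitudes) <- "complex"
  if (length(times) != nrow(amplitudes)) {
    stop("times and amplitudes disagree in length", call. = FALSE)
  }
  if (times[1] != 0 || any(diff(times) <= 0)) {
    stop("times must be strictly increasing and start at 0", call. = FALSE)
  }
  structure(
    list(times = times, amplitudes = amplitudes, coupling = coupling,
         mode = mode, solver = solver),
    class = "amplitude_trajectory"
  )
}

n_components <- function(traj) ncol(traj$amplitudes)

#' @export
print.amplitude_trajectory <- function(x, ...) {
  cat(sprintf("Amplitude trajectory [%s mode], %d components, %d points, t in [0, %g] fs\n",
              x$mode, n_components(x), length(x$times), max(x$times)))
  cat(sprintf("  final |c| per component: %s\n",
              paste(sprintf("%.6g", abs(x$amplitudes[nrow(x$amplitudes), ])),
                    collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.amplitude_trajectory <- function(x, ...) {
  out <- data.frame(t = x$times)
  for (j in seq_len(n_components(x))) {
    out[[paste0("re_c", j)]] <- Re(x$amplitudes[, j])
    out[[paste0("im_c", j)]] <- Im(x$amplitudes[, j])
  }
  out
}

#' Write / read a trajectory as CSV plus JSON metadata sidecar
#'
#' The CSV holds `t` and `re_c<j>`, `im_c<j>` columns; the sidecar
#' (`<path>.meta.json`) records the coupling parameters, solver settings and
#' mode so the run can be reconstructed.
#'
#' @param traj An [amplitude_trajectory()].
#' @param path CSV file path.
#' @param extra Optional named list merged into the sidecar (e.g. a seed).
#' @return `write_trajectory()` returns `path` invisibly; `read_trajectory()`
#'   returns the reconstructed [amplitude_trajectory()].
#' @export
write_trajectory <- function(traj, path, extra = list()) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  meta <- c(list(
    mode = traj$mode,
    coupling = if (!is.null(traj$coupling)) unclass(traj$coupling),
    solver = traj$solver,
    n_components = n_components(traj)
  ), extra)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  ncomp <- meta$n_components
  amps <- sapply(seq_len(ncomp), function(j) {
    complex(real = df[[paste0("re_c", j)]],
            imaginary = df[[paste0("im_c", j)]])
  })
  coupling <- NULL
  if (!is.null(meta$coupling)) {
    coupling <- feedback_coupling(meta$coupling$gamma0, meta$coupling$tau,
                                  meta$coupling$phi, meta$coupling$delta0,
                                  meta$coupling$omega0)
  }
  amplitude_trajectory(df$t, as.matrix(amps), coupling = coupling,
                       mode = meta$mode, solver = as.list(meta$solver))
}

sidecar_path <- function(path) paste0(path, ".meta.json")
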