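#' @export
print.csc_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("<csc_trajectory>  %d steps of %.4g y on [%.4g, %.4g]\n",
              n - 1L, x$dt, x$times[1], x$times[n]))
  if (!is.null(x$therapy)) {
    cat(sprintf("  therapy: %s, R_imm = %.4g, on from t = %.4g y\n",
                x$therapy$sched$times$name, x$therapy$R_imm,
                x$therapy$t_start))
  } else {
    cat("  therapy-free\n")
  }
  cat(sprintf("  final state: S = %.4g, D = %.4g, a = %.4g, m = %.4g\n",
              x$states[n, 1], x$states[n, 2], x$states[n, 3], x$states[n, 4]))
  invisible(x)
}

#' @export
summary.csc_trajectory <- function(object, ...) {
  st <- object$states
  out <- data.frame(
    component = colnames(st),
    initial = st[1, ],
    final = st[nrow(st), ],
    min = apply(st, 2, min),
    max = apply(st, 2, max),
    t_max = object$times[apply(st, 2, which.max)],
    row.names = NULL
  )
  class(out) <- c("summary.csc_trajectory", "data.frame")
  out
}

#' @export
as.data.frame.csc_trajectory <- function(x, ...) {
  data.frame(t_year = x$times, S = x$states[, "S"], D = x$states[, "D"],
             a = x$states[, "a"], m = x$states[, "m"])
}

#' @export
plot.csc_trajectory <- function(x, which = c("S", "D", "a", "m"),
                                log = "", ...) {
  which <- match.arg(which, several.ok = TRUE)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(which)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  labs <- c(S = "CSC concentration", D = "DC concentration",
            a = "Wnt-beta-catenin", m = "microRNA")
  for (w in which) {
    graphics::plot(x$times, x$states[, w], type = "l", log = log,
                   xlab = "time [year]", ylab = labs[[w]], main = w, ...)
    if (!is.null(x$therapy) && is.finite(x$therapy$t_start)) {
      graphics::abline(v = x$therapy$t_start, lty = 2, col = "grey40")
    }
  }
  invisible(x)
}

#' Write / read a trajectory as a tidy CSV with a JSON sidecar
#'
#' The CSV holds `t_year, S, D, a, m` at full double precision; the sidecar
#' `<file>.json` records the resolved parameters, therapy and solver
#' settings so that every number is recomputable.  The reader restores the
#' numeric content bit-exactly.
#'
#' @param traj a `csc_trajectory`.
#' @param file CSV path.
#' @return `write_trajectory()` returns `file` invisibly;
#'   `read_trajectory()` returns a list with `data` (data.frame) and
#'   `meta` (list).
#' @export
write_trajectory <- function(traj, file) {
  df <- as.data.frame(traj)
  num <- vapply(df, function(col) sprintf("%.17g", col),
                character(nrow(df)))
  utils::write.table(num, file, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = names(df))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    meta <- list(
      params = unclass(traj$params),
      dt = traj$dt, t0 = traj$t0,
      therapy = if (is.null(traj$therapy)) NULL else list(
        radionuclide = traj$therapy$sched$times$name,
        r0_gy_per_day = traj$therapy$sched$r0,
        t_start = traj$therapy$t_start,
        R_imm = traj$therapy$R_imm,
        mode = traj$therapy$mode
      )
    )
    jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(file)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(file) {
  data <- utils::read.csv(file)
  meta <- if (file.exists(paste0(file, ".json")) &&
              requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  } else NULL
  list(data = data, meta = meta)
}
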