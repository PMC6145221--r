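# Intermittent-drying schedules, the intermittency ratio, and
# total-versus-operating time accounting.

#' Intermittency of a drying/tempering cycle
#'
#' The fraction of a cycle spent actively drying,
#' \deqn{\alpha = t_D / (t_D + t_T).}
#' Continuous drying (`t_T = 0`) has `alpha = 1`.
#'
#' @param t_D Drying period duration per cycle, s (strictly positive).
#' @param t_T Tempering period duration per cycle, s (non-negative).
#' @return The intermittency, a number in (0, 1].
#' @examples
#' intermittency(600, 1800)   # 0.25
#' intermittency(1200, 1800)  # 0.4
#' @export
intermittency <- function(t_D, t_T) {
  if (!is.numeric(t_D) || length(t_D) != 1L || !is.finite(t_D) || t_D <= 0)
    stop("`t_D` must be a single positive duration in s", call. = FALSE)
  if (!is.numeric(t_T) || length(t_T) != 1L || !is.finite(t_T) || t_T < 0)
    stop("`t_T` must be a single non-negative duration in s", call. = FALSE)
  t_D / (t_D + t_T)
}

#' A single drying or tempering phase
#'
#' @param kind `"drying"` or `"tempering"`.
#' @param duration Phase duration, s (strictly positive).
#' @param ambient The [ambient_state()] during the phase.
#' @return An object of class `"schedule_phase"`.
#' @export
schedule_phase <- function(kind, duration, ambient) {
  kind <- match.arg(kind, c("drying", "tempering"))
  if (!is.numeric(duration) || length(duration) != 1L ||
      !is.finite(duration) || duration <= 0)
    stop("`duration` must be a single positive duration in s", call. = FALSE)
  stopifnot(inherits(ambient, "ambient_state"))
  structure(list(kind = kind, duration = duration, ambient = ambient),
            class = "schedule_phase")
}

#' Ordered drying/tempering schedule
#'
#' @param phases A list of [schedule_phase()] objects (possibly empty;
#'   a zero-duration schedule simulates to just the initial state).
#' @param t_D,t_T Optional periodic cycle definition carried along for
#'   bookkeeping (set by [build_periodic_schedule()]).
#' @return An object of class `"drying_schedule"`.
#' @export
drying_schedule <- function(phases, t_D = NULL, t_T = NULL) {
  if (!is.list(phases) ||
      !all(vapply(phases, inherits, logical(1), "schedule_phase")))
    stop("`phases` must be a (possibly empty) list of schedule_phase objects",
         call. = FALSE)
  structure(list(phases = phases, t_D = t_D, t_T = t_T),
            class = "drying_schedule")
}

#' @export
print.drying_schedule <- function(x, ...) {
  n <- length(x$phases)
  tot <- sum(vapply(x$phases, `[[`, numeric(1), "duration"))
  cat(sprintf("<drying_schedule> %d phase(s), total %.0f s", n, tot))
  if (!is.null(x$t_D)) {
    a <- intermittency(x$t_D, x$t_T)
    cat(sprintf(" (periodic t_D = %.0f s, t_T = %.0f s, alpha = %.3g)",
                x$t_D, x$t_T, a))
  }
  cat("\n")
  if (n > 0) {
    kinds <- vapply(x$phases, `[[`, character(1), "kind")
    durs <- vapply(x$phases, `[[`, numeric(1), "duration")
    cat("  ", paste(sprintf("%s[%.0fs]", substr(kinds, 1, 1), durs),
                    collapse = " "), "\n")
  }
  invisible(x)
}

#' Intermittency of a schedule
#'
#' For a periodic schedule, `t_D / (t_D + t_T)`; for a bare phase list,
#' the ratio of total drying time to total schedule time.
#'
#' @param schedule A [drying_schedule()].
#' @return The intermittency in (0, 1].
#' @export
schedule_alpha <- function(schedule) {
  stopifnot(inherits(schedule, "drying_schedule"))
  if (!is.null(schedule$t_D)) return(intermittency(schedule$t_D, schedule$t_T))
  kinds <- vapply(schedule$phases, `[[`, character(1), "kind")
  durs <- vapply(schedule$phases, `[[`, numeric(1), "duration")
  sum(durs[kinds == "drying"]) / sum(durs)
}

#' Build a periodic drying/tempering schedule
#'
#' Alternating phases starting with drying (matching the experimental
#' protocol), truncated at `max_total` seconds; a truncation mid-phase
#' shortens that phase. `t_T = 0` yields a single continuous drying phase
#' of `max_total` seconds.
#'
#' @param t_D Drying duration per cycle, s.
#' @param t_T Tempering duration per cycle, s (0 for continuous drying).
#' @param drying_ambient,tempering_ambient [ambient_state()]s of the two
#'   phase kinds.
#' @param max_total Total schedule length, s (must be at least `t_D`).
#' @return A [drying_schedule()].
#' @examples
#' sch <- build_periodic_schedule(600, 1800, drying_ambient(),
#'                                tempering_ambient(), max_total = 4800)
#' schedule_alpha(sch)  # 0.25
#' @export
build_periodic_schedule <- function(t_D, t_T, drying_ambient,
                                    tempering_ambient = NULL, max_total) {
  alpha <- intermittency(t_D, t_T)  # validates the durations
  if (!is.numeric(max_total) || length(max_total) != 1L || max_total < t_D)
    stop("`max_total` must be at least `t_D` = ", t_D, " s", call. = FALSE)
  if (t_T > 0 && is.null(tempering_ambient))
    stop("`tempering_ambient` is required when t_T > 0", call. = FALSE)
  if (t_T == 0)
    return(drying_schedule(list(schedule_phase("drying", max_total,
                                               drying_ambient)),
                           t_D = t_D, t_T = 0))
  phases <- list()
  t <- 0
  repeat {
    for (ph in list(c("drying", t_D), c("tempering", t_T))) {
      dur <- min(as.numeric(ph[2]), max_total - t)
      if (dur <= 0) break
      amb <- if (ph[1] == "drying") drying_ambient else tempering_ambient
      phases[[length(phases) + 1L]] <- schedule_phase(ph[1], dur, amb)
      t <- t + dur
    }
    if (t >= max_total) break
  }
  drying_schedule(phases, t_D = t_D, t_T = t_T)
}

# data.frame of phase intervals: kind, t_start, t_end.
.phase_table <- function(schedule) {
  kinds <- vapply(schedule$phases, `[[`, character(1), "kind")
  durs <- vapply(schedule$phases, `[[`, numeric(1), "duration")
  ends <- cumsum(durs)
  data.frame(kind = kinds, t_start = c(0, head(ends, -1)), t_end = ends,
             stringsAsFactors = FALSE)
}

#' Total versus operating drying time to a moisture target
#'
#' Locates the first time a drying curve reaches a target moisture content
#' (linear interpolation in `X` between output samples, so the reported
#' time is not quantized to the output grid) and splits it into total
#' elapsed (wall-clock) time and operating time, i.e. cumulative
#' drying-phase (dryer-on) time up to the crossing. A crossing during a
#' tempering phase excludes the partial tempering time from the operating
#' total.
#'
#' @param curve A `drying_curve` (see [simulate_drying()] /
#'   [as_drying_curve()]).
#' @param X_target Target moisture content, kg/kg d.b.
#' @return A list with `total_elapsed` (s), `operating` (s) and the
#'   crossing time diagnostics.
#' @export
time_accounting <- function(curve, X_target) {
  stopifnot(inherits(curve, "drying_curve"))
  t <- curve$t_s; X <- curve$X_db
  # tolerate round-off at an integrator stop exactly on the target
  if (min(X) > X_target + 1e-9)
    stop(sprintf(
      "target X = %.4g kg/kg never reached: closest approach %.4g, final X = %.4g",
      X_target, min(X), X[length(X)]), call. = FALSE)
  i <- which(X <= X_target + 1e-9)[1]
  t_cross <- if (i == 1L) t[1] else {
    denom <- X[i - 1] - X[i]
    frac <- if (denom <= 0) 1 else
      min(1, max(0, (X[i - 1] - X_target) / denom))
    t[i - 1] + (t[i] - t[i - 1]) * frac
  }
  pt <- attr(curve, "phase_table")
  if (is.null(pt)) {  # derive intervals from sample labels
    ph <- curve$phase
    brk <- which(ph[-1] != ph[-length(ph)])
    # a boundary sample closes the old phase, so the switch time is the
    # last sample carrying the outgoing label
    starts <- c(t[1], t[brk])
    ends <- c(t[brk], t[length(t)])
    pt <- data.frame(kind = ph[c(1, brk + 1)], t_start = starts, t_end = ends,
                     stringsAsFactors = FALSE)
  }
  dry <- pt[pt$kind == "drying", , drop = FALSE]
  operating <- sum(pmax(0, pmin(dry$t_end, t_cross) - pmin(dry$t_start, t_cross)))
  list(total_elapsed = t_cross, operating = operating, X_target = X_target)
}
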