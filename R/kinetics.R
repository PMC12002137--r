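#' Build a single-cycle injection schedule
#'
#' Contiguous analyte injections of increasing concentration followed by a
#' final dissociation window, the layout of single-cycle kinetics. Defaults
#' follow standard instrument practice: 120 s per injection and 600 s final
#' dissociation.
#'
#' @param concentrations molar analyte concentrations (sorted ascending).
#' @param t_inj injection duration, seconds.
#' @param t_diss final dissociation duration, seconds.
#' @param t0 time of the first injection start.
#' @return data.frame (t_start, t_end, conc) of injection steps; attribute
#'   `t_total` holds the span end including dissociation.
#' @export
spr_schedule <- function(concentrations, t_inj = 120, t_diss = 600,
                         t0 = 0) {
  if (any(concentrations <= 0)) stop_input("concentrations must be positive")
  conc <- sort(concentrations)
  n <- length(conc)
  sched <- data.frame(t_start = t0 + (seq_len(n) - 1) * t_inj,
                      t_end = t0 + seq_len(n) * t_inj,
                      conc = conc)
  attr(sched, "t_total") <- t0 + n * t_inj + t_diss
  sched
}

validate_schedule <- function(schedule) {
  need <- c("t_start", "t_end", "conc")
  if (!all(need %in% names(schedule)))
    stop_input("schedule needs columns t_start, t_end, conc")
  if (any(schedule$t_start >= schedule$t_end))
    stop_input("schedule steps must have t_start < t_end")
  s <- schedule[order(schedule$t_start), ]
  if (nrow(s) > 1L && any(s$t_start[-1] < s$t_end[-nrow(s)]))
    stop_input("schedule steps must not overlap")
  s
}

#' Closed-form 1:1 Langmuir response
#'
#' Piecewise analytic solution of `dR/dt = kon * C * (rmax - R) - koff * R`
#' on a time grid: during an injection at concentration `C` the response
#' relaxes exponentially towards `Req = kon C rmax / (kon C + koff)` with
#' rate `kon C + koff`; between and after injections it decays as
#' `exp(-koff t)`. The response is continuous across step boundaries and
#' starts at 0 at the beginning of the grid.
#'
#' @param time numeric vector, strictly increasing.
#' @param kon association rate, 1/(M s); @param koff dissociation rate,
#'   1/s; @param rmax saturation response, RU.
#' @param schedule injection steps as from [spr_schedule()].
#' @return numeric response vector (RU).
#' @export
spr_model_response <- function(time, kon, koff, rmax, schedule) {
  schedule <- validate_schedule(schedule)
  bounds <- sort(unique(c(time[1], schedule$t_start, schedule$t_end)))
  bounds <- bounds[bounds >= time[1]]
  resp <- numeric(length(time))
  r0 <- 0; t0 <- time[1]
  conc_at <- function(t) {
    hit <- schedule$conc[schedule$t_start <= t & t < schedule$t_end]
    if (length(hit)) hit[1] else 0
  }
  segment_starts <- bounds
  segment_ends <- c(bounds[-1], max(time[length(time)],
                                    bounds[length(bounds)]) + 1)
  for (s in seq_along(segment_starts)) {
    a <- segment_starts[s]; b <- segment_ends[s]
    inside <- time >= a & time < b
    if (s == length(segment_starts)) inside <- time >= a
    C <- conc_at(a)
    if (C > 0) {
      kobs <- kon * C + koff
      req <- kon * C * rmax / kobs
      if (any(inside))
        resp[inside] <- req + (r0 - req) * exp(-kobs * (time[inside] - a))
      r0 <- req + (r0 - req) * exp(-kobs * (b - a))
    } else {
      if (any(inside))
        resp[inside] <- r0 * exp(-koff * (time[inside] - a))
      r0 <- r0 * exp(-koff * (b - a))
    }
  }
  resp
}

#' Simulate a single-cycle SPR sensorgram
#'
#' Evaluates the closed-form 1:1 model on a regular grid spanning the
#' schedule plus dissociation and adds independent Gaussian noise.
#'
#' @inheritParams spr_model_response
#' @param noise_sd additive Gaussian noise, RU.
#' @param times optional explicit grid; default 2 s spacing across the
#'   schedule span.
#' @return object of class `spr_trace`: list(time, response, schedule,
#'   noise_sd); consumes the current RNG stream when `noise_sd > 0`.
#' @export
simulate_sck_trace <- function(kon, koff, rmax, schedule, noise_sd = 0,
                               times = NULL) {
  if (kon <= 0 || koff <= 0 || rmax <= 0)
    stop_input("kon, koff and rmax must be positive")
  schedule <- validate_schedule(schedule)
  if (is.null(times)) {
    t_end <- attr(schedule, "t_total")
    if (is.null(t_end)) t_end <- max(schedule$t_end) + 600
    times <- seq(min(schedule$t_start), t_end, by = 2)
  }
  resp <- spr_model_response(times, kon, koff, rmax, schedule)
  if (noise_sd > 0) resp <- resp + stats::rnorm(length(times), 0, noise_sd)
  structure(list(time = times, response = resp, schedule = schedule,
                 noise_sd = noise_sd),
            class = "spr_trace")
}

#' @export
print.spr_trace <- function(x, ...) {
  cat("Single-cycle SPR trace:", length(x$time), "points,",
      nrow(x$schedule), "injections, noise sd", x$noise_sd, "RU\n")
  invisible(x)
}

#' @export
plot.spr_trace <- function(x, ...) {
  plot(x$time, x$response, type = "l", xlab = "time (s)",
       ylab = "response (RU)", ...)
  abline(v = c(x$schedule$t_start, x$schedule$t_end), col = "grey80",
         lty = 3)
  invisible(x)
}

#' Fit the 1:1 Langmuir model to a single-cycle sensorgram
#'
#' Nonlinear least squares of the piecewise closed-form model against the
#' trace, parameterised in (log10 kon, log10 koff, log10 rmax) because
#' affinities span many orders of magnitude and single-start fits in
#' natural parameters are initialisation-sensitive. Levenberg-Marquardt
#' (via [minpack.lm::nls.lm()]) is run from a log-spaced multi-start grid
#' (kon 1e3-1e7, koff 1e-5-1e-1 by default) and the best run is kept.
#' `converged` is `FALSE` when the best residual RMS exceeds five times the
#' noise-floor estimate (the trace's known noise SD, or a
#' difference-based robust estimate).
#'
#' @param trace an `spr_trace` (or list with `time`, `response`,
#'   `schedule`).
#' @param kon_starts,koff_starts multi-start grids.
#' @param baseline if `TRUE`, a linear baseline drift nuisance term is
#'   co-fitted (for traces not perfectly double-referenced).
#' @return object of class `spr_fit` with fields kon, koff, rmax,
#'   kd (= koff/kon exactly), residual_rms, converged; supports `print`,
#'   `summary`, `coef`, `predict`, `residuals`, `fitted` and `plot`.
#' @export
fit_1to1 <- function(trace, kon_starts = 10^seq(3, 7, by = 2),
                     koff_starts = 10^seq(-5, -1, by = 2),
                     baseline = FALSE) {
  if (nrow(trace$schedule) < 2L)
    stop_input("single-cycle fit needs at least 2 injection steps")
  rng <- diff(range(trace$response))
  if (rng == 0) stop_input("degenerate trace: zero dynamic range")
  time <- trace$time; resp <- trace$response
  schedule <- validate_schedule(trace$schedule)

  model_fn <- function(par) {
    m <- spr_model_response(time, 10^par[1], 10^par[2], 10^par[3], schedule)
    if (baseline) m <- m + par[4] + par[5] * (time - time[1])
    m
  }
  resid_fn <- function(par) resp - model_fn(par)

  rmax0 <- log10(max(max(resp), rng) * 1.2)
  best <- NULL
  for (k1 in kon_starts) for (k2 in koff_starts) {
    start <- c(log10(k1), log10(k2), rmax0)
    if (baseline) start <- c(start, 0, 0)
    fit <- tryCatch(minpack.lm::nls.lm(
      par = start, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(fit$fvec^2)
    if (is.null(best) || ss < best$ss) best <- list(fit = fit, ss = ss)
  }
  if (is.null(best)) stop_input("all fit starts failed")
  par <- best$fit$par
  rms <- sqrt(best$ss / length(resp))
  noise_floor <- if (!is.null(trace$noise_sd) && !is.na(trace$noise_sd) &&
                     trace$noise_sd > 0) trace$noise_sd
  else max(stats::mad(diff(resp)) / sqrt(2), 1e-6 * rng)
  kon <- 10^par[1]; koff <- 10^par[2]
  structure(list(kon = kon, koff = koff, rmax = 10^par[3],
                 kd = koff / kon, residual_rms = rms,
                 converged = rms <= 5 * noise_floor,
                 baseline = if (baseline) par[4:5] else NULL,
                 par = par, trace = trace, n_obs = length(resp)),
            class = "spr_fit")
}

#' @export
print.spr_fit <- function(x, ...) {
  cat("1:1 Langmuir kinetics fit\n")
  cat(sprintf("  kon  = %.4g 1/(M s)\n  koff = %.4g 1/s\n", x$kon, x$koff))
  cat(sprintf("  KD   = %.4g M\n  Rmax = %.4g RU\n", x$kd, x$rmax))
  cat(sprintf("  residual RMS %.4g RU over %d points; converged: %s\n",
              x$residual_rms, x$n_obs, x$converged))
  invisible(x)
}

#' @export
summary.spr_fit <- function(object, ...) {
  out <- c(coef(object),
           residual_rms = object$residual_rms,
           n_obs = object$n_obs, converged = as.numeric(object$converged))
  class(out) <- "summary.spr_fit"
  out
}

#' @export
print.summary.spr_fit <- function(x, ...) {
  print(unclass(x)); invisible(x)
}

#' @export
coef.spr_fit <- function(object, ...) {
  c(kon = object$kon, koff = object$koff, rmax = object$rmax,
    kd = object$kd)
}

#' @export
predict.spr_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$trace$time
  m <- spr_model_response(times, object$kon, object$koff, object$rmax,
                          object$trace$schedule)
  if (!is.null(object$baseline))
    m <- m + object$baseline[1] +
      object$baseline[2] * (times - object$trace$time[1])
  m
}

#' @export
fitted.spr_fit <- function(object, ...) predict(object)

#' @export
residuals.spr_fit <- function(object, ...)
  object$trace$response - fitted(object)

#' @export
plot.spr_fit <- function(x, ...) {
  plot(x$trace, ...)
  graphics::lines(x$trace$time, fitted(x), col = "red")
  invisible(x)
}

#' @importFrom stats coef fitted predict residuals
#' @importFrom graphics abline
NULL

#' Endpoint of a titration series
#'
#' First-crossing rule: the endpoint is the largest dilution whose signal
#' stays at or above `threshold`, requiring every smaller dilution to do so
#' too. A series whose starting dilution is already below threshold has no
#' endpoint. A signal that re-crosses the threshold after first falling
#' below it still yields the first-crossing endpoint, flagged as
#' non-monotone.
#'
#' @param dilutions strictly increasing dilution factors.
#' @param signals assay signals, one per dilution.
#' @param threshold positivity cutoff on the signal scale.
#' @return list with `endpoint` (dilution, or `NA` for none) and
#'   `non_monotone` flag.
#' @export
endpoint_dilution <- function(dilutions, signals, threshold) {
  if (length(dilutions) != length(signals))
    stop_input("dilutions and signals must have equal length")
  if (any(diff(dilutions) <= 0))
    stop_input("dilutions must be strictly increasing")
  pos <- signals >= threshold
  if (!pos[1]) return(list(endpoint = NA_real_, non_monotone = FALSE))
  first_neg <- which(!pos)[1]
  if (is.na(first_neg))
    return(list(endpoint = dilutions[length(dilutions)],
                non_monotone = FALSE))
  flag <- any(pos[first_neg:length(pos)])
  if (flag)
    warning("signal re-crosses threshold after first falling below it",
            call. = FALSE)
  list(endpoint = dilutions[first_neg - 1L], non_monotone = flag)
}
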