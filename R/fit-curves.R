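# G-V / F-V construction, Boltzmann fits, photobleach correction, and
# scalar trace measurements (tail amplitudes, Rb/K ratio, percent
# increase).

#' Iso-chronal tail-current amplitude
#'
#' The standard measurement rule: the mean current over a short window
#' after repolarization, skipping a blanking interval that would hold
#' the capacitive transient in a real recording.
#'
#' @param trace a [qk_trace()] (full sweep).
#' @param tail_start_ms time of the repolarizing step in ms.
#' @param blank blanking interval after the step (default 2 ms).
#' @param window averaging window length (default 5 ms).
#' @return Mean current in the window (signed).
#' @export
tail_amplitude <- function(trace, tail_start_ms, blank = 2, window = 5) {
  seg <- slice_trace(trace, tail_start_ms + blank,
                     tail_start_ms + blank + window, rezero = FALSE)
  mean(seg$value)
}

tail_start_of <- function(protocol) {
  d <- protocol$epochs$duration_ms
  sum(d[-length(d)])
}

#' Build a conductance-voltage (G-V) curve from a trace family
#'
#' For each member of a voltage-step family ending in a common tail
#' epoch, the conductance index is the iso-chronal tail-current
#' amplitude (fixed tail voltage means a fixed driving force, so the
#' tail amplitude is proportional to the conductance at the end of the
#' test pulse).
#'
#' @param traces list of [qk_trace()], one per step voltage.
#' @param family the [qk_family()] that generated them (swept step
#'   voltage; the last epoch must be the shared tail).
#' @param blank,window tail measurement rule, see [tail_amplitude()].
#' @param normalize divide by the maximum (default TRUE).
#' @return An object of class `qk_curve`: data.frame with `x` (step mV)
#'   and `y` (conductance index), attribute `normalized`.
#' @export
build_gv <- function(traces, family, blank = 2, window = 5,
                     normalize = TRUE) {
  stopifnot(inherits(family, "qk_family"))
  prots <- protocols(family)
  if (length(traces) != length(prots)) stop("trace/protocol count mismatch")
  if (family$epoch == nrow(family$base$epochs))
    stop("swept epoch is the tail epoch; family must end in a fixed tail")
  g <- mapply(function(tr, pr) tail_amplitude(tr, tail_start_of(pr),
                                              blank, window),
              traces, prots)
  new_curve(x = family$values, y = g, normalize = normalize)
}

new_curve <- function(x, y, normalize) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  if (any(diff(x) <= 0)) stop("x values must be distinct")
  if (!all(is.finite(y))) stop("curve values must be finite")
  if (normalize) {
    if (max(abs(y)) == 0) stop("cannot normalize an all-zero curve")
    y <- y / max(abs(y))
  }
  structure(data.frame(x = x, y = y), class = c("qk_curve", "data.frame"),
            normalized = normalize)
}

#' Build a fluorescence-voltage (F-V) curve
#'
#' y(v) is the delta-F/F value at the end of each test pulse (mean over
#' the final `avg_ms`), normalized to the family maximum.  Traces should
#' be photobleach-corrected first (see [debleach()]).
#'
#' @param traces list of (debleached) fluorescence [qk_trace()].
#' @param family the generating [qk_family()] (swept test-pulse
#'   voltage).
#' @param avg_ms averaging window at the end of the test pulse
#'   (default 10 ms).
#' @param normalize divide by the family maximum (default TRUE).
#' @return A `qk_curve`.
#' @export
build_fv <- function(traces, family, avg_ms = 10, normalize = TRUE) {
  stopifnot(inherits(family, "qk_family"))
  prots <- protocols(family)
  if (length(traces) == 0) stop("empty family")
  if (length(traces) != length(prots)) stop("trace/protocol count mismatch")
  ends <- vapply(prots, function(pr)
    sum(pr$epochs$duration_ms[seq_len(family$epoch)]), numeric(1))
  f <- mapply(function(tr, tend)
    mean(slice_trace(tr, tend - avg_ms, tend, rezero = FALSE)$value),
    traces, ends)
  new_curve(x = family$values, y = f, normalize = normalize)
}

#' Fit one or two Boltzmann components to a G-V or F-V curve
#'
#' The Boltzmann component is B(V) = 1 / (1 + exp(-zF(V - V1/2)/RT))
#' with z the equivalent valence and V1/2 the half-activation voltage;
#' F and R are the Faraday and gas constants and T defaults to 295.15 K
#' (room temperature).  A single component is fitted as
#' y = w * B(V; V1/2, z); a double fit is the weighted sum of two
#' components (the standard description of stepwise VSD activation in
#' F-V curves).  Deterministic multi-start initialization; components
#' are reported in ascending V1/2 order.
#'
#' @param curve a `qk_curve` (or data.frame with `x` in mV, `y`).
#' @param n_components 1 or 2.
#' @param Tkelvin absolute temperature (default 295.15 K).
#' @return An object of class `qk_boltzmann`: `components` (data.frame
#'   `V12`, `z`, `weight`), `residual`, `Tkelvin`.
#' @export
fit_boltzmann <- function(curve, n_components = 1, Tkelvin = 295.15) {
  stopifnot(n_components %in% 1:2)
  x <- curve$x; y <- curve$y
  if (n_components == 1 && length(x) < 5) stop("need >= 5 points")
  if (n_components == 2 && length(x) < 8) stop("need >= 8 points")
  check_not_flat(y)
  s0 <- 1000 * 8.31446261815324 * Tkelvin / 96485.33212  # RT/F in mV
  B <- function(v, V12, z) stats::plogis(z * (v - V12) / s0)
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  dat <- data.frame(v = x, y = y)
  if (n_components == 1) {
    grid <- expand.grid(V12 = qs, z = c(0.8, 2, 3.5))
    fits <- lapply(seq_len(nrow(grid)), function(i)
      fit_or_null(y ~ w * B(v, V12, z), dat,
                  list(w = max(abs(y)), V12 = grid$V12[i], z = grid$z[i]),
                  lower = c(w = 1e-12, V12 = -Inf, z = 1e-3)))
    fit <- pick_best(fits, "z")
    if (is.null(fit)) stop("Boltzmann fit did not converge from any start")
    cf <- stats::coef(fit)
    comp <- data.frame(V12 = cf[["V12"]], z = cf[["z"]], weight = cf[["w"]])
  } else {
    sep <- diff(range(x)) / 4
    grid <- expand.grid(V1 = qs[1] + c(-sep / 2, 0), z0 = c(1, 2.5))
    fits <- lapply(seq_len(nrow(grid)), function(i)
      fit_or_null(y ~ w1 * B(v, V1, z1) + w2 * B(v, V2, z2), dat,
                  list(w1 = max(abs(y)) / 2, w2 = max(abs(y)) / 2,
                       V1 = grid$V1[i], V2 = grid$V1[i] + sep,
                       z1 = grid$z0[i], z2 = grid$z0[i]),
                  lower = c(w1 = 1e-12, w2 = 1e-12, V1 = -Inf, V2 = -Inf,
                            z1 = 1e-3, z2 = 1e-3)))
    fit <- pick_best(fits, "z1")
    if (is.null(fit))
      stop("double-Boltzmann fit did not converge from any start")
    cf <- stats::coef(fit)
    comp <- data.frame(V12 = c(cf[["V1"]], cf[["V2"]]),
                       z = c(cf[["z1"]], cf[["z2"]]),
                       weight = c(cf[["w1"]], cf[["w2"]]))
    comp <- comp[order(comp$V12), ]
    rownames(comp) <- NULL
  }
  structure(list(components = comp, residual = sqrt(stats::deviance(fit)),
                 Tkelvin = Tkelvin, n_components = n_components),
            class = "qk_boltzmann")
}

#' @export
print.qk_boltzmann <- function(x, ...) {
  cat("<qk_boltzmann>", x$n_components, "component(s), T =", x$Tkelvin, "K\n")
  for (i in seq_len(nrow(x$components)))
    cat(sprintf("  V1/2 = %.3g mV, z = %.3g, weight = %.3g\n",
                x$components$V12[i], x$components$z[i],
                x$components$weight[i]))
  invisible(x)
}

#' Photobleach baseline correction of a fluorescence trace
#'
#' Fits a baseline (linear by default, single-exponential optional) to
#' the first `fit_ms` of the recorded holding segment, extrapolates it
#' over the whole trace and subtracts it, so the corrected holding
#' segment has mean ~0 and the physiological signal is preserved.
#'
#' @param trace a fluorescence [qk_trace()] starting with a holding
#'   segment of at least `fit_ms`.
#' @param fit_ms length of the baseline fitting window (default
#'   2000 ms).
#' @param method `"linear"` or `"exponential"`.
#' @return A corrected [qk_trace()] (meta gains `debleached = TRUE`).
#' @export
debleach <- function(trace, fit_ms = 2000, method = c("linear",
                                                      "exponential")) {
  method <- match.arg(method)
  stopifnot(inherits(trace, "qk_trace"))
  if (max(trace$time) - min(trace$time) < fit_ms)
    stop("holding segment shorter than the baseline window")
  t <- trace$time; y <- trace$value
  sel <- t <= t[1] + fit_ms
  if (sum(sel) < 10) stop("too few samples in the baseline window")
  base <- if (method == "linear") {
    cf <- stats::coef(stats::lm(y[sel] ~ t[sel]))
    cf[1] + cf[2] * t
  } else {
    dat <- data.frame(tt = t[sel] - t[1], yy = y[sel])
    fit <- fit_or_null(yy ~ y0 + Bamp * exp(-tt / taub), dat,
                       list(y0 = y[sel][sum(sel)],
                            Bamp = y[1] - y[sel][sum(sel)],
                            taub = fit_ms / 2),
                       lower = c(y0 = -Inf, Bamp = -Inf, taub = 1e-3))
    if (is.null(fit)) stop("exponential baseline fit did not converge")
    cf <- stats::coef(fit)
    cf[["y0"]] + cf[["Bamp"]] * exp(-(t - t[1]) / cf[["taub"]])
  }
  out <- y - base
  qk_trace(t, out, c(trace$meta, list(debleached = TRUE,
                                      debleach_method = method)))
}

#' Rb+/K+ permeability ratio from tail-current amplitudes
#'
#' Ratio of iso-chronal tail-current amplitudes recorded under the same
#' protocol in 100 mM Rb+ versus 100 mM K+ external solution (same
#' measurement rule as [build_gv()]).  The ratio differs between the
#' two open states, so it reports the IO/AO composition of the
#' conducting channels.
#'
#' @param trace_rb,trace_k [qk_trace()] full sweeps in the two
#'   solutions.
#' @param tail_start_ms time of the repolarizing step.
#' @param blank,window measurement rule, see [tail_amplitude()].
#' @return Scalar ratio (Rb over K, positive).
#' @export
rb_k_ratio <- function(trace_rb, trace_k, tail_start_ms, blank = 2,
                       window = 5) {
  if (length(trace_rb$time) != length(trace_k$time) ||
      max(abs(trace_rb$time - trace_k$time)) > 1e-9)
    stop("traces must share one protocol (identical time grids)")
  amp_k <- tail_amplitude(trace_k, tail_start_ms, blank, window)
  amp_rb <- tail_amplitude(trace_rb, tail_start_ms, blank, window)
  if (abs(amp_k) < 1e-300) stop("zero-amplitude K+ tail")
  abs(amp_rb) / abs(amp_k)
}

#' Percent current increase (drug vs control)
#'
#' 100 * (I_drug - I_ctrl) / I_ctrl at the measurement point, by default
#' the mean over the last `window_ms` before `t_end_ms` (end of the
#' depolarizing step).
#'
#' @param trace_ctrl,trace_drug [qk_trace()] under the same protocol.
#' @param t_end_ms end of the measurement epoch in ms (default: end of
#'   trace).
#' @param window_ms averaging window (default 100 ms).
#' @return Percent increase (can be negative).
#' @export
percent_increase <- function(trace_ctrl, trace_drug, t_end_ms = NULL,
                             window_ms = 100) {
  if (length(trace_ctrl$time) != length(trace_drug$time) ||
      max(abs(trace_ctrl$time - trace_drug$time)) > 1e-9)
    stop("traces must share one protocol (identical time grids)")
  t_end_ms <- t_end_ms %||% max(trace_ctrl$time)
  m <- function(tr) mean(slice_trace(tr, t_end_ms - window_ms,
                                     t_end_ms, rezero = FALSE)$value)
  ic <- m(trace_ctrl); id <- m(trace_drug)
  if (abs(ic) < 1e-300) stop("zero control current at the measurement point")
  100 * (id - ic) / ic
}
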