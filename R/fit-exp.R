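# Exponential fitting of activation and tail currents.
#
# All fitters use deterministic multi-start Levenberg-Marquardt
# (minpack.lm) with starts spanning tau decades; the best fit is chosen
# by lowest residual sum of squares, ties broken by lowest fast tau, and
# two-component results are relabelled so tau_f < tau_s.

fit_or_null <- function(formula, data, start, lower = NULL, upper = NULL) {
  tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      formula, data = data, start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 300))),
    error = function(e) NULL)
}

pick_best <- function(fits, tau_name = "tau1") {
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) return(NULL)
  rss <- vapply(fits, stats::deviance, numeric(1))
  best <- which(rss <= min(rss) * (1 + 1e-9))
  if (length(best) > 1) {
    taus <- vapply(fits[best], function(f) stats::coef(f)[[tau_name]],
                   numeric(1))
    best <- best[which.min(taus)]
  } else best <- best[1]
  fits[[best]]
}

check_not_flat <- function(y) {
  if (stats::sd(y) < 1e-12 * (abs(mean(y)) + 1e-300) || stats::sd(y) == 0)
    stop("degenerate flat trace: nothing to fit")
}

#' Fit exponential components to an activation current
#'
#' Rising currents are fitted with
#' y(t) = C + sum_i A_i * (1 - exp(-t/tau_i)) (amplitude signs are free,
#' so decaying segments are handled by negative A).  In `joint` mode all
#' components are fitted together (the standard double-exponential fit
#' of control activation currents, yielding tau_f and tau_s).  In
#' `windowed` mode one single-exponential fit is performed on an early
#' window and one on a late window (split at `split_ms`), the procedure
#' used for currents whose fast component no longer grows, e.g. after
#' ML277.
#'
#' @param trace a [qk_trace()]; time is taken relative to the window
#'   start.
#' @param window `c(t0, t1)` fit window in ms (default: whole trace).
#' @param n_components 1 or 2 (joint mode).
#' @param mode `"joint"` or `"windowed"`.
#' @param split_ms split point of windowed mode (default 200 ms).
#' @return An object of class `qk_expfit`: `components` (data.frame
#'   `A`, `tau`, ascending tau; for two components the rows are tau_f
#'   then tau_s), `C`, `residual` (RSS norm), `mode`, `window`.
#' @export
fit_exponentials <- function(trace, window = NULL, n_components = 2,
                             mode = c("joint", "windowed"),
                             split_ms = 200) {
  mode <- match.arg(mode)
  stopifnot(inherits(trace, "qk_trace"), n_components %in% 1:2)
  window <- window %||% range(trace$time)
  seg <- slice_trace(trace, window[1], window[2] + 1e-9)
  t <- seg$time; y <- seg$value
  if (length(t) < 10 * n_components)
    stop("need at least 10 samples per component")
  check_not_flat(y)

  if (mode == "windowed") {
    if (split_ms <= min(t) || split_ms >= max(t))
      stop("split_ms must lie inside the window")
    f1 <- fit_exponentials(seg, c(0, split_ms), 1, "joint")
    f2 <- fit_exponentials(slice_trace(seg, split_ms, Inf), NULL, 1, "joint")
    comp <- rbind(f1$components, f2$components)
    o <- order(comp$tau)
    return(structure(list(components = comp[o, , drop = FALSE],
                          C = f1$C, residual = f1$residual + f2$residual,
                          mode = "windowed", window = window,
                          split_ms = split_ms),
                     class = "qk_expfit"))
  }

  Tw <- max(t) - min(t)
  dat <- data.frame(t = t - min(t), y = y)
  Atot <- y[length(y)] - y[1]
  if (abs(Atot) < 1e-14) Atot <- max(abs(y - y[1])) * sign(stats::median(y - y[1]) + 1e-300)
  if (n_components == 1) {
    starts <- lapply(Tw * exp(seq(log(0.005), log(0.8), length.out = 8)),
                     function(tau) list(C = y[1], A = Atot, tau1 = tau))
    fits <- lapply(starts, function(s)
      fit_or_null(y ~ C + A * (1 - exp(-t / tau1)), dat, s,
                  lower = c(C = -Inf, A = -Inf, tau1 = 1e-6)))
    fit <- pick_best(fits)
    if (is.null(fit))
      stop("exponential fit did not converge from any start")
    cf <- stats::coef(fit)
    comp <- data.frame(A = cf[["A"]], tau = cf[["tau1"]])
  } else {
    grid <- expand.grid(tf = Tw * c(0.005, 0.02, 0.08, 0.3),
                        ratio = c(5, 15))
    starts <- lapply(seq_len(nrow(grid)), function(i)
      list(C = y[1], Af = 0.7 * Atot, As = 0.3 * Atot,
           tau1 = grid$tf[i], tau2 = grid$tf[i] * grid$ratio[i]))
    fits <- lapply(starts, function(s)
      fit_or_null(y ~ C + Af * (1 - exp(-t / tau1)) +
                    As * (1 - exp(-t / tau2)), dat, s,
                  lower = c(C = -Inf, Af = -Inf, As = -Inf,
                            tau1 = 1e-6, tau2 = 1e-6)))
    fit <- pick_best(fits)
    if (is.null(fit))
      stop("double-exponential fit did not converge from any start")
    cf <- stats::coef(fit)
    comp <- data.frame(A = c(cf[["Af"]], cf[["As"]]),
                       tau = c(cf[["tau1"]], cf[["tau2"]]))
    comp <- comp[order(comp$tau), ]
    rownames(comp) <- NULL
  }
  structure(list(components = comp, C = stats::coef(fit)[["C"]],
                 residual = sqrt(stats::deviance(fit)), mode = "joint",
                 window = window),
            class = "qk_expfit")
}

#' @export
print.qk_expfit <- function(x, ...) {
  cat("<qk_expfit>", x$mode, "fit,", nrow(x$components), "component(s)\n")
  lab <- if (nrow(x$components) == 2) c("tau_f", "tau_s") else "tau"
  for (i in seq_len(nrow(x$components)))
    cat(sprintf("  %s = %.4g ms (A = %.4g)\n", lab[i],
                x$components$tau[i], x$components$A[i]))
  cat(sprintf("  C = %.4g, residual = %.4g\n", x$C, x$residual))
  invisible(x)
}

#' Decompose a hooked tail current
#'
#' Fits the tail with F(t) = A1*exp(-t/tau1) + A2*exp(-t/tau2) + C,
#' where (A1, tau1) is the deactivation component, (A2, tau2) the hook
#' component whose amplitude sign opposes the net decay and produces the
#' transient rise, and C the offset due to leak currents.  A2 is used to
#' quantify inactivation: it reflects channels deactivating from the
#' low-open-probability AO state through the higher-open-probability IO
#' state.  For monotonic tails (no oppositely-signed component) A2 is
#' reported as 0 with `hook_detected = FALSE`.
#'
#' @param trace a [qk_trace()] holding the tail segment (use
#'   [slice_trace()] to cut it from a full sweep).
#' @param blank initial interval in ms discarded as the capacitive
#'   transient (default 2 ms).
#' @return An object of class `qk_hookfit`: `A1`, `tau1`, `A2`, `tau2`,
#'   `C`, `hook_detected`, `components` (raw fitted pair), `residual`.
#' @export
fit_hook_tail <- function(trace, blank = 2) {
  stopifnot(inherits(trace, "qk_trace"), blank >= 0)
  seg <- slice_trace(trace, blank, Inf)
  t <- seg$time - seg$time[1]; y <- seg$value
  if (length(t) < 20) stop("fewer than 20 usable samples in the tail")
  check_not_flat(y)
  Tw <- max(t)
  y0 <- y[1]; yend <- y[length(y)]
  grid <- expand.grid(t1 = Tw * c(0.08, 0.25, 0.6),
                      t2 = Tw * c(0.005, 0.02, 0.06))
  starts <- c(
    lapply(seq_len(nrow(grid)), function(i)
      list(A1 = y0 - yend, A2 = -(y0 - yend) * 0.3, C = yend,
           tau1 = grid$t1[i], tau2 = grid$t2[i])),
    lapply(seq_len(nrow(grid)), function(i)   # same-sign biexponential start
      list(A1 = (y0 - yend) * 0.7, A2 = (y0 - yend) * 0.3, C = yend,
           tau1 = grid$t1[i], tau2 = grid$t2[i])))
  dat <- data.frame(t = t, y = y)
  fits <- lapply(starts, function(s)
    fit_or_null(y ~ A1 * exp(-t / tau1) + A2 * exp(-t / tau2) + C, dat, s,
                lower = c(A1 = -Inf, A2 = -Inf, C = -Inf,
                          tau1 = 1e-6, tau2 = 1e-6)))
  fit <- pick_best(fits)
  if (is.null(fit)) stop("hook-tail fit did not converge from any start")
  cf <- stats::coef(fit)
  comp <- data.frame(A = c(cf[["A1"]], cf[["A2"]]),
                     tau = c(cf[["tau1"]], cf[["tau2"]]))
  C <- cf[["C"]]
  # sign of the decaying current relative to the offset
  s_deact <- sign(mean(y[seq_len(max(3, length(y) %/% 20))]) - C)
  opp <- which(sign(comp$A) == -s_deact & comp$A != 0)
  if (length(opp)) {
    hook_i <- opp[which.max(abs(comp$A[opp]))]
    deact_i <- setdiff(1:2, hook_i)
    out <- list(A1 = comp$A[deact_i], tau1 = comp$tau[deact_i],
                A2 = comp$A[hook_i], tau2 = comp$tau[hook_i], C = C)
  } else {
    deact_i <- which.max(abs(comp$A))
    out <- list(A1 = comp$A[deact_i], tau1 = comp$tau[deact_i],
                A2 = 0, tau2 = comp$tau[setdiff(1:2, deact_i)], C = C)
  }
  # a transient rise must carry material amplitude; an oppositely-signed
  # sliver from fitting a monotonic tail with two components is not a hook
  out$hook_detected <- abs(out$A2) >= 0.02 * abs(out$A1)
  structure(c(out, list(components = comp,
                        residual = sqrt(stats::deviance(fit)),
                        blank = blank)),
            class = "qk_hookfit")
}

#' @export
print.qk_hookfit <- function(x, ...) {
  cat("<qk_hookfit>",
      if (x$hook_detected) "hook detected" else "monotonic (no hook)", "\n")
  cat(sprintf("  deactivation A1 = %.4g, tau1 = %.4g ms\n", x$A1, x$tau1))
  cat(sprintf("  hook         A2 = %.4g, tau2 = %.4g ms\n", x$A2, x$tau2))
  cat(sprintf("  C = %.4g, residual = %.4g\n", x$C, x$residual))
  invisible(x)
}

#' Development of the hook amplitude with pre-pulse duration
#'
#' Normalizes |A2| across a family of hook fits to its maximum and fits
#' the saturating development with a single exponential
#' y(d) = Amax * (1 - exp(-d/tau)), returning the development time
#' constant.
#'
#' @param fits list of [fit_hook_tail()] results, one per pre-pulse
#'   duration.
#' @param durations_ms pre-pulse durations (same order, >= 4 values).
#' @return A list with `curve` (data.frame `duration_ms`, `a2_norm`),
#'   `tau_dev` (ms), `amax`, `residual`.
#' @export
hook_development <- function(fits, durations_ms) {
  if (length(fits) != length(durations_ms)) stop("length mismatch")
  if (length(fits) < 4) stop("need at least 4 pre-pulse durations")
  if (!any(vapply(fits, function(f) isTRUE(f$hook_detected), logical(1))))
    stop("no hook detected in any family member")
  a2 <- abs(vapply(fits, function(f) f$A2, numeric(1)))
  o <- order(durations_ms)
  dat <- data.frame(d = durations_ms[o], y = (a2 / max(a2))[o])
  starts <- lapply(stats::quantile(dat$d, c(0.15, 0.4, 0.7)),
                   function(tau) list(Amax = 1, tau = unname(tau)))
  fitl <- lapply(starts, function(s)
    fit_or_null(y ~ Amax * (1 - exp(-d / tau)), dat, s,
                lower = c(Amax = 0, tau = 1e-6)))
  fit <- pick_best(fitl, "tau")
  if (is.null(fit)) stop("development fit did not converge")
  cf <- stats::coef(fit)
  list(curve = data.frame(duration_ms = dat$d, a2_norm = dat$y),
       tau_dev = cf[["tau"]], amax = cf[["Amax"]],
       residual = sqrt(stats::deviance(fit)))
}
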