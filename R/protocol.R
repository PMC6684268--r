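#' Piecewise-constant voltage-clamp protocol
#'
#' @param epochs data.frame with columns `v_mV` (finite) and
#'   `duration_ms` (> 0), one row per epoch, applied in order from the
#'   holding potential.
#' @param holding_v holding potential in mV (default -80).
#' @param sampling_interval_ms output sampling interval (default 1 ms,
#'   i.e. 1 kHz acquisition).
#' @return An object of class `qk_protocol`.
#' @export
qk_protocol <- function(epochs, holding_v = -80, sampling_interval_ms = 1) {
  epochs <- as.data.frame(epochs)
  if (!all(c("v_mV", "duration_ms") %in% names(epochs)))
    stop("epochs needs columns v_mV and duration_ms")
  if (nrow(epochs) == 0) stop("epoch list must be nonempty")
  if (!all(is.finite(epochs$v_mV))) stop("epoch voltages must be finite")
  if (!all(is.finite(epochs$duration_ms)) || any(epochs$duration_ms <= 0))
    stop("epoch durations must be positive")
  if (!is.finite(holding_v)) stop("holding_v must be finite")
  if (!is.finite(sampling_interval_ms) || sampling_interval_ms <= 0)
    stop("sampling_interval_ms must be positive")
  structure(list(holding_v = holding_v,
                 sampling_interval_ms = sampling_interval_ms,
                 epochs = epochs[c("v_mV", "duration_ms")]),
            class = "qk_protocol")
}

#' @export
print.qk_protocol <- function(x, ...) {
  cat("<qk_protocol> holding", x$holding_v, "mV, dt =",
      x$sampling_interval_ms, "ms\n")
  print(x$epochs)
  invisible(x)
}

#' Total protocol duration in ms
#' @param protocol a [qk_protocol()].
#' @export
total_duration <- function(protocol) sum(protocol$epochs$duration_ms)

#' Command voltage at given times
#'
#' Right-continuous piecewise-constant: a sample on an epoch boundary
#' belongs to the later epoch; the final instant belongs to the last
#' epoch.
#'
#' @param protocol a [qk_protocol()].
#' @param t times in ms from the start of the first epoch.
#' @return Voltages in mV.
#' @export
protocol_voltage <- function(protocol, t) {
  bounds <- cumsum(protocol$epochs$duration_ms)
  idx <- pmin(findInterval(t, c(0, bounds)), nrow(protocol$epochs))
  protocol$epochs$v_mV[pmax(idx, 1)]
}

#' Protocol family: one swept field over a base protocol
#'
#' @param base a [qk_protocol()].
#' @param epoch index of the swept epoch.
#' @param field `"v_mV"` or `"duration_ms"`.
#' @param values nonempty vector; each value must yield a valid protocol.
#' @return An object of class `qk_family`.
#' @export
family_sweep <- function(base, epoch, field = c("v_mV", "duration_ms"),
                         values) {
  stopifnot(inherits(base, "qk_protocol"))
  field <- match.arg(field)
  if (length(values) == 0) stop("values must be nonempty")
  if (epoch < 1 || epoch > nrow(base$epochs))
    stop("epoch index out of range")
  fam <- structure(list(base = base, epoch = epoch, field = field,
                        values = values), class = "qk_family")
  invisible(lapply(protocols(fam), validate_protocol))  # each must be valid
  fam
}

validate_protocol <- function(p) {
  qk_protocol(p$epochs, p$holding_v, p$sampling_interval_ms)
}

#' Expand a protocol family into its member protocols
#'
#' @param family a [qk_family()] (a single protocol is returned as a
#'   one-element list).
#' @return Named list of [qk_protocol()] objects, one per swept value.
#' @export
protocols <- function(family) {
  if (inherits(family, "qk_protocol")) return(list(family))
  stopifnot(inherits(family, "qk_family"))
  out <- lapply(family$values, function(val) {
    p <- family$base
    p$epochs[[family$field]][family$epoch] <- val
    p
  })
  names(out) <- as.character(family$values)
  out
}

#' @export
print.qk_family <- function(x, ...) {
  cat("<qk_family> sweeping epoch", x$epoch, x$field, "over",
      length(x$values), "values:", paste(signif(x$values, 4), collapse = ", "),
      "\n")
  print(x$base)
  invisible(x)
}

# 12 log-spaced pre-pulse durations spanning the printed 30--4355 ms
# range, with the printed saturating duration 2913 ms substituted for
# its nearest neighbour
hook_durations <- function() {
  dd <- exp(seq(log(30), log(4355), length.out = 12))
  dd[which.min(abs(dd - 2913))] <- 2913
  round(dd)
}

#' Standard voltage-clamp protocols of the study
#'
#' Registered protocols (holding -80 mV, 1 kHz sampling unless
#' overridden):
#' \describe{
#'   \item{iv_family}{test steps -120..+80 mV in 20 mV increments
#'     (4 s), then a -40 mV tail (1 s) for tail-current measurement.}
#'   \item{single_step_40mV_4s}{+40 mV for 4 s, then -40 mV (1 s).}
#'   \item{io_only_low_v}{-50 mV for 5 s, tail at -60 mV: restricts
#'     activation to the IO state (low voltage).}
#'   \item{io_only_brief}{+40 mV for 100 ms, tail at -60 mV: restricts
#'     activation to the IO state (brief depolarization).}
#'   \item{hook_duration_family}{+60 mV pre-pulses with 12 log-spaced
#'     durations between 30 and 4355 ms (including 2913 ms), then a
#'     -120 mV test pulse for 2 s; elicits hooked tail currents.}
#'   \item{rbk_tail}{+60 mV for 5 s, tail at -60 mV for 3 s; used for
#'     Rb+/K+ tail-ratio measurements.}
#'   \item{vcf_family}{2.5 s recorded holding segment at -80 mV (for
#'     photobleach baseline fitting), 4 s test steps -120..+80 mV,
#'     -40 mV tail (1 s).}
#' }
#'
#' @param name one of the registered names above.
#' @param overrides named list of overrides; supported keys:
#'   `step_duration_ms`, `tail_v`, `tail_duration_ms`, `prepulse_v`,
#'   `durations_ms`, `voltages`, `test_v`, `test_duration_ms`,
#'   `holding_record_ms`, `sampling_interval_ms`.
#' @return A [qk_protocol()] or [qk_family()].
#' @export
make_standard_protocol <- function(name, overrides = list()) {
  known <- c("step_duration_ms", "tail_v", "tail_duration_ms",
             "prepulse_v", "durations_ms", "voltages", "test_v",
             "test_duration_ms", "holding_record_ms",
             "sampling_interval_ms")
  bad <- setdiff(names(overrides), known)
  if (length(bad)) stop("unknown override keys: ", paste(bad, collapse = ", "))
  o <- function(key, default) overrides[[key]] %||% default
  dt <- o("sampling_interval_ms", 1)
  pr <- function(epochs) qk_protocol(epochs, holding_v = -80,
                                     sampling_interval_ms = dt)
  switch(name,
    iv_family = {
      base <- pr(data.frame(v_mV = c(40, o("tail_v", -40)),
                            duration_ms = c(o("step_duration_ms", 4000),
                                            o("tail_duration_ms", 1000))))
      family_sweep(base, 1, "v_mV", o("voltages", seq(-120, 80, by = 20)))
    },
    single_step_40mV_4s =
      pr(data.frame(v_mV = c(40, o("tail_v", -40)),
                    duration_ms = c(o("step_duration_ms", 4000),
                                    o("tail_duration_ms", 1000)))),
    io_only_low_v =
      pr(data.frame(v_mV = c(o("test_v", -50), o("tail_v", -60)),
                    duration_ms = c(o("step_duration_ms", 5000),
                                    o("tail_duration_ms", 1000)))),
    io_only_brief =
      pr(data.frame(v_mV = c(o("test_v", 40), o("tail_v", -60)),
                    duration_ms = c(o("step_duration_ms", 100),
                                    o("tail_duration_ms", 1000)))),
    hook_duration_family = {
      base <- pr(data.frame(v_mV = c(o("prepulse_v", 60), o("test_v", -120)),
                            duration_ms = c(1000,
                                            o("test_duration_ms", 2000))))
      family_sweep(base, 1, "duration_ms",
                   o("durations_ms", hook_durations()))
    },
    rbk_tail =
      pr(data.frame(v_mV = c(o("prepulse_v", 60), o("tail_v", -60)),
                    duration_ms = c(o("step_duration_ms", 5000),
                                    o("tail_duration_ms", 3000)))),
    vcf_family = {
      base <- pr(data.frame(v_mV = c(-80, 40, o("tail_v", -40)),
                            duration_ms = c(o("holding_record_ms", 2500),
                                            o("step_duration_ms", 4000),
                                            o("tail_duration_ms", 1000))))
      family_sweep(base, 2, "v_mV", o("voltages", seq(-120, 80, by = 20)))
    },
    stop("unknown protocol name: ", name)
  )
}
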