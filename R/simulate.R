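#' Conductance specification for macroscopic current
#'
#' @param g single-channel conductance in pS (default 0.18).
#' @param N channel-count scale (default 1, i.e. arbitrary units
#'   proportional to pS*mV).
#' @return An object of class `qk_conductance`.
#' @export
qk_conductance <- function(g = 0.18, N = 1) {
  if (!is.finite(g) || g <= 0) stop("g must be > 0")
  if (!is.finite(N) || N <= 0) stop("N must be > 0")
  structure(list(g = g, N = N), class = "qk_conductance")
}

#' External-solution presets
#'
#' Each solution carries a reversal potential and per-open-state
#' relative conductance factors.  `ND96` is the standard bath
#' (E_rev = -80 mV, both open states equal).  `100K` and `100Rb` are the
#' high-K+ / high-Rb+ exchange solutions (E_rev = 0 mV); in `100Rb` the
#' IO and AO states carry the state-specific tail-ratio factors 3.1 and
#' 0.6 so that the occupancy-weighted tail ratio of a simulated channel
#' falls between the pure-state values.  This per-state weighting is an
#' emulation device for testing the ratio measurement, not a mechanistic
#' claim.
#'
#' @param name `"ND96"`, `"100K"`, `"100Rb"`, or `"custom"`.
#' @param E_rev,r_IO,r_AO used when `name = "custom"` (or to override a
#'   preset field).
#' @return An object of class `qk_solution`.
#' @export
qk_solution <- function(name = "ND96", E_rev = NULL, r_IO = NULL,
                        r_AO = NULL) {
  preset <- switch(name,
    ND96  = list(E_rev = -80, r_IO = 1,   r_AO = 1),
    `100K` = list(E_rev = 0,  r_IO = 1,   r_AO = 1),
    `100Rb` = list(E_rev = 0, r_IO = 3.1, r_AO = 0.6),
    custom = list(E_rev = -80, r_IO = 1, r_AO = 1),
    stop("unknown solution name: ", name))
  out <- list(name = name,
              E_rev = E_rev %||% preset$E_rev,
              r_IO = r_IO %||% preset$r_IO,
              r_AO = r_AO %||% preset$r_AO)
  if (out$r_IO < 0 || out$r_AO < 0) stop("r factors must be >= 0")
  structure(out, class = "qk_solution")
}

# ---- propagation engine ------------------------------------------------
# Walks the protocol's epochs and propagates occupancy from sample to
# sample; `stepmat` returns the transition matrix for a constant-voltage
# segment of given length (cached per epoch x segment length).
propagate <- function(params, protocol, init, stepmat) {
  keep <- reachable_states(params)
  Qs <- lapply(protocol$epochs$v_mV, function(v)
    build_generator(params, v)[keep, keep, drop = FALSE])
  dt <- protocol$sampling_interval_ms
  bounds <- cumsum(protocol$epochs$duration_ms)
  total <- bounds[length(bounds)]
  times <- seq(0, total, by = dt)
  if (times[length(times)] < total - 1e-9) times <- c(times, total)
  occ <- matrix(0, length(times), length(keep))
  p <- init
  occ[1, ] <- p
  cache <- new.env(parent = emptyenv())
  seg_mat <- function(ep, len) {
    key <- paste0(ep, "_", format(len, digits = 15))
    m <- cache[[key]]
    if (is.null(m)) {
      m <- stepmat(Qs[[ep]], len)
      cache[[key]] <- m
    }
    m
  }
  ep <- 1
  for (i in seq_along(times)[-1]) {
    t0 <- times[i - 1]; t1 <- times[i]
    while (t0 < t1 - 1e-12) {
      while (ep < length(bounds) && t0 >= bounds[ep] - 1e-12) ep <- ep + 1
      tstop <- min(t1, bounds[ep])
      p <- as.vector(p %*% seg_mat(ep, tstop - t0))
      t0 <- tstop
    }
    occ[i, ] <- p
  }
  full <- matrix(0, length(times), 5, dimnames = list(NULL, QK_STATES))
  full[, keep] <- occ
  list(time = times, occupancy = full)
}

#' Integrate the master equation over a protocol
#'
#' Within each constant-voltage epoch the occupancy is propagated by the
#' exact matrix-exponential solution of the linear master equation
#' dp/dt = p Q(v), evaluated on the output sampling grid; the occupancy
#' is continuous across epoch boundaries and the probability sum is
#' conserved.  The initial condition defaults to the stationary
#' occupancy at the holding potential, restricted to the variant's
#' reachable state set.
#'
#' @param params a [qk_params()].
#' @param protocol a [qk_protocol()].
#' @param init optional initial occupancy: named vector over
#'   [QK_STATES] (or the reachable subset), nonnegative, summing to one
#'   within 1e-6.
#' @return An object of class `qk_trajectory` with fields `time` (ms),
#'   `occupancy` (matrix, one column per state), `voltage` (mV per
#'   sample), `label`, `protocol`.
#' @export
integrate_occupancy <- function(params, protocol, init = NULL) {
  stopifnot(inherits(protocol, "qk_protocol"))
  init <- resolve_init(params, protocol, init)
  res <- propagate(params, protocol, init, function(Q, len) {
    M <- as.matrix(Matrix::expm(Matrix::Matrix(Q * len)))
    M / rowSums(M)  # exp(Q*len) is stochastic; enforce row sums exactly
  })
  new_trajectory(res, params, protocol)
}

#' Fixed-step 4th-order reference integrator
#'
#' Independent cross-check for [integrate_occupancy()]: classical
#' Runge-Kutta with a fixed step `h` applied to the same master
#' equation.  For this linear autonomous system one RK4 step is the
#' degree-4 truncated exponential I + hQ + (hQ)^2/2 + (hQ)^3/6 +
#' (hQ)^4/24; stepping across a segment composes that one-step matrix.
#' The default h = 0.001 ms keeps the stiffest mode of the control
#' parameter set (|lambda| ~ 853 ms^-1 from the AO exit rates) well
#' inside the RK4 stability region.
#'
#' @inheritParams integrate_occupancy
#' @param h step size in ms.
#' @return A `qk_trajectory`.
#' @export
integrate_occupancy_rk4 <- function(params, protocol, init = NULL,
                                    h = 0.001) {
  stopifnot(inherits(protocol, "qk_protocol"))
  init <- resolve_init(params, protocol, init)
  rk4_step <- function(Q, len) {
    A <- Q * len
    I <- diag(nrow(Q))
    I + A %*% (I + A %*% (I + A %*% (I + A / 4) / 3) / 2)
  }
  res <- propagate(params, protocol, init, function(Q, len) {
    nfull <- floor(len / h + 1e-9)
    rem <- len - nfull * h
    M1 <- rk4_step(Q, h)
    M <- diag(nrow(Q))
    for (k in seq_len(nfull)) M <- M %*% M1
    if (rem > 1e-12) M <- M %*% rk4_step(Q, rem)
    M
  })
  new_trajectory(res, params, protocol)
}

resolve_init <- function(params, protocol, init) {
  keep <- reachable_states(params)
  if (is.null(init)) return(steady_state(params, protocol$holding_v)[keep])
  if (!is.null(names(init))) {
    full <- stats::setNames(numeric(5), QK_STATES)
    full[names(init)] <- init
    init <- full[keep]
    if (sum(full) - sum(init) > 1e-12)
      stop("initial occupancy outside the reachable state set")
  } else if (length(init) == length(keep)) {
    names(init) <- keep
  } else stop("init must be named or match the reachable set")
  if (any(init < 0) || abs(sum(init) - 1) > 1e-6)
    stop("init must be nonnegative and sum to 1 (within 1e-6)")
  init / sum(init)
}

new_trajectory <- function(res, params, protocol) {
  structure(list(time = res$time, occupancy = res$occupancy,
                 voltage = protocol_voltage(protocol, res$time),
                 label = params$label, params = params,
                 protocol = protocol),
            class = "qk_trajectory")
}

#' @export
print.qk_trajectory <- function(x, ...) {
  cat("<qk_trajectory>", x$label, "-", length(x$time), "samples over",
      max(x$time), "ms\n")
  cat("  final occupancy:",
      paste(sprintf("%s=%.4g", QK_STATES, x$occupancy[nrow(x$occupancy), ]),
            collapse = " "), "\n")
  invisible(x)
}

#' Time-series trace container
#'
#' @param time time grid in ms.
#' @param value current (N*pS*mV arbitrary units) or dimensionless
#'   delta-F/F.
#' @param meta named list of metadata (condition, solution, modality,
#'   protocol name, seed, ...).
#' @return An object of class `qk_trace`.
#' @export
qk_trace <- function(time, value, meta = list()) {
  if (length(time) != length(value)) stop("time and value lengths differ")
  if (!all(is.finite(time)) || !all(is.finite(value)))
    stop("trace values must be finite")
  if (length(time) > 1 && any(diff(time) <= 0))
    stop("time must be strictly increasing")
  structure(list(time = time, value = value, meta = meta),
            class = "qk_trace")
}

#' @export
print.qk_trace <- function(x, ...) {
  cat("<qk_trace>", length(x$time), "samples,",
    sprintf("range [%.4g, %.4g]", min(x$value), max(x$value)), "\n")
  if (length(x$meta))
    cat(" ", paste(names(x$meta), unlist(lapply(x$meta, format)),
                   sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Extract a time slice of a trace
#'
#' @param trace a [qk_trace()].
#' @param t0,t1 window bounds in ms (`t0 <= t < t1`; `t1 = Inf` for the
#'   end of the trace).
#' @param rezero subtract `t0` from the time grid of the result.
#' @export
slice_trace <- function(trace, t0 = 0, t1 = Inf, rezero = TRUE) {
  sel <- trace$time >= t0 - 1e-9 & trace$time < t1 - 1e-9
  if (!any(sel)) stop("empty slice")
  qk_trace(trace$time[sel] - if (rezero) t0 else 0,
           trace$value[sel], trace$meta)
}

#' Macroscopic current from a trajectory
#'
#' I(t) = N * g * (P_IO(t)*r_IO + P_AO(t)*r_AO) * (v(t) - E_rev).
#'
#' @param traj a [qk_trajectory()].
#' @param spec a [qk_conductance()].
#' @param solution a [qk_solution()] or preset name.
#' @return A [qk_trace()] (current, arbitrary units of N*pS*mV).
#' @export
current_from_trajectory <- function(traj, spec = qk_conductance(),
                                    solution = "ND96") {
  stopifnot(inherits(traj, "qk_trajectory"))
  if (is.character(solution)) solution <- qk_solution(solution)
  open_g <- traj$occupancy[, "IO"] * solution$r_IO +
            traj$occupancy[, "AO"] * solution$r_AO
  val <- spec$N * spec$g * open_g * (traj$voltage - solution$E_rev)
  qk_trace(traj$time, val,
           meta = list(modality = "current", condition = traj$label,
                       solution = solution$name))
}

#' Fluorescence (delta-F/F) signal from a trajectory
#'
#' Voltage-clamp fluorometry reports voltage-sensor position, not pore
#' opening: the signal is a weighted sum of the VSD classes,
#' dF/F(t) = w_I*(P_IC + P_IO) + w_A*(P_AC + P_AO), with
#' 0 <= w_I <= w_A so the intermediate position contributes a partial
#' dequench and the activated position the full one.  Bounded in
#' [0, w_A].
#'
#' @param traj a [qk_trajectory()].
#' @param w_I,w_A weights of the intermediate and activated VSD classes
#'   (defaults 0.5 and 1).
#' @return A [qk_trace()] (dimensionless delta-F/F).
#' @export
fluorescence_from_trajectory <- function(traj, w_I = 0.5, w_A = 1) {
  stopifnot(inherits(traj, "qk_trajectory"))
  if (!(w_I >= 0 && w_I <= w_A)) stop("need 0 <= w_I <= w_A")
  val <- w_I * (traj$occupancy[, "IC"] + traj$occupancy[, "IO"]) +
         w_A * (traj$occupancy[, "AC"] + traj$occupancy[, "AO"])
  qk_trace(traj$time, val,
           meta = list(modality = "fluorescence", condition = traj$label,
                       w_I = w_I, w_A = w_A))
}

#' Drug-minus-control difference current
#'
#' @param trace_drug,trace_ctrl [qk_trace()] objects on identical time
#'   grids (same protocol).
#' @return A [qk_trace()] of the pointwise difference, tagged "delta".
#' @export
delta_current <- function(trace_drug, trace_ctrl) {
  stopifnot(inherits(trace_drug, "qk_trace"), inherits(trace_ctrl, "qk_trace"))
  if (length(trace_drug$time) != length(trace_ctrl$time) ||
      max(abs(trace_drug$time - trace_ctrl$time)) > 1e-9)
    stop("time grids differ; delta requires identical protocols")
  qk_trace(trace_drug$time, trace_drug$value - trace_ctrl$value,
           meta = c(list(modality = "delta"),
                    condition = paste0(trace_drug$meta$condition %||% "drug",
                                       " - ",
                                       trace_ctrl$meta$condition %||% "ctrl")))
}
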