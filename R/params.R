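#' State labels of the five-state gating scheme
#'
#' The scheme has a closed row RC -- IC -- AC (voltage-sensing domain at
#' rest, intermediate and activated with the pore closed) and an open row
#' IO -- AO (pore open at the intermediate and activated VSD positions).
#' RC has no direct edge to either open state.
#'
#' @format Character vector of length five.
#' @export
QK_STATES <- c("RC", "IC", "AC", "IO", "AO")

#' Known mutant-variant tags
#' @keywords internal
QK_VARIANTS <- c("intermediate_locked", "activated_locked",
                 "no_AO_coupling", "no_IO_coupling")

#' Model parameters of the five-state KCNQ1 gating scheme
#'
#' Constructs (and validates) the rate parameterization.  The voltage
#' dependent transitions are exponential in voltage:
#' alpha1 = a1*exp(v/m), beta1 = c1*exp(-v/n) for RC<->IC;
#' alpha2 = a2*exp(v/b), beta2 = c2*exp(-v/d) for IC<->AC;
#' alpha3 = a3*exp(v/b), beta3 = c3*exp(-v/d) for IO<->AO.
#' The electromechanical coupling rates are voltage independent:
#' k1 (AC->AO), k2 (AO->AC), k3 (IC->IO), k4 (IO->IC).  The slope
#' factors b and d are shared between the IC<->AC and IO<->AO edges,
#' which makes the product of rates around the IC-AC-AO-IO cycle
#' voltage independent, so detailed balance can hold at every voltage.
#'
#' Defaults are the control parameter set: a1 = 0.00070, a2 = 0.0047,
#' a3 = 0.15, c1 = 0.0020, c2 = 0.00017, c3 = 0.048 (all ms^-1);
#' m = 46.0, n = 31.2, b = 37.7, d = 41.5 mV; k1 = 0.89, k2 = 853.08,
#' k3 = 0.96, k4 = 103.82 (ms^-1 assumed for the coupling rates).
#'
#' @param a1,c1 RC<->IC prefactors (ms^-1).
#' @param m,n RC<->IC slope factors (mV).
#' @param a2,c2 IC<->AC prefactors (ms^-1).
#' @param b,d shared slope factors (mV) of the IC<->AC and IO<->AO edges.
#' @param a3,c3 IO<->AO prefactors (ms^-1).
#' @param k1,k2,k3,k4 coupling rates (ms^-1); k1 or k3 may be exactly 0
#'   in coupling-ablated variants.
#' @param label condition name carried into traces and reports.
#' @param variant `NULL` for the full scheme, or one of
#'   `"intermediate_locked"`, `"activated_locked"`, `"no_AO_coupling"`,
#'   `"no_IO_coupling"` (normally set via [make_variant()]).
#' @return An object of class `qk_params`.
#' @seealso [apply_ml277()], [make_variant()], [build_generator()]
#' @export
qk_params <- function(a1 = 0.00070, c1 = 0.0020, m = 46.0, n = 31.2,
                      a2 = 0.0047, c2 = 0.00017, b = 37.7, d = 41.5,
                      a3 = 0.15, c3 = 0.048,
                      k1 = 0.89, k2 = 853.08, k3 = 0.96, k4 = 103.82,
                      label = "control", variant = NULL) {
  p <- list(a1 = a1, c1 = c1, m = m, n = n, a2 = a2, c2 = c2,
            b = b, d = d, a3 = a3, c3 = c3,
            k1 = k1, k2 = k2, k3 = k3, k4 = k4,
            label = label, variant = variant)
  class(p) <- "qk_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  num <- c("a1", "c1", "m", "n", "a2", "c2", "b", "d", "a3", "c3",
           "k1", "k2", "k3", "k4")
  vals <- unlist(p[num])
  if (!all(is.finite(vals)))
    stop("all rate parameters must be finite numbers")
  pos <- c("a1", "c1", "m", "n", "a2", "c2", "b", "d", "a3", "c3")
  if (any(vals[pos] <= 0))
    stop("prefactors and slope factors must be strictly positive: ",
         paste(pos[vals[pos] <= 0], collapse = ", "))
  if (any(vals[c("k2", "k4")] <= 0))
    stop("k2 and k4 must be strictly positive")
  if (any(vals[c("k1", "k3")] < 0))
    stop("k1 and k3 must be nonnegative")
  if (!is.null(p$variant) && !p$variant %in% QK_VARIANTS)
    stop("unknown variant: ", p$variant)
  invisible(p)
}

#' @export
print.qk_params <- function(x, ...) {
  cat("<qk_params> ", x$label,
      if (!is.null(x$variant)) paste0(" [", x$variant, "]"), "\n", sep = "")
  cat(sprintf("  RC<->IC: a1=%g c1=%g (m=%g, n=%g mV)\n", x$a1, x$c1, x$m, x$n))
  cat(sprintf("  IC<->AC: a2=%g c2=%g (b=%g, d=%g mV)\n", x$a2, x$c2, x$b, x$d))
  cat(sprintf("  IO<->AO: a3=%g c3=%g (shared b, d)\n", x$a3, x$c3))
  cat(sprintf("  coupling: k1=%g k2=%g k3=%g k4=%g ms^-1\n",
              x$k1, x$k2, x$k3, x$k4))
  invisible(x)
}

#' Exponential voltage-dependent rate law
#'
#' A rate evaluated as `prefactor * exp(direction * v / slope)`:
#' `direction = +1` for forward (depolarization-favoured, alpha) rates
#' and `-1` for backward (beta) rates.
#'
#' @param prefactor rate at 0 mV (ms^-1), strictly positive.
#' @param slope voltage scale (mV), strictly positive.
#' @param direction `+1` or `-1`.
#' @return An object of class `qk_rate_law`.
#' @export
rate_law <- function(prefactor, slope, direction = 1) {
  if (!is.finite(prefactor) || prefactor <= 0) stop("prefactor must be > 0")
  if (!is.finite(slope) || slope <= 0) stop("slope must be > 0")
  if (!direction %in% c(-1, 1)) stop("direction must be +1 or -1")
  structure(list(prefactor = prefactor, slope = slope,
                 direction = direction), class = "qk_rate_law")
}

#' Evaluate a rate law at a membrane voltage
#'
#' @param law a [rate_law()].
#' @param v membrane voltage in mV (vectorized).
#' @return Rate(s) in ms^-1.
#' @export
evaluate_rate <- function(law, v) {
  stopifnot(inherits(law, "qk_rate_law"))
  if (!all(is.finite(v))) stop("voltage must be finite")
  law$prefactor * exp(law$direction * v / law$slope)
}

#' Reachable state set of a parameter set
#'
#' The full scheme reaches all five states.  Variants restrict the set:
#' VSD-locked channels are confined to one VSD column
#' (`intermediate_locked` to IC/IO, `activated_locked` to AC/AO), and
#' coupling-ablated channels cannot populate the open state whose
#' coupling is broken (`no_AO_coupling` excludes AO, `no_IO_coupling`
#' excludes IO).
#'
#' @param params a [qk_params()].
#' @return Character vector, a subset of [QK_STATES].
#' @export
reachable_states <- function(params) {
  stopifnot(inherits(params, "qk_params"))
  switch(params$variant %||% "full",
         intermediate_locked = c("IC", "IO"),
         activated_locked    = c("AC", "AO"),
         no_AO_coupling      = c("RC", "IC", "AC", "IO"),
         no_IO_coupling      = c("RC", "IC", "AC", "AO"),
         QK_STATES)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the generator (Q) matrix at one voltage
#'
#' Off-diagonal entry (i, j) is the i -> j transition rate in ms^-1;
#' diagonals are negative row sums so every row sums to zero.  Only the
#' ten edges of the scheme are populated: RC->IC alpha1, IC->RC beta1,
#' IC->AC alpha2, AC->IC beta2, IC->IO k3, IO->IC k4, AC->AO k1,
#' AO->AC k2, IO->AO alpha3, AO->IO beta3.  There is no direct edge
#' between RC and either open state.  For variants, edges touching
#' unreachable states are removed.
#'
#' @param params a [qk_params()].
#' @param v membrane voltage in mV (scalar).
#' @return 5x5 matrix with `QK_STATES` dimnames.
#' @export
build_generator <- function(params, v) {
  validate_params(params)
  if (length(v) != 1 || !is.finite(v)) stop("v must be a finite scalar (mV)")
  Q <- matrix(0, 5, 5, dimnames = list(QK_STATES, QK_STATES))
  Q["RC", "IC"] <- params$a1 * exp( v / params$m)
  Q["IC", "RC"] <- params$c1 * exp(-v / params$n)
  Q["IC", "AC"] <- params$a2 * exp( v / params$b)
  Q["AC", "IC"] <- params$c2 * exp(-v / params$d)
  Q["IO", "AO"] <- params$a3 * exp( v / params$b)
  Q["AO", "IO"] <- params$c3 * exp(-v / params$d)
  Q["IC", "IO"] <- params$k3
  Q["IO", "IC"] <- params$k4
  Q["AC", "AO"] <- params$k1
  Q["AO", "AC"] <- params$k2
  keep <- reachable_states(params)
  drop <- setdiff(QK_STATES, keep)
  Q[drop, ] <- 0
  Q[, drop] <- 0
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Detailed-balance report for the IC-AC-AO-IO cycle
#'
#' A cyclic kinetic scheme obeys detailed balance when the product of
#' rates around the loop equals the product in the reverse direction.
#' Because alpha2/alpha3 share slope b and beta2/beta3 share slope d,
#' the voltage factors cancel and the loop ratio is voltage independent;
#' it therefore reduces to the constants:
#' forward a2*k1*c3*k4 (IC->AC->AO->IO->IC) versus reverse k3*a3*k2*c2.
#'
#' @param params a [qk_params()].
#' @return A list with `cycle` (FALSE with a `"no cycle"` message when a
#'   coupling edge is zero), `forward_product`, `reverse_product`,
#'   `ratio`, `slope_consistent`, and `max_voltage_variation` (relative
#'   variation of the full voltage-dependent loop ratio over
#'   -120..+80 mV; ~0 when the shared-slope structure holds).
#' @export
loop_balance_report <- function(params) {
  validate_params(params)
  loop <- unlist(params[c("a2", "k1", "c3", "k4", "k3", "a3", "k2", "c2")])
  if (any(loop == 0))
    return(list(cycle = FALSE, message = "no cycle",
                forward_product = NA_real_, reverse_product = NA_real_,
                ratio = NA_real_, slope_consistent = NA))
  fwd <- params$a2 * params$k1 * params$c3 * params$k4
  rev <- params$k3 * params$a3 * params$k2 * params$c2
  # loop ratio with full voltage-dependent rates, to verify that the
  # shared-slope structure really cancels the voltage factors
  vr <- vapply(c(-120, 0, 80), function(v) {
    Q <- build_generator(params, v)
    (Q["IC", "AC"] * Q["AC", "AO"] * Q["AO", "IO"] * Q["IO", "IC"]) /
      (Q["IC", "IO"] * Q["IO", "AO"] * Q["AO", "AC"] * Q["AC", "IC"])
  }, numeric(1))
  mvv <- diff(range(vr)) / abs(mean(vr))
  list(cycle = TRUE, forward_product = fwd, reverse_product = rev,
       ratio = fwd / rev, slope_consistent = mvv < 1e-10,
       max_voltage_variation = mvv)
}

#' Rebalance c3 after changing k2
#'
#' Returns the unique c3 restoring a loop ratio of one when k2 is set to
#' `k2_new`: c3 = (k3*a3*k2_new*c2) / (a2*k1*k4).  Linear in `k2_new`.
#'
#' @param params a [qk_params()] with all four coupling rates nonzero.
#' @param k2_new new AO->AC coupling rate (ms^-1).
#' @return c3 in ms^-1.
#' @export
balanced_c3 <- function(params, k2_new) {
  validate_params(params)
  den <- params$a2 * params$k1 * params$k4
  if (den == 0 || params$k3 == 0)
    stop("degenerate model: loop is open, c3 is unconstrained")
  if (!is.finite(k2_new) || k2_new <= 0) stop("k2_new must be > 0")
  (params$k3 * params$a3 * k2_new * params$c2) / den
}

#' Apply the ML277 modification rule
#'
#' ML277 stabilizes the activated-open (AO) state: both AO exit rates
#' are halved.  Implemented as k2 -> k2/2 with c3 rebalanced to keep the
#' cyclic scheme at detailed balance; since beta3 = c3*exp(-v/d), the
#' rebalancing is equivalent to halving beta3 at every voltage.  For
#' variants whose loop is open (a coupling rate is zero) c3 is halved
#' directly, which is the same operation without the balance constraint.
#'
#' @param params a [qk_params()] with nonzero k2.
#' @return A modified copy with an updated label.
#' @export
apply_ml277 <- function(params) {
  validate_params(params)
  if (params$k2 <= 0) stop("k2 must be nonzero to apply the ML277 rule")
  out <- params
  k2n <- params$k2 / 2
  bal <- loop_balance_report(params)
  out$c3 <- if (isTRUE(bal$cycle)) balanced_c3(params, k2n) else params$c3 / 2
  out$k2 <- k2n
  out$label <- paste0(params$label, "+ML277")
  validate_params(out)
  out
}

#' Construct a mutant-emulating model variant
#'
#' Variants emulate the mutant channels used to isolate the two open
#' states:
#' \describe{
#'   \item{intermediate_locked}{VSD arrested at the intermediate state
#'     (E1R/R2E-like): occupancy confined to \{IC, IO\}; constitutive
#'     IO-state gating.}
#'   \item{activated_locked}{VSD arrested at the activated state
#'     (E1R/R4E-like): occupancy confined to \{AC, AO\}; constitutive
#'     AO-state gating.}
#'   \item{no_AO_coupling}{VSD-pore coupling broken at the activated
#'     state (S338F-like): k1 = 0 and the AO state is removed, so the
#'     channel opens only to IO.}
#'   \item{no_IO_coupling}{VSD-pore coupling broken at the intermediate
#'     state (F351A-like): k3 = 0 and the IO state is removed, so the
#'     channel opens only to AO.}
#' }
#' The restriction is consumed by [build_generator()], [steady_state()]
#' and the simulator's initial-condition logic.
#'
#' @param params a [qk_params()].
#' @param variant one of `"intermediate_locked"`, `"activated_locked"`,
#'   `"no_AO_coupling"`, `"no_IO_coupling"`.
#' @return A modified copy tagged with the variant.
#' @export
make_variant <- function(params, variant) {
  validate_params(params)
  if (!is.character(variant) || length(variant) != 1 ||
      !variant %in% QK_VARIANTS)
    stop("unknown variant: ", paste(variant, collapse = ", "),
         " (expected one of ", paste(QK_VARIANTS, collapse = ", "), ")")
  out <- params
  out$variant <- variant
  if (variant == "no_AO_coupling") out$k1 <- 0
  if (variant == "no_IO_coupling") out$k3 <- 0
  out$label <- paste0(params$label, ":", variant)
  validate_params(out)
  out
}

#' Stationary occupancy at a fixed voltage
#'
#' Solves p Q = 0 with sum(p) = 1 on the variant's reachable state set.
#' Errors when the reachable set is not a single communicating class.
#'
#' @param params a [qk_params()].
#' @param v membrane voltage in mV.
#' @return Named numeric vector over all five states (zeros outside the
#'   reachable set), nonnegative, summing to one.
#' @export
steady_state <- function(params, v) {
  keep <- reachable_states(params)
  Q <- build_generator(params, v)[keep, keep, drop = FALSE]
  check_irreducible(Q)
  A <- rbind(t(Q), rep(1, length(keep)))
  p <- qr.solve(A, c(rep(0, length(keep)), 1))
  p[p < 0 & p > -1e-12] <- 0  # clip solver noise
  if (any(p < 0)) stop("stationary solve produced negative occupancy")
  p <- p / sum(p)
  full <- stats::setNames(numeric(5), QK_STATES)
  full[keep] <- p
  full
}

# error if the (restricted) chain is not one communicating class
check_irreducible <- function(Q) {
  n <- nrow(Q)
  if (n == 1) return(invisible(TRUE))
  A <- (Q > 0) & !diag(TRUE, n)
  reach <- function(M) {            # transitive closure from state 1
    r <- c(TRUE, rep(FALSE, n - 1))
    repeat {
      r2 <- r | (r %*% M > 0)
      if (all(r2 == r)) break
      r <- as.vector(r2)
    }
    r
  }
  ok <- reach(A) & reach(t(A))
  if (!all(ok))
    stop("chain is reducible; disconnected states: ",
         paste(rownames(Q)[!ok], collapse = ", "))
  invisible(TRUE)
}
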