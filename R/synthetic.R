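# Synthetic TEVC / VCF data generation with full ground truth.

#' Noise model for synthetic recordings
#'
#' Emulates the statistical structure of 1 kHz two-electrode
#' voltage-clamp and voltage-clamp fluorometry recordings: white
#' Gaussian current noise scaled to the trace peak, a constant leak
#' offset, white Gaussian fluorescence noise, and a photobleaching
#' drift (linear by default) on fluorescence traces.
#'
#' @param current_sigma current noise SD as a fraction of the trace
#'   peak absolute current (default 0.02).
#' @param leak constant leak-current offset added to current traces
#'   (default 0).
#' @param fluor_sigma fluorescence noise SD as a fraction of the trace
#'   peak absolute delta-F/F (default 0.01).
#' @param drift `"linear"` or `"exponential"` photobleach drift shape.
#' @param drift_slope linear drift in delta-F/F units per ms (default
#'   -5e-6, i.e. -0.005 per second of recording).
#' @param drift_amp,drift_tau amplitude and time constant (ms) of the
#'   exponential drift option.
#' @return An object of class `qk_noise`.
#' @export
qk_noise <- function(current_sigma = 0.02, leak = 0, fluor_sigma = 0.01,
                     drift = c("linear", "exponential"),
                     drift_slope = -5e-6, drift_amp = -0.05,
                     drift_tau = 20000) {
  drift <- match.arg(drift)
  if (current_sigma < 0 || fluor_sigma < 0) stop("sigma must be >= 0")
  structure(list(current_sigma = current_sigma, leak = leak,
                 fluor_sigma = fluor_sigma, drift = drift,
                 drift_slope = drift_slope, drift_amp = drift_amp,
                 drift_tau = drift_tau),
            class = "qk_noise")
}

drift_of <- function(noise, t) {
  if (noise$drift == "linear") noise$drift_slope * t
  else noise$drift_amp * (1 - exp(-t / noise$drift_tau))
}

add_current_noise <- function(trace, noise) {
  peak <- max(abs(trace$value))
  val <- trace$value + noise$leak +
    if (noise$current_sigma > 0 && peak > 0)
      stats::rnorm(length(trace$value), 0, noise$current_sigma * peak)
    else 0
  qk_trace(trace$time, val, c(trace$meta, list(noisy = TRUE)))
}

add_fluor_noise <- function(trace, noise) {
  peak <- max(abs(trace$value))
  val <- trace$value + drift_of(noise, trace$time) +
    if (noise$fluor_sigma > 0 && peak > 0)
      stats::rnorm(length(trace$value), 0, noise$fluor_sigma * peak)
    else 0
  qk_trace(trace$time, val, c(trace$meta, list(noisy = TRUE)))
}

#' Generate a synthetic dataset with ground truth
#'
#' Simulates the model over a protocol (or family), derives current
#' and/or fluorescence traces, and adds the noise realization.
#' Deterministic given the seed; with all sigmas zero the noisy traces
#' equal the simulator output exactly.
#'
#' @param params a [qk_params()].
#' @param protocol a [qk_protocol()] or [qk_family()].
#' @param spec a [qk_conductance()].
#' @param solution a [qk_solution()] or preset name.
#' @param noise a [qk_noise()].
#' @param modality `"current"`, `"fluorescence"` or `"both"`.
#' @param seed integer seed (mandatory).
#' @param w_I,w_A fluorescence weights, see
#'   [fluorescence_from_trajectory()].
#' @return An object of class `qk_dataset`: `traces` (noisy), `clean`
#'   (noise-free), `index` (data.frame id / modality / swept value),
#'   and `ground_truth` (generating params, protocol, conductance,
#'   solution, noise, weights, seed).
#' @export
generate_dataset <- function(params, protocol, spec = qk_conductance(),
                             solution = "ND96", noise = qk_noise(),
                             modality = c("current", "fluorescence",
                                          "both"),
                             seed, w_I = 0.5, w_A = 1) {
  modality <- match.arg(modality)
  if (missing(seed) || !is.finite(seed)) stop("seed is mandatory")
  if (is.character(solution)) solution <- qk_solution(solution)
  set.seed(as.integer(seed))
  prots <- protocols(protocol)
  values <- if (inherits(protocol, "qk_family")) protocol$values
            else NA_real_
  clean <- list(); noisy <- list(); idx <- list()
  for (i in seq_along(prots)) {
    traj <- integrate_occupancy(params, prots[[i]])
    if (modality %in% c("current", "both")) {
      tr <- current_from_trajectory(traj, spec, solution)
      tr$meta$sweep <- values[min(i, length(values))]
      id <- sprintf("current_%03d", i)
      clean[[id]] <- tr
      noisy[[id]] <- add_current_noise(tr, noise)
      idx[[length(idx) + 1]] <- data.frame(
        id = id, modality = "current",
        sweep = values[min(i, length(values))])
    }
    if (modality %in% c("fluorescence", "both")) {
      tr <- fluorescence_from_trajectory(traj, w_I, w_A)
      tr$meta$sweep <- values[min(i, length(values))]
      id <- sprintf("fluor_%03d", i)
      clean[[id]] <- tr
      noisy[[id]] <- add_fluor_noise(tr, noise)
      idx[[length(idx) + 1]] <- data.frame(
        id = id, modality = "fluorescence",
        sweep = values[min(i, length(values))])
    }
  }
  structure(list(traces = noisy, clean = clean,
                 index = do.call(rbind, idx),
                 ground_truth = list(params = params, protocol = protocol,
                                     conductance = spec,
                                     solution = solution, noise = noise,
                                     w_I = w_I, w_A = w_A,
                                     seed = as.integer(seed))),
            class = "qk_dataset")
}

#' Generate a condition-matched dataset pair (e.g. control vs ML277)
#'
#' Applies `modifier` to `params` for the second condition; both
#' datasets share the protocol, conductance spec and solution, with
#' independent noise realizations drawn from seeds `seed` (control) and
#' `seed + 1` (modified).
#'
#' @inheritParams generate_dataset
#' @param modifier function mapping params to params, e.g.
#'   [apply_ml277()] or `function(p) make_variant(p, ...)`.
#' @return A list with class `qk_dataset_pair`: `ctrl` and `drug`
#'   datasets plus `modifier_label`.
#' @export
generate_condition_pair <- function(params, modifier = apply_ml277,
                                    protocol, spec = qk_conductance(),
                                    solution = "ND96",
                                    noise = qk_noise(),
                                    modality = "current", seed,
                                    w_I = 0.5, w_A = 1) {
  if (missing(seed) || !is.finite(seed)) stop("seed is mandatory")
  params2 <- modifier(params)
  ctrl <- generate_dataset(params, protocol, spec, solution, noise,
                           modality, seed = seed, w_I = w_I, w_A = w_A)
  drug <- generate_dataset(params2, protocol, spec, solution, noise,
                           modality, seed = seed + 1L, w_I = w_I,
                           w_A = w_A)
  structure(list(ctrl = ctrl, drug = drug,
                 modifier_label = params2$label),
            class = "qk_dataset_pair")
}
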