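# File formats: trace CSV dialect ('#' key=value metadata header),
# parameter JSON, protocol JSON, dataset directories.

#' Write a trace to the CSV dialect
#'
#' Format: '#'-prefixed `key=value` metadata lines, a `time_ms,value`
#' header, then one row per sample at full precision.
#'
#' @param trace a [qk_trace()].
#' @param path output file.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "qk_trace"))
  meta <- vapply(trace$meta, function(v) format(v, digits = 17),
                 character(1))
  lines <- c(sprintf("# %s=%s", names(meta), meta),
             "time_ms,value",
             sprintf("%.17g,%.17g", trace$time, trace$value))
  writeLines(lines, path)
  invisible(path)
}

#' Read a trace from the CSV dialect
#'
#' @param path file written by [write_trace()].
#' @return A [qk_trace()] with metadata restored (as character).
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta_raw <- sub("^#\\s*", "", lines[is_meta])
  kv <- regmatches(meta_raw, regexpr("=", meta_raw), invert = TRUE)
  meta <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  body <- lines[!is_meta]
  if (length(body) < 2 || body[1] != "time_ms,value")
    stop("malformed trace header in ", path)
  dat <- utils::read.csv(text = body,
                         colClasses = c("numeric", "numeric"))
  if (!all(is.finite(dat$time_ms)) || !all(is.finite(dat$value)))
    stop("non-finite values in ", path)
  if (any(diff(dat$time_ms) <= 0))
    stop("non-monotonic time column in ", path)
  qk_trace(dat$time_ms, dat$value, meta)
}

param_fields <- c("a1", "c1", "m", "n", "a2", "c2", "b", "d",
                  "a3", "c3", "k1", "k2", "k3", "k4")

#' Write model parameters to flat JSON
#'
#' Fields a1..k4 plus `label` and optional `variant`; a `units` note
#' records that prefactors and coupling rates are in ms^-1 and slope
#' factors in mV.
#'
#' @param params a [qk_params()].
#' @param path output file.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  obj <- c(params[param_fields],
           list(label = params$label,
                units = "prefactors and k1-k4 in ms^-1; slopes in mV"))
  if (!is.null(params$variant)) obj$variant <- params$variant
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read model parameters from flat JSON
#'
#' Validates positivity and reports the detailed-balance loop ratio on
#' load (as a message).
#'
#' @param path file written by [write_params()].
#' @param quiet suppress the loop-balance message.
#' @return A [qk_params()].
#' @export
read_params <- function(path, quiet = FALSE) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing <- setdiff(param_fields, names(obj))
  if (length(missing))
    stop("parameter file lacks fields: ", paste(missing, collapse = ", "))
  p <- do.call(qk_params, c(obj[param_fields],
                            list(label = obj$label %||% "unnamed",
                                 variant = obj$variant)))
  if (!quiet) {
    bal <- loop_balance_report(p)
    message(if (isTRUE(bal$cycle))
      sprintf("loaded '%s': loop-balance ratio %.4f", p$label, bal$ratio)
      else sprintf("loaded '%s': no cycle (open loop)", p$label))
  }
  p
}

#' Write / read a protocol (or family) as JSON
#'
#' @param protocol a [qk_protocol()] or [qk_family()].
#' @param path file path.
#' @export
write_protocol <- function(protocol, path) {
  obj <- if (inherits(protocol, "qk_family")) {
    list(holding_v = protocol$base$holding_v,
         sampling_interval_ms = protocol$base$sampling_interval_ms,
         epochs = protocol$base$epochs,
         swept_epoch = protocol$epoch, swept_field = protocol$field,
         values = protocol$values)
  } else {
    stopifnot(inherits(protocol, "qk_protocol"))
    list(holding_v = protocol$holding_v,
         sampling_interval_ms = protocol$sampling_interval_ms,
         epochs = protocol$epochs)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- qk_protocol(as.data.frame(obj$epochs), obj$holding_v,
                      obj$sampling_interval_ms)
  if (!is.null(obj$swept_field))
    family_sweep(base, obj$swept_epoch, obj$swept_field, obj$values)
  else base
}

#' Write a synthetic dataset to a directory
#'
#' Layout: `traces/<id>.csv` (noisy traces in the CSV dialect),
#' `index.csv`, and `ground_truth.json` (generating parameters,
#' protocol, conductance/solution/noise specs and seed; sufficient to
#' regenerate the dataset with [generate_dataset()]).
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "qk_dataset"))
  dir.create(file.path(dir, "traces"), recursive = TRUE,
             showWarnings = FALSE)
  for (id in names(dataset$traces))
    write_trace(dataset$traces[[id]],
                file.path(dir, "traces", paste0(id, ".csv")))
  utils::write.csv(dataset$index, file.path(dir, "index.csv"),
                   row.names = FALSE)
  gt <- dataset$ground_truth
  prot <- gt$protocol
  prot_obj <- if (inherits(prot, "qk_family"))
    list(holding_v = prot$base$holding_v,
         sampling_interval_ms = prot$base$sampling_interval_ms,
         epochs = prot$base$epochs, swept_epoch = prot$epoch,
         swept_field = prot$field, values = prot$values)
  else list(holding_v = prot$holding_v,
            sampling_interval_ms = prot$sampling_interval_ms,
            epochs = prot$epochs)
  obj <- list(params = c(gt$params[param_fields],
                         list(label = gt$params$label,
                              variant = gt$params$variant)),
              protocol = prot_obj,
              conductance = unclass(gt$conductance),
              solution = unclass(gt$solution),
              noise = unclass(gt$noise),
              w_I = gt$w_I, w_A = gt$w_A, seed = gt$seed)
  jsonlite::write_json(obj, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(dir)
}
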