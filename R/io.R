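#' Read and write trace CSV files
#'
#' Traces are exchanged as plain CSV with the columns `time_ms, vcmd_mV,
#' vm_mV, vp_mV, vclamp_mV, vest_mV, iion_nA, iout_nA, ipost_nA` (header
#' required, UTF-8, `.` decimal separator). Values are written in full
#' precision so a round trip reproduces every double exactly. Comment lines
#' beginning with `#` carry provenance (package version, seed, configuration
#' hash) and are skipped on reading.
#'
#' @param trace A `vc_trace` tibble.
#' @param path File path.
#' @param seed Optional seed to record in the header comment.
#' @param config Optional configuration object; its hash is recorded.
#' @return `write_trace_csv()` returns `path` invisibly; `read_trace_csv()`
#'   returns a `vc_trace` tibble.
#' @export
write_trace_csv <- function(trace, path, seed = NULL, config = NULL) {
  stopifnot(all(trace_columns() %in% names(trace)))
  write_commented_csv(trace[trace_columns()], path, seed, config)
}

trace_columns <- function() {
  c("time_ms", "vcmd_mV", "vm_mV", "vp_mV", "vclamp_mV", "vest_mV",
    "iion_nA", "iout_nA", "ipost_nA")
}

write_commented_csv <- function(df, path, seed = NULL, config = NULL) {
  hdr <- sprintf("# voltclamp %s",
                 as.character(utils::packageVersion("voltclamp")))
  if (!is.null(seed)) hdr <- paste0(hdr, sprintf("; seed=%d", as.integer(seed)))
  if (!is.null(config)) hdr <- paste0(hdr, "; config=", rlang::hash(config))
  writeLines(hdr, path)
  # %.17g guarantees an exact double round trip (shortest form does not)
  out <- df
  for (cl in names(out)) {
    if (is.double(out[[cl]])) out[[cl]] <- sprintf("%.17g", out[[cl]])
  }
  readr::write_csv(out, path, append = TRUE, col_names = TRUE,
                   quote = "none")
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  # base R parsing: correctly-rounded doubles for an exact round trip
  df <- utils::read.csv(path, comment.char = "#")
  missing <- setdiff(trace_columns(), names(df))
  if (length(missing) > 0) {
    stop("Trace CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df[] <- lapply(df, as.double)
  new_trace(df[trace_columns()])
}

#' Read and write I-V curve CSV files
#'
#' Columns `voltage_mV, peak_current_nA, time_to_peak_ms`, plus `sem` and
#' `n` for averaged curves.
#'
#' @param iv A `vc_iv` tibble.
#' @param path File path.
#' @param seed,config Optional provenance recorded in a `#` header comment.
#' @return `write_iv_csv()` returns `path` invisibly; `read_iv_csv()` a
#'   `vc_iv` tibble.
#' @export
write_iv_csv <- function(iv, path, seed = NULL, config = NULL) {
  stopifnot(all(c("voltage_mV", "peak_current_nA") %in% names(iv)))
  write_commented_csv(iv, path, seed, config)
}

#' @rdname write_iv_csv
#' @export
read_iv_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("voltage_mV", "peak_current_nA") %in% names(df))) {
    stop("I-V CSV must have voltage_mV and peak_current_nA columns.",
         call. = FALSE)
  }
  out <- tibble::as_tibble(df)
  class(out) <- c("vc_iv", class(out))
  out
}

#' Assemble and validate a run configuration
#'
#' A run configuration bundles everything needed to reproduce a simulation:
#' amplifier settings, cell properties, ionic model choice and parameters,
#' the protocol, solver settings and the seed. [read_run_config()] loads the
#' same structure from a YAML document with nested sections `amplifier`,
#' `cell`, `ionic_model`, `protocol`, `solver` and a top-level `seed`; field
#' names match the corresponding constructor arguments exactly. All
#' constructor-level invariants are checked before any simulation runs.
#'
#' The `ionic_model` section requires a `type` of `model_cell`,
#' `generic_ina` or `none`. The `protocol` section is either
#' `{type: step, ...}` or `{type: iv, ...}` with the builder's arguments, or
#' `{segments: [[level_mV, duration_ms], ...]}`.
#'
#' @param amplifier,cell Named lists of arguments for
#'   [amplifier_settings()] / [cell_properties()] (or ready-made objects).
#' @param ionic_model Named list with a `type` field and model parameters.
#' @param protocol Named list describing the protocol (see Details).
#' @param solver Named list of `dt_out`, `dt_hold`, `rtol`, `atol`.
#' @param seed Integer seed recorded with all outputs.
#' @return An object of class `vc_config` with validated components
#'   `settings`, `cell`, `model`, `protocol` (or `protocols` for an I-V
#'   family), `solver`, `seed`.
#' @export
run_config <- function(amplifier = list(), cell = list(),
                       ionic_model = list(type = "generic_ina"),
                       protocol = list(type = "step"),
                       solver = list(), seed = 1L) {
  settings <- if (inherits(amplifier, "vc_amplifier")) amplifier else
    do.call(amplifier_settings, amplifier)
  cellp <- if (inherits(cell, "vc_cell")) cell else
    do.call(cell_properties, cell)

  model <- if (inherits(ionic_model, "vc_ionic_model")) ionic_model else {
    type <- ionic_model$type %||% "generic_ina"
    args <- ionic_model[setdiff(names(ionic_model), "type")]
    switch(type,
           model_cell = do.call(model_cell, args),
           generic_ina = do.call(generic_ina, args),
           none = no_ionic_model(),
           stop("Unknown ionic model type: ", type, call. = FALSE))
  }

  protocols <- NULL
  if (inherits(protocol, "vc_protocol")) {
    proto <- protocol
  } else if (!is.null(protocol$segments)) {
    segs <- do.call(rbind, lapply(protocol$segments, as.numeric))
    proto <- protocol(segs[, 1], segs[, 2])
  } else {
    type <- protocol$type %||% "step"
    args <- protocol[setdiff(names(protocol), "type")]
    if (identical(type, "step")) {
      proto <- do.call(step_protocol, args)
    } else if (identical(type, "iv")) {
      protocols <- do.call(iv_protocols, args)
      proto <- protocols[[1]]
    } else {
      stop("Unknown protocol type: ", type, call. = FALSE)
    }
  }

  sol <- utils::modifyList(
    list(dt_out = 0.01, dt_hold = NULL, rtol = 1e-8, atol = 1e-10),
    solver %||% list()
  )
  stopifnot(sol$dt_out > 0, sol$rtol > 0, sol$atol > 0)

  structure(list(settings = settings, cell = cellp, model = model,
                 protocol = proto, protocols = protocols, solver = sol,
                 seed = as.integer(seed)),
            class = "vc_config")
}

#' @rdname run_config
#' @param path Path to a YAML configuration file.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), c("amplifier", "cell", "ionic_model",
                               "protocol", "solver", "seed"))
  if (length(bad) > 0) {
    stop("Unknown configuration section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  run_config(amplifier = raw$amplifier %||% list(),
             cell = raw$cell %||% list(),
             ionic_model = raw$ionic_model %||% list(type = "generic_ina"),
             protocol = raw$protocol %||% list(type = "step"),
             solver = raw$solver %||% list(),
             seed = raw$seed %||% 1L)
}
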