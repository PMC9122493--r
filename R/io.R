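# Plain-text serialization: condition registries as JSON key-value config,
# datasets as a metadata table plus per-block sample matrices.

#' Write or read a condition registry as JSON
#'
#' @param registry a [condition_registry()].
#' @param path file path (`.json`).
#' @return `read_registry()` returns a [condition_registry()];
#'   `write_registry()` returns the path invisibly.
#' @export
write_registry <- function(registry, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stopf("registry JSON i/o needs the 'jsonlite' package")
  jsonlite::write_json(lapply(registry, unclass), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stopf("registry JSON i/o needs the 'jsonlite' package")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  condition_registry(lapply(raw, function(x) {
    x$second_peak_freq_hz <- x$second_peak_freq_hz %||% NA
    do.call(condition_spec, x)
  }))
}

#' Serialize a materialized dataset to a directory
#'
#' Writes `trials.csv` (participant, condition, trial, change time), the
#' generating parameters (`params.json` when jsonlite is available) and one
#' delimited sample matrix per participant-condition block
#' (`samples_p<participant>_<condition>.csv`, one column per
#' dipole-by-trial signal). Intended for small materialized datasets;
#' study-scale runs stream instead (see [run_study()]).
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(dataset$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  for (p in seq_len(dataset$n_participants)) {
    for (cn in names(dataset$blocks[[p]])) {
      utils::write.table(
        dataset$blocks[[p]][[cn]]$samples,
        file.path(dir, sprintf("samples_p%d_%s.csv", p, cn)),
        sep = ",", row.names = FALSE, col.names = FALSE)
    }
  }
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(
      list(n_participants = dataset$n_participants,
           n_trials = dataset$n_trials, n_dipoles = dataset$n_dipoles,
           seed = dataset$seed, exponent = dataset$exponent,
           noise_scale = dataset$noise_scale),
      file.path(dir, "params.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
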