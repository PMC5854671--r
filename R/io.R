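#' Read and write spike trains and voltage traces as CSV
#'
#' Spike trains are stored as a single-column CSV (`time_s`), traces as a
#' two-column CSV (`time_s,voltage_mV`); parameters that cannot be
#' recovered from the table itself (window length, sampling interval, any
#' extra metadata) go to a JSON sidecar `<file>.json`.
#'
#' @param train A [spike_train()].
#' @param file Path of the CSV file; the sidecar is `<file>.json`.
#' @param meta Optional named list of extra metadata for the sidecar.
#' @return The input object (write) or the reconstructed object (read),
#'   invisibly for writers.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_spike_train(spike_train(c(0.1, 0.3), 0.5), f)
#' read_spike_train(f)
#' @export
write_spike_train <- function(train, file, meta = list()) {
  stopifnot(inherits(train, "spike_train"))
  utils::write.csv(data.frame(time_s = train$times), file, row.names = FALSE)
  side <- c(list(type = "spike_train", duration_s = train$duration), meta)
  jsonlite::write_json(side, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(train)
}

#' @rdname write_spike_train
#' @export
read_spike_train <- function(file) {
  side <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  tab <- utils::read.csv(file)
  spike_train(tab$time_s, side$duration_s)
}

#' @rdname write_spike_train
#' @param trace A [membrane_trace()].
#' @export
write_trace <- function(trace, file, meta = list()) {
  stopifnot(inherits(trace, "membrane_trace"))
  tt <- (seq_along(trace$samples) - 1L) * trace$epsilon
  utils::write.csv(data.frame(time_s = tt, voltage_mV = trace$samples),
                   file, row.names = FALSE)
  side <- c(list(type = "membrane_trace", epsilon_s = trace$epsilon), meta)
  jsonlite::write_json(side, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(trace)
}

#' @rdname write_spike_train
#' @export
read_trace <- function(file) {
  side <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  tab <- utils::read.csv(file)
  membrane_trace(tab$voltage_mV, side$epsilon_s)
}

#' @rdname write_spike_train
#' @param stimuli A [stimulus_set()]; stored as one CSV row per stimulus
#'   (columns `nu_1 ... nu_N`) with the probabilities in the sidecar.
#' @export
write_stimulus_set <- function(stimuli, file, meta = list()) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  tab <- as.data.frame(stimuli$rates)
  names(tab) <- paste0("nu_", seq_len(ncol(tab)))
  utils::write.csv(tab, file, row.names = FALSE)
  side <- c(list(type = "stimulus_set",
                 probabilities = stimuli$probabilities), meta)
  jsonlite::write_json(side, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stimuli)
}

#' @rdname write_spike_train
#' @export
read_stimulus_set <- function(file) {
  side <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  tab <- utils::read.csv(file)
  stimulus_set(as.matrix(tab), side$probabilities)
}
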