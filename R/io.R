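#' Read / write the pipeline's columnar tables
#'
#' The analysis exchanges three plain-text formats: a trials table
#' (`trial_id, onset_s, stimulus, response_time_s, outcome`), a spikes table
#' (`unit_id, spike_time_s`), and a ground-truth JSON. Writers emit exactly
#' what the readers accept, so generated sessions round-trip.
#'
#' @param path File path.
#' @param trials Trial data frame.
#' @name session_io
NULL

#' @rdname session_io
#' @export
write_trials_csv <- function(trials, path) {
  stopifnot(all(c("trial_id", "onset_s", "stimulus", "response_time_s",
                  "outcome") %in% names(trials)))
  write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname session_io
#' @export
read_trials_csv <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "onset_s", "stimulus", "response_time_s", "outcome")
  if (!all(need %in% names(tr))) {
    stop("trials CSV must have columns: ", paste(need, collapse = ", "))
  }
  bad <- !tr$stimulus %in% c("target", "nontarget")
  if (any(bad)) stop("unknown stimulus labels in trials CSV")
  tr
}

#' @rdname session_io
#' @param spikes_list Named list of sorted spike-time vectors.
#' @export
write_spikes_csv <- function(spikes_list, path) {
  df <- data.frame(
    unit_id = rep(names(spikes_list), lengths(spikes_list)),
    spike_time_s = unlist(spikes_list, use.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname session_io
#' @export
read_spikes_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("unit_id", "spike_time_s") %in% names(df))) {
    stop("spikes CSV must have columns unit_id, spike_time_s")
  }
  lapply(split(df$spike_time_s, df$unit_id), sort)
}

#' @rdname session_io
#' @param session A `recording_session` from [simulate_session()].
#' @param dir Output directory (created if needed).
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "recording_session"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_trials_csv(session$trials, file.path(dir, "trials.csv"))
  write_spikes_csv(session$spikes, file.path(dir, "spikes.csv"))
  gt <- session$ground_truth
  gt_json <- list(
    session_spec = unclass(gt$session_spec),
    gain = gt$gain,
    units = lapply(gt$unit_specs, unclass))
  jsonlite::write_json(gt_json, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname session_io
#' @export
read_session <- function(dir) {
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  units <- lapply(seq_len(nrow(gt$units)), function(i) {
    do.call(unit_gen_spec, as.list(gt$units[i, ]))
  })
  structure(
    list(trials = read_trials_csv(file.path(dir, "trials.csv")),
         spikes = read_spikes_csv(file.path(dir, "spikes.csv")),
         ground_truth = list(
           unit_specs = units, gain = gt$gain,
           session_spec = do.call(session_gen_spec, as.list(gt$session_spec)))),
    class = "recording_session")
}
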