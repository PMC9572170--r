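# On-disk formats: per-subject CSV streams, sleep JSON, cohort manifest,
# and session bundles (flat little-endian double binary + JSON index).

#' Write a simulated subject's streams to CSV/JSON
#'
#' Emits `<id>_acc.csv` / `<id>_gyr.csv` (columns t_sec,x,y,z),
#' `<id>_rr.csv` (t_sec,rr_ms,hr_bpm), `<id>_steps.csv` (t_sec,steps) and
#' `<id>_sleep.json`.
#'
#' @param subject result of [simulate_subject()].
#' @param subject_id id used in file names.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_subject_csv <- function(subject, subject_id, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (mod in c("acc", "gyr", "rr", "steps")) {
    p <- file.path(dir, paste0(subject_id, "_", mod, ".csv"))
    write.csv(subject$streams[[mod]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  ps <- file.path(dir, paste0(subject_id, "_sleep.json"))
  jsonlite::write_json(subject$diary, ps, digits = NA)
  invisible(c(paths, ps))
}

#' Read a subject's streams back from CSV/JSON
#'
#' @param dir directory written by [write_subject_csv()].
#' @param subject_id subject id.
#' @return list with `streams` and `diary`.
#' @export
read_subject_csv <- function(dir, subject_id) {
  streams <- lapply(c(acc = "acc", gyr = "gyr", rr = "rr",
                      steps = "steps"), function(mod)
    read.csv(file.path(dir, paste0(subject_id, "_", mod, ".csv"))))
  diary <- jsonlite::fromJSON(file.path(dir,
                                        paste0(subject_id, "_sleep.json")))
  list(streams = streams, diary = as.data.frame(diary))
}

#' Write the cohort manifest JSON
#'
#' @param cohort a [simulate_cohort()] object.
#' @param dir output directory.
#' @return invisibly, the manifest path.
#' @export
write_cohort_manifest <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, "cohort_manifest.json")
  jsonlite::write_json(cohort$manifest, p, digits = NA, auto_unbox = TRUE)
  invisible(p)
}

#' Write sessions as a binary tensor bundle with a JSON index
#'
#' Slice matrices are concatenated into one flat little-endian double
#' file; the JSON index records per-session state, date and slice
#' offsets.
#'
#' @param sessions result of [simulate_sessions()].
#' @param dir output directory.
#' @return invisibly, the index path.
#' @export
write_session_bundle <- function(sessions, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bin <- file.path(dir, "sessions.bin")
  con <- file(bin, "wb")
  offset <- 0
  index <- list()
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    sizes <- vapply(s$slices, length, numeric(1))
    for (sl in s$slices)
      writeBin(as.numeric(sl), con, size = 8, endian = "little")
    index[[i]] <- list(patient_id = s$patient_id,
                       session_date = s$session_date, state = s$state,
                       n_slices = length(s$slices),
                       dims = dim(s$slices[[1]]),
                       offset = offset)
    offset <- offset + sum(sizes)
  }
  close(con)
  idx <- file.path(dir, "sessions_index.json")
  jsonlite::write_json(index, idx, digits = NA, auto_unbox = TRUE)
  invisible(idx)
}

#' Read a session bundle written by [write_session_bundle()]
#'
#' @param dir bundle directory.
#' @return list of sessions (`patient_id`, `session_date`, `state`,
#'   `slices`).
#' @export
read_session_bundle <- function(dir) {
  index <- jsonlite::fromJSON(file.path(dir, "sessions_index.json"),
                              simplifyVector = FALSE)
  con <- file(file.path(dir, "sessions.bin"), "rb")
  on.exit(close(con))
  lapply(index, function(e) {
    d <- unlist(e$dims)
    slices <- lapply(seq_len(e$n_slices), function(i)
      matrix(readBin(con, "numeric", d[1] * d[2], size = 8,
                     endian = "little"), d[1], d[2]))
    list(patient_id = e$patient_id, session_date = e$session_date,
         state = e$state, slices = slices)
  })
}

#' Write the group-comparison table to CSV
#'
#' @param comparison a [group_comparison()] table.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_comparison_csv <- function(comparison, path) {
  write.csv(as.data.frame(comparison), path, row.names = FALSE)
  invisible(path)
}
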