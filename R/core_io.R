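# Domain containers and bit-faithful readers/writers for the session CSV
# dialects and the per-sample confidence submission format.

#' Standard gravity used to convert g-unit recordings to m/s^2
#' @export
STANDARD_GRAVITY <- 9.80665

#' Load the CSV dialect declarations
#'
#' Dialects describe the column schema, sampling rate, on-disk acceleration
#' units and the meaning of the Time column for the three session formats:
#' `tdcsfog` (128 Hz protocol recordings, m/s^2), `defog` (100 Hz home
#' protocol recordings in g, with per-sample Valid and Task flags) and
#' `daily` (100 Hz unlabeled week-long recordings in g).
#'
#' @param path YAML file with dialect declarations; defaults to the copy
#'   shipped with the package.
#' @return named list of dialect configs.
#' @export
fog_dialects <- function(path = system.file("extdata", "dialects.yaml",
                                            package = "fogbench")) {
  yaml::read_yaml(path)
}

#' Construct a sensor recording
#'
#' @param acc numeric N x 3 matrix of acceleration (vertical, mediolateral,
#'   anteroposterior), in m/s^2.
#' @param sampling_rate sampling rate in Hz.
#' @param dialect one of `"tdcsfog"`, `"defog"`, `"daily"`.
#' @param subject_id,session_id opaque identifiers.
#' @param start_clock optional `POSIXct` wall-clock start (required for the
#'   daily dialect when binning by clock hour).
#' @param units_in units the source data were expressed in before
#'   normalization (`"m_per_s2"` or `"g"`); provenance only, `acc` is always
#'   stored in m/s^2.
#' @return object of class `fog_recording`.
#' @export
fog_recording <- function(acc, sampling_rate, dialect = "tdcsfog",
                          subject_id = "s01", session_id = "sess01",
                          start_clock = NULL, units_in = "m_per_s2") {
  acc <- as.matrix(acc)
  if (ncol(acc) != 3L) stop_validation("acc must have 3 columns (V, ML, AP)")
  if (nrow(acc) < 1L) stop_validation("recording must contain at least one sample")
  if (!all(is.finite(acc))) stop_validation("acceleration values must be finite")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop_validation("sampling_rate must be a positive real")
  dialect <- match.arg(dialect, c("tdcsfog", "defog", "daily"))
  if (identical(dialect, "daily") && is.null(start_clock))
    stop_validation("daily-dialect recordings require start_clock")
  colnames(acc) <- c("AccV", "AccML", "AccAP")
  structure(list(
    subject_id = subject_id, session_id = session_id, dialect = dialect,
    sampling_rate = sampling_rate, start_clock = start_clock,
    acc = acc, units_in = units_in, n = nrow(acc)
  ), class = "fog_recording")
}

#' @export
print.fog_recording <- function(x, ...) {
  cat(sprintf("<fog_recording %s/%s: %d samples @ %g Hz, dialect %s>\n",
              x$subject_id, x$session_id, x$n, x$sampling_rate, x$dialect))
  invisible(x)
}

#' Construct a per-sample label series
#'
#' Ground-truth indicators aligned to a recording. At most one of the three
#' class channels and `notype` may be true per sample; `notype` marks FOG of
#' unknown class. `valid` and `task` are the evaluation flags of the defog
#' dialect (all-true elsewhere).
#'
#' @param n series length.
#' @param start_hesitation,turn,walking,notype logical vectors (or 0/1),
#'   recycled scalars allowed.
#' @param valid,task logical evaluation flags.
#' @return object of class `fog_labels`.
#' @export
fog_labels <- function(n, start_hesitation = FALSE, turn = FALSE,
                       walking = FALSE, notype = FALSE,
                       valid = TRUE, task = TRUE) {
  f <- function(x, nm) {
    if (!is_binaryish(x)) stop_validation(paste0(nm, " must be logical/0-1"))
    x <- as.logical(x)
    if (length(x) == 1L) x <- rep(x, n)
    if (length(x) != n) stop_alignment(paste0(nm, " has wrong length"))
    x
  }
  out <- list(
    start_hesitation = f(start_hesitation, "start_hesitation"),
    turn = f(turn, "turn"), walking = f(walking, "walking"),
    notype = f(notype, "notype"), valid = f(valid, "valid"),
    task = f(task, "task")
  )
  mult <- out$start_hesitation + out$turn + out$walking + out$notype
  if (any(mult > 1L))
    stop_validation("label channels must be mutually exclusive per sample")
  structure(c(out, list(n = n)), class = "fog_labels")
}

#' Any-FOG indicator of a label series
#'
#' OR over the three class channels and `notype`: a sample counts as FOG
#' whenever its class is known or unknown-but-frozen.
#'
#' @param labels a [fog_labels] object.
#' @return logical vector.
#' @export
any_fog <- function(labels) {
  labels$start_hesitation | labels$turn | labels$walking | labels$notype
}

#' Evaluation mask from Valid/Task flags and optional walking bouts
#'
#' A sample is evaluated iff it is flagged both Valid and Task; when walking
#' bouts are supplied the mask is additionally restricted to padded bout
#' membership (see [expand_bouts]). Adding a bout restriction can only clear
#' samples, never set them.
#'
#' @param labels a [fog_labels] object.
#' @param bouts optional bout table (`start`, `end` 0-based half-open sample
#'   intervals).
#' @param sampling_rate required when `bouts` given, to convert `pad_s`.
#' @param pad_s bout padding in seconds (default 5, the daily-living rule).
#' @return logical vector of length `labels$n`.
#' @export
make_mask <- function(labels, bouts = NULL, sampling_rate = NULL, pad_s = 5) {
  mask <- labels$valid & labels$task
  if (!is.null(bouts)) {
    if (is.null(sampling_rate))
      stop_argument("sampling_rate is required when bouts are supplied")
    mask <- mask & expand_bouts(bouts, pad_s = pad_s, n = labels$n,
                                sampling_rate = sampling_rate)
  }
  mask
}

read_csv_strict <- function(path) {
  if (!file.exists(path)) stop_format(paste0("file does not exist: ", path))
  if (file.size(path) == 0) stop_format(paste0("empty file: ", path))
  df <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE)
  if (nrow(df) == 0L) stop_format(paste0("no data rows in ", path))
  df
}

check_schema <- function(cols, dialect_cfg, dialect, path) {
  want <- dialect_cfg$columns
  opt <- dialect_cfg$optional_columns %||% character()
  missing <- setdiff(want, cols)
  if (length(missing))
    stop_schema(sprintf("missing mandatory column(s) %s for dialect %s in %s",
                        paste(missing, collapse = ", "), dialect, path))
  extra <- setdiff(cols, c(want, opt))
  if (length(extra))
    stop_schema(sprintf("column(s) %s not part of dialect %s in %s",
                        paste(extra, collapse = ", "), dialect, path))
}

#' Read a labeled session CSV
#'
#' Parses one session in the declared dialect, checking the column schema
#' exactly (missing or undeclared columns raise a schema error naming the
#' column) and the uniformity of the time index. Acceleration recorded in g
#' is converted to m/s^2 with `g_constant`; the source units are kept in the
#' recording's `units_in` field.
#'
#' @param path CSV file.
#' @param dialect `"tdcsfog"`, `"defog"` or `"daily"`.
#' @param dialects dialect declarations, see [fog_dialects].
#' @param sampling_rate override of the dialect's sampling rate.
#' @param g_constant conversion constant for g-unit dialects.
#' @param subject_id,session_id,start_clock metadata (session defaults to the
#'   file name).
#' @return `list(recording = fog_recording, labels = fog_labels)`. For the
#'   unlabeled daily dialect `labels` has all class channels false.
#' @export
read_recording <- function(path, dialect, dialects = fog_dialects(),
                           sampling_rate = NULL,
                           g_constant = STANDARD_GRAVITY,
                           subject_id = "unknown",
                           session_id = sub("\\.csv$", "", basename(path)),
                           start_clock = NULL) {
  dialect <- match.arg(dialect, names(dialects))
  cfg <- dialects[[dialect]]
  df <- read_csv_strict(path)
  check_schema(names(df), cfg, dialect, path)

  tm <- df$Time
  if (!is.numeric(tm)) stop_format("Time column must be numeric")
  if (length(tm) > 1L) {
    steps <- diff(tm)
    if (any(steps <= 0) || diff(range(steps)) > 1e-6 * max(abs(steps)))
      stop_format("non-uniform time index")
  }
  fs <- sampling_rate %||% cfg$sampling_rate

  acc <- as.matrix(df[, c("AccV", "AccML", "AccAP")])
  units_in <- cfg$units
  if (identical(units_in, "g")) acc <- acc * g_constant

  rec <- fog_recording(acc, fs, dialect = dialect, subject_id = subject_id,
                       session_id = session_id, start_clock = start_clock,
                       units_in = units_in)

  n <- nrow(df)
  has <- function(cl) if (cl %in% names(df)) df[[cl]] else FALSE
  labels <- fog_labels(
    n,
    start_hesitation = has("StartHesitation"),
    turn = has("Turn"),
    walking = has("Walking"),
    notype = has("Notype"),
    valid = if ("Valid" %in% names(df)) df$Valid else TRUE,
    task = if ("Task" %in% names(df)) df$Task else TRUE
  )
  list(recording = rec, labels = labels)
}

#' Write a session CSV in a declared dialect
#'
#' Inverse of [read_recording]: acceleration is converted back to the
#' dialect's on-disk units so that write-then-read round-trips.
#'
#' @inheritParams read_recording
#' @param recording a [fog_recording].
#' @param labels a [fog_labels] (ignored for the daily dialect).
#' @export
write_recording <- function(recording, labels, path,
                            dialects = fog_dialects(),
                            g_constant = STANDARD_GRAVITY) {
  cfg <- dialects[[recording$dialect]]
  acc <- recording$acc
  if (identical(cfg$units, "g")) acc <- acc / g_constant
  df <- data.frame(Time = seq_len(recording$n) - 1L)
  df$AccV <- acc[, 1]; df$AccML <- acc[, 2]; df$AccAP <- acc[, 3]
  if (recording$dialect != "daily") {
    df$StartHesitation <- as.integer(labels$start_hesitation)
    df$Turn <- as.integer(labels$turn)
    df$Walking <- as.integer(labels$walking)
    if (recording$dialect == "defog") {
      df$Valid <- as.integer(labels$valid)
      df$Task <- as.integer(labels$task)
      if (any(labels$notype)) df$Notype <- as.integer(labels$notype)
    }
  }
  for (cl in c("AccV", "AccML", "AccAP")) df[[cl]] <- sprintf("%.17g", df[[cl]])
  data.table::fwrite(df, path, quote = FALSE)
  invisible(path)
}

#' Construct a per-sample confidence score series
#'
#' @param scores numeric N x 3 matrix, columns ordered start hesitation,
#'   turn, walking; higher means more confident.
#' @return N x 3 matrix with canonical column names.
#' @export
fog_scores <- function(scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 3L) stop_validation("scores must have 3 class columns")
  if (!all(is.finite(scores))) stop_validation("scores must be finite")
  colnames(scores) <- FOG_CLASSES
  scores
}

#' Write / read a per-sample confidence submission
#'
#' One row per sample, keyed `"<session>_<sample index>"`, with one
#' confidence column per FOG class. Values round-trip at full double
#' precision.
#'
#' @param scores named list of score matrices (see [fog_scores]), one per
#'   session; row order in the file is session order then sample order.
#' @param path CSV file.
#' @export
write_submission <- function(scores, path) {
  if (length(scores) && (is.null(names(scores)) || any(names(scores) == "")))
    stop_validation("scores must be a named list keyed by session id")
  rows <- lapply(names(scores), function(sess) {
    m <- fog_scores(scores[[sess]])
    if (anyNA(m)) stop_validation("NaN/NA confidence values are not allowed")
    data.frame(Id = sprintf("%s_%d", sess, seq_len(nrow(m)) - 1L),
               StartHesitation = sprintf("%.17g", m[, 1]),
               Turn = sprintf("%.17g", m[, 2]),
               Walking = sprintf("%.17g", m[, 3]))
  })
  df <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
        else data.frame(Id = character(), StartHesitation = character(),
                        Turn = character(), Walking = character())
  data.table::fwrite(df, path, quote = FALSE)
  invisible(path)
}

#' @rdname write_submission
#' @return `read_submission` returns a named list of score matrices.
#' @export
read_submission <- function(path) {
  if (!file.exists(path)) stop_format(paste0("file does not exist: ", path))
  df <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE,
                          colClasses = list(character = "Id"))
  want <- c("Id", "StartHesitation", "Turn", "Walking")
  missing <- setdiff(want, names(df))
  if (length(missing))
    stop_format(paste0("submission is missing column(s): ",
                       paste(missing, collapse = ", ")))
  if (anyDuplicated(df$Id)) stop_format("duplicate sample ids in submission")
  if (nrow(df) == 0L) return(list())
  sess <- sub("_[0-9]+$", "", df$Id)
  idx <- as.integer(sub("^.*_", "", df$Id))
  out <- lapply(split(seq_len(nrow(df)), factor(sess, levels = unique(sess))),
                function(i) {
                  i <- i[order(idx[i])]
                  m <- as.matrix(df[i, c("StartHesitation", "Turn", "Walking")])
                  rownames(m) <- NULL
                  fog_scores(m)
                })
  out
}
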