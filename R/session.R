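#' Construct a raw accelerometer session
#'
#' A session is one continuous recording from the abdominal belt sensor:
#' tri-axial acceleration sampled at a fixed rate (280 samples/s on the
#' device), in the sensor's uncalibrated linear unit (AMU), plus two
#' button-event channels. Button 1 marks fetal movements felt by the mother,
#' button 2 marks her own movements (laughs). Button events are exposed as
#' 1-based sample indices of the press onsets.
#'
#' @param ax,ay,az Numeric vectors of equal length: acceleration along the
#'   three sensor axes, in AMU. The Z axis is normal to the abdomen.
#' @param fs Sampling rate in samples per second.
#' @param btn1_idx,btn2_idx Strictly increasing integer vectors of 1-based
#'   sample indices at which button 1 (felt fetal movement) and button 2
#'   (maternal movement) were pressed.
#' @param meta Named list of session metadata; see [session_meta()].
#'
#' @return An object of class `fetmov_session`.
#' @seealso [read_session()], [write_session()], [session_summary()]
#' @export
#' @examples
#' s <- fm_session(az = sin(1:100), fs = 280)
#' session_summary(s)
fm_session <- function(az, ax = NULL, ay = NULL, fs = 280,
                       btn1_idx = integer(), btn2_idx = integer(),
                       meta = session_meta()) {
  az <- as.numeric(az)
  n <- length(az)
  if (n < 1L) abort("a session needs at least one sample")
  ax <- if (is.null(ax)) numeric(n) else as.numeric(ax)
  ay <- if (is.null(ay)) numeric(n) else as.numeric(ay)
  if (length(ax) != n || length(ay) != n) {
    abort("ax, ay, az must have equal length")
  }
  assert_scalar_num(fs, "fs", lo = 1e-9)
  btn1_idx <- as.integer(btn1_idx)
  btn2_idx <- as.integer(btn2_idx)
  for (b in list(btn1 = btn1_idx, btn2 = btn2_idx)) {
    if (length(b) && (any(b < 1L) || any(b > n))) {
      abort("button indices must lie within the recorded samples")
    }
    if (length(b) > 1L && any(diff(b) <= 0L)) {
      abort("button indices must be strictly increasing")
    }
  }
  meta <- validate_meta(meta)
  structure(
    list(meta = meta, fs = fs, ax = ax, ay = ay, az = az,
         btn1_idx = btn1_idx, btn2_idx = btn2_idx),
    class = "fetmov_session"
  )
}

#' Session metadata
#'
#' Basic details recorded before each session: an anonymised subject id, the
#' mother's age, gestational age in weeks, fetal gender, and free-text notes.
#'
#' @param subject_id Non-empty identifier string.
#' @param maternal_age Mother's age in years, or `NA`.
#' @param gestational_age Gestational age in weeks; when given it must lie in
#'   `[26, 42]` (the clinically monitored third-trimester range).
#' @param fetal_gender One of `"male"`, `"female"`, `"unstated"`.
#' @param session_date ISO date string or `NA`.
#' @param notes Free text.
#' @return A named list with class-checked fields.
#' @export
session_meta <- function(subject_id = "anon", maternal_age = NA_real_,
                         gestational_age = NA_real_,
                         fetal_gender = c("unstated", "male", "female"),
                         session_date = NA_character_, notes = "") {
  fetal_gender <- match.arg(fetal_gender)
  validate_meta(list(
    subject_id = subject_id, maternal_age = maternal_age,
    gestational_age = gestational_age, fetal_gender = fetal_gender,
    session_date = session_date, notes = notes
  ))
}

validate_meta <- function(meta) {
  defaults <- list(subject_id = "anon", maternal_age = NA_real_,
                   gestational_age = NA_real_, fetal_gender = "unstated",
                   session_date = NA_character_, notes = "")
  meta <- utils::modifyList(defaults, meta[!vapply(meta, is.null, logical(1))])
  if (!is.character(meta$subject_id) || !nzchar(meta$subject_id)) {
    abort("subject_id must be a non-empty string")
  }
  ga <- meta$gestational_age
  if (!is.na(ga) && (ga < 26 || ga > 42)) {
    abort("gestational_age must lie in [26, 42] weeks when given")
  }
  if (!meta$fetal_gender %in% c("male", "female", "unstated")) {
    abort("fetal_gender must be male, female or unstated")
  }
  meta
}

#' @export
print.fetmov_session <- function(x, ...) {
  cat(sprintf(
    "<fetmov_session> subject %s: %d samples @ %g Hz (%.1f s), %d/%d button events\n",
    x$meta$subject_id, length(x$az), x$fs, length(x$az) / x$fs,
    length(x$btn1_idx), length(x$btn2_idx)
  ))
  invisible(x)
}

#' @export
as_tibble.fetmov_session <- function(x, ...) {
  n <- length(x$az)
  btn1 <- integer(n); btn1[x$btn1_idx] <- 1L
  btn2 <- integer(n); btn2[x$btn2_idx] <- 1L
  tibble(i = seq_len(n) - 1L, ax = x$ax, ay = x$ay, az = x$az,
         btn1 = btn1, btn2 = btn2)
}

# On-disk session-log format -------------------------------------------------
#
# UTF-8 text. Header lines "#key=value" (fs, subject_id, ...), then the
# column header "i,ax,ay,az,btn1,btn2", then one comma-separated row per
# sample. The sample counter `i` is 0-based on disk; button channels are
# per-sample 0/1 flags, collapsed to rising-edge press indices in memory
# (a held button spanning several samples is one event at its first sample).

meta_header_keys <- c("subject_id", "maternal_age", "gestational_age",
                      "fetal_gender", "session_date", "notes")

#' Read a device session log
#'
#' Parses the columnar session-log format written by [write_session()]:
#' `#key=value` header lines followed by a `i,ax,ay,az,btn1,btn2` table
#' (see Details in [fm_session()] for the in-memory form).
#'
#' @param path Path to a session-log file.
#' @param strict If `TRUE` (default), a non-monotone sample counter is an
#'   error; if `FALSE`, rows are repaired by sorting, with a warning.
#' @return A [fm_session()] object.
#' @export
read_session <- function(path, strict = TRUE) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readr::read_lines(path)
  hdr <- grepl("^#", lines)
  n_hdr <- if (any(!hdr)) which(!hdr)[1] - 1L else length(lines)
  header <- lines[seq_len(n_hdr)]
  kv <- strsplit(sub("^#", "", header), "=", fixed = TRUE)
  bad <- lengths(kv) < 2L
  if (any(bad)) abort("malformed header line (expected #key=value)")
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = "="), "")
  hmap <- setNames(vals, keys)
  if (!"fs" %in% keys) abort("header is missing the sampling rate (#fs=...)")
  fs <- suppressWarnings(as.numeric(hmap[["fs"]]))
  if (is.na(fs) || fs <= 0) abort("invalid #fs header value")

  if (length(lines) <= n_hdr) abort("file has no data table")
  col_line <- lines[n_hdr + 1L]
  want <- c("i", "ax", "ay", "az", "btn1", "btn2")
  got <- strsplit(col_line, ",", fixed = TRUE)[[1]]
  if (!identical(trimws(got), want)) {
    abort(sprintf("bad column header %s (expected %s)",
                  col_line, paste(want, collapse = ",")))
  }
  # base read.csv: strtod parsing is correctly rounded, so %.17g-written
  # values round-trip bit-exactly
  dat <- utils::read.csv(
    text = lines[-seq_len(n_hdr + 1L)], header = FALSE, col.names = want,
    colClasses = c("numeric", "numeric", "numeric", "numeric",
                   "integer", "integer")
  )
  if (nrow(dat) < 1L) abort("file has no data rows")
  if (anyNA(dat)) abort("non-numeric or missing values in the data table")
  if (is.unsorted(dat$i, strictly = TRUE)) {
    if (strict) abort("sample counter is not strictly increasing")
    warn("sample counter not monotone; rows repaired by sorting")
    dat <- dat[order(dat$i), ]
  }

  meta <- list()
  for (k in meta_header_keys) {
    if (k %in% keys) {
      v <- hmap[[k]]
      meta[[k]] <- if (k %in% c("maternal_age", "gestational_age")) {
        suppressWarnings(as.numeric(v))
      } else v
    }
  }
  fm_session(
    az = dat$az, ax = dat$ax, ay = dat$ay, fs = fs,
    btn1_idx = rising_edges(dat$btn1), btn2_idx = rising_edges(dat$btn2),
    meta = meta
  )
}

# First sample of each run of 1s: a held press is one event.
rising_edges <- function(flag) {
  flag <- as.integer(flag != 0L)
  which(diff(c(0L, flag)) == 1L)
}

#' Write a session to the columnar session-log format
#'
#' @param session A [fm_session()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "fetmov_session"))
  m <- session$meta
  fmt_meta <- function(k) {
    v <- m[[k]]
    if (is.null(v) || (length(v) == 1L && is.na(v)) || !nzchar(v)) return(NULL)
    sprintf("#%s=%s", k, as.character(v))
  }
  header <- c(sprintf("#fs=%s", format(session$fs, digits = 15)),
              unlist(lapply(meta_header_keys, fmt_meta)))
  dat <- as_tibble(session)
  # %.17g guarantees doubles survive write -> parse -> write bit-exactly
  rows <- sprintf("%d,%.17g,%.17g,%.17g,%d,%d",
                  dat$i, dat$ax, dat$ay, dat$az, dat$btn1, dat$btn2)
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(c(header, "i,ax,ay,az,btn1,btn2", rows), con)
  invisible(path)
}

#' Summarise a session
#'
#' One row per session: duration in seconds, sample count, button-press
#' counts, and per-axis amplitude ranges. Sessions in the clinical protocol
#' were about 20 minutes long.
#'
#' @param session A [fm_session()] object.
#' @return A one-row tibble.
#' @export
#' @examples
#' session_summary(fm_session(az = rnorm(2800), fs = 280))
session_summary <- function(session) {
  stopifnot(inherits(session, "fetmov_session"))
  n <- length(session$az)
  tibble(
    subject_id = session$meta$subject_id,
    n_samples = n,
    fs = session$fs,
    duration_s = n / session$fs,
    n_btn1 = length(session$btn1_idx),
    n_btn2 = length(session$btn2_idx),
    ax_min = min(session$ax), ax_max = max(session$ax),
    ay_min = min(session$ay), ay_max = max(session$ay),
    az_min = min(session$az), az_max = max(session$az)
  )
}
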