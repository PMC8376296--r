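#' @importFrom stats sd qnorm quantile rnorm runif rexp rpois rlnorm rbinom
#'   complete.cases lm glm poisson coef anova t.test p.adjust wilcox.test
#'   factanal varimax cor cov approx pt median aggregate setNames dnorm qpois
#' @importFrom utils read.csv write.csv head tail
NULL

EVENT_KINDS <- c("DS_on", "DS_off", "NS_on", "NS_off", "active_press",
                 "inactive_press", "port_entry", "reward", "infusion")

#' Assemble a session bundle
#'
#' A session bundle holds everything recorded in one behavioral session:
#' two-LED head tracking, the behavioral event log, per-neuron spike trains,
#' and a manifest describing arena geometry and timing. All times are seconds
#' from session start; frame `k` (zero-based) occurs at `k / frame_rate`.
#'
#' @param tracking data frame with columns `frame`, `time_s`, `red_x_mm`,
#'   `red_y_mm`, `green_x_mm`, `green_y_mm`. Missing LED samples are `NA`.
#' @param events data frame with columns `time_s`, `kind`, `payload`.
#' @param spikes data frame with columns `neuron_id`, `time_s`.
#' @param manifest named list with `frame_rate_hz`, `duration_s`,
#'   `arena_mm` (width, height), `lever_xy_mm`, `receptacle_xy_mm`,
#'   `subject_id`, `session_id`, `infusion_time_s` (or `NULL`) and
#'   `infusion_condition` (or `NULL`).
#' @param check if `TRUE` (default) stop when [validate_session()] reports
#'   violations.
#' @return object of class `vp_session`.
#' @export
session_bundle <- function(tracking, events, spikes, manifest, check = TRUE) {
  b <- structure(list(tracking = tracking, events = events, spikes = spikes,
                      manifest = manifest),
                 class = "vp_session")
  if (check) {
    v <- validate_session(b)
    if (nrow(v) > 0L) {
      stop("invalid session bundle: ", paste(utils::head(v$message, 5L),
                                             collapse = "; "))
    }
  }
  b
}

#' @export
print.vp_session <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<vp_session> subject %s, session %s\n", m$subject_id, m$session_id))
  cat(sprintf("  %d frames @ %g Hz, %.0f s, %d events, %d neurons\n",
              nrow(x$tracking), m$frame_rate_hz, m$duration_s,
              nrow(x$events), length(unique(x$spikes$neuron_id))))
  invisible(x)
}

#' Validate a session bundle
#'
#' Checks every structural invariant of a bundle (monotone times, frame/time
#' consistency, cue pairing, spike monotonicity, geometry) and returns the
#' violations as data, never as an error.
#'
#' @param bundle a `vp_session` (checked leniently, so partially broken
#'   bundles can be inspected).
#' @return data frame with columns `field`, `index`, `rule`, `message`;
#'   zero rows iff the bundle is valid.
#' @export
validate_session <- function(bundle) {
  out <- list()
  bad <- function(field, index, rule, message) {
    out[[length(out) + 1L]] <<- data.frame(field = field, index = index,
                                           rule = rule, message = message,
                                           stringsAsFactors = FALSE)
  }
  m <- bundle$manifest
  fr <- m$frame_rate_hz
  dur <- m$duration_s
  if (!is.numeric(fr) || length(fr) != 1L || !is.finite(fr) || fr <= 0)
    bad("manifest.frame_rate_hz", NA, "positive", "frame rate must be a positive number")
  if (!is.numeric(dur) || length(dur) != 1L || !is.finite(dur) || dur <= 0)
    bad("manifest.duration_s", NA, "positive", "duration must be a positive number")
  if (length(m$arena_mm) == 2L && all(is.finite(unlist(m$arena_mm)))) {
    arena <- as.numeric(unlist(m$arena_mm))
    for (nm in c("lever_xy_mm", "receptacle_xy_mm")) {
      xy <- as.numeric(unlist(m[[nm]]))
      if (length(xy) != 2L || any(!is.finite(xy)))
        bad(paste0("manifest.", nm), NA, "finite_pair", paste(nm, "must be two finite numbers"))
      else if (any(xy < 0) || any(xy > arena))
        bad(paste0("manifest.", nm), NA, "inside_arena", paste(nm, "lies outside the arena"))
    }
  } else {
    bad("manifest.arena_mm", NA, "finite_pair", "arena_mm must be two finite numbers")
  }

  tr <- bundle$tracking
  if (is.data.frame(tr) && nrow(tr) > 0L && all(c("frame", "time_s") %in% names(tr))) {
    if (any(diff(tr$time_s) <= 0))
      bad("tracking.time_s", which(diff(tr$time_s) <= 0)[1L], "strictly_increasing",
          "tracking time must be strictly increasing")
    if (is.numeric(fr) && is.finite(fr) && fr > 0) {
      expected <- tr$frame / fr
      off <- which(abs(tr$time_s - expected) > 1e-6)
      if (length(off) > 0L)
        bad("tracking.time_s", off[1L], "frame_time_consistency",
            sprintf("time_s differs from frame/frame_rate by > 1e-6 at row %d", off[1L]))
    }
    for (col in c("red_x_mm", "red_y_mm", "green_x_mm", "green_y_mm")) {
      v <- tr[[col]]
      nf <- which(!is.na(v) & !is.finite(v))
      if (length(nf) > 0L)
        bad(paste0("tracking.", col), nf[1L], "finite_where_present",
            sprintf("non-finite coordinate in %s at row %d", col, nf[1L]))
    }
  }

  ev <- bundle$events
  if (is.data.frame(ev) && nrow(ev) > 0L && all(c("time_s", "kind") %in% names(ev))) {
    if (any(diff(ev$time_s) < 0))
      bad("events.time_s", which(diff(ev$time_s) < 0)[1L], "nondecreasing",
          "event times must be nondecreasing")
    unknown <- which(!(ev$kind %in% EVENT_KINDS))
    if (length(unknown) > 0L)
      bad("events.kind", unknown[1L], "known_kind",
          sprintf("unknown event kind '%s'", ev$kind[unknown[1L]]))
    if (is.numeric(dur) && is.finite(dur)) {
      oob <- which(ev$time_s < 0 | ev$time_s > dur)
      if (length(oob) > 0L)
        bad("events.time_s", oob[1L], "within_session",
            sprintf("event at %.3f s outside the %.0f s session", ev$time_s[oob[1L]], dur))
    }
    for (cue in c("DS", "NS")) {
      on_t <- ev$time_s[ev$kind == paste0(cue, "_on")]
      off_t <- ev$time_s[ev$kind == paste0(cue, "_off")]
      for (i in seq_along(on_t)) {
        nxt <- off_t[off_t > on_t[i]]
        if (length(nxt) == 0L || min(nxt) - on_t[i] > 10 + 1e-9)
          bad("events", i, "cue_pairing",
              sprintf("%s_on at %.3f s has no matching %s_off within 10 s", cue, on_t[i], cue))
      }
    }
  }

  sp <- bundle$spikes
  if (is.data.frame(sp) && nrow(sp) > 0L && all(c("neuron_id", "time_s") %in% names(sp))) {
    by_neuron <- split(sp$time_s, sp$neuron_id)
    for (id in names(by_neuron)) {
      st <- by_neuron[[id]]
      if (any(diff(st) <= 0))
        bad("spikes.time_s", id, "strictly_increasing",
            sprintf("spike times for neuron %s are not strictly increasing", id))
      if (is.numeric(dur) && is.finite(dur) && (any(st < 0) || any(st > dur)))
        bad("spikes.time_s", id, "within_session",
            sprintf("neuron %s has spikes outside the session span", id))
    }
  }

  if (length(out) == 0L)
    data.frame(field = character(), index = character(), rule = character(),
               message = character(), stringsAsFactors = FALSE)
  else
    do.call(rbind, out)
}

#' Write a session bundle to disk
#'
#' Writes `tracking.csv`, `events.csv`, `spikes.csv` and `manifest.json` into
#' `dest` at 6-decimal precision so a round-trip through [load_session()]
#' reproduces the bundle exactly at that precision.
#'
#' @param bundle valid `vp_session`.
#' @param dest directory (created if needed).
#' @return invisibly, a character vector of the files written.
#' @export
write_session <- function(bundle, dest) {
  v <- validate_session(bundle)
  if (nrow(v) > 0L)
    stop("refusing to write invalid bundle: ", v$message[1L])
  if (!dir.exists(dest) && !dir.create(dest, recursive = TRUE))
    stop("cannot create destination directory: ", dest)

  fmt <- function(x) ifelse(is.na(x), "", formatC(x, format = "f", digits = 6))
  tr <- bundle$tracking
  tr_out <- data.frame(frame = tr$frame, time_s = fmt(tr$time_s),
                       red_x_mm = fmt(tr$red_x_mm), red_y_mm = fmt(tr$red_y_mm),
                       green_x_mm = fmt(tr$green_x_mm), green_y_mm = fmt(tr$green_y_mm))
  ev <- bundle$events
  payload <- if ("payload" %in% names(ev)) ev$payload else rep("", nrow(ev))
  payload[is.na(payload)] <- ""
  ev_out <- data.frame(time_s = fmt(ev$time_s), kind = ev$kind, payload = payload)
  sp <- bundle$spikes
  sp_out <- data.frame(neuron_id = sp$neuron_id, time_s = fmt(sp$time_s))

  files <- file.path(dest, c("tracking.csv", "events.csv", "spikes.csv", "manifest.json"))
  write.csv(tr_out, files[1L], row.names = FALSE, quote = FALSE)
  write.csv(ev_out, files[2L], row.names = FALSE, quote = FALSE)
  write.csv(sp_out, files[3L], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(bundle$manifest, files[4L], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(files)
}

read_csv_checked <- function(path, required) {
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", "")),
                 error = function(e) stop("parse error in ", basename(path),
                                          ": ", conditionMessage(e)))
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L)
    stop("parse error in ", basename(path), ": missing column(s) ",
         paste(miss, collapse = ", "))
  for (col in setdiff(required, c("kind", "payload", "neuron_id"))) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      badrow <- which(!is.na(v) & is.na(coerced))
      if (length(badrow) > 0L)
        stop("parse error in ", basename(path), " at line ", badrow[1L] + 1L,
             ": non-numeric value '", v[badrow[1L]], "' in column ", col)
      df[[col]] <- coerced
    }
  }
  df
}

#' Load a session bundle from disk
#'
#' @param root directory containing `manifest.json`, `tracking.csv`,
#'   `events.csv`, `spikes.csv`.
#' @param check validate after loading (default `TRUE`).
#' @return `vp_session`.
#' @export
load_session <- function(root, check = TRUE) {
  need <- c("manifest.json", "tracking.csv", "events.csv", "spikes.csv")
  paths <- file.path(root, need)
  missing <- need[!file.exists(paths)]
  if (length(missing) > 0L)
    stop("load error: missing file(s) in ", root, ": ",
         paste(missing, collapse = ", "))
  manifest <- jsonlite::read_json(paths[1L], simplifyVector = TRUE)
  tracking <- read_csv_checked(paths[2L], c("frame", "time_s", "red_x_mm",
                                            "red_y_mm", "green_x_mm", "green_y_mm"))
  events <- read_csv_checked(paths[3L], c("time_s", "kind", "payload"))
  if (!"payload" %in% names(events)) events$payload <- NA_character_
  spikes <- read_csv_checked(paths[4L], c("neuron_id", "time_s"))
  session_bundle(tracking, events, spikes, manifest, check = check)
}

#' Cue trials recorded in an event log
#'
#' @param events event-log data frame.
#' @return data frame with one row per cue onset: `cue_type`, `onset_s`,
#'   `offset_s` (NA if unmatched).
#' @export
cue_table <- function(events) {
  rows <- list()
  for (cue in c("DS", "NS")) {
    on_t <- events$time_s[events$kind == paste0(cue, "_on")]
    off_t <- events$time_s[events$kind == paste0(cue, "_off")]
    if (length(on_t) == 0L) next
    off <- vapply(on_t, function(t0) {
      nxt <- off_t[off_t > t0]
      if (length(nxt) == 0L) NA_real_ else min(nxt)
    }, numeric(1))
    rows[[cue]] <- data.frame(cue_type = cue, onset_s = on_t, offset_s = off,
                              stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(cue_type = character(), onset_s = numeric(),
                      offset_s = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$onset_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}
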