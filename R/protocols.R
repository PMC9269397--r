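#' Activity protocol
#'
#' An ordered script of activity segments a subject executes during a data
#' acquisition session.
#'
#' @param name Protocol name.
#' @param activities Character vector of activity labels, one per segment.
#' @param durations Integer vector of segment durations in seconds (> 0).
#' @return An object of class `protocol`: a list with `name` and a
#'   data.frame `segments` (columns `activity`, `duration_s`).
#' @export
#' @examples
#' protocol("demo", c("standing", "walk_low"), c(60, 120))
protocol <- function(name, activities, durations) {
  if (length(activities) != length(durations))
    stop("'activities' and 'durations' must have equal length")
  bad <- setdiff(activities, activity_classes())
  if (length(bad)) stop("unknown activity label: ", paste(bad, collapse = ", "))
  durations <- as.numeric(durations)
  if (any(durations <= 0) || any(durations != round(durations)))
    stop("segment durations must be positive integer seconds")
  structure(list(
    name = as.character(name),
    segments = data.frame(activity = as.character(activities),
                          duration_s = durations,
                          stringsAsFactors = FALSE)
  ), class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf("Protocol '%s': %d segments, %d s total\n",
              x$name, nrow(x$segments), protocol_duration(x)))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Total duration of a protocol in seconds
#' @param p A [protocol()].
#' @return Total duration (s).
#' @export
protocol_duration <- function(p) sum(p$segments$duration_s)

#' Packaged validation protocols
#'
#' The three scripted sessions used for validation: protocols 1 and 2 last
#' 7 minutes, protocol 3 lasts 6 minutes, each mixing the four static
#' postures with walking bouts at the three speed bands.
#'
#' @return Named list of three [protocol()] objects.
#' @export
default_protocols <- function() {
  list(
    protocol1 = protocol("protocol1",
      c("walk_very_low", "standing", "walk_low", "sitting", "walk_low",
        "standing", "walk_medium", "bending", "walk_very_low", "sitting"),
      c(30, 60, 30, 90, 30, 30, 30, 30, 60, 30)),
    protocol2 = protocol("protocol2",
      c("walk_very_low", "lying", "standing", "bending", "walk_low",
        "lying", "walk_low", "standing", "walk_medium", "sitting"),
      c(60, 30, 30, 30, 30, 60, 30, 60, 60, 30)),
    protocol3 = protocol("protocol3",
      c("sitting", "standing", "walk_low", "lying", "standing",
        "bending", "walk_very_low", "sitting", "standing", "walk_very_low"),
      c(30, 30, 30, 60, 30, 30, 30, 60, 30, 30))
  )
}

#' Per-second ground-truth labels of a protocol
#'
#' Expands a protocol into one label per second, the granularity at which
#' the pipeline emits classification ticks.
#'
#' @param p A [protocol()].
#' @return Character vector of length `protocol_duration(p)`; element `i`
#'   is the activity during second `[i-1, i)`.
#' @export
protocol_labels <- function(p) {
  rep(p$segments$activity, times = p$segments$duration_s)
}

# ---- configuration file I/O -------------------------------------------------

#' Write protocols and a MET table to a YAML configuration file
#'
#' @param path Output file path.
#' @param protocols Named list of [protocol()] objects.
#' @param met A [met_table()].
#' @export
write_config <- function(path, protocols = default_protocols(),
                         met = met_table()) {
  cfg <- list(
    met = as.list(unclass(met)),
    protocols = lapply(protocols, function(p) list(
      name = p$name,
      segments = lapply(seq_len(nrow(p$segments)), function(i) list(
        activity = p$segments$activity[i],
        duration_s = p$segments$duration_s[i]))
    ))
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read protocols and a MET table from a YAML configuration file
#'
#' @param path File written by [write_config()].
#' @return List with elements `met` (a [met_table()]) and `protocols`
#'   (named list of [protocol()]).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  met <- met_table(unlist(cfg$met))
  protocols <- lapply(cfg$protocols, function(p) {
    acts <- vapply(p$segments, function(s) s$activity, character(1))
    durs <- vapply(p$segments, function(s) as.numeric(s$duration_s), numeric(1))
    protocol(p$name, acts, durs)
  })
  names(protocols) <- vapply(protocols, function(p) p$name, character(1))
  list(met = met, protocols = protocols)
}

# ---- classification ticks ---------------------------------------------------

#' Construct a tick stream
#'
#' A tick is one interval of pipeline output carrying a single activity
#' label; energy expenditure accumulates tick by tick. Ticks must be
#' ordered and non-overlapping.
#'
#' @param t Numeric vector of tick start times (s from stream start).
#' @param label Character vector of activity labels, one per tick.
#' @param dt Tick durations in seconds (default 1, recycled).
#' @return A data.frame of class `tick_stream` with columns `t_s`, `label`,
#'   `dt_s`.
#' @export
tick_stream <- function(t, label, dt = 1) {
  if (length(t) != length(label)) stop("'t' and 'label' lengths differ")
  dt <- rep_len(as.numeric(dt), length(t))
  if (length(t) && any(dt <= 0)) stop("tick durations must be positive")
  bad <- setdiff(unique(label), activity_classes())
  if (length(bad)) stop("unknown activity label: ", paste(bad, collapse = ", "))
  if (length(t) > 1L) {
    if (any(diff(t) <= 0)) stop("ticks must be strictly ordered by time")
    if (any(t[-1] < (t + dt)[-length(t)] - 1e-9))
      stop("ticks must not overlap")
  }
  structure(data.frame(t_s = as.numeric(t), label = as.character(label),
                       dt_s = dt, stringsAsFactors = FALSE),
            class = c("tick_stream", "data.frame"))
}

#' Ground-truth tick stream of a protocol
#'
#' @param p A [protocol()].
#' @param dt Tick duration in seconds (must divide every segment duration).
#' @return A [tick_stream()] covering the whole protocol.
#' @export
protocol_ticks <- function(p, dt = 1) {
  if (any(p$segments$duration_s %% dt != 0))
    stop("'dt' must divide every segment duration")
  labels <- rep(p$segments$activity, times = p$segments$duration_s / dt)
  tick_stream(seq_along(labels) * dt - dt, labels, dt)
}

#' Read / write tick streams as CSV
#'
#' Columns `t_s,label,dt_s`, header mandatory.
#' @param x A [tick_stream()].
#' @param path File path.
#' @return `read_ticks` returns a [tick_stream()].
#' @export
write_ticks <- function(x, path) {
  utils::write.csv(as.data.frame(x)[c("t_s", "label", "dt_s")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ticks
#' @export
read_ticks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_s", "label", "dt_s")
  if (!all(need %in% names(df)))
    stop("tick CSV must have columns t_s, label, dt_s")
  tick_stream(df$t_s, df$label, df$dt_s)
}
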