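#' Conditioning-protocol specification
#'
#' An ordered, non-overlapping set of labeled epochs. Built-in protocols
#' follow the standard auditory fear-conditioning design: day 1 is 2 min
#' habituation then five trials of a 20 s tone co-terminating with a 2 s
#' foot shock, each followed by 1 min of observation; day 2 is a 5 min
#' context re-exposure, and separately a cue test of 2 min habituation then
#' three trials of 20 s tone plus 1 min observation.
#'
#' @param epochs data frame with columns `label`, `start_s`, `end_s`,
#'   `kind` (one of `"habituation"`, `"tone"`, `"observation"`,
#'   `"context"`).
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(epochs) {
  stopifnot(all(c("label", "start_s", "end_s", "kind") %in% names(epochs)))
  if (any(epochs$end_s <= epochs$start_s)) .stopf("epochs must have positive length")
  o <- order(epochs$start_s)
  epochs <- epochs[o, ]
  if (any(epochs$start_s[-1] < epochs$end_s[-nrow(epochs)] - 1e-9))
    .stopf("epochs must be non-overlapping")
  structure(list(epochs = epochs), class = "protocol_spec")
}

#' @rdname protocol_spec
#' @param include_tone for the day-1 conditioning protocol: score tone
#'   periods as part of the per-trial observation window (`TRUE`) or score
#'   only the 1 min inter-trial interval (`FALSE`, default).
#' @export
protocol_day1 <- function(include_tone = FALSE) {
  t0 <- 120                                # after 2 min habituation
  rows <- list(data.frame(label = "H", start_s = 0, end_s = 120,
                          kind = "habituation"))
  for (k in 1:5) {
    tone_on <- t0 + (k - 1) * (20 + 60)
    if (include_tone) {
      rows[[length(rows) + 1L]] <- data.frame(
        label = paste0("T", k), start_s = tone_on, end_s = tone_on + 80,
        kind = "observation")
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        label = paste0("T", k), start_s = tone_on + 20, end_s = tone_on + 80,
        kind = "observation")
    }
  }
  protocol_spec(do.call(rbind, rows))
}

#' @rdname protocol_spec
#' @export
protocol_day2_context <- function() {
  protocol_spec(data.frame(label = "context", start_s = 0, end_s = 300,
                           kind = "context"))
}

#' @rdname protocol_spec
#' @export
protocol_day2_cue <- function() {
  rows <- list(data.frame(label = "H", start_s = 0, end_s = 120,
                          kind = "habituation"))
  t0 <- 120
  for (k in 1:3) {
    tone_on <- t0 + (k - 1) * (20 + 60)
    # tone-period freezing is included in the cue observation window
    rows[[length(rows) + 1L]] <- data.frame(
      label = paste0("C", k), start_s = tone_on, end_s = tone_on + 80,
      kind = "observation")
  }
  protocol_spec(do.call(rbind, rows))
}

#' Freezing session
#'
#' Bout annotations (immobility intervals) attached to a protocol.
#' Abutting or overlapping bouts are merged at construction, before the
#' minimum-duration rule is applied during scoring.
#'
#' @param protocol a [protocol_spec()].
#' @param bouts data frame with columns `start_s`, `end_s`.
#' @return An object of class `freezing_session`.
#' @export
freezing_session <- function(protocol, bouts) {
  stopifnot(inherits(protocol, "protocol_spec"))
  if (nrow(bouts)) {
    if (any(bouts$end_s <= bouts$start_s)) .stopf("bouts must have positive length")
    o <- order(bouts$start_s)
    bouts <- bouts[o, , drop = FALSE]
    # merge abutting/overlapping bouts
    merged <- bouts[1, , drop = FALSE]
    if (nrow(bouts) > 1) for (i in 2:nrow(bouts)) {
      j <- nrow(merged)
      if (bouts$start_s[i] <= merged$end_s[j] + 1e-9) {
        merged$end_s[j] <- max(merged$end_s[j], bouts$end_s[i])
      } else merged <- rbind(merged, bouts[i, ])
    }
    bouts <- merged
  }
  rownames(bouts) <- NULL
  structure(list(protocol = protocol, bouts = bouts), class = "freezing_session")
}

#' Percent time freezing within one epoch
#'
#' Only bouts whose full (merged) duration exceeds `min_bout_s` (default
#' 2 s) count as freezing; the rule is applied to the whole bout before
#' intersection with the epoch, so a long bout straddling an epoch edge
#' still contributes its in-epoch part. The result is the summed
#' intersection divided by the epoch length, x100.
#'
#' @param session a [freezing_session()].
#' @param epoch epoch label.
#' @param min_bout_s minimum full-bout duration to count, s (strict `>`).
#' @return Freezing percentage in [0, 100].
#' @export
freezing_percent <- function(session, epoch, min_bout_s = 2) {
  stopifnot(inherits(session, "freezing_session"))
  ep <- session$protocol$epochs
  row <- ep[ep$label == epoch, ]
  if (nrow(row) != 1) .stopf("unknown epoch '%s'", epoch)
  len <- row$end_s - row$start_s
  if (len <= 0) .stopf("zero-length epoch")
  b <- session$bouts
  if (!nrow(b)) return(0)
  b <- b[b$end_s - b$start_s > min_bout_s, , drop = FALSE]
  if (!nrow(b)) return(0)
  overlap <- pmax(0, pmin(b$end_s, row$end_s) - pmax(b$start_s, row$start_s))
  100 * sum(overlap) / len
}

#' Per-epoch freezing summary
#'
#' One row per scored epoch (habituation, trial observations, context /
#' cue windows), in protocol order.
#'
#' @param session a [freezing_session()].
#' @param min_bout_s minimum full-bout duration to count, s.
#' @return Data frame with columns `epoch`, `kind`, `freezing_pct`.
#' @export
session_summary <- function(session, min_bout_s = 2) {
  ep <- session$protocol$epochs
  data.frame(epoch = ep$label, kind = ep$kind,
             freezing_pct = vapply(ep$label, function(l)
               freezing_percent(session, l, min_bout_s), numeric(1)),
             row.names = NULL)
}

#' Write / read freezing bouts as CSV
#'
#' Bouts are stored as `(epoch_label, bout_start_s, bout_end_s)` rows; the
#' epoch label is informative only (scoring re-derives epochs from the
#' protocol).
#'
#' @param session a [freezing_session()].
#' @param path CSV file path.
#' @param protocol a [protocol_spec()] to attach on reading.
#' @return `write_freezing_csv` returns `path` invisibly;
#'   `read_freezing_csv` a [freezing_session()].
#' @export
write_freezing_csv <- function(session, path) {
  b <- session$bouts
  lab <- vapply(seq_len(nrow(b)), function(i) {
    ep <- session$protocol$epochs
    hit <- which(ep$start_s <= b$start_s[i] & b$start_s[i] < ep$end_s)
    if (length(hit)) ep$label[hit[1]] else ""
  }, character(1))
  utils::write.csv(data.frame(epoch_label = lab, bout_start_s = b$start_s,
                              bout_end_s = b$end_s), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_freezing_csv
#' @export
read_freezing_csv <- function(path, protocol) {
  tab <- utils::read.csv(path)
  freezing_session(protocol, data.frame(start_s = tab$bout_start_s,
                                        end_s = tab$bout_end_s))
}
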