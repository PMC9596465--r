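#' Label snapshots with present and future clinical events
#'
#' Events are mapped into the same per-patient 30-day bins as the snapshots
#' (anchored at the patient's first mention). For every snapshot and event
#' type: `present` when an event timestamp falls inside the snapshot's
#' half-open window, and `pre_event` when the snapshot strictly precedes the
#' patient's first event-containing snapshot (the basis of "future risk").
#' Pre-event flags exist only for patients who ever have the event; a
#' snapshot is never both present and pre-event for the same type. Events for
#' patients absent from the snapshot set are skipped with a warning.
#'
#' @param rows snapshot metadata (`patient_id`, `bin_index`, `anchor_day`),
#'   e.g. `x$rows` of a `snapshot_matrix`.
#' @param events data frame `patient_id`, `timestamp`, `event_type`.
#' @param bin_width bin width in days.
#' @return object of class `event_labels`: logical matrices `present` and
#'   `pre_event` (snapshots x event types) plus the `rows` metadata.
#' @export
label_events <- function(rows, events, bin_width = 30) {
  stop_if_missing_cols(events, c("patient_id", "timestamp", "event_type"),
                       "event table")
  stop_if_missing_cols(rows, c("patient_id", "bin_index", "anchor_day"),
                       "snapshot metadata")
  types <- sort(unique(as.character(events$event_type)))
  n <- nrow(rows)
  present <- pre_event <- matrix(FALSE, n, length(types),
                                 dimnames = list(NULL, types))
  anchors <- rows$anchor_day[!duplicated(rows$patient_id)]
  names(anchors) <- rows$patient_id[!duplicated(rows$patient_id)]
  pid <- as.character(events$patient_id)
  known <- pid %in% names(anchors)
  if (any(!known)) {
    warning(sum(!known), " event(s) for patients with no snapshots; skipped")
    events <- events[known, , drop = FALSE]
    pid <- pid[known]
  }
  if (nrow(events) == 0) {
    return(structure(list(present = present, pre_event = pre_event,
                          rows = rows, event_types = types),
                     class = "event_labels"))
  }
  day <- as_day_offset(events$timestamp, events$patient_id)
  ebin <- floor((day - anchors[pid]) / bin_width)
  skey <- paste(rows$patient_id, rows$bin_index, sep = "\r")
  for (ty in types) {
    sel <- events$event_type == ty
    ekey <- unique(paste(pid[sel], ebin[sel], sep = "\r"))
    present[, ty] <- skey %in% ekey
    ## first event-containing snapshot bin per patient
    pres_rows <- which(present[, ty])
    if (length(pres_rows) > 0) {
      first_bin <- tapply(rows$bin_index[pres_rows],
                          rows$patient_id[pres_rows], min)
      fb <- first_bin[rows$patient_id]
      pre_event[, ty] <- !is.na(fb) & rows$bin_index < fb
    }
  }
  structure(list(present = present, pre_event = pre_event,
                 rows = rows, event_types = types),
            class = "event_labels")
}

#' @exportS3Method base::print
print.event_labels <- function(x, ...) {
  cat("Event labels:", nrow(x$present), "snapshots x",
      length(x$event_types), "event types\n")
  invisible(x)
}

#' Present and future event prevalence per disease state
#'
#' For each (cluster, event type): the percentage of the cluster's snapshots
#' in which the event occurs (`present_pct`) and the percentage flagged as
#' preceding the patient's first event-containing snapshot (`future_pct`),
#' with the underlying counts.
#'
#' @param labels cluster label per snapshot.
#' @param event_labels a [label_events()] result.
#' @return tidy data frame (`cluster`, `event_type`, `n_snapshots`,
#'   `present_n`, `present_pct`, `future_n`, `future_pct`).
#' @export
state_risk_table <- function(labels, event_labels) {
  stopifnot(inherits(event_labels, "event_labels"),
            length(labels) == nrow(event_labels$present))
  clusters <- sort(unique(labels))
  rows <- list()
  for (cl in clusters) {
    ing <- labels == cl
    for (ty in event_labels$event_types) {
      pn <- sum(event_labels$present[ing, ty])
      fn <- sum(event_labels$pre_event[ing, ty])
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, event_type = ty, n_snapshots = sum(ing),
        present_n = pn, present_pct = 100 * pn / sum(ing),
        future_n = fn, future_pct = 100 * fn / sum(ing),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kernel density overlay of event-flagged snapshots
#'
#' Gaussian kernel density estimates over a 2D embedding of the snapshots,
#' one grid for event-present points and one for pre-event points, each
#' normalized to integrate to 1 on the grid. Bandwidths default to Scott's
#' rule for two dimensions (`sd * n^(-1/6)` per axis).
#'
#' @param coords N x 2 matrix of embedding coordinates ([embed_2d()]).
#' @param event_labels a [label_events()] result aligned with `coords`.
#' @param event event type to overlay.
#' @param grid_n grid resolution per axis.
#' @param bandwidth optional length-2 bandwidth override.
#' @return list with grid axes `x`, `y` and matrices `present`, `pre_event`
#'   (either may be `NULL` with a warning when fewer than 2 points carry the
#'   flag).
#' @export
density_overlay <- function(coords, event_labels, event, grid_n = 100,
                            bandwidth = NULL) {
  stopifnot(ncol(coords) == 2, inherits(event_labels, "event_labels"))
  if (!event %in% event_labels$event_types)
    stop("unknown event type: ", event, call. = FALSE)
  lims <- c(range(coords[, 1]), range(coords[, 2]))
  kde_for <- function(flag) {
    pts <- coords[flag, , drop = FALSE]
    if (nrow(pts) < 2) {
      warning("fewer than 2 flagged points; empty density grid")
      return(NULL)
    }
    h <- bandwidth %||% (apply(pts, 2, stats::sd) * nrow(pts)^(-1 / 6))
    h[h <= 0] <- diff(lims[1:2]) / grid_n
    ## MASS::kde2d treats h/4 as the Gaussian sd
    kd <- MASS::kde2d(pts[, 1], pts[, 2], h = 4 * h, n = grid_n, lims = lims)
    dx <- diff(kd$x[1:2]); dy <- diff(kd$y[1:2])
    kd$z <- kd$z / (sum(kd$z) * dx * dy)
    kd$z
  }
  pres <- kde_for(event_labels$present[, event])
  pre <- kde_for(event_labels$pre_event[, event])
  gx <- seq(lims[1], lims[2], length.out = grid_n)
  gy <- seq(lims[3], lims[4], length.out = grid_n)
  list(x = gx, y = gy, present = pres, pre_event = pre)
}
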