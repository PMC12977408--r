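## Communication features (total speaking time, speech ratio) and the
## path-accuracy performance score.

#' Communication features per period
#'
#' Total speaking time is the summed speaking duration of both partners;
#' speech ratio divides the Guide's speaking time by the Drawer's. Both are
#' computed before and after the disruption split. A period in which the
#' Drawer never speaks yields an invalid-flagged ratio instead of a division.
#'
#' @param guide,drawer data.frames with columns time, speaking (0/1), equal
#'   length and aligned.
#' @param split_time split between periods (s from task start).
#' @param fs behavioral sampling rate (Hz).
#' @return data.frame: period (pre/post), total_speaking_time (s),
#'   speech_ratio, valid.
#' @export
comm_features <- function(guide, drawer, split_time, fs = 10) {
  if (nrow(guide) != nrow(drawer)) data_error("speech series lengths differ")
  one <- function(sel, period) {
    g <- sum(guide$speaking[sel]) / fs
    d <- sum(drawer$speaking[sel]) / fs
    valid <- d > 0
    data.frame(period = period, total_speaking_time = g + d,
               speech_ratio = if (valid) g / d else NA_real_, valid = valid)
  }
  pre <- guide$time < split_time
  out <- rbind(one(pre, "pre"), one(!pre, "post"))
  rownames(out) <- NULL
  out
}

## Minimum distance from each point to a polyline (exact point-to-segment
## projection, not nearest-vertex).
dist_to_polyline <- function(pts, vertices) {
  if (nrow(vertices) < 2L) return(sqrt((pts[, 1] - vertices[1, 1])^2 +
                                         (pts[, 2] - vertices[1, 2])^2))
  best <- rep(Inf, nrow(pts))
  for (s in seq_len(nrow(vertices) - 1L)) {
    a <- vertices[s, ]; b <- vertices[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      d2 <- (pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2
    } else {
      t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (pts[, 1] - (a[1] + t * ab[1]))^2 + (pts[, 2] - (a[2] + t * ab[2]))^2
    }
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Path-accuracy performance score
#'
#' For each trajectory sample the local error is the Euclidean distance to
#' the nearest point on the reference path (continuous point-to-segment
#' projection). The overall score sums the local errors; the per-sample mean
#' is also reported since it is invariant to period length.
#'
#' @param traj `trajectory` (data.frame time, x, y).
#' @param ref `reference_path` (or any list with a `vertices` matrix).
#' @param split_time split between periods (s).
#' @param mode `"segment"` (continuous projection, default) or `"vertex"`
#'   (nearest recorded vertex, for comparison).
#' @return list with elements `pre` and `post`, each of class
#'   `performance_score`: list(local, sum_error, mean_error, n).
#' @export
path_error <- function(traj, ref, split_time, mode = c("segment", "vertex")) {
  mode <- match.arg(mode)
  if (nrow(traj) == 0 || nrow(ref$vertices) == 0) data_error("empty trajectory or path")
  pts <- cbind(traj$x, traj$y)
  local <- if (mode == "segment") {
    dist_to_polyline(pts, ref$vertices)
  } else {
    v <- ref$vertices
    apply(pts, 1L, function(p) sqrt(min((v[, 1] - p[1])^2 + (v[, 2] - p[2])^2)))
  }
  mk <- function(sel) {
    structure(list(local = local[sel], sum_error = sum(local[sel]),
                   mean_error = mean(local[sel]), n = sum(sel)),
              class = "performance_score")
  }
  pre <- traj$time < split_time
  list(pre = mk(pre), post = mk(!pre))
}

#' Behavioral feature table for a study
#'
#' @param study `ibs_study` (from [simulate_study()]) or a list of dyad
#'   entries with `recording` components.
#' @param split_time period split (s from task start); defaults to the
#'   disruption offset.
#' @return data.frame: dyad_id, group, period, total_speaking_time,
#'   speech_ratio, speech_valid, sum_error, mean_error.
#' @export
behavior_table <- function(study, split_time = NULL) {
  dyads <- if (inherits(study, "ibs_study")) study$dyads else study
  rows <- lapply(dyads, function(d) {
    rec <- d$recording
    split <- split_time %||% (rec$markers$disruption - rec$markers$task_start)
    cf <- comm_features(rec$speech$guide, rec$speech$drawer, split)
    pe <- path_error(rec$trajectory, rec$reference_path, split)
    data.frame(dyad_id = rec$dyad_id, group = rec$group, period = cf$period,
               total_speaking_time = cf$total_speaking_time,
               speech_ratio = cf$speech_ratio, speech_valid = cf$valid,
               sum_error = c(pe$pre$sum_error, pe$post$sum_error),
               mean_error = c(pe$pre$mean_error, pe$post$mean_error),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Perceived-difficulty table for a study
#'
#' @param study `ibs_study`.
#' @return data.frame: dyad_id, group, participant, period, score.
#' @export
difficulty_table <- function(study) {
  dyads <- if (inherits(study, "ibs_study")) study$dyads else study
  rows <- lapply(dyads, function(d) {
    rec <- d$recording
    cbind(data.frame(dyad_id = rec$dyad_id, group = rec$group,
                     stringsAsFactors = FALSE),
          rec$difficulty)
  })
  out <- do.call(rbind, rows)
  out$participant <- paste(out$dyad_id, out$participant, sep = "_")
  rownames(out) <- NULL
  out
}
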