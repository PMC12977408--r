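## Plain-text study interchange: long-format intensity CSV per participant,
## behavioral streams as CSV, one metadata JSON per dyad, and a study
## manifest CSV indexing all files.

#' Write a study to a directory of CSV/JSON files
#'
#' Per participant, intensities go to a long-format CSV (time, channel,
#' wavelength, intensity); speech to (time, speaking) CSV; the trajectory to
#' (time, x, y) CSV; the reference path to a vertex CSV; per-dyad metadata
#' (group, markers, difficulty scores) to JSON; and a manifest CSV indexes
#' everything.
#'
#' @param study `ibs_study`.
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest data.frame.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (d in study$dyads) {
    rec <- d$recording
    id <- rec$dyad_id
    files <- list()
    for (role in c("guide", "drawer")) {
      raw <- rec[[role]]
      if (is.null(raw)) next
      n <- dim(raw$intensity)[3]
      ncha <- dim(raw$intensity)[1]
      long <- data.table::data.table(
        time = rep((seq_len(n) - 1L) / raw$fs, each = 2L * ncha),
        channel = rep(rep(seq_len(ncha), times = 2L), n),
        wavelength = rep(rep(raw$wavelengths, each = ncha), n),
        intensity = as.vector(raw$intensity))
      f <- file.path(dir, sprintf("%s_%s_intensity.csv", id, role))
      data.table::fwrite(long, f)
      files[[paste0(role, "_intensity")]] <- basename(f)
      sp <- rec$speech[[role]]
      f <- file.path(dir, sprintf("%s_%s_speech.csv", id, role))
      data.table::fwrite(sp[, c("time", "speaking")], f)
      files[[paste0(role, "_speech")]] <- basename(f)
    }
    f <- file.path(dir, sprintf("%s_trajectory.csv", id))
    data.table::fwrite(rec$trajectory, f)
    files$trajectory <- basename(f)
    meta <- list(dyad_id = id, group = rec$group, fs_nirs = rec$fs_nirs,
                 markers = rec$markers,
                 roi_map = as.list(rec$guide$roi_map %||% default_roi_map()),
                 difficulty = rec$difficulty)
    f <- file.path(dir, sprintf("%s_meta.json", id))
    jsonlite::write_json(meta, f, auto_unbox = TRUE, digits = NA, dataframe = "columns")
    files$meta <- basename(f)
    rows[[id]] <- data.frame(dyad_id = id, group = rec$group,
                             key = names(files),
                             file = unlist(files, use.names = FALSE),
                             stringsAsFactors = FALSE)
  }
  f <- file.path(dir, "reference_path.csv")
  ref <- study$dyads[[1]]$recording$reference_path
  data.table::fwrite(data.table::data.table(x = ref$vertices[, 1],
                                            y = ref$vertices[, 2]), f)
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  data.table::fwrite(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

## Reshape a long intensity CSV back to the channel x wavelength x time array.
read_intensity_csv <- function(path, fs, roi_map, role, participant_id,
                               wavelengths = c(760, 850)) {
  long <- data.table::fread(path)
  chs <- sort(unique(long$channel))
  n <- length(unique(long$time))
  arr <- array(NA_real_, dim = c(length(chs), 2L, n))
  for (w in 1:2) {
    sub <- long[long$wavelength == wavelengths[w], ]
    data.table::setorderv(sub, c("channel", "time"))
    arr[, w, ] <- matrix(sub$intensity, nrow = length(chs), byrow = TRUE)
  }
  raw_intensity(arr, fs = fs, roi_map = roi_map, role = role,
                participant_id = participant_id, wavelengths = wavelengths)
}

#' Read a study written by [write_study()]
#'
#' @param dir directory containing manifest.csv.
#' @return `ibs_study`-shaped list (params = NULL).
#' @export
read_study <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) data_error("manifest.csv not found")
  manifest <- data.table::fread(mf)
  ref_v <- as.matrix(data.table::fread(file.path(dir, "reference_path.csv")))
  ref <- structure(list(vertices = unname(ref_v), icons = unname(ref_v),
                        start = ref_v[1, ], end = ref_v[nrow(ref_v), ]),
                   class = "reference_path")
  dyads <- lapply(unique(manifest$dyad_id), function(id) {
    sub <- manifest[manifest$dyad_id == id, ]
    lookup <- stats::setNames(sub$file, sub$key)
    meta <- jsonlite::read_json(file.path(dir, lookup[["meta"]]),
                                simplifyVector = TRUE)
    roi_map <- unlist(meta$roi_map)
    rec <- list(dyad_id = id, group = meta$group, fs_nirs = meta$fs_nirs,
                markers = meta$markers, reference_path = ref,
                difficulty = as.data.frame(meta$difficulty))
    for (role in c("guide", "drawer")) {
      rec[[role]] <- read_intensity_csv(file.path(dir, lookup[[paste0(role, "_intensity")]]),
                                        meta$fs_nirs, roi_map, role,
                                        sprintf("%s_%s", id, role))
      sp <- as.data.frame(data.table::fread(file.path(dir, lookup[[paste0(role, "_speech")]])))
      sp$role <- role
      rec$speech[[role]] <- sp
    }
    rec$trajectory <- as.data.frame(data.table::fread(file.path(dir, lookup[["trajectory"]])))
    class(rec) <- "dyad_recording"
    list(recording = rec, truth = NULL)
  })
  meta_df <- unique(manifest[, c("dyad_id", "group")])
  structure(list(params = NULL, dyads = dyads,
                 metadata = as.data.frame(meta_df)), class = "ibs_study")
}
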