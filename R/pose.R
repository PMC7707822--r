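# Pose-estimation tracks: the markerless-tracking CSV export carries, per
# tracked bodypart, an (x, y, likelihood) triplet per video frame under three
# header rows (scorer / bodyparts / coords). Five bodyparts are canonical
# here: the four paws and the head, seen from the side of the runway.

.canonical_bodyparts <- c("rHL", "lHL", "rFL", "lFL", "head")

#' Single-bodypart pose track
#'
#' @param bodypart label; matched case-insensitively against the canonical
#'   set `rHL, lHL, rFL, lFL, head` (other labels are kept as-is).
#' @param x,y per-frame positions (px, or cm once calibrated).
#' @param likelihood per-frame tracking confidence in `[0, 1]`.
#' @param fps video frame rate in Hz.
#' @return An object of class `pose_track`.
#' @export
pose_track <- function(bodypart, x, y, likelihood, fps) {
  if (!is_scalar_num(fps) || fps <= 0) stop_parameter("fps must be > 0")
  x <- as.numeric(x); y <- as.numeric(y); likelihood <- as.numeric(likelihood)
  n <- length(x)
  if (length(y) != n || length(likelihood) != n)
    stop_validation("x, y, likelihood must have equal length")
  if (n < 1L) stop_validation("empty pose track")
  bad <- which(!is.finite(likelihood) | likelihood < 0 | likelihood > 1)
  if (length(bad))
    stop_validation("likelihood outside [0,1] at frame %d (bodypart %s)",
                    bad[1L], bodypart)
  hit <- match(tolower(bodypart), tolower(.canonical_bodyparts))
  if (!is.na(hit)) bodypart <- .canonical_bodyparts[hit]
  structure(list(bodypart = bodypart, x = x, y = y,
                 likelihood = likelihood, fps = fps),
            class = "pose_track")
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf("<pose_track> %s: %d frames @ %g fps\n",
              x$bodypart, length(x$x), x$fps))
  invisible(x)
}

#' Read a pose-estimation CSV export
#'
#' Parses the three-header-row CSV dialect (row 1: scorer, row 2: bodypart
#' per column, row 3: coordinate name `x`/`y`/`likelihood`), one data row
#' per frame. A leading frame-index column (coordinate name `coords` or
#' empty) is tolerated and dropped. Bodypart labels are matched
#' case-insensitively against the canonical five.
#'
#' @param path CSV file path.
#' @param fps video frame rate in Hz (not stored in the file).
#' @param px_per_cm optional calibration; when given, x and y are divided by
#'   it at read time so all downstream positions are in cm.
#' @param required bodypart labels that must be present; defaults to the
#'   canonical five. Use `character(0)` to accept any subset.
#' @return named list of `pose_track`, one per bodypart in the file.
#' @export
read_pose_table <- function(path, fps, px_per_cm = NULL,
                            required = .canonical_bodyparts) {
  if (!file.exists(path)) stop_io("no such file: %s", path)
  lines <- readLines(path)
  if (length(lines) < 3L) stop_format("pose table needs 3 header rows (file has %d lines)", length(lines))
  hdr <- lapply(lines[1:3], function(l) trimws(strsplit(l, ",", fixed = TRUE)[[1L]]))
  ncol <- length(hdr[[2L]])
  if (length(hdr[[3L]]) != ncol)
    stop_format("header row 3 has %d fields, row 2 has %d", length(hdr[[3L]]), ncol)
  coords <- tolower(hdr[[3L]])
  parts  <- hdr[[2L]]
  drop <- coords %in% c("coords", "") | parts %in% c("bodyparts", "")
  keep <- which(!drop)
  if (!length(keep)) stop_format("no data columns found (line 3)")
  if (!all(coords[keep] %in% c("x", "y", "likelihood")))
    stop_format("unexpected coordinate label on line 3: %s",
                coords[keep][!coords[keep] %in% c("x", "y", "likelihood")][1L])
  dat <- utils::read.csv(text = lines[-(1:3)], header = FALSE,
                         colClasses = "numeric")
  if (ncol(dat) != ncol) stop_format("data rows have %d fields, header has %d (line 4)", ncol(dat), ncol)
  tracks <- list()
  for (bp in unique(parts[keep])) {
    idx <- keep[parts[keep] == bp]
    cols <- stats::setNames(idx, coords[idx])
    if (!all(c("x", "y", "likelihood") %in% names(cols)))
      stop_format("bodypart %s lacks a full x/y/likelihood triplet", bp)
    xx <- dat[[cols[["x"]]]]; yy <- dat[[cols[["y"]]]]
    if (!is.null(px_per_cm)) {
      if (!is_scalar_num(px_per_cm) || px_per_cm <= 0)
        stop_config("px_per_cm must be > 0")
      xx <- xx / px_per_cm; yy <- yy / px_per_cm
    }
    tr <- pose_track(bp, xx, yy, dat[[cols[["likelihood"]]]], fps)
    tracks[[tr$bodypart]] <- tr
  }
  canon <- match(tolower(required), tolower(.canonical_bodyparts))
  required[!is.na(canon)] <- .canonical_bodyparts[canon[!is.na(canon)]]
  missing <- setdiff(required, names(tracks))
  if (length(missing))
    stop_config("required bodypart missing from %s: %s", path,
                paste(missing, collapse = ", "))
  tracks
}

#' Write pose tracks as a pose-estimation CSV export
#'
#' Inverse of [read_pose_table()]: emits the three header rows and one data
#' row per frame, with a leading frame-index column. Positions are written
#' in the units the tracks carry (no calibration is applied).
#'
#' @param tracks named list of `pose_track` with equal frame counts.
#' @param path output CSV path.
#' @param scorer scorer label for header row 1.
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(tracks, path, scorer = "locoresp") {
  stopifnot(length(tracks) >= 1L, all(vapply(tracks, inherits, TRUE, "pose_track")))
  n <- length(tracks[[1L]]$x)
  if (!all(vapply(tracks, function(t) length(t$x), 1L) == n))
    stop_validation("tracks have unequal frame counts")
  parts <- vapply(tracks, `[[`, "", "bodypart")
  h1 <- c("scorer",    rep(scorer, 3L * length(tracks)))
  h2 <- c("bodyparts", rep(parts, each = 3L))
  h3 <- c("coords",    rep(c("x", "y", "likelihood"), length(tracks)))
  mat <- do.call(cbind, lapply(tracks, function(t) cbind(t$x, t$y, t$likelihood)))
  body <- apply(cbind(seq_len(n) - 1L, mat), 1L,
                function(r) paste(sprintf("%.17g", r), collapse = ","))
  ok <- tryCatch({
    writeLines(c(paste(h1, collapse = ","), paste(h2, collapse = ","),
                 paste(h3, collapse = ","), body), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_io("cannot write %s", path)
  invisible(path)
}
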