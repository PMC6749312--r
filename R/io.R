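# Motion file I/O.  The canonical interchange format is a self-describing
# delimited text file: a header block of "#key: value" lines followed by one
# tab-separated data row per frame (frame index, then w,x,y,z per segment,
# then optional pelvis position and per-sensor accelerations).  Values are
# written with 17 significant digits so a write/read round-trip is
# bit-exact.  A read-only BVH importer maps optical motion-capture joints
# onto the canonical segments.

.MOTION_FORMAT_VERSION <- 1L

#' Write a motion sequence to the text motion format
#'
#' @param seq A `motion_sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_motion <- function(seq, path) {
  stopifnot(inherits(seq, "motion_sequence"))
  segs <- dimnames(seq$orientations)[[2]]
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(
    sprintf("#format: stackpose-motion v%d", .MOTION_FORMAT_VERSION),
    sprintf("#fs: %s", format(seq$fs, digits = 17)),
    sprintf("#subject: %s", seq$subject_id),
    sprintf("#activity: %s", seq$activity),
    sprintf("#stature_m: %s", format(seq$stature_m, digits = 17)),
    sprintf("#segments: %s", paste(segs, collapse = ",")),
    sprintf("#accelerations: %s", tolower(!is.null(seq$accelerations))),
    sprintf("#pelvis_position: %s", tolower(!is.null(seq$pelvis_position))))
  writeLines(hdr, con)
  cols <- list(frame = seq_len(seq$n_frames) - 1L)
  for (s in segs) for (k in 1:4)
    cols[[paste0(s, ".", c("w", "x", "y", "z")[k])]] <- seq$orientations[, s, k]
  if (!is.null(seq$pelvis_position)) for (k in 1:3)
    cols[[paste0("PelvisPos.", c("x", "y", "z")[k])]] <- seq$pelvis_position[, k]
  if (!is.null(seq$accelerations))
    for (s in INPUT_SEGMENTS) for (k in 1:3)
      cols[[paste0(s, ".a", c("x", "y", "z")[k])]] <- seq$accelerations[, s, k]
  df <- as.data.frame(cols, check.names = FALSE)
  writeLines(paste(names(df), collapse = "\t"), con)
  body <- do.call(paste, c(lapply(df, function(x)
    formatC(x, digits = 17, format = "g")), sep = "\t"))
  writeLines(body, con)
  invisible(path)
}

.parse_header <- function(lines) {
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#([a-z_]+):[ ]?(.*)$", ln))[[1]]
    if (length(m) == 3L) kv[[m[2]]] <- m[3]
  }
  kv
}

#' Read a motion sequence from the text motion format
#'
#' Strict by default: malformed rows, missing segments or non-unit
#' quaternions (beyond 1e-3) are errors.  With `lenient = TRUE`, near-unit
#' quaternions are renormalized instead of rejected.
#'
#' @param path Path to a file written by [write_motion()].
#' @param lenient Renormalize near-unit quaternions instead of erroring.
#' @return A `motion_sequence`.
#' @export
read_motion <- function(path, lenient = FALSE) {
  lines <- readLines(path)
  hdr_lines <- lines[startsWith(lines, "#")]
  kv <- .parse_header(hdr_lines)
  if (is.null(kv$format) || !grepl("^stackpose-motion v", kv$format))
    stop("not a stackpose motion file: ", path)
  ver <- as.integer(sub("^stackpose-motion v", "", kv$format))
  if (is.na(ver) || ver != .MOTION_FORMAT_VERSION)
    stop("unsupported motion format version: ", kv$format)
  segs <- strsplit(kv$segments, ",", fixed = TRUE)[[1]]
  if (length(segs) != length(unique(segs)))
    stop("duplicate segments in header")
  if (!all(SEGMENT_NAMES %in% segs) || length(segs) != 23L)
    stop(sprintf("motion file must list all 23 canonical segments (found %d)",
                 length(segs)))
  fs <- as.numeric(kv$fs)
  if (!is.finite(fs) || fs <= 0) stop("invalid fs in header")
  has_acc <- identical(kv$accelerations, "true")
  has_pos <- identical(kv$pelvis_position, "true")

  data_lines <- lines[!startsWith(lines, "#")]
  data_lines <- data_lines[nzchar(data_lines)]
  if (length(data_lines) < 1L) stop("motion file has no data rows")
  col_names <- strsplit(data_lines[1], "\t", fixed = TRUE)[[1]]
  n_col <- length(col_names)
  rows <- strsplit(data_lines[-1], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != n_col)
  if (length(bad))
    stop(sprintf("malformed row at data line %d: expected %d fields, got %d",
                 bad[1] + 1L, n_col, length(rows[[bad[1]]])))
  vals <- suppressWarnings(matrix(as.numeric(unlist(rows)),
                                  ncol = n_col, byrow = TRUE))
  if (anyNA(vals)) {
    bad_row <- which(apply(vals, 1L, anyNA))[1]
    stop(sprintf("non-numeric value at data line %d", bad_row + 1L))
  }
  colnames(vals) <- col_names
  n <- nrow(vals)

  q <- array(NA_real_, dim = c(n, 23L, 4L),
             dimnames = list(NULL, SEGMENT_NAMES, c("w", "x", "y", "z")))
  for (s in SEGMENT_NAMES) {
    want <- paste0(s, ".", c("w", "x", "y", "z"))
    if (!all(want %in% col_names)) stop("missing columns for segment ", s)
    q[, s, ] <- vals[, want]
  }
  nrm <- sqrt(apply(q^2, c(1, 2), sum))
  off <- abs(nrm - 1) > 1e-3
  if (any(off)) {
    if (!lenient) {
      frames <- sort(unique(which(off, arr.ind = TRUE)[, 1]))
      stop("non-unit quaternions at frames: ",
           paste(utils::head(frames, 10L), collapse = ", "),
           if (length(frames) > 10L) " ..." else "")
    }
    for (k in 1:4) q[, , k] <- q[, , k] / nrm
  }
  pel <- NULL
  if (has_pos) {
    want <- paste0("PelvisPos.", c("x", "y", "z"))
    if (!all(want %in% col_names)) stop("header promises pelvis_position but columns are missing")
    pel <- vals[, want, drop = FALSE]
    colnames(pel) <- c("x", "y", "z")
  }
  acc <- NULL
  if (has_acc) {
    acc <- array(NA_real_, dim = c(n, 5L, 3L),
                 dimnames = list(NULL, INPUT_SEGMENTS, c("ax", "ay", "az")))
    for (s in INPUT_SEGMENTS) {
      want <- paste0(s, ".a", c("x", "y", "z"))
      if (!all(want %in% col_names)) stop("missing acceleration columns for ", s)
      acc[, s, ] <- vals[, want]
    }
  }
  motion_sequence(q, fs = fs, subject_id = kv$subject, activity = kv$activity,
                  stature_m = as.numeric(kv$stature_m),
                  accelerations = acc, pelvis_position = pel)
}

## ---- BVH import ---------------------------------------------------------

#' Import a BVH motion-capture file
#'
#' Parses the BVH hierarchy and motion channels, composes each joint's
#' Euler rotations (honouring the file's per-joint channel order, intrinsic
#' composition) down the hierarchy into global orientation quaternions, and
#' maps the named BVH joints onto the canonical 23 segments.  Unmapped
#' canonical segments are filled with the identity orientation and recorded
#' in the `unmapped` attribute.  Accelerations are absent.
#'
#' @param path Path to a BVH file.
#' @param mapping Named character vector: `c(BVHJointName = "SegmentName")`.
#' @param subject_id,activity,stature_m Metadata for the resulting sequence.
#' @return A `motion_sequence` (attribute `unmapped` lists segments filled
#'   with identity).
#' @export
import_bvh <- function(path, mapping, subject_id = "bvh", activity = "bvh",
                       stature_m = 1.75) {
  if (is.null(names(mapping)) || !all(mapping %in% SEGMENT_NAMES))
    stop("'mapping' must be a named vector BVH joint -> canonical segment")
  tokens <- scan(path, what = character(), quote = "", quiet = TRUE)
  hi <- match("HIERARCHY", toupper(tokens))
  mi <- match("MOTION", toupper(tokens))
  if (is.na(hi) || is.na(mi)) stop("not a BVH file (missing HIERARCHY/MOTION)")

  joints <- list()   # name -> list(parent, channels)
  stack <- character(0)
  i <- hi + 1L
  while (i < mi) {
    tk <- toupper(tokens[i])
    if (tk %in% c("ROOT", "JOINT")) {
      nm <- tokens[i + 1L]
      joints[[nm]] <- list(parent = if (length(stack)) stack[length(stack)] else NA,
                           channels = character(0))
      pending <- nm
      i <- i + 2L
    } else if (tk == "END") {      # End Site: skip its block
      pending <- NA
      i <- i + 2L
    } else if (tk == "{") {
      stack <- c(stack, pending)
      i <- i + 1L
    } else if (tk == "}") {
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (tk == "CHANNELS") {
      ncha <- as.integer(tokens[i + 1L])
      cur <- stack[length(stack)]
      joints[[cur]]$channels <- tokens[(i + 2L):(i + 1L + ncha)]
      i <- i + 2L + ncha
    } else {
      i <- i + 1L   # OFFSET values etc.
    }
  }
  missing_joints <- setdiff(names(mapping), names(joints))
  if (length(missing_joints))
    stop("mapped BVH joints not present in file: ",
         paste(missing_joints, collapse = ", "))

  # motion block
  fi <- which(toupper(tokens) == "FRAMES:")
  if (!length(fi)) stop("BVH file missing 'Frames:'")
  n_frames_file <- as.integer(tokens[fi[1] + 1L])
  ti <- which(toupper(tokens) == "TIME:")
  if (!length(ti)) stop("BVH file missing 'Frame Time:'")
  frame_time <- as.numeric(tokens[ti[1] + 1L])
  if (!is.finite(frame_time) || frame_time <= 0)
    stop("non-positive frame time in BVH file")
  values <- suppressWarnings(as.numeric(tokens[(ti[1] + 2L):length(tokens)]))
  if (anyNA(values)) stop("non-numeric motion data in BVH file")
  n_chan <- sum(vapply(joints, function(j) length(j$channels), integer(1)))
  if (length(values) < n_frames_file * n_chan)
    stop("BVH motion block shorter than Frames * channels")
  motion <- matrix(values[seq_len(n_frames_file * n_chan)],
                   nrow = n_frames_file, ncol = n_chan, byrow = TRUE)

  # channel column ranges per joint, in declaration order
  col <- 1L
  for (nm in names(joints)) {
    ncha <- length(joints[[nm]]$channels)
    joints[[nm]]$cols <- if (ncha) col:(col + ncha - 1L) else integer(0)
    col <- col + ncha
  }

  # global quaternion per joint per frame
  n <- n_frames_file
  globals <- list()
  for (nm in names(joints)) {
    j <- joints[[nm]]
    q <- quat_identity(n)
    if (is.null(dim(q))) q <- matrix(q, nrow = 1L)
    for (ci in seq_along(j$channels)) {
      ch <- toupper(j$channels[ci])
      if (!ch %in% c("XROTATION", "YROTATION", "ZROTATION")) next
      ax <- .AXES[[tolower(substr(ch, 1, 1))]]
      ang <- motion[, j$cols[ci]] * pi / 180
      q <- quat_multiply(q, quat_from_axis_angle(ax, ang))
    }
    globals[[nm]] <- if (is.na(j$parent)) q
      else quat_multiply(globals[[j$parent]], q)
  }

  quats <- array(0, dim = c(n, 23L, 4L),
                 dimnames = list(NULL, SEGMENT_NAMES, c("w", "x", "y", "z")))
  quats[, , 1] <- 1
  for (nm in names(mapping)) quats[, mapping[[nm]], ] <- globals[[nm]]
  unmapped <- setdiff(SEGMENT_NAMES, unname(mapping))
  out <- motion_sequence(quats, fs = 1 / frame_time, subject_id = subject_id,
                         activity = activity, stature_m = stature_m)
  attr(out, "unmapped") <- unmapped
  out
}
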