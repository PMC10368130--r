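# Skeleton CSV dialect: one row per joint per frame, columns
# frame_index,timestamp_s,joint,x_m,y_m,z_m,confidence  (UTF-8, '.' decimal).

.skeleton_csv_cols <- c("frame_index", "timestamp_s", "joint",
                        "x_m", "y_m", "z_m", "confidence")

#' Write a skeleton stream to CSV
#'
#' @param stream A `skeleton_stream`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_skeleton_csv <- function(stream, path) {
  nT <- n_frames(stream); nJ <- length(stream$joints)
  df <- data.frame(
    frame_index = rep(seq_len(nT), each = nJ),
    timestamp_s = rep(stream$timestamps, each = nJ),
    joint = rep(stream$joints, nT),
    x_m = as.vector(t(stream$xyz[, , 1])),
    y_m = as.vector(t(stream$xyz[, , 2])),
    z_m = as.vector(t(stream$xyz[, , 3])),
    confidence = as.vector(t(stream$conf)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a skeleton stream from CSV
#'
#' Validates the 7-column dialect row by row; frames are ordered by
#' `frame_index` and must carry non-decreasing timestamps.
#'
#' @param path Input file path.
#' @return A `skeleton_stream`.
#' @export
read_skeleton_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), .skeleton_csv_cols))
    stop(sprintf("read_skeleton_csv: expected columns %s, got %s",
                 paste(.skeleton_csv_cols, collapse = ","),
                 paste(names(df), collapse = ",")))
  num_cols <- setdiff(.skeleton_csv_cols, "joint")
  for (cc in num_cols) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cc]]))))
    if (length(bad))
      stop(sprintf("read_skeleton_csv: malformed value in column '%s' at data line %d",
                   cc, bad[1]))
    df[[cc]] <- as.numeric(df[[cc]])
  }
  df <- df[order(df$frame_index), , drop = FALSE]
  idx <- sort(unique(df$frame_index))
  joints <- unique(df$joint[df$frame_index == idx[1]])
  nT <- length(idx); nJ <- length(joints)
  xyz <- array(NA_real_, c(nT, nJ, 3)); conf <- matrix(NA_real_, nT, nJ)
  ts <- numeric(nT)
  for (i in seq_len(nT)) {
    sub <- df[df$frame_index == idx[i], , drop = FALSE]
    m <- match(joints, sub$joint)
    if (anyNA(m))
      stop(sprintf("read_skeleton_csv: frame %d lacks joint(s): %s",
                   idx[i], paste(joints[is.na(m)], collapse = ", ")))
    sub <- sub[m, , drop = FALSE]
    xyz[i, , ] <- as.matrix(sub[, c("x_m", "y_m", "z_m")])
    conf[i, ] <- sub$confidence
    ts[i] <- sub$timestamp_s[1]
  }
  if (is.unsorted(ts))
    stop("read_skeleton_csv: non-monotone timestamps across frames")
  skeleton_stream(ts, joints, xyz, conf)
}
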