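# Pose-stream I/O. The on-disk schema is a plain CSV with one row per frame
# and mouse: frame, t, mouse_id, nose_x, nose_y, center_x, center_y,
# tail_x, tail_y, detected. Units are cm and s.

POSE_COLUMNS <- c("frame", "t", "mouse_id", "nose_x", "nose_y",
                  "center_x", "center_y", "tail_x", "tail_y", "detected")

#' Write a pose stream to CSV
#'
#' @param frames Long-format pose tibble (see [read_pose_csv()] for the
#'   schema).
#' @param identities Identity table; written alongside when `identities_path`
#'   is given.
#' @param path Output CSV path.
#' @param identities_path Optional path for the identity table.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(frames, identities, path,
                           identities_path = NULL) {
  if (nrow(frames) == 0) stop("refusing to write an empty pose stream")
  if (missing(identities) || is.null(identities) || nrow(identities) == 0)
    stop("identities must be provided and non-empty")
  missing_cols <- setdiff(POSE_COLUMNS, names(frames))
  if (length(missing_cols))
    stop("pose stream lacks columns: ", paste(missing_cols, collapse = ", "))
  write.csv(frames[POSE_COLUMNS], path, row.names = FALSE, quote = FALSE)
  if (!is.null(identities_path))
    write.csv(identities, identities_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a pose stream CSV
#'
#' Rows are sorted by frame (then mouse id) on read, so row order in the
#' file does not matter. Validation failures report the offending rows.
#'
#' @param path CSV path.
#' @return A pose tibble with columns `frame`, `t`, `mouse_id`, `nose_x`,
#'   `nose_y`, `center_x`, `center_y`, `tail_x`, `tail_y`, `detected`.
#' @export
read_pose_csv <- function(path) {
  if (!file.exists(path)) stop("pose file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(POSE_COLUMNS, names(df))
  if (length(missing_cols))
    stop("pose file ", path, " lacks columns: ",
         paste(missing_cols, collapse = ", "))
  num_cols <- setdiff(POSE_COLUMNS, c("mouse_id", "detected"))
  for (cc in num_cols) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cc]]))))
    if (length(bad))
      stop("non-numeric value in column ", cc, " at row(s) ",
           paste(head(bad, 5), collapse = ", "))
    df[[cc]] <- as.numeric(df[[cc]])
  }
  df$detected <- as.logical(df$detected)
  dup <- duplicated(df[c("frame", "mouse_id")])
  if (any(dup))
    stop("duplicated (frame, mouse_id) row(s): ",
         paste(head(which(dup), 5), collapse = ", "))
  df <- df[order(df$frame, df$mouse_id), , drop = FALSE]
  # one t per frame, strictly increasing with frame
  ft <- unique(df[c("frame", "t")])
  if (anyDuplicated(ft$frame))
    stop("inconsistent timestamps: a frame maps to more than one t")
  if (is.unsorted(ft$t[order(ft$frame)], strictly = TRUE))
    stop("timestamps must be strictly increasing with frame number")
  rownames(df) <- NULL
  as_tibble(df)
}
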