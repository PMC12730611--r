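#' Write a trajectory to CSV
#'
#' Plain RFC-4180-style CSV with a header row: columns `t, x1, x2, u`, then
#' `theta1_hat, theta2_hat, theta3_hat` and `V` when the run recorded them.
#' Numbers are written with 17 significant digits so that reading the file
#' back ([read_trajectory()]) reproduces every double exactly.
#'
#' @param trajectory a `mood_trajectory` (an empty one yields a header-only
#'   file).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  if (!is.data.frame(trajectory)) {
    stop_invalid("`trajectory` must be a trajectory data frame")
  }
  cols <- intersect(c("t", "x1", "x2", "u",
                      "theta1_hat", "theta2_hat", "theta3_hat", "V"),
                    names(trajectory))
  lines <- paste(cols, collapse = ",")
  if (nrow(trajectory) > 0L) {
    formatted <- vapply(cols,
                        function(cl) sprintf("%.17g", trajectory[[cl]]),
                        character(nrow(trajectory)))
    if (nrow(trajectory) == 1L) formatted <- matrix(formatted, nrow = 1L)
    lines <- c(lines, apply(formatted, 1, paste, collapse = ","))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a trajectory CSV
#'
#' Reads a file produced by [write_trajectory()] back into a
#' `mood_trajectory` data frame (scenario metadata attributes are not
#' stored in the file and are not restored; the series themselves
#' round-trip exactly).
#'
#' @param path CSV path.
#' @return A `mood_trajectory` data frame.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("file not found: %s", path))
  df <- utils::read.csv(path)
  required <- c("t", "x1", "x2", "u")
  if (!all(required %in% names(df))) {
    stop_invalid(sprintf(
      "not a trajectory CSV (needs columns %s): %s",
      paste(required, collapse = ", "), path
    ))
  }
  kind <- if ("theta1_hat" %in% names(df)) "adaptive"
          else if ("V" %in% names(df)) "emk"
          else "untreated"
  structure(df, class = c("mood_trajectory", "data.frame"), kind = kind)
}
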