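## Plain-text layout files and matrix export.  Layout schema (versioned,
## key-value header followed by one wall segment per line):
##
##   navbasis-layout 1
##   width: 20
##   height: 20
##   goal: 10 12          (0-based x y)
##   reward: 1
##   walls:
##   5 9 N                (cell x y, blocked direction N/S/E/W)
##   ...

DIR_CODE <- c(north = "N", south = "S", east = "E", west = "W")

#' Write a gridworld layout file
#'
#' @param gw a `grid_world`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(gw, path) {
  gxy <- cell_xy(gw, gw$goal)
  lines <- c("navbasis-layout 1",
             sprintf("width: %d", gw$width),
             sprintf("height: %d", gw$height),
             sprintf("goal: %d %d", gxy[1], gxy[2]),
             sprintf("reward: %g", gw$reward),
             "walls:")
  if (nrow(gw$blocked)) {
    a <- cell_xy(gw, gw$blocked[, 1])
    b <- cell_xy(gw, gw$blocked[, 2])
    dx <- b[, 1] - a[, 1]; dy <- b[, 2] - a[, 2]
    dir <- ifelse(dy == 1, "N", ifelse(dy == -1, "S",
                  ifelse(dx == 1, "E", "W")))
    lines <- c(lines, sprintf("%d %d %s", a[, 1], a[, 2], dir))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a gridworld layout file
#'
#' @param path path to a file written by [write_layout()].
#' @return A `grid_world`.
#' @export
read_layout <- function(path) {
  lines <- readLines(path)
  if (!grepl("^navbasis-layout 1", lines[1]))
    stop("not a navbasis layout file (or unsupported version)")
  get_val <- function(key) {
    ln <- grep(sprintf("^%s:", key), lines, value = TRUE)[1]
    trimws(sub(sprintf("^%s:", key), "", ln))
  }
  W <- as.integer(get_val("width")); H <- as.integer(get_val("height"))
  goal_xy <- as.integer(strsplit(get_val("goal"), "\\s+")[[1]])
  reward <- as.numeric(get_val("reward"))
  wi <- which(lines == "walls:")
  blocked <- NULL
  wall_lines <- lines[seq_len(length(lines)) > wi]
  wall_lines <- wall_lines[nzchar(trimws(wall_lines))]
  if (length(wall_lines)) {
    parts <- strsplit(trimws(wall_lines), "\\s+")
    x <- vapply(parts, function(p) as.integer(p[1]), integer(1))
    y <- vapply(parts, function(p) as.integer(p[2]), integer(1))
    dir <- vapply(parts, function(p) p[3], character(1))
    a <- y * W + x + 1L
    dx <- c(N = 0L, S = 0L, E = 1L, W = -1L)[dir]
    dy <- c(N = 1L, S = -1L, E = 0L, W = 0L)[dir]
    b <- (y + dy) * W + (x + dx) + 1L
    blocked <- cbind(a, b)
  }
  grid_world(W, H, blocked = blocked,
             goal = goal_xy[2] * W + goal_xy[1] + 1L, reward = reward)
}

#' Export a per-state field as a delimited text matrix
#'
#' Writes one row per grid row (row `y = height - 1` first, so the file
#' reads like a map), tab-separated, preceded by `#`-prefixed header lines.
#'
#' @param values length-`M` numeric vector over states.
#' @param gw the `grid_world` the values live on.
#' @param path output path.
#' @param header named character vector of metadata to embed.
#' @return `path`, invisibly.
#' @export
write_field_matrix <- function(values, gw, path, header = character()) {
  stopifnot(length(values) == n_states(gw))
  m <- matrix(values, nrow = gw$height, ncol = gw$width, byrow = TRUE)
  m <- m[rev(seq_len(gw$height)), , drop = FALSE]
  con <- file(path, "w"); on.exit(close(con))
  for (k in names(header)) writeLines(sprintf("# %s: %s", k, header[[k]]), con)
  write.table(m, con, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a field matrix written by [write_field_matrix()]
#'
#' @param path input path.
#' @return Numeric vector over states (row-major state order), with the
#'   header lines in attribute `"header"`.
#' @export
read_field_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  m <- as.matrix(read.table(text = lines[!grepl("^#", lines)], sep = "\t"))
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  structure(as.numeric(t(m)), header = sub("^# ", "", hdr))
}
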