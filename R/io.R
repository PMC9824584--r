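#' Write an observable table as delimited text
#'
#' Tab-delimited, header row, full double precision (`%.17g`) so that a
#' write/read round trip is lossless to the last bit.  The table must have
#' a `t` column with ascending times.
#'
#' @param df data.frame of per-time observables (column `t` required).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_observables <- function(df, path) {
  if (!"t" %in% names(df)) stop("observable tables require a 't' column")
  if (is.unsorted(df$t, strictly = FALSE)) stop("times must be ascending")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  body <- do.call(paste, c(lapply(df, function(col)
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)),
    sep = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read an observable table written by [write_observables()]
#'
#' Tolerant reader: unknown extra columns are preserved.  Missing `t`
#' column or non-monotone times raise a parse error naming the offending
#' line.
#'
#' @param path input file.
#' @return A data.frame.
#' @export
read_observables <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  if (!"t" %in% names(df))
    stop(sprintf("%s: missing required column 't'", path))
  bad <- which(diff(df$t) < 0)
  if (length(bad))
    stop(sprintf("%s: non-monotone time at line %d", path, bad[1] + 2L))
  df
}

#' Write a trajectory in XYZ format
#'
#' Standard XYZ: per frame a bead-count line, a comment line carrying
#' `t=<time>`, then one `M x y z` line per bead.
#'
#' @param frames list of N x 3 position matrices (shared bead count).
#' @param path output file.
#' @param times frame time stamps.
#' @param element element symbol written in the first column.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path, times = seq_along(frames) - 1,
                      element = "M") {
  if (!length(frames)) {
    warning("zero frames: writing an empty file")
    file.create(path)
    return(invisible(path))
  }
  ns <- vapply(frames, nrow, 0L)
  if (length(unique(ns)) != 1) stop("inconsistent bead counts across frames")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(frames)) {
    writeLines(c(sprintf("%d", ns[1]), sprintf("t=%.17g", times[i])), con)
    writeLines(sprintf("%s %.10g %.10g %.10g", element,
                       frames[[i]][, 1], frames[[i]][, 2],
                       frames[[i]][, 3]), con)
  }
  invisible(path)
}

#' Read an XYZ trajectory written by [write_xyz()]
#'
#' @param path input file.
#' @return A list with `frames` (list of N x 3 matrices) and `times`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  times <- numeric(0)
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    if (is.na(n)) stop(sprintf("%s: bad bead count at line %d", path, i))
    tm <- suppressWarnings(as.numeric(sub("^t=", "", lines[i + 1])))
    rows <- lines[(i + 2):(i + 1 + n)]
    mat <- do.call(rbind, lapply(strsplit(rows, "\\s+"), function(p)
      as.numeric(p[2:4])))
    frames[[length(frames) + 1]] <- mat
    times <- c(times, tm)
    i <- i + 2 + n
  }
  list(frames = frames, times = times)
}

#' Write a run manifest
#'
#' YAML manifest of a run: full configuration echo, per-replica seeds,
#' package version, and an inventory of output files with MD5 checksums.
#' Re-running from the same configuration and master seed reproduces the
#' outputs bit-identically.
#'
#' @param path manifest file.
#' @param config configuration list.
#' @param seeds per-replica seeds.
#' @param files output files to inventory.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seeds = NULL, files = character()) {
  inv <- lapply(files, function(f)
    list(file = basename(f), md5 = unname(tools::md5sum(f))))
  # flatten non-scalar entries for a clean YAML echo
  cfg <- rapply(config, function(x)
    if (is.function(x)) deparse(substitute(x)) else x, how = "replace")
  yaml::write_yaml(list(
    package = "chainexpand",
    version = as.character(utils::packageVersion("chainexpand")),
    config = cfg, seeds = seeds, inventory = inv), path)
  invisible(path)
}

#' Read a run manifest
#' @param path manifest file.
#' @return The manifest as a list.
#' @export
read_manifest <- function(path) yaml::read_yaml(path)
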