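## Plain-text interchange formats. Trajectories: a tidy CSV with one record
## per (frame, agent) pair — columns frame, agent (0-based), x, y (metres),
## state (moving/stationary/unknown), present. Crockers: a commented header
## (version, mode, k, averaged flag, time grid, eps grid) followed by the
## Betti matrix as CSV. Both round-trip losslessly.

#' Write a trajectory to CSV
#'
#' One record per (frame, agent), frame-major then by agent id, 0-based
#' indices, coordinates in metres. By default only present records are
#' written; `keepMasked = TRUE` also writes masked records (with their
#' internally retained coordinates and `present = false`), making the round
#' trip lossless under dropouts. Headings are not serialized.
#'
#' @param traj A [TrajectorySet-class].
#' @param path Output path.
#' @param keepMasked Write masked (dropout) records too.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(traj, path, keepMasked = FALSE) {
  Tn <- nFrames(traj); n <- nAgents(traj)
  frame <- rep(seq_len(Tn) - 1L, each = n)
  agent <- rep(seq_len(n) - 1L, times = Tn)
  x <- as.vector(t(traj@positions[, , 1]))
  y <- as.vector(t(traj@positions[, , 2]))
  mv <- as.vector(t(traj@moving))
  state <- ifelse(is.na(mv), "unknown",
                  ifelse(mv, "moving", "stationary"))
  present <- as.vector(t(traj@present))
  df <- data.frame(frame = frame, agent = agent, x = x, y = y,
                   state = state, present = tolower(as.character(present)))
  if (!keepMasked) df <- df[present, , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory from CSV
#'
#' Reconstructs dense T x N grids from the record format of
#' [writeTrajectory()]. `(frame, agent)` pairs absent from the file are
#' marked not-present with `NA` coordinates; frames with no present agent
#' still advance the frame index. Duplicate `(frame, agent)` records and
#' non-numeric coordinates are rejected with the offending row number.
#'
#' @param path Input path.
#' @param arena Arena the coordinates live in.
#' @return A [TrajectorySet-class] (headings `NA`: they are not serialized).
#' @export
readTrajectory <- function(path, arena = arenaConfig()) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("frame", "agent", "x", "y", "state", "present")
  if (!all(need %in% names(df)))
    stop("trajectory file must have columns ", paste(need, collapse = ", "))
  frame <- suppressWarnings(as.integer(df$frame))
  agent <- suppressWarnings(as.integer(df$agent))
  x <- suppressWarnings(as.numeric(df$x))
  y <- suppressWarnings(as.numeric(df$y))
  bad <- which(is.na(frame) | is.na(agent) | is.na(x) | is.na(y))
  if (length(bad))
    stop("malformed trajectory record at data row ", bad[1])
  key <- paste(frame, agent)
  if (anyDuplicated(key))
    stop("duplicate (frame, agent) record at data row ",
         which(duplicated(key))[1])
  Tn <- max(frame) + 1L; n <- max(agent) + 1L
  pos <- array(NA_real_, c(Tn, n, 2))
  mov <- matrix(NA, Tn, n)
  present <- matrix(FALSE, Tn, n)
  ti <- frame + 1L; ai <- agent + 1L
  pos[cbind(ti, ai, 1L)] <- x
  pos[cbind(ti, ai, 2L)] <- y
  mov[cbind(ti, ai)] <- ifelse(df$state == "unknown", NA,
                               df$state == "moving")
  present[cbind(ti, ai)] <- tolower(df$present) %in% c("true", "t", "1")
  trajectorySet(pos, moving = mov, present = present, arena = arena)
}

#' Write a crocker to CSV
#'
#' Commented header carrying a format version, mode, homology dimension,
#' averaged flag, time grid and eps grid, followed by the Betti matrix (one
#' row per eps value).
#'
#' @param crocker A [Crocker-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeCrocker <- function(crocker, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# crocker v1",
               paste0("# mode: ", crocker@mode),
               paste0("# k: ", crocker@k),
               paste0("# averaged: ", crocker@averaged),
               paste0("# times: ", paste(crocker@times, collapse = ",")),
               paste0("# eps: ",
                      paste(sprintf("%.17g", crocker@epsGrid),
                            collapse = ","))),
             con)
  utils::write.table(crocker@betti, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a crocker from CSV
#'
#' @param path Input path (format of [writeCrocker()]).
#' @return A [Crocker-class].
#' @export
readCrocker <- function(path) {
  if (!file.exists(path)) stop("no such crocker file: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  if (!length(hdr) || !grepl("^# crocker v", hdr[1]))
    stop("not a crocker file (missing version header)")
  field <- function(name) {
    ln <- grep(paste0("^# ", name, ": "), hdr, value = TRUE)
    if (!length(ln)) stop("crocker header missing field: ", name)
    sub(paste0("^# ", name, ": "), "", ln[1])
  }
  mode <- field("mode")
  k <- suppressWarnings(as.integer(field("k")))
  averaged <- as.logical(field("averaged"))
  times <- as.integer(strsplit(field("times"), ",")[[1]])
  eps <- as.numeric(strsplit(field("eps"), ",")[[1]])
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  betti <- do.call(rbind, lapply(strsplit(body, ","), as.numeric))
  if (!identical(dim(betti), c(length(eps), length(times))))
    stop("crocker matrix shape does not match header grids")
  newCrocker(betti, eps, times, k, mode, averaged)
}
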