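# Readers and writers. Raw samples travel as CSV (long format, one row per
# sample), results as TSV, environments and reports as JSON; all files UTF-8,
# coordinates in vm, times in seconds.

#' Read trajectories from a long-format CSV
#'
#' Expected header: `participant_id,trial_id,t,x,y`. Rows may arrive in any
#' order; samples are grouped by `(participant_id, trial_id)` and sorted by
#' `t`, then validated against the fixed-rate contract.
#'
#' @param path CSV file path.
#' @return named list (by participant) of lists (by trial) of
#'   [trajectory()] objects.
#' @export
read_trajectories <- function(path) {
  dt <- data.table::fread(path, sep = ",")
  need <- c("participant_id", "trial_id", "t", "x", "y")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("parse error: missing column(s) ", paste(miss, collapse = ", "),
         " in ", path)
  for (cc in c("t", "x", "y")) {
    bad <- which(!is.finite(dt[[cc]]))
    if (length(bad))
      stop("parse error: non-finite ", cc, " at data row ", bad[1],
           " of ", path)
  }
  dt <- dt[order(dt$participant_id, dt$trial_id, dt$t), ]
  out <- list()
  for (pid in unique(dt$participant_id)) {
    sub_p <- dt[dt$participant_id == pid, ]
    trials <- list()
    for (tid in unique(sub_p$trial_id)) {
      sub <- sub_p[sub_p$trial_id == tid, ]
      trials[[as.character(tid)]] <-
        trajectory(pid, tid, sub$t, sub$x, sub$y)
    }
    out[[as.character(pid)]] <- trials
  }
  out
}

#' Write trajectories to a long-format CSV
#'
#' Inverse of [read_trajectories()].
#'
#' @param trajs a list of [trajectory()] objects, or a nested
#'   participant/trial list as returned by [read_trajectories()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  flat <- list()
  collect <- function(x) {
    if (inherits(x, "nav_trajectory")) {
      flat[[length(flat) + 1]] <<- data.frame(
        participant_id = attr(x, "participant_id"),
        trial_id = attr(x, "trial_id"),
        t = x$t, x = x$x, y = x$y)
    } else if (is.list(x)) lapply(x, collect)
  }
  collect(trajs)
  data.table::fwrite(do.call(rbind, flat), path, sep = ",")
  invisible(path)
}

#' Read a cognitive-score table
#'
#' CSV with one row per participant; a `participant_id` column is required,
#' everything else passes through.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_cognitive <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = ","))
  if (!"participant_id" %in% names(df))
    stop("parse error: cognitive table lacks a participant_id column")
  df
}

#' Write a results table as TSV
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  data.table::fwrite(as.data.frame(df), path, sep = "\t")
  invisible(path)
}
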