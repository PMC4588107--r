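#' Generate a multi-session block protocol schedule
#'
#' Builds the event schedule of the acquisition protocol: `n_sessions`
#' sessions of `n_blocks` blocks; each block opens with a `baseline_s` second
#' baseline followed by `reps * length(tasks)` task intervals of `task_s`
#' seconds of task performance and `rest_s` seconds of rest. Within a block
#' every task appears exactly `reps` times, in an order randomised
#' independently per block. Onsets are block-local seconds (each block is its
#' own recording). With the defaults (5 sessions x 3 blocks x 6 tasks x 4
#' repetitions) each task occurs 60 times and a block lasts
#' 30 + 24*(20+17) = 918 s.
#'
#' @param n_sessions,n_blocks protocol dimensions.
#' @param tasks character vector of task labels.
#' @param reps repetitions of each task per block.
#' @param task_s,rest_s,baseline_s interval durations in seconds.
#' @param seed integer seed; the schedule is deterministic given the seed.
#' @return data frame of class `nirs_schedule` with columns `session`,
#'   `block`, `onset_s`, `duration_s`, `task` (NA outside task phases) and
#'   `phase` (baseline/task/rest).
#' @examples
#' sch <- generate_protocol(seed = 1)
#' table(sch$task[sch$phase == "task"])  # 60 each
#' @export
generate_protocol <- function(n_sessions = 5, n_blocks = 3,
                              tasks = c("MM", "WG", "HT", "RF", "RS", "RR"),
                              reps = 4, task_s = 20, rest_s = 17,
                              baseline_s = 30, seed = 1) {
  n_int <- reps * length(tasks)
  if (n_int < 1 || reps < 1)
    stop2("reps * number of tasks must give a positive interval count")
  if (anyDuplicated(tasks)) stop2("task labels must be unique")
  rows <- with_stream(seed, "protocol", {
    out <- vector("list", n_sessions * n_blocks)
    k <- 0L
    for (s in seq_len(n_sessions)) for (b in seq_len(n_blocks)) {
      order_b <- sample(rep(tasks, reps))
      onset <- baseline_s + (seq_len(n_int) - 1) * (task_s + rest_s)
      k <- k + 1L
      out[[k]] <- rbind(
        data.frame(session = s, block = b, onset_s = 0,
                   duration_s = baseline_s, task = NA_character_,
                   phase = "baseline"),
        data.frame(session = s, block = b,
                   onset_s = rep(onset, each = 2) +
                     rep(c(0, task_s), n_int),
                   duration_s = rep(c(task_s, rest_s), n_int),
                   task = as.vector(rbind(order_b, NA_character_)),
                   phase = rep(c("task", "rest"), n_int))
      )
    }
    do.call(rbind, out)
  })
  rownames(rows) <- NULL
  structure(rows, class = c("nirs_schedule", "data.frame"),
            tasks = tasks, task_s = task_s, rest_s = rest_s,
            baseline_s = baseline_s)
}

block_duration <- function(schedule) {
  b1 <- schedule[schedule$session == schedule$session[1] &
                   schedule$block == schedule$block[1], ]
  max(b1$onset_s + b1$duration_s)
}
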