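#' Simulate a pouch-formation timeline
#'
#' Emits the pouch-formation events falling inside an observation window.
#' The default wild-type schedule places p1 at 16 hpf and p2 at 20 hpf
#' (the first two pouches are in place by 20 hpf), with p3-p6 following at
#' one new pouch every 4 h: 24, 28, 32 and 36 hpf.  The `tbx1` class forms
#' only p1 (at 16 hpf) and shows no outpocketing afterwards, so any window
#' starting at or after 26 hpf is empty for this class.
#'
#' @param class_name `"wild_type"` or `"tbx1"`, unless a custom `schedule`
#'   is supplied.
#' @param start_hpf Window start in hours post-fertilization.
#' @param window_h Window length in hours, > 0.
#' @param schedule Optional named numeric vector overriding the class
#'   schedule: names are pouch indices (`"1"`..`"6"`), values formation
#'   times in hpf.
#' @param jitter_sd_h Gaussian jitter (s.d., hours) added to each formation
#'   time; 0 (the default) keeps the schedule deterministic.
#' @param seed Seed used only when `jitter_sd_h > 0`.
#' @return A data frame with columns `pouch_index` and `formation_time_hpf`,
#'   sorted by time, containing the events with
#'   `formation_time_hpf` in `[start_hpf, start_hpf + window_h]`.
#' @examples
#' simulate_pouch_timeline("wild_type", start_hpf = 26, window_h = 10)
#' simulate_pouch_timeline("tbx1", start_hpf = 26, window_h = 10)
#' @export
simulate_pouch_timeline <- function(class_name, start_hpf = 26, window_h = 10,
                                    schedule = NULL, jitter_sd_h = 0,
                                    seed = 1L) {
  check_scalar_number(start_hpf, "start_hpf")
  check_scalar_number(window_h, "window_h")
  if (window_h <= 0) config_error("window_h", "must be > 0")
  check_scalar_number(jitter_sd_h, "jitter_sd_h", lower = 0)
  if (is.null(schedule)) {
    schedule <- switch(
      class_name,
      wild_type = c("1" = 16, "2" = 20, "3" = 24, "4" = 28, "5" = 32, "6" = 36),
      tbx1 = c("1" = 16),
      config_error("class_name",
                   sprintf("unknown timeline class '%s' (supply `schedule` for custom classes)",
                           class_name))
    )
  }
  if (is.null(names(schedule)) || anyDuplicated(names(schedule))) {
    config_error("schedule", "must have unique pouch-index names")
  }
  times <- unname(schedule)
  if (jitter_sd_h > 0) {
    times <- with_seed(seed, times + stats::rnorm(length(times), 0, jitter_sd_h))
  }
  keep <- times >= start_hpf & times <= start_hpf + window_h
  out <- data.frame(pouch_index = as.integer(names(schedule))[keep],
                    formation_time_hpf = times[keep])
  out <- out[order(out$formation_time_hpf), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a 2x2 marker-contribution contingency table
#'
#' Draws the numbers of marker-positive and marker-negative cells that
#' contribute to a growing pouch as independent binomials, emulating the
#' contribution counts tested with Fisher's exact test (e.g. dusp6 reporter
#' positive vs negative endodermal cells).
#'
#' @param n_pos,n_neg Numbers of marker-positive / negative cells (>= 0).
#' @param p_pos,p_neg Per-cell contribution probabilities, in `[0, 1]`.
#' @param seed Integer seed; identical arguments give an identical table.
#' @return A 2x2 integer matrix, rows `marker_pos` / `marker_neg`, columns
#'   `contributes` / `no_contribution`.
#' @export
simulate_contribution_table <- function(n_pos, n_neg, p_pos, p_neg, seed = 1L) {
  check_scalar_number(n_pos, "n_pos", lower = 0)
  check_scalar_number(n_neg, "n_neg", lower = 0)
  check_scalar_number(p_pos, "p_pos", lower = 0, upper = 1)
  check_scalar_number(p_neg, "p_neg", lower = 0, upper = 1)
  with_seed(seed, {
    a <- stats::rbinom(1L, n_pos, p_pos)
    c_ <- stats::rbinom(1L, n_neg, p_neg)
    matrix(as.integer(c(a, n_pos - a, c_, n_neg - c_)), nrow = 2L,
           byrow = TRUE,
           dimnames = list(c("marker_pos", "marker_neg"),
                           c("contributes", "no_contribution")))
  })
}
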