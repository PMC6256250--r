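#' Generate an external spike train
#'
#' Spike times of one external signal source on `[0, duration]`. In `poisson`
#' mode the train is a homogeneous Poisson process of the given rate; in
#' `periodic` mode spikes fall at `k / rate` for `k = 1, 2, ...`. Poisson
#' trains for distinct sources should be generated under distinct seeds (or a
#' running RNG stream) so they are independent.
#'
#' @param rate Firing rate (Hz, >= 0).
#' @param duration Train duration (s, > 0).
#' @param mode `"poisson"` (default) or `"periodic"`.
#' @param seed Optional integer seed applied via [set.seed()] before drawing
#'   (Poisson mode only). Leave `NULL` to draw from the current RNG stream.
#' @return Strictly increasing numeric vector of spike times (s); may be empty.
#' @examples
#' spike_train(10, 1, seed = 1)
#' spike_train(10, 0.5, mode = "periodic")
#' @export
spike_train <- function(rate, duration, mode = c("poisson", "periodic"),
                        seed = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate < 0)
    stop("spike_train: rate must be a finite non-negative scalar")
  if (!is.numeric(duration) || duration <= 0)
    stop("spike_train: duration must be > 0")
  if (rate == 0) return(numeric(0))
  if (mode == "periodic") {
    return(seq(1 / rate, duration, by = 1 / rate))
  }
  if (!is.null(seed)) set.seed(seed)
  # draw exponential gaps in blocks until past the horizon
  expected <- rate * duration
  times <- numeric(0)
  t_last <- 0
  repeat {
    n <- max(100L, ceiling(expected - length(times) + 4 * sqrt(expected + 1)))
    gaps <- stats::rexp(n, rate)
    block <- t_last + cumsum(gaps)
    times <- c(times, block)
    t_last <- times[length(times)]
    if (t_last > duration) break
  }
  times[times <= duration]
}

#' Write spike events as two-column text
#'
#' @param events Data frame with columns `source_id` and `time_s` (or a numeric
#'   vector of times for a single source, written with source_id 1).
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_spikes <- function(events, path) {
  if (is.numeric(events))
    events <- data.frame(source_id = 1L, time_s = events)
  stopifnot(all(c("source_id", "time_s") %in% names(events)))
  utils::write.table(events[, c("source_id", "time_s")], path,
                     row.names = FALSE, col.names = TRUE, quote = FALSE,
                     sep = "\t")
  invisible(path)
}
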