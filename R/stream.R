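#' Causal moving average
#'
#' At position k the output is the mean of the last `min(window, k)` values —
#' only past data, so the operator can run live on a growing focus graph.
#' Output length equals input length; an empty input gives an empty output.
#'
#' @param x numeric vector (ordered series).
#' @param window number of points averaged (>= 1); the default 4 keeps the
#'   time delay short while visibly steadying a noisy graph.
#' @param na.rm drop non-finite values from each window (a window with no
#'   finite value yields `NA`).
#' @return numeric vector, same length as `x`.
#' @export
moving_average <- function(x, window = 4L, na.rm = FALSE) {
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  n <- length(x)
  if (n == 0L) return(numeric(0))
  vapply(seq_len(n), function(k) {
    w <- x[max(1L, k - window + 1L):k]
    if (na.rm) w <- w[is.finite(w)]
    if (length(w) == 0L) NA_real_ else mean(w)
  }, numeric(1))
}

#' Integrate (pixelwise average) the last n frames of a stream
#'
#' Averaging n frames with independent noise reduces the noise standard
#' deviation by sqrt(n) at the cost of a time lag of n - 1 frames.
#'
#' @param frames list of numeric matrices with identical dimensions.
#' @param n number of trailing frames to average (>= 1, <= length(frames)).
#' @return numeric matrix.
#' @export
integrate_frames <- function(frames, n = 4L) {
  stopifnot(is.list(frames))
  if (n < 1 || n > length(frames)) {
    stop("need n >= 1 frames available for integration", call. = FALSE)
  }
  last <- frames[(length(frames) - n + 1L):length(frames)]
  d <- dim(last[[1L]])
  for (f in last) {
    if (!identical(dim(f), d)) stop("frame dimensions differ within the stream",
                                    call. = FALSE)
  }
  Reduce(`+`, last) / n
}

apply_reduction <- function(f, r) {
  for (i in seq_len(r)) f <- block_average(f)
  f
}

#' Evaluate a focus or stigmator sweep into a focus graph
#'
#' Walks an ordered frame stream with one control value (focus setting,
#' stigmator setting, ...) per frame and produces the time-ordered metric
#' graph an operator would watch. Per metric tick: the last `2 * integration`
#' frames are split into two adjacent non-overlapping windows of
#' `integration` frames, each window is pixelwise averaged, both averages are
#' reduced in lockstep to the configured 2x2 reduction level, and the
#' two-frame SNR (or, in `metric = "cov"` mode, the sample covariance) is
#' recorded. The smoothed series is a causal moving average, so every output
#' at tick k depends only on frames up to k.
#'
#' Non-overlapping integration windows keep the two averaged frames free of
#' shared raw frames, so their noise stays independent and the covariance
#' SNR model remains valid. With `integration = 1` this is plain
#' consecutive-frame pairing.
#'
#' Samples with `status = "zero_noise"` are stored with an `Inf` sentinel and
#' excluded from smoothing and peak detection.
#'
#' @param frames list of frames, ordered by acquisition time.
#' @param controls numeric vector, one control value per frame.
#' @param reduction `"auto"` (run [reduction_sweep()] on the first pair and
#'   fix its chosen level for the whole sweep) or a fixed integer level >= 0.
#' @param window causal moving-average length (default 4).
#' @param integration frames per integration window (default 1 = no
#'   integration; 4 matches the operator practice the package emulates).
#' @param r_max maximum level considered when `reduction = "auto"`.
#' @param metric `"snr"` (default) or `"cov"` (cheaper; the sample covariance
#'   is graphed instead of the SNR).
#' @return an object of class `"focus_graph"`: list with `samples` (tibble
#'   `tick`, `control`, `snr_raw`, `snr_smooth`, `status`), `window`,
#'   `integration`, `level`, `metric`, `peak_tick` (from
#'   [detect_just_focus()], `NA` if no usable peak).
#' @export
evaluate_sweep <- function(frames, controls, reduction = "auto",
                           window = 4L, integration = 1L, r_max = 5L,
                           metric = c("snr", "cov")) {
  metric <- match.arg(metric)
  stopifnot(is.list(frames), length(frames) == length(controls))
  n <- as.integer(integration)
  if (n < 1) stop("integration must be >= 1", call. = FALSE)
  nf <- length(frames)
  if (nf < 2L * n) stop("stream too short for the integration setting",
                        call. = FALSE)

  pair_at <- function(k) {
    list(t1 = integrate_frames(frames[seq_len(k - n)], n),
         t2 = integrate_frames(frames[seq_len(k)], n))
  }

  first <- pair_at(2L * n)
  level <- if (identical(reduction, "auto")) {
    reduction_sweep(first$t1, first$t2, r_max = r_max)$chosen
  } else {
    as.integer(reduction)
  }
  if (level < 0) stop("reduction level must be >= 0", call. = FALSE)

  ticks <- seq.int(2L * n, nf)
  raw <- numeric(length(ticks))
  status <- character(length(ticks))
  for (i in seq_along(ticks)) {
    p <- pair_at(ticks[i])
    est <- estimate_snr(apply_reduction(p$t1, level),
                        apply_reduction(p$t2, level))
    raw[i] <- if (metric == "snr") est$snr else est$cov
    status[i] <- est$status
  }

  smooth <- moving_average(ifelse(is.finite(raw), raw, NA_real_),
                           window = window, na.rm = TRUE)
  graph <- structure(
    list(samples = tibble::tibble(tick = ticks, control = controls[ticks],
                                  snr_raw = raw, snr_smooth = smooth,
                                  status = status),
         window = as.integer(window), integration = n,
         level = level, metric = metric, peak_tick = NA_integer_),
    class = "focus_graph"
  )
  graph$peak_tick <- detect_just_focus(graph)
  graph
}

#' Detect the just-focus point of a focus graph
#'
#' The just-focus setting is where the smoothed metric changes from rising to
#' falling. The detector returns the tick of the global maximum of the
#' smoothed series, provided the rise to the maximum from its left and the
#' fall from it to its right each exceed a prominence threshold; otherwise it
#' returns `NA` ("no usable peak" — the honest answer for a graph buried in
#' noise).
#'
#' The default threshold is `2 * sigma * sqrt(2 * log(n))`, where `sigma` is
#' the tick-to-tick jitter of the *raw* series (`sd(diff(raw)) / sqrt(2)`)
#' and `n` the number of samples. The `sqrt(2 log n)` factor is the expected
#' extreme deviation of `n` independent jitter draws, so a peak must stand at
#' about twice the height that pure noise would reach by chance in a series
#' of this length — a plain multiple of the jitter would flag the noise's own
#' maximum as a peak on any flat graph.
#'
#' @param graph a `"focus_graph"` object (>= 3 finite smoothed samples).
#' @param prominence override the prominence threshold (same units as the
#'   graphed metric); `NULL` for the default described above.
#' @return integer tick of the detected peak, or `NA_integer_`.
#' @export
detect_just_focus <- function(graph, prominence = NULL) {
  stopifnot(inherits(graph, "focus_graph"))
  s <- graph$samples
  ok <- is.finite(s$snr_smooth)
  if (sum(ok) < 3L) return(NA_integer_)
  y <- s$snr_smooth[ok]
  ticks <- s$tick[ok]
  thr <- if (is.null(prominence)) {
    raw <- s$snr_raw[is.finite(s$snr_raw)]
    sigma <- if (length(raw) >= 3L) stats::sd(diff(raw)) / sqrt(2) else 0
    2 * sigma * sqrt(2 * log(length(y)))
  } else {
    prominence
  }
  i <- which.max(y)
  rise <- y[i] - min(y[seq_len(i)])
  fall <- y[i] - min(y[i:length(y)])
  if (rise > thr && fall > thr) ticks[i] else NA_integer_
}

#' Is the focusing signal at this reduction level sufficient?
#'
#' The acquired data are sufficient when the stability index of the selected
#' level reaches a user-set threshold; an insufficient verdict is the trigger
#' to reinforce the signal, e.g. by searching nearby fields of view
#' ([search_best_field()]).
#'
#' @param index_value stability index of the evaluated level (scalar), or a
#'   one-row tibble with an `index_value` column as returned by
#'   [select_optimal_reduction()].
#' @param threshold required index value (>= 0).
#' @return `"sufficient"` or `"insufficient"`.
#' @export
assess_sufficiency <- function(index_value, threshold) {
  if (is.data.frame(index_value)) index_value <- index_value$index_value
  stopifnot(length(index_value) == 1L, length(threshold) == 1L, threshold >= 0)
  if (index_value >= threshold) "sufficient" else "insufficient"
}

#' @export
print.focus_graph <- function(x, ...) {
  cat(sprintf("Focus graph: %d samples, metric %s, reduction level %d, window %d, integration %d\n",
              nrow(x$samples), x$metric, x$level, x$window, x$integration))
  if (is.na(x$peak_tick)) cat("  no usable peak detected\n")
  else cat(sprintf("  just-focus peak at tick %d (control %.4g)\n", x$peak_tick,
                   x$samples$control[match(x$peak_tick, x$samples$tick)]))
  invisible(x)
}

#' Tidy a focus graph
#'
#' @param x a `"focus_graph"` object.
#' @param ... unused.
#' @return tibble `tick`, `control`, `snr_raw`, `snr_smooth`, `status`, and a
#'   logical `peak` flag marking the detected just-focus tick.
#' @export
tidy.focus_graph <- function(x, ...) {
  dplyr::mutate(x$samples,
                peak = !is.na(x$peak_tick) & .data$tick == x$peak_tick)
}

#' One-row summary of a focus graph
#'
#' @param x a `"focus_graph"` object.
#' @param ... unused.
#' @return one-row tibble: `n_samples`, `metric`, `level`, `window`,
#'   `integration`, `peak_tick`, `peak_control`.
#' @export
glance.focus_graph <- function(x, ...) {
  pc <- if (is.na(x$peak_tick)) NA_real_ else
    x$samples$control[match(x$peak_tick, x$samples$tick)]
  tibble::tibble(n_samples = nrow(x$samples), metric = x$metric,
                 level = x$level, window = x$window,
                 integration = x$integration,
                 peak_tick = x$peak_tick, peak_control = pc)
}

#' Plot a focus graph
#'
#' Raw metric as light points, causal moving average as a line, detected
#' just-focus tick circled.
#'
#' @param object a `"focus_graph"` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.focus_graph <- function(object, ...) {
  d <- tidy(object)
  ylab <- if (object$metric == "snr") "SNR" else "sample covariance"
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$tick)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$snr_raw), alpha = 0.3, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$snr_smooth)) +
    ggplot2::labs(x = "frame tick", y = ylab) +
    ggplot2::theme_minimal()
  if (any(d$peak)) {
    p <- p + ggplot2::geom_point(data = d[d$peak, ],
                                 ggplot2::aes(y = .data$snr_smooth),
                                 shape = 1, size = 5)
  }
  p
}
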