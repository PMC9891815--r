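#' Reduce a frame by simple 2x2 block averaging
#'
#' Each output pixel is the arithmetic mean of a 2x2 block of the source; the
#' output is `floor(h/2) x floor(w/2)`. A trailing odd row or column is
#' discarded (padding would bias the block means). For an image whose desired
#' signal is oversampled (constant over each 2x2 block) this halves the noise
#' standard deviation while leaving the signal untouched, doubling the SNR at
#' the cost of three quarters of the pixels.
#'
#' @param f numeric matrix with at least 2 rows and 2 columns.
#' @return numeric matrix of the reduced frame.
#' @export
block_average <- function(f) {
  check_frame(f)
  h2 <- nrow(f) %/% 2L
  w2 <- ncol(f) %/% 2L
  f <- f[seq_len(2L * h2), seq_len(2L * w2), drop = FALSE]
  (f[seq(1L, 2L * h2, by = 2L), seq(1L, 2L * w2, by = 2L), drop = FALSE] +
   f[seq(2L, 2L * h2, by = 2L), seq(1L, 2L * w2, by = 2L), drop = FALSE] +
   f[seq(1L, 2L * h2, by = 2L), seq(2L, 2L * w2, by = 2L), drop = FALSE] +
   f[seq(2L, 2L * h2, by = 2L), seq(2L, 2L * w2, by = 2L), drop = FALSE]) / 4
}

#' Sweep repeated 2x2 reductions of a frame pair and score each level
#'
#' Both frames are reduced in lockstep so the two-frame covariance model stays
#' valid at every level. At each repetition count r = 0, 1, ..., `r_max` the
#' SNR ([estimate_snr()]) and the stability index ([stability_index()], with
#' `m` the pixel count *at that level*) are recorded. The sweep stops early if
#' a further halving would drop below 2x2 pixels.
#'
#' @param t1,t2 registered frames of identical dimensions.
#' @param r_max maximum number of 2x2 reductions (default 5).
#' @return an object of class `"reduction_sweep"`: list with `levels` (tibble
#'   with columns `level`, `width`, `height`, `m`, `snr`, `index_value`) and
#'   `chosen` (level maximising the index, ties toward the smaller level).
#' @export
reduction_sweep <- function(t1, t2, r_max = 5L) {
  check_pair(t1, t2)
  if (r_max < 0) stop("r_max must be >= 0", call. = FALSE)
  rows <- vector("list", r_max + 1L)
  for (r in 0:r_max) {
    est <- estimate_snr(t1, t2)
    idx <- if (is.finite(est$snr)) stability_index(est$snr, est$m) else Inf
    rows[[r + 1L]] <- tibble::tibble(
      level = r, width = ncol(t1), height = nrow(t1), m = est$m,
      snr = est$snr, index_value = idx
    )
    if (r == r_max || nrow(t1) < 4L || ncol(t1) < 4L) break
    t1 <- block_average(t1)
    t2 <- block_average(t2)
  }
  levels <- dplyr::bind_rows(rows)
  structure(
    list(levels = levels, chosen = levels$level[which.max(levels$index_value)]),
    class = "reduction_sweep"
  )
}

#' Pick the reduction level with the largest stability index
#'
#' Returns the row of the sweep at the index-maximising level. Ties are broken
#' toward the smaller repetition count, preserving resolution when the index
#' is indifferent.
#'
#' @param sweep a `"reduction_sweep"` object.
#' @return one-row tibble (`level`, `width`, `height`, `m`, `snr`,
#'   `index_value`).
#' @export
select_optimal_reduction <- function(sweep) {
  stopifnot(inherits(sweep, "reduction_sweep"), nrow(sweep$levels) >= 1L)
  sweep$levels[which.max(sweep$levels$index_value), ]
}

#' @export
print.reduction_sweep <- function(x, ...) {
  cat(sprintf("2x2 SNR-priority reduction sweep (%d levels, chosen r = %d)\n",
              nrow(x$levels), x$chosen))
  print(x$levels)
  invisible(x)
}

#' Tidy a reduction sweep
#'
#' @param x a `"reduction_sweep"` object.
#' @param ... unused.
#' @return tibble with one row per level (`level`, `width`, `height`, `m`,
#'   `snr`, `index_value`, and logical `chosen`).
#' @export
tidy.reduction_sweep <- function(x, ...) {
  dplyr::mutate(x$levels, chosen = .data$level == x$chosen)
}

#' One-row summary of a reduction sweep
#'
#' @param x a `"reduction_sweep"` object.
#' @param ... unused.
#' @return one-row tibble: the chosen level plus `n_levels`.
#' @export
glance.reduction_sweep <- function(x, ...) {
  dplyr::mutate(select_optimal_reduction(x), n_levels = nrow(x$levels))
}

#' Plot stability index and SNR against reduction level
#'
#' @param object a `"reduction_sweep"` object.
#' @param ... unused.
#' @return a ggplot object: index (and SNR, dotted) vs repetitions, the chosen
#'   level circled.
#' @export
autoplot.reduction_sweep <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$level, y = .data$index_value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = d[d$chosen, ], shape = 1, size = 5) +
    ggplot2::labs(x = "2x2 averaging repetitions",
                  y = "stability index  M SNR^4 / (2 SNR^2 + 1)") +
    ggplot2::theme_minimal()
}
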