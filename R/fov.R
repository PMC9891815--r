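#' Field-of-view search by beam shift
#'
#' When the current field's focusing signal is too weak
#' ([assess_sufficiency()] says `"insufficient"`), a stronger desired signal
#' can usually be found near the observation region by shifting the beam —
#' without moving the stage — and ranking candidate fields by their stability
#' index. A rough focus suffices: the ranking survives defocus blur because
#' blur attenuates all candidates' signals together.
#'
#' @name fov_search
NULL

#' Default candidate grid: a ring of beam shifts plus the centre
#'
#' @param radius ring radius in specimen pixels.
#' @param n_ring number of shifts on the ring (default 8).
#' @param center include the zero shift (the current field) as the first
#'   candidate.
#' @return tibble with columns `dx`, `dy`, in scan order (centre first, then
#'   counter-clockwise from +x).
#' @export
ring_shifts <- function(radius, n_ring = 8L, center = TRUE) {
  ang <- 2 * pi * (seq_len(n_ring) - 1L) / n_ring
  g <- tibble::tibble(dx = round(radius * cos(ang)), dy = round(radius * sin(ang)))
  if (center) g <- dplyr::bind_rows(tibble::tibble(dx = 0, dy = 0), g)
  g
}

#' Build a frame-pair provider from the virtual microscope
#'
#' Returns a function of a beam shift `(dx, dy)` that renders a registered
#' frame pair at that shift, with all other optics fixed — the source
#' expected by [evaluate_field()] and [search_best_field()]. All candidates
#' share one optics state (same defocus, same current), as a real search does.
#'
#' @param spec a `"virtual_specimen"`.
#' @param optics an `"optics_state"`; its `beam_shift` is replaced per call.
#' @param acq an `"acquisition_params"`.
#' @return function `(dx, dy) -> list(t1 =, t2 =)`.
#' @export
sem_pair_provider <- function(spec, optics, acq) {
  force(spec); force(optics); force(acq)
  function(dx, dy) {
    st <- optics
    st$beam_shift <- c(dx, dy)
    sig <- render_signal(spec, st, acq)
    ns <- noise_sd(st, acq)
    list(t1 = sig + matrix(stats::rnorm(length(sig), sd = ns), nrow(sig), ncol(sig)),
         t2 = sig + matrix(stats::rnorm(length(sig), sd = ns), nrow(sig), ncol(sig)))
  }
}

#' Evaluate one candidate field of view
#'
#' Obtains a registered pair at the given beam shift, applies the configured
#' 2x2 reduction level, and scores the field by its SNR and stability index.
#'
#' @param source a frame-pair provider: function `(dx, dy) -> list(t1, t2)`,
#'   e.g. from [sem_pair_provider()]. It should signal an error for an
#'   out-of-bounds shift.
#' @param dx,dy beam shift in specimen pixels.
#' @param reduction 2x2 reduction repetitions applied before scoring
#'   (normally the level already chosen by [select_optimal_reduction()]).
#' @return one-row tibble: `dx`, `dy`, `snr`, `index_value`.
#' @export
evaluate_field <- function(source, dx = 0, dy = 0, reduction = 0L) {
  p <- source(dx, dy)
  est <- estimate_snr(apply_reduction(p$t1, reduction),
                      apply_reduction(p$t2, reduction))
  idx <- if (is.finite(est$snr)) stability_index(est$snr, est$m) else Inf
  tibble::tibble(dx = dx, dy = dy, snr = est$snr, index_value = idx)
}

#' Rank candidate fields of view by stability index
#'
#' Evaluates every candidate shift and returns them sorted by decreasing
#' index value; the head of the table is the recommended field. Ties keep
#' the candidates' scan order (the sort is stable).
#'
#' @param shifts data frame with columns `dx`, `dy` (candidate beam shifts,
#'   e.g. [ring_shifts()]).
#' @param source frame-pair provider, as in [evaluate_field()].
#' @param reduction 2x2 reduction repetitions applied before scoring.
#' @return tibble `dx`, `dy`, `snr`, `index_value`, `rank` (1 = best),
#'   sorted by rank.
#' @export
search_best_field <- function(shifts, source, reduction = 0L) {
  stopifnot(is.data.frame(shifts), nrow(shifts) >= 1L,
            all(c("dx", "dy") %in% names(shifts)))
  res <- purrr::pmap(list(shifts$dx, shifts$dy),
                     function(dx, dy) evaluate_field(source, dx, dy, reduction))
  res <- dplyr::bind_rows(res)
  ord <- order(-res$index_value)  # stable: ties keep scan order
  res <- res[ord, ]
  res$rank <- seq_len(nrow(res))
  res
}
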