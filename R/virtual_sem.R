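#' Virtual scanning-electron-microscope forward model
#'
#' The simulator renders registered, noisy video frames from a noise-free
#' specimen texture under a controllable optics state, reproducing the
#' statistical model the two-frame covariance estimator assumes: the desired
#' signal is identical between frames taken at the same state, while the
#' additive noise is drawn independently per frame with standard deviation
#' `dwell_scale / sqrt(current_pA * dwell_s)` — noise amplitude falls with the
#' square root of probe current times dwell time, which is why a slow scan or
#' a larger current cleans the image up.
#'
#' @name virtual_sem
NULL

#' Generate a virtual specimen texture
#'
#' A seeded Gaussian random field: white noise smoothed with an isotropic
#' Gaussian of sigma `feature_scale / 2`, then standardised to mean 0 and
#' standard deviation 1, so `feature_scale` is roughly the correlation length
#' of the surface features in specimen pixels. An optional `strength_profile`
#' (matrix of multipliers, same dimensions) modulates the local signal
#' amplitude — the tool for planting strong- and weak-texture regions in
#' field-of-view search scenarios.
#'
#' @param width,height specimen map size in pixels.
#' @param feature_scale feature correlation length in specimen pixels (>= 1).
#' @param strength_profile optional `height x width` matrix of non-negative
#'   amplitude multipliers.
#' @param seed integer seed; the texture is fully reproducible from it.
#' @return an object of class `"virtual_specimen"`: list with `texture`
#'   (matrix), `feature_scale`, `seed`.
#' @export
generate_specimen <- function(width = 1024L, height = 1024L,
                              feature_scale = 8, strength_profile = NULL,
                              seed = 1L) {
  if (feature_scale < 1) stop("feature_scale must be >= 1", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tx <- matrix(stats::rnorm(width * height), nrow = height, ncol = width)
  if (feature_scale > 1) {
    tx <- EBImage::gblur(tx, sigma = feature_scale / 2)
  }
  tx <- (tx - mean(tx)) / stats::sd(tx)
  if (!is.null(strength_profile)) {
    if (!identical(dim(strength_profile), dim(tx))) {
      stop("strength_profile must match the specimen dimensions", call. = FALSE)
    }
    tx <- tx * strength_profile
  }
  structure(list(texture = tx, feature_scale = feature_scale, seed = seed),
            class = "virtual_specimen")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Optics control state of the virtual microscope
#'
#' @param defocus focus offset in focal units; 0 is just focus. The blur
#'   sigma grows linearly with `|defocus|` at `psf_scale` output pixels per
#'   focal unit (see [acquisition_params()]).
#' @param astig_x,astig_y stigmator offsets; (0, 0) is corrected astigmatism.
#'   Their magnitude `a = hypot(astig_x, astig_y)` splits the point-spread
#'   function into two orthogonal line foci with sigmas
#'   `psf_scale * |defocus + a|` and `psf_scale * |defocus - a|`, oriented at
#'   angle `atan2(astig_y, astig_x) / 2`: at `defocus = 0` an astigmatic beam
#'   still blurs anisotropically, and no single focus setting removes the
#'   blur in both directions.
#' @param beam_shift length-2 integer-ish vector (dx, dy): field translation
#'   in specimen pixels without stage motion.
#' @param magnification output pixels per specimen pixel (> 0). Values above
#'   1 oversample the texture — the regime in which 2x2 averaging barely
#'   touches the desired signal.
#' @param current probe current in pA (> 0).
#' @return an object of class `"optics_state"` (named list).
#' @export
optics_state <- function(defocus = 0, astig_x = 0, astig_y = 0,
                         beam_shift = c(0, 0), magnification = 1,
                         current = 26) {
  if (magnification <= 0) stop("magnification must be > 0", call. = FALSE)
  if (current <= 0) stop("current must be > 0", call. = FALSE)
  structure(list(defocus = defocus, astig_x = astig_x, astig_y = astig_y,
                 beam_shift = beam_shift, magnification = magnification,
                 current = current),
            class = "optics_state")
}

#' Acquisition parameters of the virtual microscope
#'
#' @param width,height output frame size in pixels.
#' @param frame_rate frames per second; per-frame dwell is `1 / frame_rate`
#'   unless `dwell` is given. The default 25 frames/s is a TV scan (0.04 s
#'   per frame).
#' @param dwell explicit per-frame dwell time in seconds (overrides
#'   `frame_rate` for the noise model; use e.g. 80 for a slow scan).
#' @param dwell_scale noise scaling constant: noise sd =
#'   `dwell_scale / sqrt(current * dwell)`. The default 3.4 places a 26 pA
#'   TV-scan frame of a unit-sd specimen at SNR ~ 0.3, the "low but workable"
#'   regime.
#' @param psf_scale blur sigma in output pixels per focal unit of defocus.
#' @param sampling `"bilinear"` (smooth textures) or `"nearest"`
#'   (pixel-replication; with an integer magnification the signal is exactly
#'   constant on magnification-sized blocks).
#' @param seed integer seed used by [sem_stream()].
#' @return an object of class `"acquisition_params"` (named list).
#' @export
acquisition_params <- function(width = 640L, height = 480L, frame_rate = 25,
                               dwell = NULL, dwell_scale = 3.4,
                               psf_scale = 2, sampling = c("bilinear", "nearest"),
                               seed = 1L) {
  sampling <- match.arg(sampling)
  if (frame_rate <= 0) stop("frame_rate must be > 0", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 frame_rate = frame_rate, dwell = dwell,
                 dwell_scale = dwell_scale, psf_scale = psf_scale,
                 sampling = sampling, seed = as.integer(seed)),
            class = "acquisition_params")
}

frame_dwell <- function(acq) {
  if (is.null(acq$dwell)) 1 / acq$frame_rate else acq$dwell
}

noise_sd <- function(optics, acq) {
  acq$dwell_scale / sqrt(optics$current * frame_dwell(acq))
}

psf_sigmas <- function(optics, acq) {
  a <- sqrt(optics$astig_x^2 + optics$astig_y^2)
  list(su = acq$psf_scale * abs(optics$defocus + a),
       sv = acq$psf_scale * abs(optics$defocus - a),
       theta = atan2(optics$astig_y, optics$astig_x) / 2)
}

# Elliptical Gaussian convolution kernel with principal sigmas su (axis at
# angle theta from the column direction) and sv (orthogonal), normalised to
# sum 1. Matrix convention: rows = y, columns = x.
anisotropic_gaussian_kernel <- function(su, sv, theta) {
  r <- max(1L, ceiling(3 * max(su, sv)))
  xy <- seq(-r, r)
  x <- matrix(xy, 2 * r + 1, 2 * r + 1, byrow = TRUE)
  y <- matrix(xy, 2 * r + 1, 2 * r + 1)
  u <- cos(theta) * x + sin(theta) * y
  v <- -sin(theta) * x + cos(theta) * y
  k <- exp(-0.5 * ((u / max(su, 1e-12))^2 + (v / max(sv, 1e-12))^2))
  # a sigma of exactly 0 collapses that axis to its central line
  if (su < 1e-12) k[abs(u) > 0.5] <- 0
  if (sv < 1e-12) k[abs(v) > 0.5] <- 0
  k / sum(k)
}

# Noise-free rendering: crop at beam shift / magnification, then optical blur.
render_signal <- function(spec, optics, acq) {
  s <- psf_sigmas(optics, acq)
  margin <- ceiling(3 * max(s$su, s$sv)) + 2L
  # round up to a multiple of 16 so integer-magnification block structure
  # stays aligned with the 2x2 reduction grid through repeated reductions
  margin <- margin + ((16L - margin %% 16L) %% 16L)
  out_h <- acq$height + 2L * margin
  out_w <- acq$width + 2L * margin

  # specimen window needed, centred on the map centre plus beam shift
  mag <- optics$magnification
  int_mag <- acq$sampling == "nearest" && abs(mag - round(mag)) < 1e-9 && mag >= 1
  win_h <- ceiling(out_h / mag) + 2L
  win_w <- ceiling(out_w / mag) + 2L
  tx <- spec$texture
  cy <- floor(nrow(tx) / 2) + round(optics$beam_shift[2])
  cx <- floor(ncol(tx) / 2) + round(optics$beam_shift[1])
  r0 <- cy - floor(win_h / 2)
  c0 <- cx - floor(win_w / 2)
  if (r0 < 1 || c0 < 1 || r0 + win_h - 1 > nrow(tx) || c0 + win_w - 1 > ncol(tx)) {
    stop("field of view (crop window) outside the specimen map", call. = FALSE)
  }
  win <- tx[r0:(r0 + win_h - 1L), c0:(c0 + win_w - 1L), drop = FALSE]

  if (int_mag) {
    # exact pixel replication: the signal is constant on mag x mag blocks
    # aligned to the output grid (the strict oversampling regime)
    img <- kronecker(win, matrix(1, round(mag), round(mag)))
    img <- img[seq_len(out_h), seq_len(out_w), drop = FALSE]
  } else {
    filt <- if (acq$sampling == "nearest") "none" else "bilinear"
    img <- EBImage::resize(win, w = out_h, h = out_w, filter = filt)
    img <- matrix(as.numeric(img), nrow = out_h, ncol = out_w)
  }

  if (s$su > 1e-9 || s$sv > 1e-9) {
    k <- anisotropic_gaussian_kernel(s$su, s$sv, s$theta)
    img <- EBImage::filter2(img, k, boundary = "circular")
    img <- matrix(as.numeric(img), nrow = out_h, ncol = out_w)
  }
  img[(margin + 1L):(margin + acq$height),
      (margin + 1L):(margin + acq$width), drop = FALSE]
}

#' Render one noisy frame from the virtual microscope
#'
#' Pipeline: crop the specimen at the beam shift and magnification (bilinear
#' or nearest-neighbour sampling), convolve with the elliptical Gaussian
#' point-spread function implied by defocus and stigmator state, then add
#' per-frame independent zero-mean noise with sd
#' `dwell_scale / sqrt(current * dwell)`. Repeated calls at the same state
#' share the identical noise-free signal and differ only in the noise draw —
#' exactly the model under which the two-frame covariance SNR is defined.
#'
#' Noise is drawn from the current R random stream; seed it (or use
#' [sem_stream()], which seeds from `acq$seed`) for reproducibility.
#'
#' @param spec a `"virtual_specimen"`.
#' @param optics an `"optics_state"`.
#' @param acq an `"acquisition_params"`.
#' @param noise `"gaussian"` (default; additive, current-dependent sd) or
#'   `"poisson"` (signal-dependent shot noise; the covariance model then
#'   holds only approximately, see the methods vignette).
#' @return numeric matrix (`acq$height` x `acq$width`).
#' @export
render_frame <- function(spec, optics, acq, noise = c("gaussian", "poisson")) {
  noise <- match.arg(noise)
  sig <- render_signal(spec, optics, acq)
  ns <- noise_sd(optics, acq)
  if (noise == "gaussian") {
    sig + matrix(stats::rnorm(length(sig), sd = ns), nrow(sig), ncol(sig))
  } else {
    # shot-noise mode: scale the (offset) signal to expected counts such that
    # the Poisson sd at the mean intensity equals the Gaussian model's sd
    offset <- sig - min(sig) + 1
    cpu <- mean(offset) / max(ns^2, 1e-12)  # counts per intensity unit
    counts <- matrix(stats::rpois(length(offset), cpu * offset),
                     nrow(sig), ncol(sig))
    counts / cpu + min(sig) - 1
  }
}

#' Ground-truth SNR of the virtual microscope at a given state
#'
#' The oracle for parameter-recovery tests: the standard deviation of the
#' blurred noise-free crop divided by the noise sd computed from the
#' generator settings. No noise is drawn.
#'
#' @inheritParams render_frame
#' @return scalar dimensionless SNR.
#' @export
ground_truth_snr <- function(spec, optics, acq) {
  stats::sd(render_signal(spec, optics, acq)) / noise_sd(optics, acq)
}

#' Render a frame stream along an optics trajectory
#'
#' Replays an operator session: one or more frames per optics state, with the
#' per-frame control metadata recorded in a sidecar tibble. All randomness is
#' seeded from `acq$seed`, so reruns with the same configuration are
#' identical.
#'
#' @param spec a `"virtual_specimen"`.
#' @param trajectory list of `"optics_state"` objects (one per step), e.g.
#'   from [ramp_trajectory()].
#' @param acq an `"acquisition_params"`.
#' @param frames_per_state frames rendered at each state (default 1).
#' @param noise noise model passed to [render_frame()].
#' @return an object of class `"sem_stream"`: list with `frames` (list of
#'   matrices) and `meta` (tibble: `tick`, `defocus`, `astig_x`, `astig_y`,
#'   `shift_x`, `shift_y`, `magnification`, `current`, `dwell`).
#' @export
sem_stream <- function(spec, trajectory, acq, frames_per_state = 1L,
                       noise = "gaussian") {
  stopifnot(is.list(trajectory), length(trajectory) >= 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(acq$seed)
  frames <- list()
  meta <- list()
  tick <- 0L
  for (st in trajectory) {
    sig <- render_signal(spec, st, acq)
    ns <- noise_sd(st, acq)
    for (j in seq_len(frames_per_state)) {
      tick <- tick + 1L
      frames[[tick]] <- sig +
        matrix(stats::rnorm(length(sig), sd = ns), nrow(sig), ncol(sig))
      meta[[tick]] <- tibble::tibble(
        tick = tick, defocus = st$defocus,
        astig_x = st$astig_x, astig_y = st$astig_y,
        shift_x = st$beam_shift[1], shift_y = st$beam_shift[2],
        magnification = st$magnification, current = st$current,
        dwell = frame_dwell(acq))
    }
  }
  structure(list(frames = frames, meta = dplyr::bind_rows(meta)),
            class = "sem_stream")
}

#' Linear ramp of one optics control
#'
#' Convenience builder for focus and stigmator sweeps: a base optics state
#' with one field (`defocus`, `astig_x` or `astig_y`) ramped linearly.
#'
#' @param base an `"optics_state"` used for all other fields.
#' @param control field to ramp: `"defocus"`, `"astig_x"` or `"astig_y"`.
#' @param from,to ramp endpoints (instrument units).
#' @param n_steps number of states.
#' @return list of `"optics_state"` objects.
#' @export
ramp_trajectory <- function(base, control = c("defocus", "astig_x", "astig_y"),
                            from = -3, to = 3, n_steps = 48L) {
  control <- match.arg(control)
  vals <- seq(from, to, length.out = n_steps)
  lapply(vals, function(v) { st <- base; st[[control]] <- v; st })
}

#' @export
print.sem_stream <- function(x, ...) {
  cat(sprintf("Virtual SEM stream: %d frames of %dx%d\n", length(x$frames),
              nrow(x$frames[[1]]), ncol(x$frames[[1]])))
  invisible(x)
}

#' @export
print.virtual_specimen <- function(x, ...) {
  cat(sprintf("Virtual specimen: %dx%d texture, feature scale %.3g, seed %d\n",
              nrow(x$texture), ncol(x$texture), x$feature_scale, x$seed))
  invisible(x)
}
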