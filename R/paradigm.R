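#' Construct a task paradigm
#'
#' Low-level constructor validating timing fields. Conditions are limited
#' to the emotion-matching design vocabulary: `cue`, `face`, `shape`.
#'
#' @param tr repetition time in seconds (> 0).
#' @param n_volumes number of acquired volumes.
#' @param events data.frame with columns `onset` (s), `duration` (s) and
#'   `condition`; may have zero rows (resting acquisition).
#' @return object of class `fold_paradigm`.
#' @export
fold_paradigm <- function(tr, n_volumes, events) {
  assert_scalar_num(tr, "tr", 0, strict = TRUE)
  assert_scalar_num(n_volumes, "n_volumes", 1)
  events <- as.data.frame(events)
  if (nrow(events)) {
    stopifnot(all(c("onset", "duration", "condition") %in% names(events)))
    if (!all(events$condition %in% c("cue", "face", "shape")))
      stopf("conditions must be drawn from {cue, face, shape}")
    if (any(events$onset + events$duration > tr * n_volumes + 1e-9))
      stopf("events extend past the end of the scan")
    if (any(events$onset < 0) || any(events$duration < 0))
      stopf("onsets and durations must be nonnegative")
  }
  structure(list(tr = tr, n_volumes = as.integer(n_volumes), events = events),
            class = "fold_paradigm")
}

#' Emotion-matching block paradigm
#'
#' The fast-TR block design used throughout the package: TR = 0.72 s,
#' 176 volumes, six alternating blocks (3 face-matching, 3 shape-matching),
#' each block a 3 s cue followed by six 3 s trials (21 s per block).
#'
#' @return a `fold_paradigm`.
#' @examples
#' p <- make_paradigm()
#' p$n_volumes          # 176
#' p$tr * p$n_volumes   # 126.72 s total
#' @export
make_paradigm <- function() {
  blocks <- data.frame(
    onset = (0:5) * 21,
    condition = rep(c("face", "shape"), 3))
  events <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(b) {
    data.frame(
      onset = c(blocks$onset[b], blocks$onset[b] + 3),
      duration = c(3, 18),
      condition = c("cue", blocks$condition[b]))
  }))
  fold_paradigm(tr = 0.72, n_volumes = 176L, events = events)
}

#' @export
print.fold_paradigm <- function(x, ...) {
  cat(sprintf("fold_paradigm: TR %.3g s, %d volumes, %d events (%s)\n",
              x$tr, x$n_volumes, nrow(x$events),
              paste(unique(x$events$condition), collapse = ", ")))
  invisible(x)
}

#' Double-gamma hemodynamic response kernel
#'
#' Canonical HRF sampled at multiples of `tr`: a gamma density peaking at
#' `peak` seconds minus `undershoot_ratio` times a gamma density peaking
#' at `undershoot` seconds (gamma shape = mode + 1 at rate 1, so the mode
#' sits exactly at the requested peak).
#'
#' @param tr sampling interval in seconds.
#' @param n number of samples.
#' @param peak,undershoot,undershoot_ratio shape of the response
#'   (defaults: peak 6 s, undershoot 16 s, ratio 1/6; ratio 0 removes the
#'   undershoot term).
#' @return numeric vector of length `n`.
#' @export
hrf_kernel <- function(tr, n, peak = 6, undershoot = 16,
                       undershoot_ratio = 1 / 6) {
  tt <- (seq_len(n) - 1L) * tr
  dgamma(tt, shape = peak + 1, rate = 1) -
    undershoot_ratio * dgamma(tt, shape = undershoot + 1, rate = 1)
}

#' Convolve a task condition with the hemodynamic response
#'
#' Samples the condition's boxcar at volume acquisition times (volume k is
#' active if any event of the condition covers time `k * tr`) and convolves
#' it discretely with [hrf_kernel()], truncated to `n_volumes`. A condition
#' with no events yields an all-zero series.
#'
#' @param paradigm a `fold_paradigm`.
#' @param condition one of `"cue"`, `"face"`, `"shape"`.
#' @inheritParams hrf_kernel
#' @return numeric vector of length `n_volumes`.
#' @examples
#' reg <- hrf_convolve(make_paradigm(), "face")
#' @export
hrf_convolve <- function(paradigm, condition, peak = 6, undershoot = 16,
                         undershoot_ratio = 1 / 6) {
  stopifnot(inherits(paradigm, "fold_paradigm"))
  known <- unique(c("cue", "face", "shape", paradigm$events$condition))
  if (!is.character(condition) || length(condition) != 1L ||
      !(condition %in% known))
    stopf("unknown condition '%s'", as.character(condition)[1])
  n <- paradigm$n_volumes
  times <- (seq_len(n) - 1L) * paradigm$tr
  ev <- paradigm$events[paradigm$events$condition == condition, , drop = FALSE]
  box <- rep(0, n)
  for (k in seq_len(nrow(ev)))
    box[times >= ev$onset[k] - 1e-9 & times < ev$onset[k] + ev$duration[k] - 1e-9] <- 1
  if (!any(box != 0)) return(box)
  h <- hrf_kernel(paradigm$tr, n, peak, undershoot, undershoot_ratio)
  convolve(box, rev(h), type = "open")[seq_len(n)]
}
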