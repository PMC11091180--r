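#' Default spatial-frequency ladder
#'
#' Seven SF conditions in cycles/degree spanning the 0.5-20 c/deg range used
#' for parafoveal V1, with 0.625 c/deg as the lowest condition.
#'
#' @return Numeric vector of SFs (c/deg).
#' @export
default_sf_ladder <- function() c(0.625, 1.25, 2.5, 5, 7.5, 10, 15)

#' Generate a randomized flashed-grating stimulus sequence
#'
#' Emulates the reverse-correlation protocol: a stream of 20-ms frames, each
#' either a blank (probability 0.10) or a sinusoidal grating drawn uniformly
#' from 9 orientations (equally spaced over 0-180 degrees) x 8 spatial phases,
#' at a single fixed SF per sequence.
#'
#' @param n_frames Number of frames (>= 1); 150 frames make one typical 3-s
#'   trial segment.
#' @param sf SF condition in cycles/degree (constant within the sequence).
#' @param seed Integer seed; the sequence is reproducible for a fixed seed.
#' @param frame_duration_ms Frame duration in ms (fixed at 20 in the
#'   protocol).
#' @param blank_prob Probability that a frame is a blank (default 0.10).
#' @return A tibble of class `stimulus_sequence` with columns `onset_ms`,
#'   `orientation_idx` (0-8, NA for blanks), `phase_idx` (0-7, NA for blanks),
#'   `blank`, `sf_cpd`; frame duration and seed are stored as attributes.
#' @export
#' @examples
#' seq <- make_stimulus_sequence(150, sf = 2.5, seed = 1)
#' max(seq$onset_ms) + attr(seq, "frame_duration_ms") # 3000 ms
make_stimulus_sequence <- function(n_frames, sf, seed,
                                   frame_duration_ms = 20,
                                   blank_prob = 0.10) {
  if (length(n_frames) != 1 || n_frames < 1) {
    abort("`n_frames` must be a positive count")
  }
  n_frames <- as.integer(n_frames)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  blank <- runif(n_frames) < blank_prob
  ori <- ifelse(blank, NA_integer_, sample.int(9L, n_frames, replace = TRUE) - 1L)
  phase <- ifelse(blank, NA_integer_, sample.int(8L, n_frames, replace = TRUE) - 1L)
  out <- tibble::tibble(
    onset_ms = (seq_len(n_frames) - 1) * frame_duration_ms,
    orientation_idx = as.integer(ori),
    phase_idx = as.integer(phase),
    blank = blank,
    sf_cpd = sf
  )
  attr(out, "frame_duration_ms") <- frame_duration_ms
  attr(out, "seed") <- seed
  class(out) <- c("stimulus_sequence", class(out))
  out
}

# save/restore the global RNG state so seeded generators do not perturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write / read a stimulus sequence as tab-separated text
#'
#' @param x A `stimulus_sequence`.
#' @param path File path.
#' @return `write_stimulus_sequence()` returns `path` invisibly;
#'   `read_stimulus_sequence()` returns the tibble.
#' @export
write_stimulus_sequence <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_stimulus_sequence
#' @export
read_stimulus_sequence <- function(path) {
  df <- utils::read.delim(path)
  out <- tibble::as_tibble(df)
  out$blank <- as.logical(out$blank)
  class(out) <- c("stimulus_sequence", class(out))
  attr(out, "frame_duration_ms") <- if (nrow(out) > 1)
    diff(out$onset_ms[1:2]) else 20
  out
}
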