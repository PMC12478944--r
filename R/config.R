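#' Default pipeline configuration
#'
#' Returns the full nested configuration used by every stage of the
#' recognition pipeline. All values are overridable from a YAML file via
#' [load_config()] or programmatically by passing a nested list of
#' replacements.
#'
#' Key defaults: 8 kHz sampling, 256-sample (32 ms) Hamming frames with
#' 50% overlap, activity-gate energy threshold 40 (the energy of a quiet
#' pen recording stays below 40 while 1 s coughs and screams exceed 200),
#' over-subtraction factor 2 with spectral floor 0.01, IMCRA bias
#' compensation 1.47, 24 mel filters over 0--4000 Hz yielding 12 MFCC +
#' 12 delta-MFCC per frame.
#'
#' @param overrides nested named list of values replacing the defaults;
#'   unknown keys are rejected with an error naming them.
#' @return nested list of class `pig_config`.
#' @export
#' @examples
#' cfg <- pig_config()
#' cfg$preprocess$energy_threshold
#' cfg <- pig_config(list(preprocess = list(energy_threshold = 60)))
pig_config <- function(overrides = NULL) {
  cfg <- list(
    rate = 8000,
    preprocess = list(
      frame_length = 256L,
      frame_shift = 128L,
      energy_threshold = 40,
      endpoint = list(
        high_frac = 0.25,
        low_frac = 0.05,
        zcr_factor = 1.5,
        min_frames = 3L
      )
    ),
    denoise = list(
      alpha = 2.0,
      beta = 0.01,
      epsilon = 1.47,
      alpha_d = 0.85,
      fft_size = 256L,
      min_track_window = 40L,
      snr_threshold = 5,
      p_smooth = 0.9
    ),
    features = list(
      n_mels = 24L,
      n_mfcc = 12L,
      f_low = 0,
      f_high = 4000,
      delta_mode = "diff",
      log_floor = 1e-10
    ),
    wsvdd = list(
      C = NULL,            # NULL: 1 / (0.05 * q) at training time
      sigma = NULL,        # NULL: median pairwise distance heuristic
      radius_mode = "min_max",
      weighted = TRUE
    ),
    multisvdd = list(
      vote_priority = c("cough", "scream", "other", "unknown"),
      max_train_frames = 2000L
    ),
    pso = list(
      swarm_size = 60L,
      max_iter = 200L,
      c1 = 1.5,
      c2 = 2.0,
      inertia = 1.0,
      inertia_decay = FALSE,
      folds = 10L,
      c_bounds = c(0.01, 10),
      sigma_bounds = c(0.1, 20),
      velocity_frac = 0.2,
      seed = 1L
    ),
    synth = list(
      duration = 1.0,
      noise_kind = "white",
      snr_db = 15
    )
  )
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides, path = "")
  class(cfg) <- c("pig_config", "list")
  cfg
}

# recursive merge; rejects keys absent from the defaults
merge_config <- function(base, over, path) {
  if (!is.list(over)) stop("config override at '", path, "' must be a named list")
  nm <- names(over)
  if (length(over) && (is.null(nm) || any(nm == "")))
    stop("config override at '", path, "' has unnamed entries")
  for (k in nm) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(base)) stop("unknown config key: '", full, "'")
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], over[[k]], full)
    } else {
      base[[k]] <- over[[k]]
    }
  }
  base
}

#' Load pipeline configuration from a YAML file
#'
#' Reads a (possibly partial) YAML file and merges it over the defaults of
#' [pig_config()]. An empty file yields the all-defaults configuration;
#' keys not present in the default schema cause an error naming the
#' offending key.
#'
#' @param path path to a YAML file.
#' @return nested list of class `pig_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  over <- yaml::read_yaml(path)
  if (is.null(over)) return(pig_config())
  pig_config(over)
}
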