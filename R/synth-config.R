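#' Configuration for the synthetic gait study generator
#'
#' Bundles every parameter the simulators need: study design (fish, cycles),
#' per-behaviour stroke-cycle structure, kinematic amplitudes, the muscle
#' burst schedule, EMG noise model and sampling rates. Defaults describe a
#' four-fish study with ten strokes per fish and behaviour, swimming cycles
#' of 0.25 s and walking cycles of 0.60 s, kinematic amplitudes centred on
#' values typical for pectoral-fin walkers, and one scheduled activity burst
#' per muscle and cycle (three for the walking adductor, which fires in
#' trains).
#'
#' @param n_fish Number of individuals.
#' @param cycles_per_fish Stroke cycles recorded per fish and behaviour.
#' @param behaviours Character vector of behaviours simulated.
#' @param cycle_duration Named list per behaviour with elements `mean` and
#'   `sd` (seconds).
#' @param propulsion_fraction Named numeric, fraction of the cycle spent in
#'   the propulsive phase (stance for walking), strictly in (0, 1).
#' @param kinematic_params Named list per behaviour; see Details.
#' @param burst_schedule Data frame with columns `muscle`, `behaviour`,
#'   `onset_phase`, `offset_phase`, `amp`. Phases are cycle fractions;
#'   `offset_phase` may exceed 1 (burst runs into the next cycle) but must
#'   exceed `onset_phase`, with `onset_phase` in [0, 1).
#' @param timing_kappa von Mises concentration of the burst-timing jitter on
#'   the cycle circle. Larger is more repeatable.
#' @param noise_sd Baseline EMG noise standard deviation (V).
#' @param artifact_rate Low-frequency movement-artifact events per second.
#' @param artifact_amp Peak amplitude of an artifact (V).
#' @param fs_emg EMG sampling rate (samples per second).
#' @param fs_video Video sampling rate (frames per second).
#' @param random_fish_sd Standard deviation of the per-fish random intercept
#'   used by [generate_study()].
#' @param study_effects Named list with `grand_mean`, `behaviour_effect`
#'   (walking minus swimming), `muscle_effects` (named numeric over
#'   muscles), `interaction` (named numeric over muscles, added for walking
#'   only) and `residual_sd` for [generate_study()].
#' @param seed Integer seed; every generator is deterministic given the
#'   config and its seed.
#'
#' @details `kinematic_params` per behaviour:
#' \describe{
#'   \item{speed_bl_s}{forward speed over ground, body lengths per second}
#'   \item{add_centre_deg, add_amp_deg}{centre and half-amplitude of the
#'     sinusoidal fin adduction angle (degrees); phase set so maximum
#'     adduction falls at `add_max_phase` (cycle fraction)}
#'   \item{elev_centre_bl, elev_amp_bl, elev_max_phase}{fin tip elevation
#'     sinusoid (body lengths)}
#'   \item{nose_elev_amp_bl, nose_elev_max_phase}{nose elevation sinusoid
#'     (zero when swimming: the head stays level)}
#'   \item{nose_lat_amp_bl}{lateral nose oscillation (walking only)}
#'   \item{caudal_amp_bl}{lateral caudal-fin oscillation}
#' }
#'
#' @return An object of class `gait_sim_config` (a validated list).
#' @export
gait_sim_config <- function(n_fish = 4,
                            cycles_per_fish = 10,
                            behaviours = c("swimming", "walking"),
                            cycle_duration = list(
                              swimming = c(mean = 0.25, sd = 0.03),
                              walking = c(mean = 0.60, sd = 0.08)
                            ),
                            propulsion_fraction = c(swimming = 0.5, walking = 0.5),
                            kinematic_params = default_kinematic_params(),
                            burst_schedule = default_burst_schedule(),
                            timing_kappa = 8,
                            noise_sd = 0.1,
                            artifact_rate = 0.2,
                            artifact_amp = 0.3,
                            fs_emg = 10000,
                            fs_video = 500,
                            random_fish_sd = 5,
                            study_effects = default_study_effects(),
                            seed = 1L) {
  cfg <- list(
    n_fish = as.integer(n_fish), cycles_per_fish = as.integer(cycles_per_fish),
    behaviours = behaviours, cycle_duration = cycle_duration,
    propulsion_fraction = propulsion_fraction,
    kinematic_params = kinematic_params, burst_schedule = burst_schedule,
    timing_kappa = timing_kappa, noise_sd = noise_sd,
    artifact_rate = artifact_rate, artifact_amp = artifact_amp,
    fs_emg = fs_emg, fs_video = fs_video,
    random_fish_sd = random_fish_sd, study_effects = study_effects,
    seed = as.integer(seed)
  )
  class(cfg) <- "gait_sim_config"
  validate_gait_sim_config(cfg)
  cfg
}

#' @rdname gait_sim_config
#' @export
default_kinematic_params <- function() {
  list(
    swimming = list(
      speed_bl_s = 0.53,
      add_centre_deg = 187, add_amp_deg = 11, add_max_phase = 256 / 360,
      elev_centre_bl = -0.0485, elev_amp_bl = 0.0065, elev_max_phase = 197 / 360,
      nose_elev_amp_bl = 0, nose_elev_max_phase = 0.12,
      nose_lat_amp_bl = 0, caudal_amp_bl = 0.10
    ),
    walking = list(
      speed_bl_s = 0.56,
      add_centre_deg = 178.5, add_amp_deg = 31.5, add_max_phase = 238 / 360,
      elev_centre_bl = -0.0485, elev_amp_bl = 0.0125, elev_max_phase = 198 / 360,
      nose_elev_amp_bl = 0.03, nose_elev_max_phase = 43 / 360,
      nose_lat_amp_bl = 0.12, caudal_amp_bl = 0.35
    )
  )
}

#' @rdname gait_sim_config
#' @export
default_burst_schedule <- function() {
  # Onset/offset phases follow the observed polar timings of each muscle on
  # the stroke circle (phase = degrees / 360); offsets past 1 wrap into the
  # next cycle. Amplitude scales are relative carrier RMS levels.
  data.frame(
    muscle = c("Abd", "Add", "Cmt", "Zpt",
               "Abd", "Add", "Add", "Add", "Cmt", "Zpt"),
    behaviour = c(rep("swimming", 4), rep("walking", 6)),
    onset_phase = c(179, 310, 215, 18, 292, 7, 162, 288, 277, 96) / 360,
    offset_phase = c(373, 521, 465, 257, 508, 115, 252, 349, 474, 388) / 360,
    amp = c(1.0, 1.0, 0.8, 0.9, 1.2, 1.1, 0.9, 0.8, 1.0, 1.1),
    stringsAsFactors = FALSE
  )
}

#' @rdname gait_sim_config
#' @export
default_study_effects <- function() {
  list(
    grand_mean = 60,
    behaviour_effect = 8,
    muscle_effects = c(Abd = 0, Add = 4, Cmt = -2, Zpt = 2),
    interaction = c(Abd = 0, Add = 0, Cmt = 0, Zpt = 0),
    residual_sd = 10
  )
}

validate_gait_sim_config <- function(cfg) {
  stopifnot(cfg$n_fish >= 1, cfg$cycles_per_fish >= 1)
  stopifnot(length(cfg$behaviours) >= 1)
  for (b in cfg$behaviours) {
    cd <- cfg$cycle_duration[[b]]
    if (is.null(cd) || !all(c("mean", "sd") %in% names(cd)) || cd[["mean"]] <= 0 || cd[["sd"]] < 0)
      stop("invalid cycle_duration for behaviour '", b, "'")
    pf <- cfg$propulsion_fraction[[b]]
    if (is.null(pf) || pf <= 0 || pf >= 1)
      stop("propulsion_fraction for '", b, "' must be in (0, 1)")
    if (is.null(cfg$kinematic_params[[b]]))
      stop("missing kinematic_params for behaviour '", b, "'")
  }
  bs <- cfg$burst_schedule
  stopifnot(is.data.frame(bs),
            all(c("muscle", "behaviour", "onset_phase", "offset_phase", "amp") %in% names(bs)))
  if (any(bs$onset_phase < 0 | bs$onset_phase >= 1))
    stop("burst onset_phase must lie in [0, 1)")
  if (any(bs$offset_phase <= bs$onset_phase))
    stop("burst offset_phase must exceed onset_phase (unwrapped)")
  stopifnot(cfg$fs_emg > 0, cfg$fs_video > 0, cfg$noise_sd >= 0,
            cfg$timing_kappa >= 0, cfg$artifact_rate >= 0,
            cfg$random_fish_sd >= 0)
  invisible(cfg)
}

# Deterministic per-trial seed derived from the config seed. Kept below 2^31.
trial_seed <- function(seed, fish, behaviour, what = "trial") {
  b <- sum(utf8ToInt(paste0(behaviour, what)))
  (as.integer(seed) * 1009L + as.integer(fish) * 131071L + b * 7919L) %% 2147483647L
}
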