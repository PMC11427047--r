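# Synthetic robotic-manipulandum rigidity trials and the two quantitative
# rigidity measures: stiffness (torque-vs-angle slope) and angular impulse
# (slope of the time-integrated rectified torque, equivalently the mean
# rectified torque).

#' Synthetic rigidity trial parameters
#'
#' A minimal linear forearm model: resistive torque = elastic + viscous +
#' white noise. The elastic stiffness K is multiplied by `activation_gain`
#' during the contralateral activation manoeuvre and reduced multiplicatively
#' by DBS (`dbs_effect` is the fractional reduction at full effect; the
#' default 0.35 matches the typical one-third stiffness reduction seen under
#' clinically optimized stimulation).
#'
#' @param K elastic stiffness, N.m/deg.
#' @param B viscous coefficient, N.m.s/deg.
#' @param noise_sd torque noise s.d., N.m.
#' @param activation_gain multiplier on K in the active condition (> 0).
#' @param dbs_effect fractional reduction of K per unit pathway drive (0-1).
#' @return object of class `rigidity_params`.
#' @export
rigidity_params <- function(K = 0.010, B = 0.0008, noise_sd = 0.05,
                            activation_gain = 1.3, dbs_effect = 0.35) {
  stopifnot(K >= 0, B >= 0, noise_sd >= 0, activation_gain > 0,
            dbs_effect >= 0, dbs_effect <= 1)
  structure(list(K = K, B = B, noise_sd = noise_sd,
                 activation_gain = activation_gain, dbs_effect = dbs_effect),
            class = "rigidity_params")
}

#' Generate a synthetic manipulandum trial
#'
#' The imposed trajectory is a +/-40 degree, 1 Hz sinusoid about the
#' supination-pronation axis; torque is K' theta + B dtheta/dt + eps with
#' i.i.d. Gaussian noise, where K' includes the activation-manoeuvre gain and
#' any DBS-induced stiffness reduction (`dbs_drive` between 0 and 1 scales
#' `dbs_effect`).
#'
#' @param params a [rigidity_params()].
#' @param condition `"passive"` or `"active"`.
#' @param duration trial length, s (default 45, giving 45 cycles at 1 Hz).
#' @param fs sampling rate, Hz (default 1000).
#' @param dbs_drive modelled pathway drive between 0 and 1; 0 = DBS off.
#' @param dbs_state label recorded with the trial.
#' @param hemisphere id recorded with the trial.
#' @param seed integer seed (trials are deterministic per seed).
#' @param amplitude_deg,freq_hz trajectory amplitude and frequency.
#' @return object of class `manipulandum_trial`: `time` (s), `angle` (deg),
#'   `torque` (N.m) plus metadata.
#' @export
generate_trial <- function(params = rigidity_params(),
                           condition = c("passive", "active"),
                           duration = 45, fs = 1000, dbs_drive = 0,
                           dbs_state = "off", hemisphere = 1L, seed = 1,
                           amplitude_deg = 40, freq_hz = 1) {
  condition <- match.arg(condition)
  stopifnot(duration > 0, fs > 0, dbs_drive >= 0, dbs_drive <= 1)
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  theta <- amplitude_deg * sin(2 * pi * freq_hz * t)
  dtheta <- amplitude_deg * 2 * pi * freq_hz * cos(2 * pi * freq_hz * t)
  K <- params$K * (1 - params$dbs_effect * dbs_drive)
  if (condition == "active") K <- K * params$activation_gain
  eps <- with_seed(seed, rnorm(length(t), 0, params$noise_sd))
  torque <- K * theta + params$B * dtheta + eps
  structure(list(time = t, angle = theta, torque = torque,
                 fs = fs, duration = duration, condition = condition,
                 dbs_state = dbs_state, hemisphere = hemisphere, seed = seed,
                 amplitude_deg = amplitude_deg, freq_hz = freq_hz),
            class = "manipulandum_trial")
}

#' @export
print.manipulandum_trial <- function(x, ...) {
  cat(sprintf("<manipulandum_trial> %g s at %g Hz sampling, +/-%g deg %g Hz, %s condition, DBS %s\n",
              x$duration, x$fs, x$amplitude_deg, x$freq_hz, x$condition, x$dbs_state))
  invisible(x)
}

#' Read / write manipulandum trials as CSV
#'
#' Columns: `t_s`, `angle_deg`, `torque_Nm`.
#'
#' @param trial a `manipulandum_trial`.
#' @param path CSV file path.
#' @export
write_trial_csv <- function(trial, path) {
  write.csv(data.frame(t_s = trial$time, angle_deg = trial$angle,
                       torque_Nm = trial$torque), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  df <- read.csv(path)
  fs <- 1 / stats::median(diff(df$t_s))
  structure(list(time = df$t_s, angle = df$angle_deg, torque = df$torque_Nm,
                 fs = fs, duration = max(df$t_s) + 1 / fs,
                 condition = "passive", dbs_state = "unknown",
                 hemisphere = NA_integer_, seed = NA_integer_,
                 amplitude_deg = max(abs(df$angle_deg)), freq_hz = NA_real_),
            class = "manipulandum_trial")
}

#' Forearm stiffness from a trial
#'
#' Ordinary least-squares slope of torque against angular displacement over
#' the whole trial. Over an integer number of cycles the viscous (velocity)
#' component is orthogonal to position, so the slope recovers the elastic
#' stiffness.
#'
#' @param trial a `manipulandum_trial`.
#' @return stiffness, N.m/deg.
#' @export
stiffness <- function(trial) {
  if (var(trial$angle) == 0) stop("constant angle: stiffness undefined")
  unname(coef(lm(trial$torque ~ trial$angle))[2])
}

#' Angular impulse from a trial
#'
#' The cumulative rectified-torque integral I(t) = int_0^t |tau| ds
#' (trapezoidal) is fit against time by OLS; the slope — equivalently the
#' mean rectified torque — is the angular impulse measure.
#'
#' @param trial a `manipulandum_trial`.
#' @return angular impulse, N.m.
#' @export
angular_impulse <- function(trial) {
  at <- abs(trial$torque)
  dt <- diff(trial$time)
  I <- c(0, cumsum((at[-1] + at[-length(at)]) / 2 * dt))
  unname(coef(lm(I ~ trial$time))[2])
}

#' Rigidity measures of a trial
#'
#' @param trial a `manipulandum_trial`.
#' @return object of class `rigidity_measures`: `stiffness`,
#'   `angular_impulse`, plus the trial's condition / DBS state / hemisphere.
#' @export
rigidity_measures <- function(trial) {
  structure(list(stiffness = stiffness(trial),
                 angular_impulse = angular_impulse(trial),
                 condition = trial$condition, dbs_state = trial$dbs_state,
                 hemisphere = trial$hemisphere),
            class = "rigidity_measures")
}

#' DBS ON-minus-OFF change scores
#'
#' Signed differences (on - off) for both measures; negative values are
#' improvements (rigidity reduction).
#'
#' @param on,off `rigidity_measures` for the same hemisphere and condition.
#' @return list: `stiffness_change`, `angular_impulse_change`.
#' @export
change_score <- function(on, off) {
  if (!identical(on$condition, off$condition))
    stop("change scores need matching conditions")
  if (!identical(on$hemisphere, off$hemisphere))
    stop("change scores need matching hemispheres")
  list(stiffness_change = on$stiffness - off$stiffness,
       angular_impulse_change = on$angular_impulse - off$angular_impulse)
}
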