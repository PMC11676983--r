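#' Measurement protocol for synthetic datasets
#'
#' Defaults mirror the fluorometer protocol the package emulates: one reading
#' every 10 s for 90 min (541 points), three replicates per reaction system,
#' and additive Gaussian noise at 2% of the calibrated dynamic range.
#'
#' @param sample_interval Sampling interval, seconds (> 0).
#' @param duration Total duration, seconds (>= `sample_interval`).
#' @param n_replicates Number of replicate traces per role (>= 1).
#' @param noise_sd Noise standard deviation on the normalized (substitution
#'   ratio) scale; applied to intensities as `noise_sd * (f100 - f0)`.
#' @param f0,f100 Quenched baseline and positive-control intensity levels,
#'   a.u.; `f100 > f0`.
#' @param seed Integer seed; required so every dataset is reproducible.
#' @param drift_per_hour Optional linear instrument drift added to reaction
#'   traces, a.u. per hour (default 0).
#' @return A `synthetic_protocol`.
#' @export
synthetic_protocol <- function(sample_interval = 10, duration = 5400,
                               n_replicates = 3L, noise_sd = 0.02,
                               f0 = 100, f100 = 1000, seed,
                               drift_per_hour = 0) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop_config("`seed` is required for a synthetic protocol")
  if (sample_interval <= 0) stop_config("`sample_interval` must be > 0")
  if (duration < sample_interval)
    stop_config("`duration` must be >= `sample_interval`")
  if (n_replicates < 1) stop_config("`n_replicates` must be >= 1")
  if (noise_sd < 0) stop_config("`noise_sd` must be >= 0")
  if (f100 <= f0) stop_config("`f100` must exceed `f0`")
  structure(list(sample_interval = sample_interval, duration = duration,
                 n_replicates = as.integer(n_replicates), noise_sd = noise_sd,
                 f0 = f0, f100 = f100, seed = as.integer(seed),
                 drift_per_hour = drift_per_hour),
            class = "synthetic_protocol")
}

#' Sampling grid for a protocol
#'
#' `{0, d, 2d, ...}` truncated at the duration (the last point never exceeds
#' it). The default protocol yields 541 points.
#'
#' @param protocol A [synthetic_protocol()].
#' @return Numeric vector of times in seconds.
#' @export
make_time_grid <- function(protocol) {
  seq(0, protocol$duration, by = protocol$sample_interval)
}

#' Generate a synthetic fluorescence dataset with known ground truth
#'
#' Reaction traces are the noiseless model prediction
#' ([simulate_tmsdr()] then [predict_fluorescence()]) plus i.i.d. Gaussian
#' noise of SD `noise_sd * (f100 - f0)` and optional linear drift; baseline
#' traces fluctuate about `f0` and positive-control traces about `f100`.
#' Each replicate and calibration trace gets independent noise. The same
#' seed reproduces the dataset bit for bit.
#'
#' @param system A [tmsdr_system()] — the ground-truth rate constants.
#' @param initial Initial concentrations, see [reaction_state()].
#' @param protocol A [synthetic_protocol()].
#' @return A `synthetic_dataset`: list with elements `reaction`, `baseline`,
#'   `positive_control` (lists of `fluorescence_trace`) and `ground_truth`
#'   (system, initial state and protocol).
#' @examples
#' sys <- tmsdr_system(ka = 1.74e-4, kd = 8.51e-4)
#' ds <- generate_dataset(sys, reaction_state(10, 10),
#'                        synthetic_protocol(seed = 1))
#' length(ds$reaction)
#' @export
generate_dataset <- function(system, initial, protocol) {
  initial <- check_state(initial)
  times <- make_time_grid(protocol)
  traj <- simulate_tmsdr(system, initial, times)
  clean <- predict_fluorescence(traj, system, protocol$f0, protocol$f100)
  n <- length(times)
  sd_au <- protocol$noise_sd * (protocol$f100 - protocol$f0)
  drift <- protocol$drift_per_hour * times / 3600
  withr::with_seed(protocol$seed, {
    reaction <- lapply(seq_len(protocol$n_replicates), function(k)
      fluorescence_trace(times, clean$signal + drift + rnorm(n, 0, sd_au),
                         label = "reaction", replicate_id = k))
    baseline <- lapply(seq_len(protocol$n_replicates), function(k)
      fluorescence_trace(times, protocol$f0 + rnorm(n, 0, sd_au),
                         label = "baseline", replicate_id = k))
    positive <- lapply(seq_len(protocol$n_replicates), function(k)
      fluorescence_trace(times, protocol$f100 + rnorm(n, 0, sd_au),
                         label = "positive_control", replicate_id = k))
  })
  structure(list(reaction = reaction, baseline = baseline,
                 positive_control = positive,
                 ground_truth = list(system = system, initial = initial,
                                     protocol = protocol)),
            class = "synthetic_dataset")
}

#' Write / read a synthetic dataset directory
#'
#' Traces go to `{role}_{rep}.csv` files and the ground truth to a
#' `manifest.yaml` that round-trips through [read_dataset()].
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (role in c("reaction", "baseline", "positive_control")) {
    for (tr in dataset[[role]]) {
      write_trace_csv(tr, file.path(dir, sprintf("%s_%d.csv", role,
                                                 attr(tr, "replicate_id"))))
    }
  }
  gt <- dataset$ground_truth
  manifest <- list(system = unclass(gt$system),
                   initial = as.list(gt$initial),
                   protocol = unclass(gt$protocol))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  files <- list.files(dir, pattern = "^(reaction|baseline|positive_control)_[0-9]+\\.csv$")
  if (length(files) == 0L)
    stop_data("no trace files in %s (need reaction/baseline/positive_control CSVs)", dir)
  traces <- lapply(file.path(dir, files), read_trace_csv)
  roles <- vapply(traces, attr, character(1), "label")
  missing <- setdiff(c("reaction", "baseline", "positive_control"), roles)
  if (length(missing) > 0L)
    stop_data("dataset in %s is missing roles: %s", dir,
              paste(missing, collapse = ", "))
  out <- list(reaction = traces[roles == "reaction"],
              baseline = traces[roles == "baseline"],
              positive_control = traces[roles == "positive_control"],
              ground_truth = NULL)
  mpath <- file.path(dir, "manifest.yaml")
  if (file.exists(mpath)) {
    m <- yaml::read_yaml(mpath)
    out$ground_truth <- list(
      system = do.call(tmsdr_system, m$system[c("ka", "kd", "toehold_orientation",
                                                "modification", "reporter_species",
                                                "toehold_length", "recognition_length")]),
      initial = do.call(reaction_state, m$initial),
      protocol = do.call(synthetic_protocol, m$protocol))
  }
  structure(out, class = "synthetic_dataset")
}
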