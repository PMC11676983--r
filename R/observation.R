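#' Construct a fluorescence trace
#'
#' A single measured (or synthesized) intensity time series from the FAM
#' channel. The role of the trace and its replicate number are carried as
#' attributes; on disk they are encoded in the file name (`{role}_{rep}.csv`).
#'
#' @param times Times in seconds, strictly increasing.
#' @param intensity Intensities in arbitrary units, finite.
#' @param label Trace role: `"reaction"`, `"baseline"` (quenched gate only,
#'   no reaction possible) or `"positive_control"` (fluorophore-only species,
#'   defines the 100% substitution level).
#' @param replicate_id Integer replicate index.
#' @return A `fluorescence_trace`: data.frame with columns `time_s`, `signal`.
#' @export
fluorescence_trace <- function(times, intensity,
                               label = c("reaction", "baseline", "positive_control"),
                               replicate_id = 1L) {
  label <- match.arg(label)
  if (length(times) != length(intensity))
    stop_config("times and intensity differ in length (%d vs %d)",
                length(times), length(intensity))
  if (length(times) > 1L && any(diff(times) <= 0))
    stop_config("trace times must be strictly increasing")
  if (any(!is.finite(intensity)))
    stop_config("trace intensities must be finite")
  structure(data.frame(time_s = as.numeric(times), signal = as.numeric(intensity)),
            class = c("fluorescence_trace", "data.frame"),
            label = label, replicate_id = as.integer(replicate_id))
}

#' Predict the fluorescence trace of a simulated reaction
#'
#' The FRET readout is affine in the reporter-species concentration: fully
#' quenched gives `f0`, full substitution (reporter at the initial invader
#' concentration) gives `f100`, so
#' `F(t) = f0 + (f100 - f0) * reporter(t) / x1_0`.
#'
#' @param trajectory A `tmsdr_trajectory` from [simulate_tmsdr()].
#' @param system A [tmsdr_system()]; selects which species (X3 or X4) carries
#'   the unquenched fluorophore.
#' @param f0 Baseline (fully quenched) intensity, a.u.
#' @param f100 Positive-control (100% substitution) intensity, a.u.; must
#'   exceed `f0`.
#' @param initial_x1 Initial invader concentration, nM; defaults to the
#'   trajectory's stored initial state.
#' @return A `fluorescence_trace` with role `"reaction"`.
#' @export
predict_fluorescence <- function(trajectory, system, f0, f100, initial_x1 = NULL) {
  if (f100 <= f0)
    stop_config("`f100` (%g) must exceed `f0` (%g)", f100, f0)
  col <- switch(system$reporter_species, X3 = "x3_nM", X4 = "x4_nM")
  if (is.null(col) || !col %in% names(trajectory))
    stop_config("reporter species %s not present in trajectory",
                system$reporter_species)
  if (is.null(initial_x1)) initial_x1 <- attr(trajectory, "initial")[["x1"]]
  if (is.null(initial_x1) || initial_x1 <= 0)
    stop_config("`initial_x1` must be positive")
  fluorescence_trace(trajectory$time_s,
                     f0 + (f100 - f0) * trajectory[[col]] / initial_x1,
                     label = "reaction")
}

#' Bundle calibration traces
#'
#' @param baseline One `fluorescence_trace` or a list of them: the quenched
#'   gate alone (both fluorophore and quencher present, no reaction occurs).
#' @param positive_control One trace or a list: the fluorophore-only species
#'   at the reference concentration, defining 100% substitution.
#' @param reference_concentration Concentration (nM) of the positive-control
#'   species; metadata.
#' @return A `calibration_set`.
#' @export
calibration_set <- function(baseline, positive_control,
                            reference_concentration = NA_real_) {
  baseline <- as_trace_list(baseline)
  positive_control <- as_trace_list(positive_control)
  f0 <- mean(unlist(lapply(baseline, function(tr) tr$signal)))
  f100 <- mean(unlist(lapply(positive_control, function(tr) tr$signal)))
  if (!is.finite(f0) || !is.finite(f100) || f100 <= f0)
    stop_data("calibration failure: mean positive control (%.4g) must exceed mean baseline (%.4g)",
              f100, f0)
  structure(list(baseline = baseline, positive_control = positive_control,
                 reference_concentration = reference_concentration,
                 f0_bar = f0, f100_bar = f100),
            class = "calibration_set")
}

as_trace_list <- function(x) {
  if (inherits(x, "fluorescence_trace")) return(list(x))
  if (is.list(x) && length(x) > 0 &&
      all(vapply(x, inherits, logical(1), "fluorescence_trace"))) return(x)
  stop_config("expected a fluorescence_trace or a list of them")
}

#' Normalize a fluorescence trace to a substitution-ratio time course
#'
#' Calibration levels are time-averaged scalars per role (robust to
#' instrument jitter): `r(t) = (F(t) - F_base) / (F_pos - F_base)`. A trace
#' identical to the baseline maps to ~0, to the positive control to ~1.
#' Noise can push values slightly outside \[0, 1\]; they are deliberately not
#' clipped (clipping would bias downstream least-squares fitting).
#'
#' @param reaction A `fluorescence_trace` with role `"reaction"`.
#' @param calib A [calibration_set()].
#' @return A `substitution_course`: data.frame with columns `time_s`, `ratio`.
#' @export
normalize_to_substitution <- function(reaction, calib) {
  if (!inherits(calib, "calibration_set"))
    stop_config("`calib` must be a calibration_set")
  r <- (reaction$signal - calib$f0_bar) / (calib$f100_bar - calib$f0_bar)
  structure(data.frame(time_s = reaction$time_s, ratio = r),
            class = c("substitution_course", "data.frame"),
            replicate_id = attr(reaction, "replicate_id"))
}

#' Pointwise mean and standard deviation across replicate time courses
#'
#' @param courses A list of `substitution_course` objects (or data.frames
#'   with `time_s` and `ratio`) on identical time grids.
#' @return A data.frame with columns `time_s`, `mean`, `sd` and attribute
#'   `n_replicates`. The sample standard deviation uses the n-1 denominator;
#'   with a single trace the SD column is 0 and attribute
#'   `single_replicate = TRUE` is set (with a warning).
#' @export
aggregate_replicates <- function(courses) {
  if (inherits(courses, "data.frame")) courses <- list(courses)
  if (length(courses) < 1L) stop_data("no replicate time courses supplied")
  grid <- courses[[1L]]$time_s
  for (k in seq_along(courses)) {
    if (length(courses[[k]]$time_s) != length(grid) ||
        any(abs(courses[[k]]$time_s - grid) > 1e-9))
      stop_data("replicate %d is on a different time grid", k)
  }
  mat <- vapply(courses, function(cc) cc$ratio, numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  single <- ncol(mat) == 1L
  if (single)
    warning("single replicate: standard deviation reported as 0", call. = FALSE)
  structure(data.frame(time_s = grid,
                       mean = rowMeans(mat),
                       sd = if (single) 0 else apply(mat, 1L, sd)),
            class = c("substitution_summary", "data.frame"),
            n_replicates = ncol(mat), single_replicate = single)
}

#' Read / write fluorescence trace CSVs
#'
#' Traces are stored one file per replicate with header `time_s,signal`. The
#' trace role and replicate number are taken from the file name convention
#' `{role}_{rep}.csv` (e.g. `reaction_2.csv`) unless given explicitly.
#'
#' @param path File path.
#' @param label,replicate_id Override the role/replicate parsed from the name.
#' @return `read_trace_csv`: a `fluorescence_trace`.
#' @export
read_trace_csv <- function(path, label = NULL, replicate_id = NULL) {
  df <- read.csv(path)
  if (!all(c("time_s", "signal") %in% names(df)))
    stop_data("trace CSV %s must have columns time_s,signal", path)
  base <- sub("\\.csv$", "", basename(path))
  m <- regmatches(base, regexec("^(reaction|baseline|positive_control)_([0-9]+)$", base))[[1L]]
  if (is.null(label)) {
    if (length(m) == 0L)
      stop_data("cannot infer trace role from file name %s; expected {role}_{rep}.csv",
                basename(path))
    label <- m[2L]
  }
  if (is.null(replicate_id))
    replicate_id <- if (length(m) > 0L) as.integer(m[3L]) else 1L
  fluorescence_trace(df$time_s, df$signal, label = label,
                     replicate_id = replicate_id)
}

#' @rdname read_trace_csv
#' @param trace A `fluorescence_trace` to write.
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(data.frame(time_s = trace$time_s, signal = trace$signal),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
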