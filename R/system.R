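#' Describe a reversible TMSDR construct
#'
#' A reversible toehold-mediated strand displacement reaction (TMSDR) exchanges
#' an invader strand X1 into a gate duplex X2, releasing the product gate X3
#' and the incumbent strand X4. Both gates carry a toehold (t1 on X2, t2 on
#' X3), so the exchange runs in both directions with lumped bimolecular rate
#' constants `ka` (forward) and `kd` (backward).
#'
#' @param ka Forward rate constant, nM^-1 s^-1. Must be positive.
#' @param kd Backward rate constant, nM^-1 s^-1. `kd = 0` denotes the
#'   irreversible special case.
#' @param toehold_orientation Placement of the invader toehold t1 on the gate
#'   X2: `"five_prime"` or `"three_prime"`.
#' @param modification Reporter placement scheme: `"symmetric"` (fluorophore
#'   and quencher adjacent, maximal FRET) or `"asymmetric"` (separated by the
#'   toehold length).
#' @param reporter_species Species whose concentration drives the unquenched
#'   fluorescence signal, `"X4"` or `"X3"`.
#' @param toehold_length Toehold length in nucleotides (default 6).
#' @param recognition_length Recognition-domain length in nucleotides
#'   (metadata only, default 20).
#'
#' @return An object of class `tmsdr_system`.
#' @examples
#' sys <- tmsdr_system(ka = 1.74e-4, kd = 8.51e-4,
#'                     toehold_orientation = "five_prime",
#'                     modification = "asymmetric")
#' sys
#' @export
tmsdr_system <- function(ka, kd,
                         toehold_orientation = c("five_prime", "three_prime"),
                         modification = c("symmetric", "asymmetric"),
                         reporter_species = c("X4", "X3"),
                         toehold_length = 6L,
                         recognition_length = 20L) {
  toehold_orientation <- match.arg(toehold_orientation)
  modification <- match.arg(modification)
  reporter_species <- match.arg(reporter_species)
  if (!is.numeric(ka) || length(ka) != 1L || !is.finite(ka) || ka <= 0)
    stop_config("`ka` must be a single positive number (nM^-1 s^-1), got %s",
                deparse(substitute(ka)))
  if (!is.numeric(kd) || length(kd) != 1L || !is.finite(kd) || kd < 0)
    stop_config("`kd` must be a single nonnegative number (nM^-1 s^-1)")
  if (toehold_length < 1) stop_config("`toehold_length` must be >= 1 nt")
  structure(
    list(toehold_orientation = toehold_orientation,
         modification = modification,
         reporter_species = reporter_species,
         ka = as.numeric(ka), kd = as.numeric(kd),
         toehold_length = as.integer(toehold_length),
         recognition_length = as.integer(recognition_length)),
    class = "tmsdr_system")
}

#' @export
print.tmsdr_system <- function(x, ...) {
  cat("Reversible TMSDR construct\n")
  cat(sprintf("  toehold: %s (%d nt), recognition %d nt\n",
              sub("_", "-", x$toehold_orientation), x$toehold_length,
              x$recognition_length))
  cat(sprintf("  reporter modification: %s (signal from %s)\n",
              x$modification, x$reporter_species))
  cat(sprintf("  ka = %.3g nM^-1 s^-1, kd = %.3g nM^-1 s^-1\n", x$ka, x$kd))
  invisible(x)
}

#' Concentration state of the reaction mixture
#'
#' @param x1,x2,x3,x4 Concentrations in nM of the invader strand (X1), input
#'   gate (X2), product gate (X3) and released strand (X4). Products default
#'   to zero.
#' @return A named numeric vector `c(x1, x2, x3, x4)`.
#' @examples
#' reaction_state(10, 10)
#' @export
reaction_state <- function(x1, x2, x3 = 0, x4 = 0) {
  s <- c(x1 = as.numeric(x1), x2 = as.numeric(x2),
         x3 = as.numeric(x3), x4 = as.numeric(x4))
  check_state(s)
  s
}

# Accepts named or positional numeric length-4 input.
check_state <- function(state) {
  if (!is.numeric(state) || length(state) != 4L)
    stop_config("a reaction state must be 4 concentrations (x1, x2, x3, x4)")
  if (any(!is.finite(state)))
    stop_config("reaction-state concentrations must be finite")
  if (any(state < 0))
    stop_config("negative concentration in reaction state: %s",
                paste(sprintf("%.3g", state), collapse = ", "))
  if (is.null(names(state))) names(state) <- c("x1", "x2", "x3", "x4")
  state
}

#' Reference rate-constant estimates for the four labelled constructs
#'
#' Fitted forward/backward rate constants for the four FAM/BHQ1 reporter
#' configurations of a 6-nt-toehold reversible strand-exchange system: the
#' toehold on the gate at the 5' or 3' end, each with the fluorophore and
#' quencher placed adjacent (symmetric) or a toehold-length apart
#' (asymmetric). These serve as operating points for the synthetic-data
#' studies and for comparison against the theoretical rate constant of
#' 5.0e-4 nM^-1 s^-1 predicted for a 6-mer toehold.
#'
#' @return A data.frame with columns `toehold`, `modification`, `ka`, `kd`
#'   (rates in nM^-1 s^-1), one row per construct.
#' @examples
#' reference_rate_constants()
#' @export
reference_rate_constants <- function() {
  data.frame(
    toehold = c("five_prime", "five_prime", "three_prime", "three_prime"),
    modification = c("symmetric", "asymmetric", "asymmetric", "symmetric"),
    ka = c(4.78e-5, 1.74e-4, 6.48e-4, 9.68e-5),
    kd = c(4.60e-3, 8.51e-4, 2.98e-5, 1.60e-3),
    stringsAsFactors = FALSE)
}

#' Theoretical rate constants by toehold length
#'
#' Literature-predicted lumped TMSDR rate constants keyed by toehold length.
#' The default table carries the single entry used throughout this package:
#' 5.0e-4 nM^-1 s^-1 for a 6-nt toehold.
#'
#' @param entries Named numeric vector mapping toehold length (nt, as the
#'   name) to a rate constant in nM^-1 s^-1.
#' @return An object of class `theory_table`.
#' @export
theoretical_rate_table <- function(entries = c("6" = 5.0e-4)) {
  if (is.null(names(entries)) || any(!nzchar(names(entries))))
    stop_config("theory table entries must be named by toehold length (nt)")
  if (any(entries <= 0)) stop_config("theoretical rate constants must be positive")
  structure(as.list(entries), class = "theory_table")
}
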