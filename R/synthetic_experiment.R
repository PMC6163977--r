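#' Measurement-noise specification
#'
#' Gaussian, independent per sample.  Three conventions for the standard
#' deviation of the strain reading:
#'
#' * `"stress-equivalent"` (default, `magnitude = 1e4` Pa): a stress-unit
#'   noise level is mapped to strain through the linear compliance of the
#'   generating truth, \eqn{sd_\epsilon = sd_\sigma / \mu} — a displacement
#'   sensor whose error (10 kPa by default) is quoted against the load
#'   scale.  This is the reading under which all three reference parameters,
#'   including the weak elastic nonlinearity, are identifiable.
#' * `"relative"`: \eqn{sd_i = magnitude \cdot |\epsilon_i|} per datum
#'   (e.g. 10% Gaussian noise on each reading), with an absolute floor
#'   `sd_floor` so the zero-strain first sample keeps a positive variance.
#' * `"absolute-strain"`: constant \eqn{sd_i = magnitude} (dimensionless
#'   strain).
#'
#' @param mode One of `"stress-equivalent"`, `"relative"`,
#'   `"absolute-strain"`.
#' @param magnitude Noise magnitude in the mode's units (> 0); default
#'   `1e4` Pa (stress-equivalent).
#' @param sd_floor Minimum per-sample strain sd (used by `"relative"`),
#'   default `1e-3`.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(mode = c("stress-equivalent", "relative",
                                "absolute-strain"),
                       magnitude = 1e4, sd_floor = 1e-3) {
  mode <- match.arg(mode)
  if (!is.numeric(magnitude) || length(magnitude) != 1L || magnitude <= 0)
    stop("noise magnitude must be a positive scalar", call. = FALSE)
  if (sd_floor <= 0) stop("sd_floor must be > 0", call. = FALSE)
  structure(list(mode = mode, magnitude = magnitude, sd_floor = sd_floor),
            class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf("<noise_spec> %s, magnitude %g, floor %g\n",
              x$mode, x$magnitude, x$sd_floor))
  invisible(x)
}

# Per-sample strain sd implied by a noise spec for a noiseless series.
noise_sd <- function(noise, strain, mu_truth = NULL) {
  switch(noise$mode,
    "relative" = pmax(noise$magnitude * abs(strain), noise$sd_floor),
    "absolute-strain" = rep(noise$magnitude, length(strain)),
    "stress-equivalent" = {
      if (is.null(mu_truth))
        stop("stress-equivalent noise needs the truth shear modulus",
             call. = FALSE)
      rep(noise$magnitude / mu_truth, length(strain))
    })
}

#' Generate a synthetic stress-controlled experiment
#'
#' Forward-simulates a known truth under a hypothesis and adds seeded i.i.d.
#' Gaussian measurement noise, recording per-sample variances consistently
#' with the noise model so that inference on the generated data is
#' self-consistent.  The default configuration reproduces the package's
#' reference experiment: truth H1 with mu = 1 MPa, eta = 10 MPa s,
#' A = 15 kPa, triangular stress 0 -> 1 MPa -> 0 over 2 s, samples every
#' 0.1 s (21 data), stress-equivalent Gaussian noise of sd 10 kPa.
#'
#' @param hyp Hypothesis id or [hypothesis()]; default `"H1"`.
#' @param truth Named list of generating parameter values (SI units).
#' @param protocol A [load_protocol()].
#' @param noise A [noise_spec()].
#' @param seed Integer seed; identical seeds give identical data.
#' @param dt_int Forward-integration step (s).
#' @return An `observation_set`: a `data.frame` with columns `time_s`,
#'   `stress_Pa`, `strain`, `strain_sd`, and attributes `noiseless`
#'   (noise-free strains), `provenance` (truth hypothesis, parameters,
#'   protocol, noise, seed).
#' @export
#' @examples
#' obs <- generate_observations(seed = 1)
#' nrow(obs)   # 21
generate_observations <- function(hyp = "H1",
                                  truth = list(mu = 1e6, eta = 1e7, A = 1.5e4),
                                  protocol = load_protocol(),
                                  noise = noise_spec(),
                                  seed = 1L,
                                  dt_int = 1e-3) {
  hyp <- hypothesis(hyp)
  sim <- simulate_strain(hyp, truth, protocol, dt_int)
  mu_truth <- unlist(truth)[["mu"]]
  sd <- noise_sd(noise, sim$strain, mu_truth)
  eps_obs <- with_seed(seed, sim$strain + stats::rnorm(length(sd), sd = sd))
  out <- data.frame(time_s = sim$time_s, stress_Pa = sim$stress_Pa,
                    strain = eps_obs, strain_sd = sd)
  attr(out, "noiseless") <- sim$strain
  attr(out, "provenance") <- list(hypothesis = hyp$id, truth = truth,
                                  protocol = unclass(protocol),
                                  noise = unclass(noise), seed = seed)
  class(out) <- c("observation_set", "data.frame")
  out
}

#' Wrap an external stress-strain series as an observation set
#'
#' @param time_s,stress_Pa,strain Equal-length numeric vectors.
#' @param strain_sd Per-sample strain standard deviations (> 0); scalar
#'   values are recycled.
#' @return An `observation_set` with provenance `"external"`.
#' @export
observation_set <- function(time_s, stress_Pa, strain, strain_sd) {
  n <- length(time_s)
  if (length(stress_Pa) != n || length(strain) != n)
    stop("time, stress and strain must have equal lengths", call. = FALSE)
  if (length(strain_sd) == 1L) strain_sd <- rep(strain_sd, n)
  if (length(strain_sd) != n || any(strain_sd <= 0))
    stop("strain_sd must be positive, length 1 or matching the series",
         call. = FALSE)
  if (is.unsorted(time_s, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  out <- data.frame(time_s = time_s, stress_Pa = stress_Pa,
                    strain = strain, strain_sd = strain_sd)
  attr(out, "provenance") <- list(hypothesis = "external")
  class(out) <- c("observation_set", "data.frame")
  out
}

#' @export
print.observation_set <- function(x, ...) {
  pr <- attr(x, "provenance")
  cat(sprintf("<observation_set> %d samples over [0, %g] s (source: %s)\n",
              nrow(x), max(x$time_s),
              if (is.null(pr)) "unknown" else pr$hypothesis))
  NextMethod()
}

#' Write an observation set to delimited text
#'
#' Comma-separated with header `time_s, stress_Pa, strain, strain_var`;
#' numbers at 17 significant digits so a write/read round trip is lossless.
#'
#' @param obs An `observation_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  stopifnot(inherits(obs, "observation_set"))
  df <- data.frame(time_s = format(obs$time_s, digits = 17, trim = TRUE),
                   stress_Pa = format(obs$stress_Pa, digits = 17, trim = TRUE),
                   strain = format(obs$strain, digits = 17, trim = TRUE),
                   strain_var = format(obs$strain_sd^2, digits = 17, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an observation set from delimited text
#'
#' Expects a header with at least `time_s`, `stress_Pa`, `strain`; a
#' `strain_var` column is optional (if absent, supply `strain_sd`).
#' Comma-, semicolon- or tab-delimited files are accepted.
#'
#' @param path Input file path.
#' @param strain_sd Fallback per-sample strain sd when the file has no
#'   variance column.
#' @return An `observation_set`.
#' @export
read_observations <- function(path, strain_sd = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(";", header)) ";" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          strip.white = TRUE, stringsAsFactors = FALSE)
  need <- c("time_s", "stress_Pa", "strain")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("'%s': missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  for (cn in intersect(c(need, "strain_var"), names(df))) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cn]]))))
    if (length(bad))
      stop(sprintf("'%s': non-numeric value in column '%s' at line %d",
                   path, cn, bad[1] + 1L), call. = FALSE)
    df[[cn]] <- as.numeric(df[[cn]])
  }
  nm <- which(diff(df$time_s) <= 0)
  if (length(nm))
    stop(sprintf("'%s': times not strictly increasing at line %d",
                 path, nm[1] + 2L), call. = FALSE)
  sd <- if ("strain_var" %in% names(df)) {
    if (any(df$strain_var <= 0))
      stop(sprintf("'%s': nonpositive strain_var", path), call. = FALSE)
    sqrt(df$strain_var)
  } else if (!is.null(strain_sd)) {
    strain_sd
  } else {
    stop(sprintf("'%s' has no strain_var column; supply strain_sd", path),
         call. = FALSE)
  }
  observation_set(df$time_s, df$stress_Pa, df$strain, sd)
}

# Reconstruct the load protocol implied by an observation set (peak stress,
# ramp time, sampling interval), validating that the recorded stresses match
# a triangular history.
infer_protocol <- function(obs) {
  pr <- attr(obs, "provenance")
  if (!is.null(pr$protocol))
    return(load_protocol(pr$protocol$sigma_max, pr$protocol$half_duration,
                         pr$protocol$dt_sample))
  k <- which.max(obs$stress_Pa)
  p <- load_protocol(sigma_max = max(obs$stress_Pa),
                     half_duration = obs$time_s[k],
                     dt_sample = obs$time_s[2] - obs$time_s[1])
  if (max(abs(stress_at(obs$time_s, p) - obs$stress_Pa)) >
      1e-6 * p$sigma_max)
    stop("observed stresses are not a triangular constant-rate history",
         call. = FALSE)
  p
}
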