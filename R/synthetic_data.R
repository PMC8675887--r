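#' Kinetic specification for a synthetic OJIP transient
#'
#' The generator models the polyphasic fluorescence rise as a sum of three
#' saturating exponentials with strictly ordered rate constants, the
#' simplest strictly increasing family that places J- and I-like
#' inflections at controllable times and gives every JIP quantity a closed
#' form: `F(t) = F0 + (FM - F0) * sum_i w_i (1 - exp(-k_i t))`. The default
#' rates (1500, 80, 4) s^-1 put the three phases near 2 ms, 30 ms and the
#' final approach to FM within a 1 s acquisition.
#'
#' @param F0_true True minimal fluorescence (a.u., > 0).
#' @param FM_true True maximal fluorescence (a.u., > `F0_true`).
#' @param weights Three non-negative phase amplitudes summing to 1.
#' @param rates Three rate constants in s^-1, strictly decreasing, all
#'   positive.
#' @return A list of class `kinetic_spec`.
#' @export
kinetic_spec <- function(F0_true = 5000, FM_true = 25000,
                         weights = c(0.45, 0.30, 0.25),
                         rates = c(1500, 80, 4)) {
  stopifnot(F0_true > 0, FM_true > F0_true,
            length(weights) == 3L, length(rates) == 3L)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-12)
    stop("weights must be non-negative and sum to 1 (within 1e-12)")
  if (any(rates <= 0) || any(diff(rates) >= 0))
    stop("rates must be positive and strictly decreasing")
  structure(list(F0_true = F0_true, FM_true = FM_true,
                 weights = as.numeric(weights), rates = as.numeric(rates)),
            class = "kinetic_spec")
}

#' Evaluate the noise-free generator curve
#'
#' @param spec A [kinetic_spec()].
#' @param t Time(s) in seconds, positive.
#' @return Fluorescence value(s) in a.u.; strictly increasing in `t` and
#'   approaching `FM_true` as `t` grows.
#' @export
transient_value <- function(spec, t) {
  stopifnot(inherits(spec, "kinetic_spec"), all(t > 0))
  rise <- vapply(t, function(tt)
    sum(spec$weights * (1 - exp(-spec$rates * tt))), numeric(1))
  spec$F0_true + (spec$FM_true - spec$F0_true) * rise
}

#' Log-spaced sampling grid
#'
#' Emulates continuous-excitation fluorometer acquisition: log-spaced
#' times from 10 us to 1 s, 160 points by default. The grid must start
#' before the 50 us origin convention.
#'
#' @param t_min First acquisition time (s), below 50 us.
#' @param t_max Last acquisition time (s), at least 50 us.
#' @param points Number of samples, at least 50.
#' @return A list of class `sampling_grid` with a `times` vector.
#' @export
sampling_grid <- function(t_min = 1e-5, t_max = 1, points = 160L) {
  stopifnot(t_min > 0, t_min < 5e-5, t_max >= 5e-5, points >= 50L)
  times <- 10^seq(log10(t_min), log10(t_max), length.out = as.integer(points))
  structure(list(t_min = t_min, t_max = t_max, points = as.integer(points),
                 times = times),
            class = "sampling_grid")
}

#' Closed-form JIP parameters of a kinetic specification
#'
#' The ground-truth oracle for the generator: cardinal values are the
#' exact curve values at the convention times (F0 at 50 us, F300 at
#' 300 us, FJ at 2 ms), `FM = FM_true`, and the complementary area is the
#' analytic integral `(FM_true - F0_true) * sum_i w_i / k_i *
#' (exp(-k_i t_start) - exp(-k_i t_end))` over the acquisition window.
#' All derived quantities then use the same formulas as
#' [compute_jip_parameters()], so the recovery error of the pipeline on
#' noise-free data isolates sampling/interpolation effects only. Note that
#' `FM_true` is fully observable from the window only when
#' `t_end >= 10 / k3`.
#'
#' @param spec A [kinetic_spec()].
#' @param conventions A [jip_conventions()].
#' @param sampling A [sampling_grid()] defining the integration window.
#' @param sample_id Optional id stored in the output row.
#' @return A one-row `jip_parameters` data frame.
#' @export
true_jip_parameters <- function(spec, conventions = jip_conventions(),
                                sampling = sampling_grid(),
                                sample_id = NA_character_) {
  F0 <- transient_value(spec, conventions$t0)
  F300 <- transient_value(spec, conventions$t300)
  FJ <- transient_value(spec, conventions$tJ)
  FM <- spec$FM_true
  VJ <- (FJ - F0) / (FM - F0)
  M0 <- 4 * (F300 - F0) / (FM - F0)
  area <- (spec$FM_true - spec$F0_true) *
    sum(spec$weights / spec$rates *
          (exp(-spec$rates * sampling$t_min) - exp(-spec$rates * sampling$t_max)))
  compute_jip_parameters(
    list(sample_id = sample_id, F0 = F0, FM = FM, VJ = VJ, M0 = M0),
    area = area)
}

#' Simulate one noisy OJIP transient
#'
#' Evaluates the generator curve on the sampling grid and applies
#' independent multiplicative Gaussian noise, `F_obs = F(t) (1 + eps)`,
#' `eps ~ N(0, noise_sd)`, clipped to stay positive — multiplicative noise
#' matches detector behavior at high signal. Fully reproducible from the
#' seed, which is applied locally (the global RNG state is untouched).
#'
#' @param spec A [kinetic_spec()].
#' @param sampling A [sampling_grid()].
#' @param noise_sd Relative noise standard deviation, non-negative.
#' @param seed Integer seed.
#' @param sample_id Sample label.
#' @return A [fluorescence_transient()].
#' @export
simulate_transient <- function(spec, sampling = sampling_grid(),
                               noise_sd = 0.02, seed = 1L,
                               sample_id = "sim") {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  f_true <- transient_value(spec, sampling$times)
  eps <- if (noise_sd == 0) rep(0, length(f_true)) else
    withr::with_seed(as.integer(seed), stats::rnorm(length(f_true), 0, noise_sd))
  f_obs <- pmax(f_true * (1 + eps), .Machine$double.eps)
  fluorescence_transient(sample_id, sampling$times, f_obs)
}

.default_cell_kinetics <- function(population, season, period) {
  # Cell effects: population shifts F0 (antenna absorption per
  # cross-section), season shifts FM (and hence phi_po), period shifts the
  # fast-phase weight (and hence VJ / psi_o).
  F0 <- if (population == "Norway") 5000 else 5800
  FM <- if (season == "summer") 5.0 * F0 else 3.85 * F0
  w <- if (period == "day") c(0.45, 0.30, 0.25) else c(0.55, 0.27, 0.18)
  kinetic_spec(F0_true = F0, FM_true = FM, weights = w, rates = c(1500, 80, 4))
}

#' Factorial experiment design for the simulator
#'
#' @param cells List of cells, each a list with `population`, `season`,
#'   `period`, `n` (replicates) and `kinetics` (a [kinetic_spec()]).
#' @param noise_sd Relative measurement noise SD (default 0.02).
#' @param sampling A [sampling_grid()].
#' @param seed Integer master seed for the experiment.
#' @param jitter_sd Between-sample relative SD applied to `F0_true` and
#'   `FM_true` (biological replicate variation; default 0.03).
#' @param weight_jitter_sd Between-sample SD added to the phase weights
#'   before renormalization (default 0.02).
#' @return A list of class `design_spec`.
#' @export
design_spec <- function(cells, noise_sd = 0.02, sampling = sampling_grid(),
                        seed = 1L, jitter_sd = 0.03, weight_jitter_sd = 0.02) {
  if (length(cells) == 0L) stop("design has no cells")
  for (cell in cells)
    stopifnot(is.list(cell), !is.null(cell$population), !is.null(cell$season),
              !is.null(cell$period), cell$n >= 1L,
              inherits(cell$kinetics, "kinetic_spec"))
  stopifnot(noise_sd >= 0, jitter_sd >= 0, weight_jitter_sd >= 0)
  structure(list(cells = cells, noise_sd = noise_sd, sampling = sampling,
                 seed = as.integer(seed), jitter_sd = jitter_sd,
                 weight_jitter_sd = weight_jitter_sd),
            class = "design_spec")
}

#' Default factorial design: 2 populations x 2 seasons x day/night x 10
#'
#' Eight cells (Norway/France x summer/winter x day/night) of 10
#' replicates each, 80 samples in total. Cell kinetics differ along three
#' axes — F0 by population, FM (hence the maximum quantum yield) by
#' season, fast-phase weight (hence VJ) by day/night — with between-sample
#' kinetic jitter and 2% multiplicative measurement noise, so that the
#' cell centroids are separated by several within-cell standard deviations
#' in JIP parameter space.
#'
#' @param seed Integer master seed.
#' @param n_rep Replicates per cell (default 10).
#' @param noise_sd Measurement noise SD (default 0.02).
#' @return A [design_spec()].
#' @export
default_design <- function(seed = 1L, n_rep = 10L, noise_sd = 0.02) {
  cells <- list()
  for (pop in c("Norway", "France"))
    for (season in c("summer", "winter"))
      for (period in c("day", "night"))
        cells[[length(cells) + 1L]] <- list(
          population = pop, season = season, period = period, n = n_rep,
          kinetics = .default_cell_kinetics(pop, season, period))
  design_spec(cells, noise_sd = noise_sd, seed = seed)
}

# Per-sample jitter of a cell's kinetic spec; draws consumed from the
# caller's RNG context.
.jitter_spec <- function(spec, jitter_sd, weight_jitter_sd) {
  F0 <- spec$F0_true * (1 + stats::rnorm(1, 0, jitter_sd))
  FM <- spec$FM_true * (1 + stats::rnorm(1, 0, jitter_sd))
  F0 <- max(F0, 0.1 * spec$F0_true)
  FM <- max(FM, F0 * 1.2)
  w <- spec$weights + stats::rnorm(3, 0, weight_jitter_sd)
  w <- pmax(w, 0.02)
  w <- w / sum(w)
  kinetic_spec(F0, FM, w, spec$rates)
}

#' Simulate a full factorial OJIP experiment
#'
#' One noisy transient per replicate per cell, with per-sample jittered
#' kinetics; alongside the transients it returns the metadata table and a
#' per-sample ground-truth parameter table (from the jittered kinetics)
#' for recovery scoring. A single master seed drives all randomness, so
#' identical designs give identical output.
#'
#' @param design A [design_spec()].
#' @return List with `transients` (named list), `metadata` (data frame)
#'   and `truth` (data frame of true JIP parameters per sample).
#' @export
simulate_experiment <- function(design) {
  stopifnot(inherits(design, "design_spec"))
  transients <- list(); meta <- list(); truth <- list()
  withr::with_seed(design$seed, {
    for (cell in design$cells) {
      for (r in seq_len(cell$n)) {
        id <- sprintf("%s_%s_%s_r%02d", cell$population, cell$season,
                      cell$period, r)
        sp <- .jitter_spec(cell$kinetics, design$jitter_sd,
                           design$weight_jitter_sd)
        s <- sample.int(2^30, 1L)
        transients[[id]] <- simulate_transient(sp, design$sampling,
                                               design$noise_sd, seed = s,
                                               sample_id = id)
        meta[[id]] <- data.frame(sample_id = id, population = cell$population,
                                 season = cell$season, period = cell$period,
                                 replicate = r, stringsAsFactors = FALSE)
        truth[[id]] <- true_jip_parameters(sp, sampling = design$sampling,
                                           sample_id = id)
      }
    }
  })
  metadata <- do.call(rbind, meta); rownames(metadata) <- NULL
  truth_tab <- do.call(rbind, truth); rownames(truth_tab) <- NULL
  list(transients = transients, metadata = metadata, truth = truth_tab)
}
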