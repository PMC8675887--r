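#' Extraction conventions for JIP-test cardinal points
#'
#' The JIP test anchors its parameters at fixed times on the induction
#' curve: the origin F0 at 50 us (the conventional earliest reliable
#' reading), F300 at 300 us (for the initial slope M0) and FJ at the J-step,
#' 2 ms. Landmark values are obtained by interpolating fluorescence against
#' log10(time), which suits log-spaced acquisition; plain linear-time
#' interpolation is available as an option.
#'
#' @param t0 Origin time in seconds (default 50 us).
#' @param t300 Slope time in seconds (default 300 us).
#' @param tJ J-step time in seconds (default 2 ms).
#' @param interpolation `"log-time"` (default) or `"linear"`.
#' @param degenerate `"flag"` (default): degenerate transients become
#'   flagged rejects in batch analysis; `"error"`: they abort it.
#' @return A list of class `jip_conventions`.
#' @export
jip_conventions <- function(t0 = 5e-5, t300 = 3e-4, tJ = 2e-3,
                            interpolation = c("log-time", "linear"),
                            degenerate = c("flag", "error")) {
  interpolation <- match.arg(interpolation)
  degenerate <- match.arg(degenerate)
  stopifnot(t0 > 0, t0 < t300, t300 < tJ)
  structure(list(t0 = t0, t300 = t300, tJ = tJ,
                 interpolation = interpolation, degenerate = degenerate),
            class = "jip_conventions")
}

.interp_fluorescence <- function(transient, t, interpolation) {
  x <- if (interpolation == "log-time") log10(transient$times) else transient$times
  xout <- if (interpolation == "log-time") log10(t) else t
  stats::approx(x, transient$fluorescence, xout = xout, ties = "ordered")$y
}

#' Extract cardinal points from one OJIP transient
#'
#' Reads off the landmark fluorescence values of the JIP test: F0 at the
#' origin time, F300 at the slope time, FJ at the J-step, and FM as the
#' maximum observed fluorescence (no smoothing). From these it derives the
#' relative variable fluorescence at J, `VJ = (FJ - F0)/(FM - F0)`, and the
#' initial slope of the relative rise, `M0 = 4 (F300 - F0)/(FM - F0)`
#' (per ms; the factor 4 converts the 0.25 ms rise F0 -> F300 to a per-ms
#' rate). A transient whose maximum does not exceed F0, or whose maximum
#' sits at the first timepoint, is flagged degenerate rather than raising
#' an error; its ratio fields are `NA`.
#'
#' @param transient A [fluorescence_transient()].
#' @param conventions A [jip_conventions()] object.
#' @return A list of class `cardinal_points` with fields `F0`, `F300`,
#'   `FJ`, `FM`, `t_FM`, `VJ`, `M0`, `degenerate`, `sample_id`.
#' @export
extract_cardinal_points <- function(transient, conventions = jip_conventions()) {
  stopifnot(inherits(transient, "fluor_transient"))
  tmin <- transient$times[1L]
  tmax <- transient$times[length(transient$times)]
  for (nm in c("t0", "t300", "tJ")) {
    t_nominal <- conventions[[nm]]
    if (t_nominal < tmin || t_nominal > tmax)
      stop(sprintf("sample '%s': transient does not span the %s landmark at %g s",
                   transient$sample_id, nm, t_nominal))
  }
  vals <- .interp_fluorescence(transient,
                               c(conventions$t0, conventions$t300, conventions$tJ),
                               conventions$interpolation)
  F0 <- vals[1L]; F300 <- vals[2L]; FJ <- vals[3L]
  imax <- which.max(transient$fluorescence)
  FM <- transient$fluorescence[imax]
  t_FM <- transient$times[imax]
  degenerate <- FM <= F0 || imax == 1L
  if (degenerate) {
    VJ <- NA_real_; M0 <- NA_real_
  } else {
    VJ <- relative_variable_fluorescence(FJ, F0, FM)
    M0 <- 4 * (F300 - F0) / (FM - F0)
  }
  structure(list(sample_id = transient$sample_id, F0 = F0, F300 = F300,
                 FJ = FJ, FM = FM, t_FM = t_FM, VJ = VJ, M0 = M0,
                 degenerate = degenerate),
            class = "cardinal_points")
}

#' Relative variable fluorescence
#'
#' `V = (F - F0)/(FM - F0)`, the fraction of the variable fluorescence
#' span reached at fluorescence level `F`. Values of `F` outside
#' `[F0, FM]` are clamped with a warning (interpolation jitter on noisy
#' curves); `FM <= F0` is a degenerate transient and an error.
#'
#' @param f Fluorescence value(s) (a.u.).
#' @param f0 Minimal fluorescence F0 (a.u.).
#' @param fm Maximal fluorescence FM (a.u.), must exceed `f0`.
#' @return Value(s) in `[0, 1]`.
#' @export
relative_variable_fluorescence <- function(f, f0, fm) {
  if (!is.finite(f0) || !is.finite(fm) || fm <= f0)
    stop("degenerate transient: FM must exceed F0")
  if (any(f < f0) || any(f > fm)) {
    warning("fluorescence outside [F0, FM] clamped")
    f <- pmin(pmax(f, f0), fm)
  }
  (f - f0) / (fm - f0)
}

#' Complementary area above the induction curve
#'
#' Trapezoidal integral of `FM - F(t)` from the first acquired timepoint up
#' to the time of FM; a proxy for the size of the oxidized quinone pool
#' (the larger the pool, the longer the curve stays below FM).
#'
#' @param transient A [fluorescence_transient()].
#' @param fm Maximal fluorescence (a.u.).
#' @param t_fm Time of FM in seconds; must lie within the acquisition window.
#' @return Non-negative area in a.u. * s.
#' @export
compute_area <- function(transient, fm, t_fm) {
  stopifnot(inherits(transient, "fluor_transient"))
  if (t_fm < transient$times[1L] || t_fm > transient$times[length(transient$times)])
    stop(sprintf("sample '%s': t_FM = %g s outside the acquisition window",
                 transient$sample_id, t_fm))
  keep <- transient$times <= t_fm
  tt <- transient$times[keep]
  ff <- transient$fluorescence[keep]
  if (length(tt) < 2L) return(0)
  max(0, pracma::trapz(tt, fm - ff))
}

#' Compute the JIP-test parameter vector from cardinal points
#'
#' Implements the standard JIP-test parameter set on an absorption /
#' cross-section basis:
#' \itemize{
#'   \item `phi_po = 1 - F0/FM`, maximum quantum yield of primary
#'     photochemistry (TR0/ABS);
#'   \item `psi_o = 1 - VJ`, probability that a trapped electron moves
#'     beyond the primary quinone acceptor QA (ET0/TR0);
#'   \item energy fluxes per excited cross-section: `abs_cs = F0`,
#'     `tr0_cs = phi_po * abs_cs`, `et0_cs = phi_po * psi_o * abs_cs`,
#'     `di0_cs = abs_cs - tr0_cs`;
#'   \item `rc0_cs = phi_po * (VJ/M0) * abs_cs`, density of oxidized
#'     reaction centers per cross-section, and `gamma_rc_odds = rc0_cs /
#'     abs_cs` (= RC/ABS, the odds form of the antenna/RC partition);
#'   \item the performance index `pi_abs = gamma_rc_odds * tr0_di0 *
#'     psi_odds` with `tr0_di0 = phi_po/(1 - phi_po)` (light reactions) and
#'     `psi_odds = psi_o/(1 - psi_o)` (dark reactions).
#' }
#' Limits: `FM == F0` gives the fully quenched curve (`phi_po = 0`, all
#' photochemical fluxes 0, `pi_abs = 0`); `F0 = 0` (`phi_po = 1`) or
#' `VJ = 0` (`psi_o = 1`) leave the affected odds and `pi_abs` as `NA`,
#' with all remaining fields computed.
#'
#' @param cp A `cardinal_points` object (or a list with `F0`, `FM`, `VJ`,
#'   `M0`).
#' @param area Complementary area from [compute_area()] (a.u. * s).
#' @return A one-row data frame of class `jip_parameters` with the 14
#'   parameter fields plus `sample_id`.
#' @export
compute_jip_parameters <- function(cp, area) {
  F0 <- cp$F0; FM <- cp$FM
  stopifnot(is.finite(F0), is.finite(FM), F0 >= 0, FM >= F0)
  quenched <- FM <= F0
  phi_po <- if (FM > 0) 1 - F0 / FM else 0
  vj <- if (quenched) NA_real_ else cp$VJ
  m0 <- if (quenched) NA_real_ else cp$M0
  psi_o <- 1 - vj
  abs_cs <- F0
  tr0_cs <- phi_po * abs_cs
  di0_cs <- abs_cs - tr0_cs
  et0_cs <- if (phi_po == 0) 0 else phi_po * psi_o * abs_cs
  rc0_cs <- if (phi_po == 0) 0 else phi_po * (vj / m0) * abs_cs
  gamma_rc_odds <- if (abs_cs > 0) rc0_cs / abs_cs else NA_real_
  tr0_di0 <- if (phi_po < 1) phi_po / (1 - phi_po) else NA_real_
  psi_odds <- if (quenched) NA_real_ else if (psi_o < 1) psi_o / (1 - psi_o) else NA_real_
  pi_abs <- if (phi_po == 0) 0 else gamma_rc_odds * tr0_di0 * psi_odds
  out <- data.frame(
    sample_id = if (!is.null(cp$sample_id)) cp$sample_id else NA_character_,
    phi_po = phi_po, psi_o = psi_o, vj = vj, m0 = m0, area = area,
    abs_cs = abs_cs, tr0_cs = tr0_cs, et0_cs = et0_cs, di0_cs = di0_cs,
    rc0_cs = rc0_cs, gamma_rc_odds = gamma_rc_odds, tr0_di0 = tr0_di0,
    psi_odds = psi_odds, pi_abs = pi_abs,
    stringsAsFactors = FALSE)
  class(out) <- c("jip_parameters", "data.frame")
  out
}

#' Names of the numeric JIP parameter columns
#' @return Character vector of the 14 parameter field names.
#' @export
jip_parameter_names <- function() {
  c("phi_po", "psi_o", "vj", "m0", "area", "abs_cs", "tr0_cs", "et0_cs",
    "di0_cs", "rc0_cs", "gamma_rc_odds", "tr0_di0", "psi_odds", "pi_abs")
}

#' Batch JIP analysis of a transient collection
#'
#' Runs cardinal-point extraction, area integration and parameter
#' computation for every transient. Degenerate transients (flat or
#' non-rising curves) and extraction failures are collected in a rejects
#' table instead of silently dropping samples; with
#' `conventions$degenerate == "error"` they abort the batch.
#'
#' @param transients Non-empty list of [fluorescence_transient()] objects.
#' @param conventions A [jip_conventions()] object.
#' @return A list with `parameters` (data frame, one row per analyzed
#'   sample, sorted by `sample_id`) and `rejects` (data frame with
#'   `sample_id`, `reason`).
#' @export
analyze_transients <- function(transients, conventions = jip_conventions()) {
  if (length(transients) == 0L) stop("no transients to analyze")
  rows <- list()
  rejects <- list()
  for (tr in transients) {
    res <- tryCatch({
      cp <- extract_cardinal_points(tr, conventions)
      if (cp$degenerate) {
        list(reject = "degenerate")
      } else {
        area <- compute_area(tr, cp$FM, cp$t_FM)
        list(row = compute_jip_parameters(cp, area))
      }
    }, error = function(e) list(reject = conditionMessage(e)))
    if (!is.null(res$reject)) {
      if (conventions$degenerate == "error")
        stop(sprintf("sample '%s': %s", tr$sample_id, res$reject))
      rejects[[length(rejects) + 1L]] <-
        data.frame(sample_id = tr$sample_id, reason = res$reject,
                   stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- res$row
    }
  }
  params <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(data.frame(matrix(nrow = 0, ncol = 15)),
                    c("sample_id", jip_parameter_names()))
  params <- params[order(params$sample_id), , drop = FALSE]
  rownames(params) <- NULL
  rej <- if (length(rejects)) do.call(rbind, rejects) else
    data.frame(sample_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  list(parameters = params, rejects = rej)
}
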