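#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided rank-sum comparison of two independent samples, reported as
#' the Mann-Whitney U statistic for the first sample. The exact null
#' distribution is used when the pooled size is at most `exact_max_n` and
#' there are no ties; otherwise the normal approximation with tie
#' correction and continuity correction. Two samples whose pooled values
#' are all identical give `p = 1` (no evidence of a shift, not an error).
#'
#' @param x,y Numeric vectors of finite values, both non-empty.
#' @param exact_max_n Largest pooled sample size for which the exact
#'   distribution is used (default 12).
#' @return List with `statistic` (U) and `p.value`.
#' @export
rank_sum_test <- function(x, y, exact_max_n = 12L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("samples must be finite")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L)
    return(list(statistic = length(x) * length(y) / 2, p.value = 1))
  ties <- anyDuplicated(pooled) > 0L
  use_exact <- !ties && (length(x) + length(y)) <= exact_max_n
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = min(1, ht$p.value))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: sort ascending, multiply
#' `p_(i)` by `m/i`, enforce monotonicity from the largest down, cap at 1,
#' and return in the input order.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (anyNA(pvals) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Significance codes from adjusted p-values
#'
#' `"****"` below 1e-4, `"***"` below 1e-3, `"**"` below 0.01, `"*"` below
#' 0.05, otherwise `"ns"`.
#'
#' @param p_adj Numeric vector of adjusted p-values.
#' @return Character vector of codes.
#' @export
significance_stars <- function(p_adj) {
  vapply(p_adj, function(p) {
    if (is.na(p)) NA_character_
    else if (p < 1e-4) "****"
    else if (p < 1e-3) "***"
    else if (p < 0.01) "**"
    else if (p < 0.05) "*"
    else "ns"
  }, character(1))
}

.group_key <- function(population, season, period) {
  paste(population, season, period, sep = ":")
}

#' Default contrast set for a factorial photophysiology design
#'
#' Builds the bracket comparisons of a 2-population x 2-season x day/night
#' experiment: day vs night within each population x season, summer vs
#' winter within each population x period, and every population pair at
#' matched season x period.
#'
#' @param metadata Metadata data frame (see [read_metadata()]).
#' @return Data frame with columns `a_population`, `a_season`, `a_period`,
#'   `b_population`, `b_season`, `b_period`.
#' @export
default_contrasts <- function(metadata) {
  pops <- sort(unique(metadata$population))
  seasons <- sort(unique(metadata$season))
  periods <- sort(unique(metadata$period))
  rows <- list()
  add <- function(a, b) rows[[length(rows) + 1L]] <<-
    data.frame(a_population = a[1], a_season = a[2], a_period = a[3],
               b_population = b[1], b_season = b[2], b_period = b[3],
               stringsAsFactors = FALSE)
  for (p in pops) for (s in seasons)
    if (length(periods) == 2L) add(c(p, s, periods[1]), c(p, s, periods[2]))
  for (p in pops) for (d in periods)
    if (length(seasons) == 2L) add(c(p, seasons[1], d), c(p, seasons[2], d))
  for (s in seasons) for (d in periods)
    if (length(pops) >= 2L)
      for (i in seq_len(length(pops) - 1L)) for (j in seq(i + 1L, length(pops)))
        add(c(pops[i], s, d), c(pops[j], s, d))
  do.call(rbind, rows)
}

#' Pairwise rank-sum tests of JIP parameters across groups
#'
#' For every parameter and every contrast, compares the two sample groups
#' (defined by population x season x period cells) with [rank_sum_test()],
#' then applies Benjamini-Hochberg adjustment. The adjustment family is by
#' default each parameter's own set of contrasts (matching per-panel star
#' displays); `family = "global"` pools all parameters into one family.
#' Contrasts with fewer than 2 samples on either side are reported in a
#' skipped table, not silently dropped.
#'
#' @param params Data frame with `sample_id` plus numeric parameter columns.
#' @param metadata Metadata data frame with `sample_id`, `population`,
#'   `season`, `period`.
#' @param contrasts Contrast data frame as from [default_contrasts()], or
#'   `NULL` for the default set.
#' @param parameters Character vector of parameter columns to test
#'   (default: all of [jip_parameter_names()] present in `params`).
#' @param family `"per_parameter"` (default) or `"global"` adjustment scope.
#' @param exact_max_n Passed to [rank_sum_test()].
#' @return List with `results` (parameter, group_a, group_b, n_a, n_b,
#'   statistic, p_raw, p_adj, stars) and `skipped` (contrast + reason).
#' @export
pairwise_parameter_tests <- function(params, metadata, contrasts = NULL,
                                     parameters = NULL,
                                     family = c("per_parameter", "global"),
                                     exact_max_n = 12L) {
  family <- match.arg(family)
  if (is.null(contrasts)) contrasts <- default_contrasts(metadata)
  if (is.null(parameters))
    parameters <- intersect(jip_parameter_names(), names(params))
  if (length(parameters) == 0L) stop("no parameter columns to test")
  dat <- merge(params, metadata, by = "sample_id")
  dat$.group <- .group_key(dat$population, dat$season, dat$period)
  rows <- list(); skipped <- list()
  for (k in seq_len(nrow(contrasts))) {
    key_a <- .group_key(contrasts$a_population[k], contrasts$a_season[k],
                        contrasts$a_period[k])
    key_b <- .group_key(contrasts$b_population[k], contrasts$b_season[k],
                        contrasts$b_period[k])
    ia <- dat$.group == key_a
    ib <- dat$.group == key_b
    if (key_a == key_b) stop("contrast compares a group with itself: ", key_a)
    for (par in parameters) {
      xa <- dat[[par]][ia]; xb <- dat[[par]][ib]
      xa <- xa[is.finite(xa)]; xb <- xb[is.finite(xb)]
      if (length(xa) < 2L || length(xb) < 2L) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          parameter = par, group_a = key_a, group_b = key_b,
          reason = "fewer than 2 samples on one side", stringsAsFactors = FALSE)
        next
      }
      ht <- rank_sum_test(xa, xb, exact_max_n = exact_max_n)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = par, group_a = key_a, group_b = key_b,
        n_a = length(xa), n_b = length(xb),
        statistic = ht$statistic, p_raw = ht$p.value,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(parameter = character(), group_a = character(),
               group_b = character(), n_a = integer(), n_b = integer(),
               statistic = numeric(), p_raw = numeric(),
               stringsAsFactors = FALSE)
  if (nrow(res)) {
    res$p_adj <- NA_real_
    if (family == "global") {
      res$p_adj <- bh_adjust(res$p_raw)
    } else {
      for (par in unique(res$parameter)) {
        i <- res$parameter == par
        res$p_adj[i] <- bh_adjust(res$p_raw[i])
      }
    }
    res$stars <- significance_stars(res$p_adj)
  } else {
    res$p_adj <- numeric(); res$stars <- character()
  }
  rownames(res) <- NULL
  skip <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(parameter = character(), group_a = character(),
               group_b = character(), reason = character(),
               stringsAsFactors = FALSE)
  list(results = res, skipped = skip)
}
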