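# Per-diameter-class branching statistics driving the stochastic
# tree generator: symmetry distributions, an area-growth model and
# length-to-diameter ratio distributions, with an extrapolation rule
# below the smallest observed class.

#' Specify per-class branching statistics
#'
#' Bundles, per diameter class, a daughter-symmetry sampler, an
#' area-growth model A(d_M, S), and a length-to-diameter-ratio
#' sampler, plus the extrapolation rule used for diameters below the
#' lowest class edge.
#'
#' Samplers are lists with a `type` field:
#' \itemize{
#'   \item `list(type = "beta", shape1, shape2)` — Beta on (0,1)
#'     (symmetry only);
#'   \item `list(type = "lognormal", meanlog, sdlog)` — positive
#'     (length ratio only);
#'   \item `list(type = "fixed", value)` — degenerate;
#'   \item `list(type = "empirical", values)` — resampling.
#' }
#' The area-growth model is `list(type = "fixed", value)`,
#' `list(type = "scaling", gamma)` (the area growth implied by the
#' diameter scaling law d_M^gamma = d_L^gamma + d_S^gamma at the
#' drawn symmetry), or
#' `list(type = "linear", intercept, slope_d_mm, slope_S, sd = 0,
#' d_mm_cap, min, max)` giving
#' A = intercept + slope_d_mm * min(d_M in mm, d_mm_cap) + slope_S * S,
#' clamped to [min, max], with optional Gaussian noise `sd` (the
#' deterministic `sd = 0` is the default mode).
#'
#' @param classes data frame from [diameter_classes()].
#' @param symmetry list of samplers, one per class (smallest first).
#' @param area_growth a single area-growth model applied at any
#'   diameter, or a list of per-class models.
#' @param length_ratio list of samplers, one per class.
#' @param extrapolation_slope increase of the symmetry median per
#'   decade of log10-diameter below the lowest class edge (capped so
#'   the target median stays below 0.98).
#' @return object of class `branching_statistics`.
#' @export
branching_statistics <- function(classes, symmetry, area_growth,
                                 length_ratio,
                                 extrapolation_slope = 0) {
  k <- nrow(classes)
  stopifnot(length(symmetry) == k, length(length_ratio) == k)
  if (!is.null(area_growth$type)) area_growth <- rep(list(area_growth), k)
  stopifnot(length(area_growth) == k)
  structure(list(classes = classes, symmetry = symmetry,
                 area_growth = area_growth, length_ratio = length_ratio,
                 extrapolation_slope = extrapolation_slope),
            class = "branching_statistics")
}

sample_from <- function(spec, n) {
  switch(spec$type,
    beta = stats::rbeta(n, spec$shape1, spec$shape2),
    lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog),
    fixed = rep(spec$value, n),
    empirical = sample(spec$values, n, replace = TRUE),
    stop("unknown sampler type: ", spec$type, call. = FALSE))
}

sampler_median <- function(spec) {
  switch(spec$type,
    beta = stats::qbeta(0.5, spec$shape1, spec$shape2),
    lognormal = exp(spec$meanlog),
    fixed = spec$value,
    empirical = stats::median(spec$values))
}

# class index with sub-class extrapolation: diameters below the lowest
# edge map to class 1 but are marked for median-shifted resampling
stats_class <- function(d, stats) {
  ci <- class_index(d, stats$classes)
  below <- ci == 0L
  ci[below] <- 1L
  list(index = ci, below = below)
}

# Sample daughter symmetry for mother diameters d (meters). Below the
# smallest class, samples from the smallest class are power-warped so
# their median follows a linear continuation on log10-diameter,
# capped at 0.98.
sample_symmetry <- function(d, stats) {
  sc <- stats_class(d, stats)
  out <- numeric(length(d))
  for (k in unique(sc$index)) {
    sel <- sc$index == k
    out[sel] <- sample_from(stats$symmetry[[k]], sum(sel))
  }
  if (any(sc$below) && stats$extrapolation_slope != 0) {
    m0 <- sampler_median(stats$symmetry[[1]])
    d0 <- stats$classes$lower[1]
    sel <- sc$below
    target <- m0 + stats$extrapolation_slope * (log10(d0) - log10(d[sel]))
    target <- pmin(pmax(target, 1e-3), 0.98)
    q <- log(target) / log(m0)  # S^q maps median m0 -> target, keeps (0,1)
    out[sel] <- out[sel]^q
  }
  # rejection guard: samplers must stay in (0, 1]
  bad <- !(out > 0 & out <= 1)
  tries <- 0L
  while (any(bad) && tries < 20L) {
    out[bad] <- sample_symmetry(d[bad], stats)
    bad <- !(out > 0 & out <= 1)
    tries <- tries + 1L
  }
  if (any(bad)) stop("symmetry sampler produced values outside (0,1]",
                     call. = FALSE)
  out
}

# Area growth A(d_M, S), vectorized; consumes RNG only when sd > 0.
eval_area_growth <- function(d, S, stats) {
  sc <- stats_class(d, stats)
  out <- numeric(length(d))
  for (k in unique(sc$index)) {
    sel <- sc$index == k
    m <- stats$area_growth[[k]]
    if (m$type == "fixed") {
      out[sel] <- m$value
    } else if (m$type == "scaling") {
      # A implied by d_M^gamma = d_L^gamma + d_S^gamma
      out[sel] <- area_growth_from_scaling(S[sel], m$gamma)
    } else if (m$type == "linear") {
      d_mm <- pmin(d[sel] * 1e3, m$d_mm_cap %||% Inf)
      a <- m$intercept + m$slope_d_mm * d_mm + m$slope_S * S[sel]
      if ((m$sd %||% 0) > 0) a <- a + stats::rnorm(sum(sel), 0, m$sd)
      out[sel] <- pmin(pmax(a, m$min %||% 0.5), m$max %||% 3)
    } else stop("unknown area-growth model type: ", m$type, call. = FALSE)
  }
  out
}

# length/diameter ratio sampled by the segment's OWN diameter class
sample_length_ratio <- function(d, stats) {
  sc <- stats_class(d, stats)
  out <- numeric(length(d))
  for (k in unique(sc$index)) {
    sel <- sc$index == k
    out[sel] <- sample_from(stats$length_ratio[[k]], sum(sel))
  }
  if (any(out <= 0)) stop("length-ratio sampler produced non-positive values",
                          call. = FALSE)
  out
}

#' Reference branching statistics
#'
#' A documented default fixture encoding the qualitative structure of
#' human coronary branching: symmetry medians increasing (and
#' dispersion tightening) as diameter decreases, from about 0.55 in
#' the largest class to about 0.80 in the smallest; area growth
#' following the linear model A = 1.13 - 0.66 d_M[mm] + 0.34 S
#' (mother diameter capped at 0.6 mm), so A is about 1 at and above
#' 400 um and grows toward the microcirculation; and right-skewed
#' lognormal length-to-diameter ratios whose class medians are
#' roughly constant over 75-200 um, smaller for the smallest and the
#' epicardial classes.
#'
#' @param classes data frame from [diameter_classes()].
#' @return a `branching_statistics` object.
#' @export
reference_statistics <- function(classes = diameter_classes()) {
  # class order: smallest diameter first
  s_median <- c(0.80, 0.78, 0.76, 0.74, 0.72, 0.70, 0.68, 0.65, 0.60, 0.55)
  s_conc   <- c(10, 10, 9, 9, 8, 8, 7, 6, 5, 5)  # beta shape1+shape2
  ld_median <- c(2.5, 3.5, 4.5, 5.5, 5.5, 5.5, 5.0, 4.0, 2.5, 1.5)
  k <- nrow(classes)
  stopifnot(k == length(s_median))
  symmetry <- lapply(seq_len(k), function(i) {
    list(type = "beta", shape1 = s_median[i] * s_conc[i],
         shape2 = (1 - s_median[i]) * s_conc[i])
  })
  length_ratio <- lapply(seq_len(k), function(i) {
    list(type = "lognormal", meanlog = log(ld_median[i]), sdlog = 0.7)
  })
  area_growth <- list(type = "linear", intercept = 1.13,
                      slope_d_mm = -0.66, slope_S = 0.34, sd = 0,
                      d_mm_cap = 0.6, min = 0.85, max = 1.8)
  branching_statistics(classes, symmetry, area_growth, length_ratio,
                       extrapolation_slope = 0.03)
}
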