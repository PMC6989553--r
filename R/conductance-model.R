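# Distal-conductance imputation: empirical (diameter, downstream
# conductance) table pooled over an in silico ensemble, with a
# power-law fallback, plus stochastic-variability analysis of the
# imputed hemodynamics.

#' Build a diameter -> distal-conductance model from a tree ensemble
#'
#' Pools (segment diameter, downstream conductance) pairs over the
#' ensemble, fits a power law on the log-log pooled data, and
#' supports median-in-window lookups: for a query diameter d, the
#' window holds all tabulated segments whose diameter is within the
#' fractional half-width (default 2.5%) of d. Empty windows fall back
#' to the power law and are flagged.
#'
#' @param ensemble list of loop-free `vascular_graph` trees (e.g.
#'   from [generate_ensemble()]).
#' @param viscosity viscosity model or constant, passed to
#'   [downstream_conductance()].
#' @param window fractional window half-width.
#' @param diameter_range optional band (meters) restricting which
#'   segments enter the pooled table.
#' @return object of class `conductance_model`: `table` (sorted by
#'   diameter), `fit` (a `power_law_fit` in log space), `window`.
#' @export
build_conductance_model <- function(ensemble, viscosity = viscosity_model(),
                                    window = 0.025,
                                    diameter_range = NULL) {
  if (inherits(ensemble, "vascular_graph")) ensemble <- list(ensemble)
  tabs <- lapply(seq_along(ensemble), function(i) {
    tr <- ensemble[[i]]
    data.frame(tree = i, d = tr$segments$diameter,
               G = downstream_conductance(tr, viscosity))
  })
  tab <- do.call(rbind, tabs)
  if (!is.null(diameter_range)) {
    tab <- tab[tab$d >= diameter_range[1] & tab$d <= diameter_range[2], ,
               drop = FALSE]
  }
  if (nrow(tab) < 3L) stop("too few segments to build a conductance model",
                           call. = FALSE)
  tab <- tab[order(tab$d), , drop = FALSE]
  fit <- fit_power_law(tab$d, tab$G, log_space = TRUE)
  structure(list(table = tab, fit = fit, window = window),
            class = "conductance_model")
}

#' @export
print.conductance_model <- function(x, ...) {
  cat(sprintf("<conductance_model> %d pooled segments, window +/- %.1f%%\n",
              nrow(x$table), 100 * x$window))
  cat(sprintf("  power law: G = %.3g * d^%.3f (log-log r2 = %.3f)\n",
              x$fit$a, x$fit$gamma, x$fit$r_squared))
  invisible(x)
}

# window of tabulated values around diameter d (|d_i/d - 1| <= w)
model_window <- function(model, d) {
  lo <- d * (1 - model$window); hi <- d * (1 + model$window)
  i0 <- findInterval(lo, model$table$d) + 1L
  i1 <- findInterval(hi, model$table$d)
  if (i1 < i0) return(numeric(0))
  model$table$G[i0:i1]
}

#' Query the conductance model
#'
#' @param model a `conductance_model`.
#' @param d query diameters, meters.
#' @param mode `"median"` (window median), `"powerfit"` (power-law
#'   evaluation) or `"stochastic"` (uniform draw from the window
#'   values; seeded by the caller).
#' @return list with `G` (m^3/(Pa s)) and `fallback` (logical: TRUE
#'   where the window was empty and the power law was used).
#' @export
query_conductance <- function(model, d,
                              mode = c("median", "powerfit", "stochastic")) {
  mode <- match.arg(mode)
  n <- length(d)
  G <- numeric(n); fb <- logical(n)
  if (mode == "powerfit") {
    G <- model$fit$a * d^model$fit$gamma
    return(list(G = G, fallback = fb))
  }
  for (k in seq_len(n)) {
    w <- model_window(model, d[k])
    if (length(w) == 0L) {
      G[k] <- model$fit$a * d[k]^model$fit$gamma
      fb[k] <- TRUE
    } else if (mode == "median") {
      G[k] <- stats::median(w)
    } else {
      G[k] <- w[sample.int(length(w), 1L)]
    }
  }
  list(G = G, fallback = fb)
}

#' Impute terminal distal conductances on a network
#'
#' Assigns every terminal node of `graph` a distal conductance looked
#' up from the model at the terminal segment's diameter, in one of
#' three modes: `stochastic` (independent uniform draw from the
#' empirical window per terminal), `median` (window median;
#' deterministic) or `powerfit` (power-law evaluation;
#' deterministic).
#'
#' @param graph a `vascular_graph`.
#' @param model a `conductance_model`.
#' @param mode imputation mode.
#' @param seed RNG seed (stochastic mode).
#' @param P_in,P_cap boundary pressures, Pa.
#' @return a [boundary_conditions()] with per-terminal `G_dist`;
#'   attribute `fallback` flags terminals served by the power-law
#'   fallback.
#' @export
impute_terminal_conductance <- function(graph, model,
                                        mode = c("median", "powerfit",
                                                 "stochastic"),
                                        seed = 1L,
                                        P_in = mmHg_to_Pa(90),
                                        P_cap = mmHg_to_Pa(20)) {
  mode <- match.arg(mode)
  deg <- node_degrees(graph)
  is_term <- deg == 1L & !graph$nodes$is_root
  term_ids <- graph$nodes$id[is_term]
  # diameter of the (single) segment incident to each terminal
  seg <- graph$segments
  d_term <- vapply(term_ids, function(t) {
    seg$diameter[seg$node_a == t | seg$node_b == t][1]
  }, numeric(1))
  q <- if (mode == "stochastic") {
    with_seed(seed, query_conductance(model, d_term, mode))
  } else {
    query_conductance(model, d_term, mode)
  }
  bc <- boundary_conditions(P_in, P_cap,
                            stats::setNames(q$G, term_ids))
  attr(bc, "fallback") <- stats::setNames(q$fallback, term_ids)
  bc
}

#' Stochastic-imputation variability analysis
#'
#' Solves the network hemodynamics under `n_runs` independent
#' stochastic imputations of the terminal distal conductances and
#' summarizes, per quantity (node pressure, segment flow, wall shear
#' stress): the median and 95th percentile across elements of the
#' per-element coefficient of variation and median absolute
#' deviation, and the agreement of each deterministic imputation mode
#' (window median, power fit) with the per-element stochastic median
#' (Pearson correlation and zero-intercept regression slope beta).
#'
#' @param graph a `vascular_graph`.
#' @param model a `conductance_model`.
#' @param n_runs number of stochastic runs (>= 2).
#' @param seed master seed; run i uses a derived sub-seed.
#' @param viscosity viscosity model or constant.
#' @param P_in,P_cap boundary pressures, Pa.
#' @return object of class `variability_report`: data frame
#'   `variability` (rows pressure/flow/wss; CV and MAD medians and
#'   P95) and data frame `agreement` (PCC and beta per deterministic
#'   mode and quantity), plus the per-element stochastic medians.
#' @export
stochastic_ensemble_analysis <- function(graph, model, n_runs = 200L,
                                         seed = 1L,
                                         viscosity = viscosity_model(),
                                         P_in = mmHg_to_Pa(90),
                                         P_cap = mmHg_to_Pa(20)) {
  stopifnot(n_runs >= 2L)
  nP <- nrow(graph$nodes); nS <- nrow(graph$segments)
  Pm <- matrix(NA_real_, nP, n_runs)
  Qm <- matrix(NA_real_, nS, n_runs)
  Tm <- matrix(NA_real_, nS, n_runs)
  for (r in seq_len(n_runs)) {
    bc <- impute_terminal_conductance(graph, model, mode = "stochastic",
                                      seed = derive_seed(seed, r),
                                      P_in = P_in, P_cap = P_cap)
    st <- solve_pressures(graph, bc, viscosity)
    Pm[, r] <- st$nodes$P
    Qm[, r] <- abs(st$segments$Q)
    Tm[, r] <- st$segments$tau
  }
  row_mad <- function(M) apply(M, 1, function(x)
    stats::median(abs(x - stats::median(x))))
  row_cv <- function(M) {
    mu <- rowMeans(M)
    sd <- apply(M, 1, stats::sd)
    ifelse(abs(mu) > 0, sd / abs(mu), 0)
  }
  summarize <- function(M) {
    cv <- row_cv(M); mad <- row_mad(M)
    c(cv_median = stats::median(cv), cv_p95 = stats::quantile(cv, 0.95,
                                                              names = FALSE),
      mad_median = stats::median(mad), mad_p95 = stats::quantile(mad, 0.95,
                                                                 names = FALSE))
  }
  variability <- rbind(pressure = summarize(Pm), flow = summarize(Qm),
                       wss = summarize(Tm))
  med <- list(pressure = apply(Pm, 1, stats::median),
              flow = apply(Qm, 1, stats::median),
              wss = apply(Tm, 1, stats::median))

  agree <- list()
  for (mode in c("median", "powerfit")) {
    bc <- impute_terminal_conductance(graph, model, mode = mode,
                                      P_in = P_in, P_cap = P_cap)
    st <- solve_pressures(graph, bc, viscosity)
    det <- list(pressure = st$nodes$P, flow = abs(st$segments$Q),
                wss = st$segments$tau)
    for (q in names(det)) {
      x <- med[[q]]; y <- det[[q]]
      pcc <- if (stats::sd(x) == 0 || stats::sd(y) == 0) 1
             else stats::cor(x, y)
      beta <- sum(x * y) / sum(x * x)
      agree[[length(agree) + 1L]] <- data.frame(
        mode = mode, quantity = q, pcc = pcc, beta = beta)
    }
  }
  structure(list(variability = as.data.frame(variability),
                 agreement = do.call(rbind, agree),
                 stochastic_median = med, n_runs = n_runs),
            class = "variability_report")
}

#' @export
print.variability_report <- function(x, ...) {
  cat(sprintf("<variability_report> %d stochastic runs\n", x$n_runs))
  cat("Variability (per-element CV and MAD across runs):\n")
  print(round(x$variability, 4))
  cat("Agreement of deterministic modes with the stochastic median:\n")
  print(transform(x$agreement, pcc = round(pcc, 4), beta = round(beta, 4)))
  invisible(x)
}

#' Diameter-binned hemodynamic profiles
#'
#' Bins solved segments into log-spaced diameter bins and reports the
#' median and quartiles of segment mean pressure, flow magnitude,
#' centerline velocity and wall shear stress per bin, plus optional
#' power-law fits of each quantity against diameter over a diameter
#' window.
#'
#' @param state a `hemodynamic_state`.
#' @param n_bins number of log-spaced bins.
#' @param fit_windows named list of diameter windows (meters), e.g.
#'   `list(flow = c(30e-6, 400e-6))`, for per-quantity power-law
#'   fits; fits use the per-segment data, not bin medians.
#' @return list with `profile` data frame and `fits` (list of
#'   `power_law_fit`).
#' @export
diameter_binned_profiles <- function(state, n_bins = 12L,
                                     fit_windows = list()) {
  seg <- state$segments
  Pn <- state$nodes$P[match(seg$node_a, state$nodes$id)] / 2 +
        state$nodes$P[match(seg$node_b, state$nodes$id)] / 2
  d <- seg$diameter
  edges <- exp(seq(log(min(d)) - 1e-9, log(max(d)) + 1e-9,
                   length.out = n_bins + 1L))
  bin <- pmax(pmin(findInterval(d, edges, rightmost.closed = TRUE),
                   n_bins), 1L)
  qs <- function(v) if (length(v)) stats::quantile(v, c(0.25, 0.5, 0.75),
                                                   names = FALSE)
                    else rep(NA_real_, 3)
  rows <- lapply(seq_len(n_bins), function(k) {
    s <- bin == k
    p <- qs(Pn[s]); q <- qs(abs(seg$Q[s])); vv <- qs(seg$v[s])
    tt <- qs(seg$tau[s])
    data.frame(bin = k, d_lo = edges[k], d_hi = edges[k + 1],
               n = sum(s),
               P_q1 = p[1], P_med = p[2], P_q3 = p[3],
               Q_q1 = q[1], Q_med = q[2], Q_q3 = q[3],
               v_q1 = vv[1], v_med = vv[2], v_q3 = vv[3],
               tau_q1 = tt[1], tau_med = tt[2], tau_q3 = tt[3])
  })
  vals <- list(pressure = Pn, flow = abs(seg$Q), velocity = seg$v,
               wss = seg$tau)
  fits <- lapply(names(fit_windows), function(q) {
    w <- fit_windows[[q]]
    s <- d >= w[1] & d <= w[2] & vals[[q]] > 0
    if (sum(s) < 3) return(NULL)
    fit_power_law(d[s], vals[[q]][s])
  })
  names(fits) <- names(fit_windows)
  list(profile = do.call(rbind, rows), fits = fits)
}
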