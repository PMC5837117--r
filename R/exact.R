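#' Construct an IICR curve object
#'
#' The central output container: a strictly increasing time grid with the
#' IICR evaluated on it, plus unit and provenance metadata. Before scaling
#' (see [scale_curve()]) times are in units of `N_ref` generations and
#' values are multiples of `N_ref` (the reference haploid deme size).
#'
#' @param times strictly increasing, non-negative time grid.
#' @param values IICR values (> 0; may be `Inf` at the origin for
#'   different-deme sampling, `NA` for empty estimator bins).
#' @param time_unit one of `"coalescent"`, `"generations"`, `"years"`.
#' @param size_unit `"N_ref"` (dimensionless multiples) or `"haploid_genes"`.
#' @param provenance `"exact"` or `"estimated"`.
#' @param sampling optional [sampling_scheme()].
#' @param model_hash optional model digest (see [model_hash()]).
#' @param n_obs optional per-bin observation counts (estimated curves).
#' @return an object of class `iicr_curve`.
#' @export
iicr_curve <- function(times, values,
                       time_unit = "coalescent", size_unit = "N_ref",
                       provenance = c("exact", "estimated"),
                       sampling = NULL, model_hash = NULL, n_obs = NULL) {
  provenance <- match.arg(provenance)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (any(times < 0) || any(diff(times) <= 0))
    stop("times must be non-negative and strictly increasing")
  if (any(values[!is.na(values)] <= 0))
    stop("IICR values must be positive where defined")
  structure(list(times = times, values = values,
                 time_unit = time_unit, size_unit = size_unit,
                 provenance = provenance, sampling = sampling,
                 model_hash = model_hash, n_obs = n_obs),
            class = "iicr_curve")
}

#' @method print iicr_curve
#' @export
print.iicr_curve <- function(x, ...) {
  cat(sprintf("iicr_curve (%s): %d points, t in [%g, %g] %s, values in %s\n",
              x$provenance, length(x$times), min(x$times), max(x$times),
              x$time_unit, x$size_unit))
  fin <- is.finite(x$values)
  if (any(fin))
    cat(sprintf("  value range (finite): [%g, %g]; %d non-finite/missing\n",
                min(x$values[fin]), max(x$values[fin]), sum(!fin)))
  invisible(x)
}

#' Step plot of an IICR curve on log axes (PSMC-style)
#'
#' Purely a rendering; never alters the curve data.
#' @param x an `iicr_curve`.
#' @param add overlay on an existing plot?
#' @param ... passed to [graphics::plot()] / [graphics::lines()].
#' @export
plot.iicr_curve <- function(x, add = FALSE, ...) {
  ok <- is.finite(x$values) & x$times > 0
  if (!any(ok)) stop("no finite values to plot")
  if (add) {
    graphics::lines(x$times[ok], x$values[ok], type = "s", ...)
  } else {
    graphics::plot(x$times[ok], x$values[ok], type = "s", log = "xy",
                   xlab = sprintf("time (%s)", x$time_unit),
                   ylab = sprintf("IICR (%s)", x$size_unit), ...)
  }
  invisible(x)
}

#' Survival function and density of the pairwise coalescence time
#'
#' Computes `S(t) = P(T2 > t)` and the density `f(t)` of the coalescence
#' time of two lineages under a piecewise-constant structured model, by
#' propagating the initial pair-location distribution through each epoch's
#' absorbing-chain exponential (a phase-type distribution, piecewise across
#' epochs). Epoch remaps are applied instantaneously at the boundary before
#' the new epoch's generator acts; `S` and `f` are left-continuous at
#' boundaries. The density equals the instantaneous absorption flux, i.e.
#' the transient distribution times the per-state coalescence rates.
#'
#' @param model a [make_custom_model()] model.
#' @param sampling a [sampling_scheme()].
#' @param t vector of times (>= 0), in units of `N_ref` generations.
#' @param allow_infinite accept models under which coalescence is not
#'   certain (disconnected demes); the returned `S` then does not tend to 0.
#' @return list with vectors `S` and `f` matching `t`.
#' @export
survival_and_density <- function(model, sampling, t, allow_infinite = FALSE) {
  stopifnot(inherits(model, "demographic_model"))
  t <- as.numeric(t)
  if (any(t < 0)) stop("times must be >= 0")
  ch <- model_chain(model, sampling, allow_infinite)
  # epoch k covers (start_k, start_{k+1}]; t = 0 evaluates epoch 1 at dt = 0
  k_of <- pmax(findInterval(t, ch$starts, left.open = TRUE), 1L)
  S <- numeric(length(t)); f <- numeric(length(t))
  for (k in unique(k_of)) {
    sel <- k_of == k
    ev <- kit_eval(ch$kits[[k]], t[sel] - ch$starts[k])
    S[sel] <- ev$S; f[sel] <- ev$f
  }
  list(S = S, f = f)
}

#' Exact IICR curve of a structured demographic model
#'
#' Evaluates `IICR(t) = P(T2 > t) / f(t)` on a time grid from the exact
#' phase-type representation of the pairwise coalescence time. Under
#' panmixia the IICR equals the (time-varying) population size in units of
#' `N_ref`; under structure it is a sampling-scheme-dependent trajectory
#' that methods like PSMC estimate but that need not match any census size.
#' At `t = 0` the analytic limit is reported: the local deme size for
#' same-deme sampling, `+Inf` for different-deme sampling (two lineages in
#' different demes have zero instantaneous coalescence rate).
#'
#' @inheritParams survival_and_density
#' @param times strictly increasing grid of evaluation times (>= 0).
#' @return an [iicr_curve()] with provenance `"exact"`.
#' @examples
#' m <- make_n_island(10, 0.1)
#' exact_iicr(m, sampling_scheme(1, 1), make_time_grid(0.01, 500, 32))
#' @export
exact_iicr <- function(model, sampling, times = make_time_grid(),
                       allow_infinite = FALSE) {
  sampling <- check_sampling(model, sampling)
  sf <- survival_and_density(model, sampling, times, allow_infinite)
  vals <- ifelse(sf$f > 0, sf$S / sf$f, Inf)
  zero_interior <- sf$f == 0 & times > 0
  if (any(zero_interior))
    warning(sum(zero_interior),
            " grid point(s) with zero coalescence density; IICR recorded as +Inf")
  iicr_curve(times, vals, provenance = "exact", sampling = sampling,
             model_hash = model_hash(model))
}

# ---- n-island closed form --------------------------------------------------

# The two-lineage chain of the symmetric n-island model lumps exactly into
# two transient states, "same deme" and "different demes". With gamma =
# M/(n-1) the lumped generator is
#     same:      -(1+M)      M
#     different:  gamma     -gamma
# and absorption (coalescence) happens from "same" at rate 1. The transient
# eigenvalues are -alpha and -beta with
#   alpha + beta = 1 + nM/(n-1),  alpha * beta = gamma,
# beta being the smaller root; N/beta is the ancient plateau of the IICR.
nisland_rates <- function(n, M) {
  gamma <- M / (n - 1)
  tr <- 1 + M + gamma
  disc <- sqrt(tr^2 - 4 * gamma)
  list(gamma = gamma, alpha = (tr + disc) / 2, beta = (tr - disc) / 2)
}

#' Closed-form IICR of the symmetric n-island model
#'
#' Evaluates the two-exponential closed form obtained by eigen-decomposition
#' of the lumped (same-deme / different-demes) transient chain. This is an
#' independent route to the same curve as [exact_iicr()] on
#' [make_n_island()] and agrees with it to near machine precision.
#'
#' @param n number of demes (>= 2).
#' @param M scaled total immigration rate per deme (> 0).
#' @param scheme `"same"` or `"different"` deme sampling.
#' @param times strictly increasing evaluation grid (>= 0).
#' @return an [iicr_curve()] (values in multiples of the deme size `N`).
#' @examples
#' nisland_iicr_closed_form(2, 1, "same", c(0, 1, 10))
#' @export
nisland_iicr_closed_form <- function(n, M, scheme = c("same", "different"),
                                     times = make_time_grid()) {
  scheme <- match.arg(scheme)
  if (n < 2) stop("n must be >= 2 (use a panmictic model for n = 1)")
  if (M <= 0) stop("M must be > 0")
  r <- nisland_rates(n, M)
  al <- r$alpha; be <- r$beta; gamma <- r$gamma
  d <- al - be
  if (scheme == "same") {
    # p_same(0) = 1, p_diff(0) = 0
    A <- ((1 + M) - be) / d;  B <- (al - (1 + M)) / d   # p_same coefficients
    C <- -M / d;              D <- M / d                # p_diff coefficients
  } else {
    A <- -gamma / d;          B <- gamma / d
    C <- (gamma - be) / d;    D <- (al - gamma) / d
  }
  ea <- exp(-al * times); eb <- exp(-be * times)
  f <- A * ea + B * eb                     # coalescence flux = p_same * 1
  S <- (A + C) * ea + (B + D) * eb
  vals <- ifelse(f > 0, S / f, Inf)
  iicr_curve(times, vals, provenance = "exact",
             sampling = if (scheme == "same") sampling_scheme(1, 1) else
               sampling_scheme(1, 2))
}

#' Ancient-plateau eigenvalue of the n-island model
#'
#' The same-deme IICR of the n-island model tends, for large `t`, to
#' `N / beta` where `beta` is the smallest-magnitude eigenvalue of the
#' lumped two-lineage chain:
#' `beta = (1 + nM/(n-1) - sqrt((1 + nM/(n-1))^2 - 4M/(n-1))) / 2`.
#' For small `M`, `N / beta` approaches `N (n-1) / M`; for large `M` it
#' approaches the total size `n N`.
#'
#' @param n number of demes (>= 2).
#' @param M scaled migration rate (> 0).
#' @return `beta`, with `0 < beta < 1`.
#' @examples
#' 1 / beta_asymptote(10, 0.1)   # plateau in units of N, ~ 99.1
#' @export
beta_asymptote <- function(n, M) {
  if (n < 2) stop("n must be >= 2")
  if (M <= 0) stop("M must be > 0")
  nisland_rates(n, M)$beta
}

#' Nucleotide-diversity effective size of the n-island model
#'
#' The classical `Ne` that matches expected pairwise diversity:
#' `Ne = N (n + (n-1)^2 / (n M))`. It approximates the ancient IICR plateau
#' `N / beta` when migration is strong, and tends to the total size `n N`
#' as `M` grows.
#'
#' @param n number of demes.
#' @param N haploid deme size.
#' @param M scaled migration rate (> 0 when `n >= 2`).
#' @return the effective size, in the units of `N`.
#' @examples
#' nei_takahata_ne(2, 1, 1)   # 2.5 (i.e. 2.5 N)
#' @export
nei_takahata_ne <- function(n, N, M) {
  if (n < 1 || N <= 0) stop("need n >= 1 and N > 0")
  if (n == 1) return(N)
  if (M <= 0) stop("M must be > 0 for a subdivided population")
  N * (n + (n - 1)^2 / (n * M))
}

#' Low-migration limit of the ancient IICR plateau
#'
#' When `M` is small the plateau `N / beta` tends to `N (n - 1) / M`, which
#' can vastly exceed the total population size `n N`: e.g. 10 islands of
#' 1000 genes at `M = 0.1` plateau near 90,000 although only 10,000 genes
#' exist.
#'
#' @inheritParams nei_takahata_ne
#' @return `N (n - 1) / M`.
#' @export
small_m_plateau <- function(n, N, M) {
  if (n < 2) stop("n must be >= 2")
  if (M <= 0) stop("M must be > 0")
  N * (n - 1) / M
}
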