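# Absorbing Markov chain over the locations of two uncoalesced lineages.
#
# For an epoch with n demes the transient states are the unordered deme
# pairs {i, j} (i <= j), n(n+1)/2 of them, plus one absorbing "coalesced"
# state kept as the last row/column of the generator. Lumping ordered pairs
# into unordered ones is exact because the two lineages are exchangeable.

#' Enumerate the two-lineage state space of an epoch
#'
#' @param n_demes number of demes.
#' @return list with `pairs` (2-column matrix, row `k` = the unordered pair
#'   of state `k`, i <= j), `n_states` (transient count), `index` a function
#'   `(i, j) -> state`.
#' @keywords internal
#' @export
pair_state_space <- function(n_demes) {
  n <- as.integer(n_demes)
  stopifnot(n >= 1L)
  pairs <- cbind(
    i = unlist(lapply(seq_len(n), function(i) rep(i, n - i + 1L))),
    j = unlist(lapply(seq_len(n), function(i) i:n)))
  # state of pair {i, j}, i <= j: offset of block i plus position of j
  lookup <- matrix(NA_integer_, n, n)
  lookup[pairs] <- seq_len(nrow(pairs))
  index <- function(i, j) lookup[cbind(pmin(i, j), pmax(i, j))]
  list(pairs = pairs, n_states = nrow(pairs), index = index)
}

#' Build the absorbing-chain rate matrix of one epoch
#'
#' Rates follow the coalescent scaling in which time is counted in units of
#' `N_ref` generations: two lineages in deme `i` of relative size `s_i`
#' coalesce at rate `1 / s_i`, and each lineage in deme `i` jumps to deme
#' `k` at rate `M_ik / 2` (the `M = 2Nm` convention). The returned matrix
#' `Q` has the transient pair states first and the absorbing coalesced state
#' last; every row sums to zero and the absorbing row is identically zero.
#'
#' @param e an [epoch()].
#' @return list of class `pair_generator`: `Q` (full generator),
#'   `space` (the [pair_state_space()]), `abs_rates` (per-state coalescence
#'   rate, the column of `Q` into the absorbing state).
#' @export
build_pair_generator <- function(e) {
  e <- validate_epoch(e)
  n <- length(e$deme_sizes)
  sp <- pair_state_space(n)
  np <- sp$n_states
  Q <- matrix(0, np + 1L, np + 1L)
  for (k in seq_len(np)) {
    i <- sp$pairs[k, 1]; j <- sp$pairs[k, 2]
    if (i == j) {
      Q[k, np + 1L] <- Q[k, np + 1L] + 1 / e$deme_sizes[i]
      for (d in seq_len(n)) if (d != i && e$migration[i, d] > 0) {
        # either of the two lineages may jump
        Q[k, sp$index(i, d)] <- Q[k, sp$index(i, d)] + e$migration[i, d]
      }
    } else {
      for (d in seq_len(n)) {
        if (d != i && e$migration[i, d] > 0)
          Q[k, sp$index(d, j)] <- Q[k, sp$index(d, j)] + e$migration[i, d] / 2
        if (d != j && e$migration[j, d] > 0)
          Q[k, sp$index(i, d)] <- Q[k, sp$index(i, d)] + e$migration[j, d] / 2
      }
    }
    Q[k, k] <- 0
    Q[k, k] <- -sum(Q[k, ])
  }
  structure(list(Q = Q, space = sp, abs_rates = Q[seq_len(np), np + 1L]),
            class = "pair_generator")
}

# Lineage-level remap matrix R[d_old, d_new]: probability that a lineage in
# old deme d is found in new deme d' immediately after the epoch boundary.
lineage_remap_matrix <- function(remap, n_old, n_new) {
  R <- matrix(0, n_old, n_new)
  if (is.null(remap)) {
    stopifnot(n_old == n_new)
    diag(R) <- 1
    return(R)
  }
  for (d in seq_len(n_old)) {
    p <- remap$p[d]
    R[d, remap$map[d]] <- R[d, remap$map[d]] + p
    if (p < 1) R[d, d] <- R[d, d] + (1 - p)
  }
  R
}

# Pair-state transition matrix across an epoch boundary; the two lineages
# move independently. Rows: old transient states (+ absorbing last), columns
# likewise for the new epoch.
pair_remap_matrix <- function(remap, n_old, n_new) {
  R <- lineage_remap_matrix(remap, n_old, n_new)
  sp_o <- pair_state_space(n_old)
  sp_n <- pair_state_space(n_new)
  P <- matrix(0, sp_o$n_states + 1L, sp_n$n_states + 1L)
  for (k in seq_len(sp_o$n_states)) {
    i <- sp_o$pairs[k, 1]; j <- sp_o$pairs[k, 2]
    for (l in seq_len(sp_n$n_states)) {
      a <- sp_n$pairs[l, 1]; b <- sp_n$pairs[l, 2]
      P[k, l] <- if (a == b) R[i, a] * R[j, a] else
        R[i, a] * R[j, b] + R[i, b] * R[j, a]
    }
  }
  P[sp_o$n_states + 1L, sp_n$n_states + 1L] <- 1
  P
}

# Spectral (or expm-fallback) propagation kit for one epoch, given the row
# distribution `p_in` over transient states at the epoch start.
epoch_kit <- function(gen, p_in) {
  np <- gen$space$n_states
  QT <- gen$Q[seq_len(np), seq_len(np), drop = FALSE]
  a <- gen$abs_rates
  kit <- list(QT = QT, a = a, p_in = p_in, np = np, spectral = FALSE)
  eg <- tryCatch(eigen(QT), error = function(e) NULL)
  if (!is.null(eg)) {
    Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    recon_ok <- !is.null(Vi) && {
      err <- max(Mod(eg$vectors %*% (eg$values * Vi) - QT))
      err <= 1e-9 * (1 + max(abs(QT)))
    }
    if (recon_ok) {
      w <- as.vector((p_in %*% eg$vectors))      # weights in eigenbasis
      kit$spectral <- TRUE
      kit$lambda <- eg$values
      kit$Vi <- Vi
      kit$w <- w
      kit$cS <- w * as.vector(Vi %*% rep(1, np))
      kit$cf <- w * as.vector(Vi %*% a)
    }
  }
  kit
}

# Vectorized survival/density/distribution over transient states at elapsed
# times dt (>= 0) within one epoch.
kit_eval <- function(kit, dt) {
  # dt = 0 is evaluated directly from the entering distribution so that a
  # structurally zero density (different-deme sampling) is exactly zero
  if (any(dt == 0)) {
    z <- dt == 0
    ev <- kit_eval(kit, dt[!z])
    S <- numeric(length(dt)); f <- numeric(length(dt))
    S[z] <- sum(kit$p_in); f[z] <- sum(kit$p_in * kit$a)
    S[!z] <- ev$S; f[!z] <- ev$f
    return(list(S = S, f = f))
  }
  if (kit$spectral) {
    E <- exp(outer(dt, kit$lambda))              # |dt| x np
    S <- Re(E %*% kit$cS)
    f <- Re(E %*% kit$cf)
    list(S = pmax(as.vector(S), 0), f = pmax(as.vector(f), 0))
  } else {
    S <- numeric(length(dt)); f <- numeric(length(dt))
    for (q in seq_along(dt)) {
      p <- as.vector(kit$p_in %*% as.matrix(Matrix::expm(kit$QT * dt[q])))
      S[q] <- sum(p); f[q] <- sum(p * kit$a)
    }
    list(S = S, f = f)
  }
}

# Distribution over transient states after elapsed time dt (row vector).
kit_state <- function(kit, dt) {
  if (kit$spectral) {
    p <- Re((kit$w * exp(kit$lambda * dt)) %*% kit$Vi)
    pmax(as.vector(p), 0)
  } else {
    as.vector(kit$p_in %*% as.matrix(Matrix::expm(kit$QT * dt)))
  }
}

# Prepare the full piecewise chain: one generator + kit per epoch, with the
# entering distribution propagated across boundaries (remaps applied
# instantaneously at the boundary before the new epoch's generator acts).
model_chain <- function(model, sampling, allow_infinite = FALSE) {
  sampling <- check_sampling(model, sampling)
  K <- length(model$epochs)
  gens <- lapply(model$epochs, build_pair_generator)
  starts <- vapply(model$epochs, function(e) e$start_time, numeric(1))
  p0 <- numeric(gens[[1]]$space$n_states)
  p0[gens[[1]]$space$index(sampling$deme_a, sampling$deme_b)] <- 1
  kits <- vector("list", K)
  p_in <- p0
  for (k in seq_len(K)) {
    if (k > 1) {
      n_prev <- length(model$epochs[[k - 1]]$deme_sizes)
      n_here <- length(model$epochs[[k]]$deme_sizes)
      P <- pair_remap_matrix(model$epochs[[k]]$remap, n_prev, n_here)
      np_prev <- gens[[k - 1]]$space$n_states
      p_in <- as.vector(p_in %*% P[seq_len(np_prev),
                                   seq_len(gens[[k]]$space$n_states),
                                   drop = FALSE])
    }
    kits[[k]] <- epoch_kit(gens[[k]], p_in)
    if (k < K) p_in <- kit_state(kits[[k]], starts[k + 1] - starts[k])
  }
  if (!allow_infinite) check_absorbing_reachable(gens, model, sampling)
  list(gens = gens, kits = kits, starts = starts, sampling = sampling)
}

# Error unless absorption is certain: in the final epoch, every transient
# state reachable from the support of the entering distribution must have a
# path to the absorbing state.
check_absorbing_reachable <- function(gens, model, sampling) {
  K <- length(gens)
  support <- numeric(gens[[1]]$space$n_states)
  support[gens[[1]]$space$index(sampling$deme_a, sampling$deme_b)] <- 1
  reach_forward <- function(Q, s) {
    # boolean closure of s under positive transient->transient rates
    np <- length(s)
    A <- Q[seq_len(np), seq_len(np), drop = FALSE] > 0
    repeat {
      s2 <- (s | as.vector(s %*% A) > 0)
      if (all(s2 == s)) return(s)
      s <- s2
    }
  }
  for (k in seq_len(K)) {
    support <- reach_forward(gens[[k]]$Q, support > 0) > 0
    if (k < K) {
      n_prev <- length(model$epochs[[k]]$deme_sizes)
      n_here <- length(model$epochs[[k + 1]]$deme_sizes)
      P <- pair_remap_matrix(model$epochs[[k + 1]]$remap, n_prev, n_here)
      np_next <- gens[[k + 1]]$space$n_states
      support <- as.vector(support %*% P[seq_along(support), seq_len(np_next),
                                         drop = FALSE]) > 0
    }
  }
  # backward reachability of the absorbing state in the last epoch
  Q <- gens[[K]]$Q
  np <- gens[[K]]$space$n_states
  can <- gens[[K]]$abs_rates > 0
  A <- Q[seq_len(np), seq_len(np), drop = FALSE] > 0
  repeat {
    can2 <- can | as.vector(A %*% can) > 0
    if (all(can2 == can)) break
    can <- can2
  }
  if (any(support & !can))
    stop("coalescence is not certain under this model/sampling ",
         "(disconnected demes); set allow_infinite = TRUE to accept a ",
         "defective coalescence-time distribution")
  invisible(TRUE)
}
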