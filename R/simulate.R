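#' Simulate independent pairwise coalescence times
#'
#' Draws i.i.d. realisations of the coalescence time `T2` of two lineages
#' under a structured demographic model by exact stochastic simulation of
#' the two-lineage absorbing Markov chain: exponential waiting times at the
#' current state's total rate, with epoch-boundary truncation (a waiting
#' time that crosses the next epoch start is discarded, the lineages are
#' advanced to the boundary, the boundary remap applied, and the wait
#' resampled under the new epoch's generator — exact for piecewise-constant
#' rates). Identical arguments and seed give bit-identical output.
#'
#' @param model a [make_custom_model()] model.
#' @param sampling a [sampling_scheme()].
#' @param n_rep number of independent replicates (>= 1).
#' @param seed integer RNG seed.
#' @param allow_infinite accept models under which coalescence is not
#'   certain; trapped replicates then yield `Inf`.
#' @return an object of class `t2_sample`: `values` (times in units of
#'   `N_ref` generations), `seed`, `model_hash`, `sampling`, `n_rep`.
#' @examples
#' s <- simulate_t2(make_n_island(2, 1), sampling_scheme(1, 1), 1000, seed = 7)
#' mean(s$values)   # ~ n = 2 for same-deme sampling
#' @export
simulate_t2 <- function(model, sampling, n_rep, seed,
                        allow_infinite = FALSE) {
  stopifnot(inherits(model, "demographic_model"))
  sampling <- check_sampling(model, sampling)
  n_rep <- as.integer(n_rep)
  if (is.na(n_rep) || n_rep < 1L) stop("n_rep must be >= 1")
  gens <- lapply(model$epochs, build_pair_generator)
  if (!allow_infinite) check_absorbing_reachable(gens, model, sampling)
  starts <- vapply(model$epochs, function(e) e$start_time, numeric(1))
  K <- length(gens)
  set.seed(as.integer(seed))

  st <- rep(gens[[1]]$space$index(sampling$deme_a, sampling$deme_b), n_rep)
  tm <- numeric(n_rep)
  res <- rep(NA_real_, n_rep)
  alive <- rep(TRUE, n_rep)

  # per-epoch embedded-chain tables
  for (k in seq_len(K)) {
    Q <- gens[[k]]$Q
    np <- gens[[k]]$space$n_states
    tot <- -diag(Q)[seq_len(np)]
    t_end <- if (k < K) starts[k + 1] else Inf
    if (k > 1) {
      n_prev <- length(model$epochs[[k - 1]]$deme_sizes)
      n_here <- length(model$epochs[[k]]$deme_sizes)
      P <- pair_remap_matrix(model$epochs[[k]]$remap, n_prev, n_here)
      idx <- which(alive)
      if (length(idx)) {
        st_old <- st[idx]
        for (s in unique(st_old)) {
          sel <- idx[st_old == s]
          pr <- P[s, seq_len(np)]
          st[sel] <- sample.int(np, length(sel), replace = TRUE, prob = pr)
        }
      }
    }
    repeat {
      idx <- which(alive & tm < t_end)
      if (!length(idx)) break
      rate <- tot[st[idx]]
      stuck <- rate <= 0
      if (any(stuck)) {           # no outgoing rate: hold until the boundary
        tm[idx[stuck]] <- t_end
        idx <- idx[!stuck]; rate <- rate[!stuck]
        if (!length(idx)) break
      }
      t_new <- tm[idx] + stats::rexp(length(idx), rate)
      crossed <- t_new > t_end
      tm[idx[crossed]] <- t_end   # truncate-and-resample at the boundary
      jump <- idx[!crossed]
      if (length(jump)) {
        tm[jump] <- t_new[!crossed]
        st_old <- st[jump]
        for (s in unique(st_old)) {
          sel <- jump[st_old == s]
          pr <- Q[s, ]; pr[s] <- 0
          dest <- sample.int(np + 1L, length(sel), replace = TRUE, prob = pr)
          st[sel] <- dest
          hit <- sel[dest == np + 1L]
          if (length(hit)) {
            res[hit] <- tm[hit]
            alive[hit] <- FALSE
          }
        }
      }
    }
  }
  res[alive] <- Inf
  structure(list(values = res, seed = as.integer(seed),
                 model_hash = model_hash(model), sampling = sampling,
                 n_rep = n_rep),
            class = "t2_sample")
}

#' @method print t2_sample
#' @export
print.t2_sample <- function(x, ...) {
  cat(sprintf("t2_sample: %d replicates, seed %d, mean %.4g (N_ref generations)\n",
              x$n_rep, x$seed, mean(x$values[is.finite(x$values)])))
  invisible(x)
}

#' Write / read a T2 sample as plain text
#'
#' One value per line, full double precision, preceded by `#` header lines
#' carrying the seed, replicate count, model hash and sampling scheme.
#'
#' @param sample a `t2_sample`.
#' @param path file path.
#' @return `write_t2_sample` returns `path` invisibly; `read_t2_sample`
#'   returns a `t2_sample`.
#' @export
write_t2_sample <- function(sample, path) {
  stopifnot(inherits(sample, "t2_sample"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# iicr t2 sample",
    sprintf("# seed: %d", sample$seed),
    sprintf("# n_rep: %d", sample$n_rep),
    sprintf("# model_hash: %s", sample$model_hash),
    sprintf("# sampling: %d %d", sample$sampling$deme_a, sample$sampling$deme_b),
    sprintf("%.17g", sample$values)), con)
  invisible(path)
}

#' @rdname write_t2_sample
#' @export
read_t2_sample <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  get <- function(key) {
    m <- grep(sprintf("^# %s:", key), lines[hdr], value = TRUE)
    if (!length(m)) return(NA_character_)
    trimws(sub(sprintf("^# %s:", key), "", m[1]))
  }
  vals <- suppressWarnings(as.numeric(lines[!hdr & nzchar(lines)]))
  if (anyNA(vals)) stop("malformed t2 sample file: non-numeric value line")
  samp <- strsplit(get("sampling"), "\\s+")[[1]]
  structure(list(values = vals,
                 seed = as.integer(get("seed")),
                 model_hash = get("model_hash"),
                 sampling = if (length(samp) == 2)
                   sampling_scheme(as.integer(samp[1]), as.integer(samp[2]))
                 else NULL,
                 n_rep = length(vals)),
            class = "t2_sample")
}

#' Emit an equivalent ms command line
#'
#' Builds the Hudson's-ms command that simulates the same demography, for
#' optional external cross-validation. Unit conversion: ms measures time in
#' units of `4 N0` generations and scales migration entries as `4 N0 m`;
#' identifying the haploid reference deme size `N_ref` with `2 N0` makes the
#' relative deme sizes carry over unchanged, the migration entries equal the
#' package's `M = 2Nm` values, and divides times by 2. The conversion is
#' noted in a trailing comment on the emitted line.
#'
#' Later epochs are representable when produced by [add_population_split()]
#' (deterministic merges become `-ej`, the ancestral size a `-en`, and
#' migration changes an `-ema`). Probabilistic remaps are refused.
#'
#' @param model a `demographic_model`.
#' @param sampling a [sampling_scheme()].
#' @param n_rep replicate count for the command's second argument.
#' @return a single string (the ms command plus a `#` comment).
#' @export
emit_ms_command <- function(model, sampling, n_rep) {
  stopifnot(inherits(model, "demographic_model"))
  sampling <- check_sampling(model, sampling)
  e1 <- model$epochs[[1]]
  n1 <- length(e1$deme_sizes)
  parts <- c("ms", "2", format(as.integer(n_rep)), "-T")
  if (n1 > 1) {
    counts <- integer(n1)
    counts[sampling$deme_a] <- counts[sampling$deme_a] + 1L
    counts[sampling$deme_b] <- counts[sampling$deme_b] + 1L
    parts <- c(parts, "-I", n1, counts, "0")
    for (i in seq_len(n1)) if (e1$deme_sizes[i] != 1)
      parts <- c(parts, "-n", i, fmt_ms(e1$deme_sizes[i]))
    parts <- c(parts, "-ma", ms_matrix(e1$migration))
  } else if (e1$deme_sizes[1] != 1) {
    parts <- c(parts, "-eN", 0, fmt_ms(e1$deme_sizes[1]))
  }
  # ms population index of each current-epoch deme (merged demes keep the
  # index of the first population folded into them)
  ms_idx <- seq_len(n1)
  for (k in seq_len(length(model$epochs))[-1]) {
    e <- model$epochs[[k]]
    t_ms <- fmt_ms(e$start_time / 2)
    r <- e$remap
    if (is.null(r)) r <- list(map = seq_along(ms_idx), p = rep(1, length(ms_idx)))
    if (any(r$p < 1))
      stop("probabilistic remaps are not representable as an ms command")
    n_new <- length(e$deme_sizes)
    new_idx <- integer(n_new)
    for (d_new in seq_len(n_new)) {
      srcs <- which(r$map == d_new)
      if (!length(srcs)) stop("epoch ", k, " has a deme no lineage can enter; ",
                              "not representable in ms")
      host <- ms_idx[srcs[1]]
      for (s in srcs[-1])
        parts <- c(parts, "-ej", t_ms, ms_idx[s], host)
      new_idx[d_new] <- host
      parts <- c(parts, "-en", t_ms, host, fmt_ms(e$deme_sizes[d_new]))
    }
    ms_idx <- new_idx
    if (n1 > 1) {
      full <- matrix(0, n1, n1)
      full[ms_idx, ms_idx] <- e$migration
      parts <- c(parts, "-ema", t_ms, n1, ms_matrix(full))
    }
  }
  paste0(paste(parts, collapse = " "),
         "  # time unit 4*N0 gens with N_ref = 2*N0; t_ms = t/2, ",
         "migration entries = M")
}

fmt_ms <- function(x) format(x, digits = 12, scientific = FALSE, trim = TRUE)

ms_matrix <- function(m) {
  out <- format(m, digits = 12, scientific = FALSE, trim = TRUE)
  diag(out) <- "x"
  paste(t(out))
}
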