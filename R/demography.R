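#' Define one epoch of a piecewise-constant structured demography
#'
#' A demographic model is a sequence of epochs, each of which is a classical
#' structured-coalescent island configuration: a set of demes with relative
#' haploid sizes and a matrix of scaled migration rates. Time runs backward
#' from the sampling time and is measured in units of `N_ref` generations,
#' where `N_ref` is the reference haploid deme size of the model the epoch
#' belongs to.
#'
#' Migration follows the classical scaled convention `M = 2Nm`: the entry
#' `migration[i, j]` is the scaled rate at which deme `i` receives immigrant
#' genes from deme `j` (equivalently, the scaled rate at which an ancestral
#' lineage currently in deme `i` jumps to deme `j`, which happens at rate
#' `M_ij / 2` per lineage on the coalescent time scale). The diagonal is
#' ignored and stored as zero.
#'
#' `remap` describes what happens to lineage locations at the instant
#' (backward in time) this epoch begins. `remap$map[d]` gives the deme of the
#' new epoch that a lineage sitting in deme `d` of the previous epoch moves
#' to; `remap$p[d]` is the probability that the move is applied (1 for a
#' deterministic population split, `p < 1` for an admixture pulse, in which
#' case deme `d` must still exist in the new epoch so the lineage can stay
#' put). The number of demes may change between epochs only through a remap.
#'
#' @param start_time time at which the epoch begins, in units of `N_ref`
#'   generations; the first epoch of a model must start at 0.
#' @param deme_sizes vector of relative haploid deme sizes `s_i > 0`
#'   (absolute size `s_i * N_ref`).
#' @param migration square matrix of scaled rates `M_ij = 2Nm_ij`; may be
#'   `NULL` for a single deme.
#' @param remap `NULL`, or `list(map =, p =)` as described above; `p` is
#'   recycled to the previous epoch's deme count and defaults to 1.
#' @return an object of class `iicr_epoch`.
#' @seealso [make_custom_model()] which validates a full epoch sequence.
#' @export
epoch <- function(start_time, deme_sizes, migration = NULL, remap = NULL) {
  n <- length(deme_sizes)
  if (is.null(migration)) migration <- matrix(0, n, n)
  migration <- as.matrix(migration)
  e <- structure(
    list(start_time = as.numeric(start_time),
         deme_sizes = as.numeric(deme_sizes),
         migration = migration,
         remap = remap),
    class = "iicr_epoch")
  validate_epoch(e)
}

validate_epoch <- function(e) {
  n <- length(e$deme_sizes)
  if (n < 1) stop("epoch must contain at least one deme")
  if (any(!is.finite(e$deme_sizes)) || any(e$deme_sizes <= 0))
    stop("deme sizes must be finite and > 0")
  if (e$start_time < 0 || !is.finite(e$start_time))
    stop("epoch start_time must be finite and >= 0")
  m <- e$migration
  if (!is.matrix(m) || nrow(m) != n || ncol(m) != n)
    stop("migration must be a ", n, "x", n, " matrix")
  if (any(!is.finite(m))) stop("migration rates must be finite")
  off <- m; diag(off) <- 0
  if (any(off < 0)) stop("negative migration rate")
  diag(m) <- 0  # diagonal carries no meaning
  e$migration <- m
  if (!is.null(e$remap)) {
    if (is.null(e$remap$map)) stop("remap must contain a 'map' vector")
    e$remap$map <- as.integer(e$remap$map)
    if (any(is.na(e$remap$map)))
      stop("remap targets must be integer deme indices")
    if (any(e$remap$map < 1L | e$remap$map > n))
      stop("remap target outside the deme range of this epoch")
    p <- if (is.null(e$remap$p)) 1 else e$remap$p
    p <- rep_len(as.numeric(p), length(e$remap$map))
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
      stop("remap probabilities must lie in [0, 1]")
    # a lineage that does not move keeps its old index, which must exist here
    stay <- which(p < 1)
    if (any(stay > n))
      stop("remap with p < 1 requires the source deme to persist in the new epoch")
    e$remap$p <- p
  }
  e
}

#' Assemble and validate a structured demographic model
#'
#' This is the fully general constructor: every preset
#' ([make_n_island()], [make_stepping_stone()], [make_continent_island()],
#' [add_population_split()]) funnels through it, so re-validating a preset is
#' a no-op. Epoch start times must be strictly increasing with the first at
#' 0; the last epoch extends to infinity. Every epoch after the first whose
#' deme count differs from its predecessor's must carry a `remap`.
#'
#' @param epochs list of [epoch()] objects.
#' @param N_ref reference haploid deme size (number of genes); sets the time
#'   unit (`N_ref` generations) and the size unit of IICR values.
#' @param label free-text model description.
#' @return an object of class `demographic_model`.
#' @examples
#' two_asym <- make_custom_model(list(
#'   epoch(0, c(1, 1), matrix(c(0, 1, 0.1, 0), 2, 2, byrow = TRUE))
#' ), N_ref = 500, label = "asymmetric two-island")
#' @export
make_custom_model <- function(epochs, N_ref = 1, label = "") {
  if (!is.list(epochs) || length(epochs) == 0)
    stop("a model needs at least one epoch")
  epochs <- lapply(epochs, function(e) {
    if (!inherits(e, "iicr_epoch")) e <- do.call(epoch, e)
    validate_epoch(e)
  })
  starts <- vapply(epochs, function(e) e$start_time, numeric(1))
  if (starts[1] != 0) stop("the first epoch must start at time 0")
  if (any(diff(starts) <= 0)) stop("epoch start times must be strictly increasing")
  if (!is.numeric(N_ref) || N_ref <= 0) stop("N_ref must be > 0")
  for (k in seq_along(epochs)) {
    n_prev <- if (k == 1) length(epochs[[1]]$deme_sizes) else
      length(epochs[[k - 1]]$deme_sizes)
    n_here <- length(epochs[[k]]$deme_sizes)
    r <- epochs[[k]]$remap
    if (k == 1) {
      if (!is.null(r)) stop("the first epoch cannot carry a remap")
      next
    }
    if (is.null(r)) {
      if (n_here != n_prev)
        stop("deme count may change only through a remap_at_start")
    } else {
      if (length(r$map) != n_prev)
        stop("remap map must have one entry per deme of the previous epoch")
    }
  }
  structure(list(epochs = epochs, N_ref = as.numeric(N_ref),
                 label = as.character(label)),
            class = "demographic_model")
}

#' @method print demographic_model
#' @export
print.demographic_model <- function(x, ...) {
  cat("demographic_model:", if (nzchar(x$label)) x$label else "<unlabelled>", "\n")
  cat("  N_ref =", x$N_ref, "haploid genes; time unit = N_ref generations\n")
  for (k in seq_along(x$epochs)) {
    e <- x$epochs[[k]]
    cat(sprintf("  epoch %d: t >= %g, %d deme(s), sizes [%s]%s\n",
                k, e$start_time, length(e$deme_sizes),
                paste(signif(e$deme_sizes, 4), collapse = ", "),
                if (is.null(e$remap)) "" else " (remap at start)"))
  }
  invisible(x)
}

#' Where the two sampled lineages sit at time 0
#'
#' Two genes sampled in the same deme give the curve usually written IICR_s;
#' two genes from different demes give IICR_d. The distinction matters: under
#' population structure the two curves differ over recent times (IICR_d
#' diverges as t -> 0 because two lineages in different demes cannot coalesce
#' before one migrates) yet share the same ancient plateau.
#'
#' @param deme_a,deme_b 1-based deme indices in the first epoch.
#' @return an object of class `sampling_scheme`.
#' @export
sampling_scheme <- function(deme_a = 1L, deme_b = deme_a) {
  a <- as.integer(deme_a); b <- as.integer(deme_b)
  if (is.na(a) || is.na(b) || a < 1L || b < 1L)
    stop("deme indices must be positive integers")
  structure(list(deme_a = a, deme_b = b,
                 same_deme = a == b),
            class = "sampling_scheme")
}

check_sampling <- function(model, sampling) {
  if (!inherits(sampling, "sampling_scheme"))
    sampling <- do.call(sampling_scheme, as.list(sampling))
  n <- length(model$epochs[[1]]$deme_sizes)
  if (sampling$deme_a > n || sampling$deme_b > n)
    stop("sampling scheme refers to a deme absent from the first epoch")
  sampling
}

#' The n-island (finite island) model
#'
#' `n` demes of equal size exchange migrants symmetrically: each deme
#' receives a total of `M = 2Nm` immigrant genes per generation (on the
#' scaled clock), split evenly over the `n - 1` source demes, so each
#' off-diagonal entry is `M / (n - 1)`.
#'
#' @param n number of demes (>= 1).
#' @param M scaled total immigration rate per deme; must be 0 when `n = 1`.
#' @param N_ref reference haploid deme size.
#' @return a single-epoch `demographic_model`.
#' @examples
#' make_n_island(10, 0.1)
#' @export
make_n_island <- function(n, M, N_ref = 1) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  if (M < 0) stop("negative migration rate")
  if (n == 1L && M > 0) stop("a single deme cannot receive migrants (M must be 0)")
  mig <- matrix(if (n > 1L) M / (n - 1L) else 0, n, n)
  diag(mig) <- 0
  make_custom_model(list(epoch(0, rep(1, n), mig)), N_ref = N_ref,
                    label = sprintf("n-island (n=%d, M=%g)", n, M))
}

#' Nearest-neighbour stepping stone models on a 1D or 2D lattice
#'
#' Demes sit on a line or rectangular grid and exchange migrants only with
#' lattice neighbours (4-neighbourhood in 2D). By default the lattice is
#' bounded (edge and corner demes have fewer neighbours); `circular = TRUE`
#' wraps it into a ring/torus. Deme indexing is row-major: on a `r x c` grid,
#' deme `(i, j)` has index `(i - 1) * c + j`.
#'
#' Two rate conventions are offered. The default (`rate_mode = "total"`)
#' fixes every deme's total scaled emigration at `M`, split equally among its
#' neighbours, which keeps the per-deme immigrant count comparable with an
#' n-island model of the same `M`; `rate_mode = "per_link"` instead puts rate
#' `M` on every lattice edge.
#'
#' @param dims integer vector of length 1 or 2: lattice extent.
#' @param M scaled migration rate (interpreted per `rate_mode`).
#' @param circular wrap the lattice into a ring (1D) or torus (2D)?
#' @param rate_mode `"total"` (default) or `"per_link"`.
#' @param N_ref reference haploid deme size.
#' @return a single-epoch `demographic_model`.
#' @examples
#' make_stepping_stone(c(3, 3), M = 1)        # bounded 3x3 grid
#' make_stepping_stone(5, M = 1, circular = TRUE)  # ring of 5
#' @export
make_stepping_stone <- function(dims, M, circular = FALSE,
                                rate_mode = c("total", "per_link"),
                                N_ref = 1) {
  rate_mode <- match.arg(rate_mode)
  dims <- as.integer(dims)
  if (length(dims) < 1L || length(dims) > 2L || any(is.na(dims)) || any(dims < 1L))
    stop("dims must be one or two positive integers")
  if (M < 0) stop("negative migration rate")
  n <- prod(dims)
  if (n == 1L && M > 0) stop("a single deme cannot receive migrants (M must be 0)")
  nr <- if (length(dims) == 2L) dims[1] else 1L
  nc <- if (length(dims) == 2L) dims[2] else dims[1]
  idx <- function(i, j) (i - 1L) * nc + j
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    here <- idx(i, j)
    nb <- list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))
    for (q in nb) {
      qi <- q[1]; qj <- q[2]
      if (circular) {
        qi <- ((qi - 1L) %% nr) + 1L
        qj <- ((qj - 1L) %% nc) + 1L
      }
      if (qi >= 1L && qi <= nr && qj >= 1L && qj <= nc) {
        there <- idx(qi, qj)
        if (there != here) adj[here, there] <- TRUE
      }
    }
  }
  mig <- matrix(0, n, n)
  if (n > 1L) {
    deg <- rowSums(adj)
    rate <- if (rate_mode == "total") M / deg else rep(M, n)
    mig[adj] <- 0  # filled row-wise below
    for (d in seq_len(n)) mig[d, adj[d, ]] <- rate[d]
  }
  make_custom_model(list(epoch(0, rep(1, n), mig)), N_ref = N_ref,
                    label = sprintf("stepping stone (%s, M=%g, %s, %s)",
                                    paste(dims, collapse = "x"), M,
                                    if (circular) "circular" else "bounded",
                                    rate_mode))
}

#' Continent-island model
#'
#' Two demes: a continent `size_ratio` times larger than the island (deme 1
#' is the continent, deme 2 the island). By default exchange is conservative:
#' the island's scaled immigration rate is `M` and the continent's is
#' `M / size_ratio`, so both demes exchange the same expected number of
#' migrant genes per generation. `symmetric = TRUE` instead sets both scaled
#' rates to `M`.
#'
#' @param size_ratio continent size relative to the island (>= 1).
#' @param M island scaled immigration rate.
#' @param symmetric use equal scaled rates in both directions?
#' @param N_ref reference haploid deme size (the island's size).
#' @return a single-epoch `demographic_model`.
#' @examples
#' make_continent_island(10, 1)   # the continent is ten times larger
#' @export
make_continent_island <- function(size_ratio, M, symmetric = FALSE, N_ref = 1) {
  if (size_ratio < 1) stop("size_ratio must be >= 1 (deme 1 is the continent)")
  if (M < 0) stop("negative migration rate")
  cont_in <- if (symmetric) M else M / size_ratio
  mig <- matrix(c(0, cont_in,
                  M, 0), 2, 2, byrow = TRUE)
  make_custom_model(list(epoch(0, c(size_ratio, 1), mig)), N_ref = N_ref,
                    label = sprintf("continent-island (ratio=%g, M=%g)",
                                    size_ratio, M))
}

#' Append a (backward-time) population split to a model
#'
#' Backward in time, at time `T`, the lineages of all `derived` demes merge
#' into a single ancestral deme of relative size `ancestral_size`; forward in
#' time this is the ancestral population splitting into the derived demes at
#' `T`. Any demes not listed in `derived` persist through the split, keep the
#' migration rates they had among themselves, and exchange migrants with the
#' ancestral deme at scaled rate `ancestral_M` (0 for an isolated ancestor).
#' In the new epoch the persisting demes keep their relative order and the
#' ancestral deme is appended last.
#'
#' @param model a `demographic_model`.
#' @param T split time, strictly later than the last existing epoch start.
#' @param derived indices (in the current last epoch) of the demes that merge;
#'   defaults to all demes.
#' @param ancestral_size relative haploid size of the ancestral deme.
#' @param ancestral_M scaled migration rate between the ancestral deme and
#'   each persisting deme.
#' @return the extended `demographic_model`.
#' @examples
#' # two demes exchanging M = 1 merge at T = 2 into an ancestor of size 2,
#' # so the total number of genes is constant through the split
#' split2 <- add_population_split(make_n_island(2, 1), T = 2,
#'                                ancestral_size = 2)
#' @export
add_population_split <- function(model, T, derived = NULL,
                                 ancestral_size = 1, ancestral_M = 0) {
  stopifnot(inherits(model, "demographic_model"))
  last <- model$epochs[[length(model$epochs)]]
  if (!is.numeric(T) || T <= last$start_time)
    stop("split time must lie beyond the start of the last epoch")
  n_old <- length(last$deme_sizes)
  if (is.null(derived)) derived <- seq_len(n_old)
  derived <- sort(unique(as.integer(derived)))
  if (any(is.na(derived)) || any(derived < 1L) || any(derived > n_old))
    stop("unknown deme index in 'derived'")
  if (ancestral_size <= 0) stop("ancestral_size must be > 0")
  keep <- setdiff(seq_len(n_old), derived)
  n_new <- length(keep) + 1L
  anc <- n_new
  map <- integer(n_old)
  map[keep] <- seq_along(keep)
  map[derived] <- anc
  sizes <- c(last$deme_sizes[keep], ancestral_size)
  mig <- matrix(0, n_new, n_new)
  if (length(keep) > 0) {
    mig[seq_along(keep), seq_along(keep)] <- last$migration[keep, keep, drop = FALSE]
    mig[seq_along(keep), anc] <- ancestral_M
    mig[anc, seq_along(keep)] <- ancestral_M
  }
  e <- epoch(T, sizes, mig, remap = list(map = map, p = rep(1, n_old)))
  make_custom_model(c(model$epochs, list(e)), N_ref = model$N_ref,
                    label = model$label)
}

# ---- serialization ---------------------------------------------------------

#' Serialize a demographic model to its canonical JSON form
#'
#' The JSON schema mirrors the model structure: `N_ref`, `label`, and a list
#' of epochs each with `start_time`, `deme_sizes`, a full `migration` matrix
#' and an optional `remap` (`{"map": [...], "p": [...]}`, 1-based indices).
#' Times are in units of `N_ref` generations, rates in the `M = 2Nm`
#' convention. `model_from_json(model_to_json(x))` reproduces `x`, and
#' re-serializing a parsed document reproduces the document byte-for-byte.
#'
#' @param model a `demographic_model`.
#' @return a single JSON string.
#' @export
model_to_json <- function(model) {
  stopifnot(inherits(model, "demographic_model"))
  eps <- lapply(model$epochs, function(e) {
    list(start_time = e$start_time,
         deme_sizes = e$deme_sizes,
         migration = e$migration,
         remap = if (is.null(e$remap)) NULL else
           list(map = e$remap$map, p = e$remap$p))
  })
  doc <- list(N_ref = model$N_ref, label = model$label, epochs = eps)
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                null = "null", always_decimal = FALSE))
}

#' Parse a demographic model from JSON
#'
#' @param txt a JSON string or the path of a JSON file.
#' @return a validated `demographic_model`.
#' @rdname model_to_json
#' @export
model_from_json <- function(txt) {
  doc <- jsonlite::fromJSON(txt, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  if (is.null(doc$epochs)) stop("model JSON lacks an 'epochs' field")
  eps <- lapply(doc$epochs, function(e) {
    mig <- e$migration
    if (!is.null(mig)) mig <- matrix(unlist(mig), nrow = length(e$deme_sizes),
                                     byrow = is.list(mig))
    remap <- e$remap
    if (!is.null(remap)) remap <- list(map = remap$map, p = remap$p)
    epoch(e$start_time, e$deme_sizes, mig, remap)
  })
  make_custom_model(eps, N_ref = if (is.null(doc$N_ref)) 1 else doc$N_ref,
                    label = if (is.null(doc$label)) "" else doc$label)
}

#' Short content hash of a model (for provenance headers)
#' @param model a `demographic_model`.
#' @return a 32-character hex digest of the canonical JSON form.
#' @export
model_hash <- function(model) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(model_to_json(model), f)
  unname(tools::md5sum(f))
}
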