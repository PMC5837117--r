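#' Physical scaling constants for curve display
#'
#' IICR computations run on the coalescent scale: time in units of `N_ref`
#' generations, sizes in multiples of `N_ref`. This object carries the
#' constants needed to express a curve in generations or years and in
#' haploid gene counts. The defaults — a haploid deme size of 500 genes, 25
#' years per generation, and a per-site per-generation mutation rate of
#' 2.5e-8 — are the conventional humanised scaling used when comparing with
#' sequence-based (PSMC-style) inferences; the mutation rate is carried as
#' metadata only, since no sequence is ever simulated here.
#'
#' @param N_ref reference haploid deme size (genes).
#' @param generation_time years per generation.
#' @param mutation_rate per-site per-generation rate (metadata only).
#' @return an object of class `scaling_config`.
#' @export
scaling_config <- function(N_ref = 500, generation_time = 25,
                           mutation_rate = 2.5e-8) {
  if (N_ref <= 0 || generation_time <= 0 || mutation_rate <= 0)
    stop("all scaling constants must be positive")
  structure(list(N_ref = N_ref, generation_time = generation_time,
                 mutation_rate = mutation_rate),
            class = "scaling_config")
}

#' Rescale an IICR curve between coalescent and physical units
#'
#' Times are multiplied by `N_ref` (to generations) and additionally by the
#' generation time (to years); values are multiplied by `N_ref`, turning
#' dimensionless multiples into haploid gene counts. Scaling is invertible:
#' request `"coalescent"` on a scaled curve to descale it. A diploid
#' display divides sizes by 2 (one diploid individual = two genes) and is
#' labelled as such.
#'
#' @param curve an [iicr_curve()].
#' @param config a [scaling_config()].
#' @param time_unit target unit: `"coalescent"`, `"generations"`, `"years"`.
#' @param diploid report sizes as diploid individuals instead of haploid
#'   genes?
#' @return the rescaled `iicr_curve`.
#' @examples
#' cu <- iicr_curve(1, 1, provenance = "exact")
#' scale_curve(cu, scaling_config(500, 25), "years")  # t = 12500, size = 500
#' @export
scale_curve <- function(curve, config = scaling_config(),
                        time_unit = c("years", "generations", "coalescent"),
                        diploid = FALSE) {
  stopifnot(inherits(curve, "iicr_curve"), inherits(config, "scaling_config"))
  time_unit <- match.arg(time_unit)
  # bring back to the coalescent scale first
  tfac_now <- switch(curve$time_unit,
                     coalescent = 1,
                     generations = config$N_ref,
                     years = config$N_ref * config$generation_time,
                     stop("unknown time unit tag: ", curve$time_unit))
  sfac_now <- switch(curve$size_unit,
                     N_ref = 1,
                     haploid_genes = config$N_ref,
                     diploid_individuals = config$N_ref / 2,
                     stop("unknown size unit tag: ", curve$size_unit))
  times <- curve$times / tfac_now
  values <- curve$values / sfac_now
  tfac <- switch(time_unit, coalescent = 1, generations = config$N_ref,
                 years = config$N_ref * config$generation_time)
  if (time_unit == "coalescent") {
    sfac <- 1; size_unit <- "N_ref"
  } else if (diploid) {
    sfac <- config$N_ref / 2; size_unit <- "diploid_individuals"
  } else {
    sfac <- config$N_ref; size_unit <- "haploid_genes"
  }
  iicr_curve(times * tfac, values * sfac, time_unit = time_unit,
             size_unit = size_unit, provenance = curve$provenance,
             sampling = curve$sampling, model_hash = curve$model_hash,
             n_obs = curve$n_obs)
}

#' Write / read an IICR curve as tab-separated text
#'
#' Two columns `time<TAB>iicr` preceded by `#` header lines with the unit
#' metadata, provenance, sampling scheme and model hash. Missing estimator
#' bins are written as `NA` and survive the round trip.
#'
#' @param curve an `iicr_curve`.
#' @param path file path.
#' @return `write_iicr_tsv` returns `path` invisibly; `read_iicr_tsv`
#'   returns the `iicr_curve`.
#' @export
write_iicr_tsv <- function(curve, path) {
  stopifnot(inherits(curve, "iicr_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(
    "# iicr curve",
    sprintf("# time_unit: %s", curve$time_unit),
    sprintf("# size_unit: %s", curve$size_unit),
    sprintf("# provenance: %s", curve$provenance),
    if (!is.null(curve$model_hash))
      sprintf("# model_hash: %s", curve$model_hash),
    if (!is.null(curve$sampling))
      sprintf("# sampling: %d %d", curve$sampling$deme_a, curve$sampling$deme_b),
    "time\tiicr")
  writeLines(hdr, con)
  writeLines(sprintf("%.17g\t%.17g", curve$times, curve$values), con)
  invisible(path)
}

#' @rdname write_iicr_tsv
#' @export
read_iicr_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  get <- function(key) {
    m <- grep(sprintf("^# %s:", key), lines[hdr], value = TRUE)
    if (!length(m)) return(NULL)
    trimws(sub(sprintf("^# %s:", key), "", m[1]))
  }
  for (key in c("time_unit", "size_unit", "provenance"))
    if (is.null(get(key)))
      stop("malformed curve file: missing '# ", key, ":' header")
  body <- lines[!hdr & nzchar(lines)]
  if (!length(body) || body[1] != "time\tiicr")
    stop("malformed curve file: expected a 'time\\tiicr' column header")
  body <- body[-1]
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2)
  if (length(bad))
    stop("malformed curve file at data line ", bad[1], ": ",
         dQuote(body[bad[1]]))
  num <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                ncol = 2, byrow = TRUE)
  bad <- which(is.na(num[, 1]))
  if (length(bad))
    stop("malformed curve file at data line ", bad[1], ": ",
         "non-numeric time ", dQuote(body[bad[1]]))
  samp <- get("sampling")
  if (!is.null(samp)) {
    ab <- as.integer(strsplit(samp, "\\s+")[[1]])
    samp <- sampling_scheme(ab[1], ab[2])
  }
  iicr_curve(num[, 1], num[, 2],
             time_unit = get("time_unit"), size_unit = get("size_unit"),
             provenance = get("provenance"), sampling = samp,
             model_hash = get("model_hash"))
}
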