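#' Normalized 3D radial position of a fluorescent signal
#'
#' Casts a ray from the nucleus center of mass through the signal's center
#' of mass, finds the mask boundary crossing along that ray by sub-voxel
#' stepping, and returns the signal's distance from the center divided by
#' the center-to-boundary distance, clamped to `[0, 1]` (0 = nuclear
#' center, 1 = periphery). Normalizing by the boundary distance along the
#' same ray accounts for natural variation in nuclear size and shape.
#'
#' @param signal_com length-3 physical coordinates of the signal center of
#'   mass (microns).
#' @param nucleus a `nucleus_mask`.
#' @param step_frac ray step as a fraction of the smallest voxel edge
#'   (default 1/4).
#' @return Radial fraction in `[0, 1]`. A signal whose center of mass lies
#'   outside the mask raises an error with condition class
#'   `nucleoscape_outside_nucleus`; a signal coincident with the nuclear
#'   center returns 0.
#' @export
radial_fraction <- function(signal_com, nucleus, step_frac = 0.25) {
  stopifnot(inherits(nucleus, "nucleus_mask"), length(signal_com) == 3L)
  vx <- nucleus$voxel_size
  dims <- dim(nucleus$mask)
  in_mask <- function(p) {
    idx <- .point_to_voxel(p, dims, vx)
    !is.null(idx) && nucleus$mask[idx[1], idx[2], idx[3]]
  }
  if (!in_mask(signal_com))
    stop(structure(class = c("nucleoscape_outside_nucleus", "error", "condition"),
                   list(message = "OutsideNucleus: signal center of mass not inside the nucleus mask",
                        call = sys.call())))
  ctr <- nucleus$center
  d <- signal_com - ctr
  r <- sqrt(sum(d^2))
  if (r == 0) return(0)
  u <- d / r
  step <- min(vx) * step_frac
  # march outward from the signal until the ray leaves the mask
  s_in <- r
  s <- r
  max_s <- sqrt(sum((dims * vx)^2))  # grid diagonal: guaranteed outside
  while (s <= max_s) {
    s <- s + step
    if (!in_mask(ctr + s * u)) break
    s_in <- s
  }
  boundary <- s_in + step / 2  # linear midpoint of the crossing interval
  min(1, r / boundary)
}

#' Shell index of a radial fraction
#'
#' Five concentric shells of 20% relative radius each: `[0, 0.2)` is shell
#' 1, ..., `[0.8, 1.0]` is shell 5 (a fraction of exactly 1 belongs to
#' shell 5).
#'
#' @param fraction numeric vector of radial fractions in `[0, 1]`.
#' @return Integer shell indices in 1..5.
#' @export
shell_index <- function(fraction) {
  if (any(fraction < 0 | fraction > 1, na.rm = TRUE))
    stop("radial fractions must lie in [0, 1]")
  pmin(5L, 1L + as.integer(floor(fraction / 0.2)))
}

#' Five-shell histogram and cumulative distribution of radial positions
#'
#' @param fractions numeric vector of radial fractions in `[0, 1]` (empty
#'   input is valid and yields zero counts).
#' @return An object of class `shell_histogram`: `counts` (named integer,
#'   shells 1..5, summing to `n`), `breaks`, `n`, `modal_shell` (smallest
#'   shell index attaining the maximum count; `NA` when empty) and `cum`, a
#'   data.frame of sorted fractions with their empirical cumulative
#'   proportions (plot-ready).
#' @export
shell_histogram <- function(fractions) {
  fractions <- as.numeric(fractions)
  idx <- shell_index(fractions)
  counts <- tabulate(idx, nbins = 5L)
  names(counts) <- paste0("shell", 1:5)
  n <- length(fractions)
  cum <- if (n > 0) {
    s <- sort(fractions)
    data.frame(fraction = s, cumulative = seq_len(n) / n)
  } else data.frame(fraction = numeric(0), cumulative = numeric(0))
  structure(list(counts = counts, breaks = seq(0, 1, by = 0.2), n = n,
                 modal_shell = if (n > 0) as.integer(which.max(counts)) else NA_integer_,
                 cum = cum),
            class = "shell_histogram")
}

#' @export
print.shell_histogram <- function(x, ...) {
  cat("<shell_histogram> n =", x$n, "\n")
  print(x$counts)
  invisible(x)
}

#' Kolmogorov-Smirnov comparison of two radial distributions
#'
#' Two-sample 1D KS test: D is the supremum of the absolute ECDF difference
#' over the pooled sample points; the p-value comes from the asymptotic
#' Kolmogorov distribution at effective sample size
#' `n_a * n_b / (n_a + n_b)`.
#'
#' @param fractions_a,fractions_b numeric samples (each of size >= 1).
#' @return list with `D` and `p`.
#' @export
ks_compare <- function(fractions_a, fractions_b) {
  if (length(fractions_a) < 1L || length(fractions_b) < 1L)
    stop("each sample must contain at least one observation")
  res <- suppressWarnings(ks.test(fractions_a, fractions_b, exact = FALSE))
  list(D = unname(res$statistic), p = res$p.value)
}

#' Proportions test for object counts per nucleus
#'
#' Compares the average number of objects per nucleus between two
#' treatments as pooled rates: a two-sample z test on
#' `total objects / total nuclei` with pooled-variance standard error,
#' two-sided.
#'
#' @param counts_a,counts_b integer vectors of per-nucleus object counts
#'   (one entry per nucleus; >= 1 nucleus per group).
#' @return list with `z`, `p`, `rate_a`, `rate_b`.
#' @export
compare_counts <- function(counts_a, counts_b) {
  if (length(counts_a) < 1L || length(counts_b) < 1L)
    stop("each group needs at least one nucleus")
  na <- length(counts_a); nb <- length(counts_b)
  ra <- sum(counts_a) / na; rb <- sum(counts_b) / nb
  pooled <- (sum(counts_a) + sum(counts_b)) / (na + nb)
  if (pooled == 0) return(list(z = 0, p = 1, rate_a = ra, rate_b = rb))
  z <- (ra - rb) / sqrt(pooled * (1 / na + 1 / nb))
  list(z = z, p = 2 * pnorm(-abs(z)), rate_a = ra, rate_b = rb)
}

#' Welch t test for mean volumes or fluorescence intensities
#'
#' @param values_a,values_b numeric samples (each of size >= 2).
#' @return list with `t`, `df`, `p` (two-sided, unequal variances).
#' @export
compare_means <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each sample must contain at least two observations")
  res <- t.test(values_a, values_b)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Per-condition summary of segmented nuclei and objects
#'
#' Aggregates the quantification tables into the per-treatment read-outs:
#' object count per nucleus, mean object volume and fluorescence intensity
#' (each with standard error), and mean nuclear volume.
#'
#' @param objects data.frame of detected objects (as from
#'   [quantify_dataset()]), with `nucleus_id`, `volume`, `mean_intensity`
#'   and `condition` columns.
#' @param nuclei data.frame of segmented nuclei with `nucleus_id`, `volume`
#'   and `condition` columns.
#' @param condition condition label to summarize (must be present in
#'   `nuclei`).
#' @return One-row data.frame: `condition`, `n_nuclei`, `n_objects`,
#'   `objects_per_nucleus`, `mean_volume`, `se_volume`,
#'   `mean_nuclear_volume`, `mean_intensity`, `se_intensity`. Means over
#'   zero objects are `NA`.
#' @export
summarize_condition <- function(objects, nuclei, condition) {
  nuc <- nuclei[!is.na(nuclei$condition) & nuclei$condition == condition, , drop = FALSE]
  if (nrow(nuc) == 0L) stop("condition not present in `nuclei`: ", condition)
  obj <- objects[!is.na(objects$condition) & objects$condition == condition, , drop = FALSE]
  n_obj <- nrow(obj)
  se <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  data.frame(condition = condition,
             n_nuclei = nrow(nuc),
             n_objects = n_obj,
             objects_per_nucleus = n_obj / nrow(nuc),
             mean_volume = if (n_obj) mean(obj$volume) else NA_real_,
             se_volume = if (n_obj) se(obj$volume) else NA_real_,
             mean_nuclear_volume = mean(nuc$volume),
             mean_intensity = if (n_obj) mean(obj$mean_intensity) else NA_real_,
             se_intensity = if (n_obj) se(obj$mean_intensity) else NA_real_)
}

#' Radial records for detected locus signals
#'
#' Runs [radial_fraction()] for every detected object against its nucleus
#' mask and bins the result into shells. Signals whose center of mass falls
#' marginally outside the mask (e.g. pushed by blur at the very periphery)
#' are rejected, not clamped, and counted in the `n_rejected` attribute.
#'
#' @param objects data.frame of detected objects (`nucleus_id`, `x`, `y`,
#'   `z`, optional `condition`).
#' @param masks list of `nucleus_mask` objects indexed by `nucleus_id`.
#' @return data.frame of radial records: `nucleus_id`, `signal_id`,
#'   `radial_fraction`, `shell`, `condition`; attribute `n_rejected`.
#' @export
radial_records <- function(objects, masks) {
  rows <- list()
  rejected <- 0L
  for (i in seq_len(nrow(objects))) {
    ob <- objects[i, ]
    msk <- masks[[ob$nucleus_id]]
    f <- tryCatch(radial_fraction(c(ob$x, ob$y, ob$z), msk),
                  nucleoscape_outside_nucleus = function(e) NA_real_)
    if (is.na(f)) { rejected <- rejected + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      nucleus_id = ob$nucleus_id, signal_id = ob$object_id,
      radial_fraction = f, shell = shell_index(f),
      condition = if ("condition" %in% names(ob)) ob$condition else NA_character_)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(nucleus_id = integer(0), signal_id = integer(0),
               radial_fraction = numeric(0), shell = integer(0),
               condition = character(0))
  attr(out, "n_rejected") <- rejected
  out
}
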