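#' Configuration for the synthetic microscopy generator
#'
#' Describes one acquisition condition: nuclear geometry, voxel size, object
#' populations and the imaging model (PSF blur + shot noise). Defaults
#' emulate the study conditions quantified by the imaging pipeline: adherent
#' cell nuclei of ~250 um^3 imaged with 250 nm axial separation, right-skewed
#' chromocenter volumes, and FISH locus spots placed by a radial law.
#'
#' @param nucleus_semiaxes length-3 numeric, ellipsoid semiaxes in microns.
#'   The default `c(5, 5, 2.387)` gives a nuclear volume of ~250 um^3.
#' @param nucleus_cv coefficient of variation of the per-nucleus volume;
#'   semiaxes are scaled isotropically. Default 0.10.
#' @param voxel_size voxel edge lengths in microns; default
#'   `c(0.2, 0.2, 0.25)` (250 nm axial separation).
#' @param n_nuclei number of nuclei (one field/stack per nucleus).
#' @param chromocenter_count_law list with `law` ("poisson" or "fixed") and
#'   `mean`: chromocenters per nucleus. Default Poisson with mean 3, chosen
#'   so discrete objects remain resolvable by a connected-component
#'   quantifier that does not split merged aggregates.
#' @param chromocenter_volume_law list with `law` ("lognormal"), `mean` and
#'   `sd` in um^3. Default mean 8, sd 30% of mean (right-skewed, positive).
#' @param focus_channel `NULL`, or a list with `offset_sd` (microns): renders
#'   an H3K9me3-like focus channel whose foci are the chromocenters displaced
#'   by an isotropic Gaussian offset.
#' @param locus_law `NULL`, or a radial law (see [place_locus_spots()]) for
#'   FISH locus spots.
#' @param spots_per_nucleus locus spots per nucleus (e.g. 2 alleles).
#' @param spot_radius locus spot radius in microns, default 0.4 (typical of
#'   a hybridized BAC probe signal after blur).
#' @param psf_sigma per-axis Gaussian PSF sigma in microns; default
#'   `c(0.15, 0.15, 0.3)` (typical confocal lateral/axial scale).
#' @param noise list with `model` ("poisson" or "none"), `background` and
#'   `amplitude` in expected photon counts. The defaults (5, 100) give an
#'   object SNR of ~9.5 under Poisson noise.
#' @param min_gap minimum surface-to-surface gap between placed objects in
#'   microns (default 0.6, wide enough that the default PSF cannot bridge
#'   neighbours).
#' @param max_attempts placement attempts per object before the object is
#'   placed regardless of overlap and flagged `overlapping` in the truth.
#' @param overlap_cap if the fraction of overlapping objects exceeds this,
#'   a warning message is recorded in the truth table.
#' @param margin empty border around the nucleus in microns.
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @return An object of class `generation_config`.
#' @export
generation_config <- function(nucleus_semiaxes = c(5, 5, 2.387),
                              nucleus_cv = 0.10,
                              voxel_size = c(0.2, 0.2, 0.25),
                              n_nuclei = 10L,
                              chromocenter_count_law = list(law = "poisson", mean = 3),
                              chromocenter_volume_law = list(law = "lognormal", mean = 8, sd = 2.4),
                              focus_channel = NULL,
                              locus_law = NULL,
                              spots_per_nucleus = 2L,
                              spot_radius = 0.4,
                              psf_sigma = c(0.15, 0.15, 0.3),
                              noise = list(model = "poisson", background = 5, amplitude = 100),
                              min_gap = 0.6,
                              max_attempts = 2000L,
                              overlap_cap = 0.05,
                              margin = 0.8,
                              seed = 1L) {
  cfg <- list(nucleus_semiaxes = as.numeric(nucleus_semiaxes),
              nucleus_cv = nucleus_cv, voxel_size = as.numeric(voxel_size),
              n_nuclei = as.integer(n_nuclei),
              chromocenter_count_law = chromocenter_count_law,
              chromocenter_volume_law = chromocenter_volume_law,
              focus_channel = focus_channel, locus_law = locus_law,
              spots_per_nucleus = as.integer(spots_per_nucleus),
              spot_radius = spot_radius, psf_sigma = as.numeric(psf_sigma),
              noise = noise, min_gap = min_gap,
              max_attempts = as.integer(max_attempts),
              overlap_cap = overlap_cap, margin = margin,
              seed = as.integer(seed))
  .validate_config(cfg)
  structure(cfg, class = "generation_config")
}

.validate_config <- function(cfg) {
  stopifnot(length(cfg$nucleus_semiaxes) == 3L, all(cfg$nucleus_semiaxes > 0),
            length(cfg$voxel_size) == 3L, all(cfg$voxel_size > 0),
            cfg$n_nuclei >= 0L, cfg$nucleus_cv >= 0, cfg$margin >= 0,
            length(cfg$psf_sigma) == 3L, all(cfg$psf_sigma >= 0),
            cfg$noise$model %in% c("poisson", "none"),
            cfg$noise$amplitude > 0, cfg$noise$background >= 0)
  # resolution guard: expected object diameters must span >= 2 voxels per axis
  dmax <- 2 * max(cfg$voxel_size)
  if (cfg$chromocenter_count_law$mean > 0) {
    vl <- cfg$chromocenter_volume_law
    if (!identical(vl$law, "lognormal")) stop("unsupported chromocenter volume law: ", vl$law)
    v01 <- qlnorm(0.01, .lnorm_pars(vl$mean, vl$sd)["meanlog"],
                  .lnorm_pars(vl$mean, vl$sd)["sdlog"])
    if (2 * .sphere_radius(v01) < dmax)
      stop("resolution error: chromocenter diameters < 2 voxels at this voxel size",
           call. = FALSE)
  }
  if (!is.null(cfg$locus_law)) {
    .check_radial_law(cfg$locus_law)
    if (2 * cfg$spot_radius < dmax)
      stop("resolution error: locus spot diameter < 2 voxels at this voxel size",
           call. = FALSE)
    if (cfg$spots_per_nucleus < 0L) stop("spots_per_nucleus must be >= 0")
  }
  invisible(TRUE)
}

# lognormal parameters from arithmetic mean/sd
.lnorm_pars <- function(mean, sd) {
  mean <- unname(mean); sd <- unname(sd)
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  c(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

.sphere_radius <- function(v) (3 * v / (4 * pi))^(1 / 3)

.check_radial_law <- function(law) {
  if (!is.list(law) || is.null(law$law)) stop("radial law must be a list with a `law` field")
  supp <- switch(law$law,
    fixed = c(law$at, law$at),
    uniform = c(law$min, law$max),
    uniform_volume = c(0, 1),
    stop("unsupported radial law: ", law$law))
  if (any(supp < 0) || any(supp > 1) || supp[1] > supp[2])
    stop("radial law support must lie within [0, 1]")
  invisible(TRUE)
}

.sample_radial_law <- function(law, n) {
  switch(law$law,
    fixed = rep(law$at, n),
    uniform = runif(n, law$min, law$max),
    uniform_volume = runif(n)^(1 / 3))
}

#' Place FISH locus spots by a radial law
#'
#' Draws spot centers inside an ellipsoidal nucleus so that each spot's true
#' radial fraction (distance from the nuclear center divided by the distance
#' from the center to the boundary along the same ray; 0 = center, 1 =
#' periphery) follows `radial_law`, with directions uniform on the sphere.
#'
#' Supported laws: `list(law = "fixed", at = f)`, a point mass;
#' `list(law = "uniform", min = a, max = b)`, uniform radial fraction on
#' `[a, b]` (e.g. `min = 0.8, max = 1` emulates peripheral loci); and
#' `list(law = "uniform_volume")`, uniform placement in the nuclear volume
#' (radial-fraction CDF `r^3` in a sphere).
#'
#' @param radial_law radial law, support within `[0, 1]`.
#' @param n_spots number of spots (>= 0).
#' @param nucleus_geometry list with `center` (length-3, microns) and
#'   `semiaxes` (length-3, microns).
#' @param seed optional integer seed.
#' @return data.frame with columns `x`, `y`, `z` (microns) and
#'   `radial_fraction`.
#' @export
place_locus_spots <- function(radial_law, n_spots, nucleus_geometry, seed = NULL) {
  if (n_spots < 0) stop("`n_spots` must be >= 0")
  .check_radial_law(radial_law)
  if (!is.null(seed)) set.seed(seed)
  ctr <- nucleus_geometry$center
  semi <- nucleus_geometry$semiaxes
  u <- .sample_radial_law(radial_law, n_spots)
  # uniform directions on the sphere
  v <- matrix(rnorm(3 * n_spots), ncol = 3)
  nv <- sqrt(rowSums(v^2))
  nv[nv == 0] <- 1
  v <- v / nv
  # distance from center to the ellipsoid boundary along each direction
  tb <- 1 / sqrt(rowSums(sweep(v, 2, semi, "/")^2))
  if (n_spots == 0)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      radial_fraction = numeric(0)))
  p <- sweep(v * (u * tb), 2, ctr, "+")
  data.frame(x = p[, 1], y = p[, 2], z = p[, 3], radial_fraction = u)
}

# sample per-nucleus chromocenter count
.sample_count <- function(law, n) {
  switch(law$law,
    poisson = rpois(n, law$mean),
    fixed = rep(as.integer(round(law$mean)), n),
    stop("unsupported count law: ", law$law))
}

# Sequential placement of spheres inside an ellipsoid (largest first),
# rejecting overlaps; an unplaceable sphere is placed anyway and flagged.
.place_spheres <- function(radii, center, semi, min_gap, max_attempts) {
  ord <- order(radii, decreasing = TRUE)
  ctr <- matrix(NA_real_, length(radii), 3)
  overlapping <- logical(length(radii))
  placed_r <- numeric(0)
  placed_c <- matrix(NA_real_, 0, 3)
  for (i in ord) {
    r <- radii[i]
    eff <- pmax(semi - r, 0.05 * semi)  # keep spheres inside the nucleus
    best <- NULL
    best_margin <- -Inf
    for (a in seq_len(max_attempts)) {
      u <- runif(3, -1, 1)
      if (sum(u^2) > 1) next
      p <- center + u * eff
      if (nrow(placed_c) == 0L) { best <- p; best_margin <- Inf; break }
      d <- sqrt(colSums((t(placed_c) - p)^2))
      margin <- min(d - (placed_r + r))
      if (margin > best_margin) { best <- p; best_margin <- margin }
      if (margin >= min_gap) break
    }
    # when no candidate satisfies the gap, keep the best-separated one and
    # flag a true geometric overlap
    overlapping[i] <- best_margin < 0
    ctr[i, ] <- best
    placed_r <- c(placed_r, r)
    placed_c <- rbind(placed_c, best)
  }
  list(centers = ctr, overlapping = overlapping)
}

# add a solid sphere (indicator * amplitude) to an intensity array in place
.add_sphere <- function(img, voxel_size, center, radius, amplitude) {
  dims <- dim(img)
  i1 <- pmax(1L, floor((center - radius) / voxel_size))
  i2 <- pmin(dims, ceiling((center + radius) / voxel_size) + 1L)
  if (any(i1 > i2)) return(img)
  sx <- i1[1]:i2[1]; sy <- i1[2]:i2[2]; sz <- i1[3]:i2[3]
  d2 <- outer(outer(((sx - 0.5) * voxel_size[1] - center[1])^2,
                    ((sy - 0.5) * voxel_size[2] - center[2])^2, "+"),
              ((sz - 0.5) * voxel_size[3] - center[3])^2, "+")
  img[sx, sy, sz] <- img[sx, sy, sz] + amplitude * (d2 <= radius^2)
  img
}

# count voxels whose centers fall inside a sphere (voxelized volume)
.voxelized_sphere_volume <- function(center, radius, voxel_size, dims) {
  i1 <- pmax(1L, floor((center - radius) / voxel_size))
  i2 <- pmin(dims, ceiling((center + radius) / voxel_size) + 1L)
  sx <- i1[1]:i2[1]; sy <- i1[2]:i2[2]; sz <- i1[3]:i2[3]
  d2 <- outer(outer(((sx - 0.5) * voxel_size[1] - center[1])^2,
                    ((sy - 0.5) * voxel_size[2] - center[2])^2, "+"),
              ((sz - 0.5) * voxel_size[3] - center[3])^2, "+")
  sum(d2 <= radius^2) * prod(voxel_size)
}

.apply_imaging <- function(img, cfg) {
  if (any(cfg$psf_sigma > 0))
    img <- .blur_gauss3d(img, dim(img), cfg$psf_sigma / cfg$voxel_size)
  if (identical(cfg$noise$model, "poisson")) {
    d <- dim(img)
    img <- array(rpois(length(img), pmax(img, 0)), d)
  }
  img
}

#' Generate a synthetic nuclear imaging dataset with ground truth
#'
#' Renders `n_nuclei` multi-channel confocal-like z-stacks (one field per
#' nucleus): a DAPI channel covering an axis-aligned ellipsoidal nucleus,
#' optionally a pan-centromeric channel of solid spherical chromocenters, an
#' H3K9me3-like focus channel, and a FISH locus-spot channel. Objects are
#' rendered as solid shapes, convolved with a separable Gaussian PSF, and
#' degraded with shot noise. Every rendered object has exactly one row in
#' the returned ground-truth table; objects that could not be placed without
#' overlap are flagged.
#'
#' @param config a [generation_config()].
#' @return An object of class `nuclei_dataset`: a list with `nuclei` (per
#'   nucleus: named list of [voxel_grid()] channels plus geometry), `truth`
#'   (list of data.frames `nuclei` and `objects`, plus `warnings`) and
#'   `config`. Deterministic for a fixed seed.
#' @export
generate_nuclei_dataset <- function(config) {
  stopifnot(inherits(config, "generation_config"))
  .validate_config(config)
  set.seed(config$seed)
  cfg <- config
  vx <- cfg$voxel_size
  v0 <- 4 / 3 * pi * prod(cfg$nucleus_semiaxes)

  has_cc <- cfg$chromocenter_count_law$mean > 0
  has_focus <- !is.null(cfg$focus_channel)
  has_locus <- !is.null(cfg$locus_law) && cfg$spots_per_nucleus > 0L

  nuclei <- vector("list", cfg$n_nuclei)
  truth_nuc <- vector("list", cfg$n_nuclei)
  truth_obj <- list()

  for (i in seq_len(cfg$n_nuclei)) {
    s <- if (cfg$nucleus_cv > 0) {
      vi <- max(rnorm(1, v0, cfg$nucleus_cv * v0), 0.2 * v0)
      (vi / v0)^(1 / 3)
    } else 1
    semi <- cfg$nucleus_semiaxes * s
    dims <- as.integer(ceiling((2 * semi + 2 * cfg$margin) / vx))
    ctr <- dims * vx / 2
    vol_true <- 4 / 3 * pi * prod(semi)

    xs <- .axis_centers(dims[1], vx[1]); ys <- .axis_centers(dims[2], vx[2])
    zs <- .axis_centers(dims[3], vx[3])
    inside <- outer(outer(((xs - ctr[1]) / semi[1])^2,
                          ((ys - ctr[2]) / semi[2])^2, "+"),
                    ((zs - ctr[3]) / semi[3])^2, "+") <= 1

    bg <- cfg$noise$background; amp <- cfg$noise$amplitude
    channels <- list()
    channels$dapi <- array(bg, dims) + amp * inside

    n_overlap <- 0L
    if (has_cc) {
      k <- .sample_count(cfg$chromocenter_count_law, 1)
      cc_img <- array(bg, dims)
      if (k > 0) {
        vl <- cfg$chromocenter_volume_law
        lp <- .lnorm_pars(vl$mean, vl$sd)
        vols <- rlnorm(k, lp["meanlog"], lp["sdlog"])
        radii <- .sphere_radius(vols)
        pl <- .place_spheres(radii, ctr, semi, cfg$min_gap, cfg$max_attempts)
        n_overlap <- sum(pl$overlapping)
        for (j in seq_len(k))
          cc_img <- .add_sphere(cc_img, vx, pl$centers[j, ], radii[j], amp)
        truth_obj[[length(truth_obj) + 1L]] <- data.frame(
          nucleus_id = i, object_id = seq_len(k), channel = "centromere",
          x = pl$centers[, 1], y = pl$centers[, 2], z = pl$centers[, 3],
          volume = vols, radius = radii, radial_fraction = NA_real_,
          overlapping = pl$overlapping)
        if (has_focus) {
          off <- matrix(rnorm(3 * k, 0, cfg$focus_channel$offset_sd), ncol = 3)
          fc <- pl$centers + off
          focus_img <- array(bg, dims)
          for (j in seq_len(k))
            focus_img <- .add_sphere(focus_img, vx, fc[j, ], radii[j], amp)
          channels$h3k9me3 <- .apply_imaging(focus_img, cfg)
          truth_obj[[length(truth_obj) + 1L]] <- data.frame(
            nucleus_id = i, object_id = seq_len(k), channel = "h3k9me3",
            x = fc[, 1], y = fc[, 2], z = fc[, 3],
            volume = vols, radius = radii, radial_fraction = NA_real_,
            overlapping = pl$overlapping)
        }
      } else if (has_focus) {
        channels$h3k9me3 <- .apply_imaging(array(bg, dims), cfg)
      }
      channels$centromere <- .apply_imaging(cc_img, cfg)
    }

    if (has_locus) {
      sp <- place_locus_spots(cfg$locus_law, cfg$spots_per_nucleus,
                              list(center = ctr, semiaxes = semi))
      loc_img <- array(bg, dims)
      for (j in seq_len(nrow(sp)))
        loc_img <- .add_sphere(loc_img, vx, as.numeric(sp[j, 1:3]),
                               cfg$spot_radius, amp)
      channels$locus <- .apply_imaging(loc_img, cfg)
      truth_obj[[length(truth_obj) + 1L]] <- data.frame(
        nucleus_id = i, object_id = seq_len(nrow(sp)), channel = "locus",
        x = sp$x, y = sp$y, z = sp$z,
        volume = 4 / 3 * pi * cfg$spot_radius^3, radius = cfg$spot_radius,
        radial_fraction = sp$radial_fraction, overlapping = FALSE)
    }

    channels$dapi <- .apply_imaging(channels$dapi, cfg)
    grids <- lapply(names(channels), function(nm)
      voxel_grid(channels[[nm]], vx, nm))
    names(grids) <- names(channels)

    nuclei[[i]] <- list(id = i, channels = grids, semiaxes = semi,
                        center = ctr, dims = dims)
    truth_nuc[[i]] <- data.frame(nucleus_id = i, volume = vol_true,
                                 a = semi[1], b = semi[2], c = semi[3],
                                 n_overlapping = n_overlap)
  }

  objects <- if (length(truth_obj)) do.call(rbind, truth_obj) else
    data.frame(nucleus_id = integer(0), object_id = integer(0),
               channel = character(0), x = numeric(0), y = numeric(0),
               z = numeric(0), volume = numeric(0), radius = numeric(0),
               radial_fraction = numeric(0), overlapping = logical(0))
  nuc_df <- if (length(truth_nuc)) do.call(rbind, truth_nuc) else
    data.frame(nucleus_id = integer(0), volume = numeric(0), a = numeric(0),
               b = numeric(0), c = numeric(0), n_overlapping = integer(0))

  warnings <- character(0)
  if (nrow(objects) > 0) {
    ov_frac <- mean(objects$overlapping)
    if (ov_frac > cfg$overlap_cap)
      warnings <- sprintf("overlapping-object fraction %.3f exceeds cap %.3f",
                          ov_frac, cfg$overlap_cap)
  }

  structure(list(nuclei = nuclei,
                 truth = list(nuclei = nuc_df, objects = objects,
                              warnings = warnings),
                 config = config),
            class = "nuclei_dataset")
}

#' @export
print.nuclei_dataset <- function(x, ...) {
  cat(sprintf("<nuclei_dataset> %d nuclei, %d truth objects, seed %d\n",
              length(x$nuclei), nrow(x$truth$objects), x$config$seed))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' One 16-bit multi-page TIFF per nucleus per channel
#' (`nucleus<i>_<channel>.tif`, one page per z-slice), a `voxel_size.json`
#' sidecar with the grid geometry, the ground truth as `truth.json`, and the
#' generating configuration as `dataset.yaml`.
#'
#' @param dataset a `nuclei_dataset`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_nuclei_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "nuclei_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nuc in dataset$nuclei) {
    for (ch in names(nuc$channels)) {
      path <- file.path(dir, sprintf("nucleus%03d_%s.tif", nuc$id, ch))
      write_voxel_grid(nuc$channels[[ch]], path)
      files <- c(files, path)
    }
  }
  sidecar <- file.path(dir, "voxel_size.json")
  jsonlite::write_json(list(voxel_size_um = dataset$config$voxel_size),
                       sidecar, auto_unbox = FALSE, digits = NA)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(dataset$truth, truth_path, dataframe = "columns",
                       auto_unbox = FALSE, digits = NA)
  cfg_path <- file.path(dir, "dataset.yaml")
  cfg <- dataset$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, cfg_path)
  invisible(c(files, sidecar, truth_path, cfg_path))
}

#' Write one voxel grid as a 16-bit multi-page TIFF
#'
#' Intensities are stored as rounded counts (clamped to 0..65535); one TIFF
#' page per z-slice.
#'
#' @param grid a `voxel_grid`.
#' @param path output file path.
#' @export
write_voxel_grid <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  img <- pmin(pmax(round(grid$intensities), 0), 65535)
  pages <- lapply(seq_len(dim(img)[3]), function(k) img[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF z-stack as a voxel grid
#'
#' @param path TIFF file path (one page per z-slice, as written by
#'   [write_voxel_grid()]).
#' @param voxel_size length-3 voxel size in microns, or the path of a JSON
#'   sidecar holding `voxel_size_um`.
#' @param channel channel label for the resulting grid.
#' @return A [voxel_grid()], with intensities on the original count scale.
#' @export
read_voxel_grid <- function(path, voxel_size, channel = "unknown") {
  if (is.character(voxel_size)) {
    meta <- jsonlite::read_json(voxel_size, simplifyVector = TRUE)
    voxel_size <- as.numeric(meta$voxel_size_um)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * 65535
  voxel_grid(round(arr), voxel_size, channel)
}
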