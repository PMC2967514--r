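#' Run an end-to-end analysis pipeline
#'
#' Orchestrates the package's stages from one declarative configuration:
#' `simulate_images` -> `quantify` -> `radial` -> `compare` for the imaging
#' arm, and `simulate_expression` -> `enrich` for the expression arm. All
#' randomness flows from the one root seed: each stage draws from a seed
#' derived deterministically from the root seed, the stage name and its
#' position, so reruns of the same configuration are bit-identical and
#' adding a stage does not perturb the draws of the others.
#'
#' @param config a list (or the path of a YAML file) with fields `seed`
#'   (integer), `out_dir` (output directory) and `stages`: a list of
#'   `list(name = <stage>, params = <list>)` entries run in declared
#'   order. Supported stages and their main params:
#'   \describe{
#'     \item{simulate_images}{[generation_config()] arguments plus
#'       `condition` (label attached to downstream rows).}
#'     \item{quantify}{`channels` (default `"centromere"`), `min_volume`,
#'       `min_size`; consumes every simulated imaging condition.}
#'     \item{radial}{bins detected `locus` objects into shells; writes
#'       `radial.csv` and cumulative-distribution points.}
#'     \item{compare}{`metric` (`"volume"`, `"count"`, `"intensity"` or
#'       `"radial"`), `a`, `b` (condition labels); appends to
#'       `stats.json`.}
#'     \item{simulate_expression}{[generate_expression()] arguments; `sets`
#'       as a list of [planted_set()] argument lists.}
#'     \item{enrich}{`class` (tested class for permutation heat values),
#'       `class_a`, `class_b` (DE contrast), `n_perm`, optional `gene2go`
#'       path.}
#'   }
#' @return Invisibly, `list(status = 0, manifest = <list>)`. The manifest
#'   (also written as `manifest.json`) records per stage the name, derived
#'   seed, parameters and output files. A stage failure raises an error
#'   naming the stage after writing the partial manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- if (is.null(config$out_dir)) stop("config needs `out_dir`") else config$out_dir
  stages <- if (is.null(config$stages)) list() else config$stages
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ctx <- new.env(parent = emptyenv())
  ctx$imaging <- list(); ctx$quant <- NULL; ctx$radial <- NULL
  ctx$stats <- list(); ctx$expression <- NULL

  manifest <- list(seed = seed, out_dir = out_dir, stages = list())
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }

  for (i in seq_along(stages)) {
    st <- stages[[i]]
    nm <- st$name
    params <- if (is.null(st$params)) list() else st$params
    st_seed <- .stage_seed(seed, nm, i)
    outputs <- tryCatch(
      .run_stage(nm, params, st_seed, out_dir, ctx),
      error = function(e) {
        manifest$stages[[length(manifest$stages) + 1L]] <<-
          list(name = nm, seed = st_seed, params = params,
               error = conditionMessage(e))
        write_manifest()
        stop(sprintf("pipeline stage '%s' failed: %s", nm,
                     conditionMessage(e)), call. = FALSE)
      })
    manifest$stages[[length(manifest$stages) + 1L]] <-
      list(name = nm, seed = st_seed, params = params, outputs = outputs)
  }
  write_manifest()
  invisible(list(status = 0L, manifest = manifest))
}

# deterministic per-stage seed: root seed + a stage-name substream offset,
# kept inside the 32-bit integer range
.stage_seed <- function(seed, name, index) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) + 131L * index
  as.integer((as.numeric(seed) + 97L * h) %% 2147483647)
}

.run_stage <- function(name, params, st_seed, out_dir, ctx) {
  switch(name,
    simulate_images = {
      condition <- if (is.null(params$condition)) "condition1" else params$condition
      params$condition <- NULL
      params$seed <- st_seed
      cfg <- do.call(generation_config, params)
      ds <- generate_nuclei_dataset(cfg)
      ctx$imaging[[condition]] <- ds
      dir <- file.path(out_dir, paste0("images_", condition))
      write_nuclei_dataset(ds, dir)
      list.files(dir, full.names = TRUE)
    },
    quantify = {
      if (length(ctx$imaging) == 0L) stop("no simulated images to quantify")
      channels <- if (is.null(params$channels)) "centromere" else params$channels
      all_nuc <- list(); all_obj <- list(); masks <- list()
      for (cond in names(ctx$imaging)) {
        q <- quantify_dataset(ctx$imaging[[cond]], channels = channels,
                              condition = cond,
                              min_volume = if (is.null(params$min_volume)) 30 else params$min_volume,
                              min_size = if (is.null(params$min_size)) 8L else params$min_size)
        off <- length(masks)
        q$nuclei$nucleus_id <- q$nuclei$nucleus_id + off
        if (nrow(q$objects)) q$objects$nucleus_id <- q$objects$nucleus_id + off
        masks <- c(masks, q$masks)
        all_nuc[[cond]] <- q$nuclei
        all_obj[[cond]] <- q$objects
      }
      ctx$quant <- list(nuclei = do.call(rbind, all_nuc),
                        objects = do.call(rbind, all_obj), masks = masks)
      f1 <- file.path(out_dir, "nuclei.csv")
      f2 <- file.path(out_dir, "objects.csv")
      write.csv(ctx$quant$nuclei, f1, row.names = FALSE)
      write.csv(ctx$quant$objects, f2, row.names = FALSE)
      c(f1, f2)
    },
    radial = {
      if (is.null(ctx$quant)) stop("quantify must run before radial")
      loci <- ctx$quant$objects[ctx$quant$objects$channel == "locus", , drop = FALSE]
      rec <- radial_records(loci, ctx$quant$masks)
      ctx$radial <- rec
      f1 <- file.path(out_dir, "radial.csv")
      write.csv(rec, f1, row.names = FALSE)
      f2 <- file.path(out_dir, "radial_cumulative.csv")
      cums <- lapply(split(rec$radial_fraction, rec$condition), function(fr) {
        h <- shell_histogram(fr)
        h$cum
      })
      cum_df <- do.call(rbind, lapply(names(cums), function(cd)
        cbind(condition = cd, cums[[cd]])))
      write.csv(cum_df, f2, row.names = FALSE)
      c(f1, f2)
    },
    compare = {
      if (is.null(ctx$quant)) stop("quantify must run before compare")
      metric <- params$metric
      a <- params$a; b <- params$b
      obj <- ctx$quant$objects; nuc <- ctx$quant$nuclei
      pick_obj <- function(cond) obj[!is.na(obj$condition) & obj$condition == cond, , drop = FALSE]
      res <- switch(metric,
        volume = compare_means(pick_obj(a)$volume, pick_obj(b)$volume),
        intensity = compare_means(pick_obj(a)$mean_intensity,
                                  pick_obj(b)$mean_intensity),
        count = {
          per_nuc <- function(cond) {
            nn <- nuc[nuc$condition == cond, , drop = FALSE]
            oo <- pick_obj(cond)
            as.integer(table(factor(oo$nucleus_id, levels = nn$nucleus_id)))
          }
          compare_counts(per_nuc(a), per_nuc(b))
        },
        radial = {
          if (is.null(ctx$radial)) stop("radial must run before radial compare")
          ra <- ctx$radial[ctx$radial$condition == a, "radial_fraction"]
          rb <- ctx$radial[ctx$radial$condition == b, "radial_fraction"]
          ks_compare(ra, rb)
        },
        stop("unknown compare metric: ", metric))
      ctx$stats[[paste(metric, a, "vs", b, sep = "_")]] <- res
      f <- file.path(out_dir, "stats.json")
      jsonlite::write_json(ctx$stats, f, auto_unbox = TRUE, digits = NA)
      f
    },
    simulate_expression = {
      params$seed <- st_seed
      if (!is.null(params$sets))
        params$sets <- lapply(params$sets, function(s) do.call(planted_set, s))
      ds <- do.call(generate_expression, params)
      ctx$expression <- ds
      dir <- file.path(out_dir, "expression")
      write_expression_dataset(ds, dir)
      list.files(dir, full.names = TRUE)
    },
    enrich = {
      if (is.null(ctx$expression)) stop("simulate_expression must run before enrich")
      ds <- ctx$expression
      class_a <- params$class_a; class_b <- params$class_b
      de <- gene_de_test(ds$expr, ds$classes, class_a, class_b)
      f_de <- file.path(out_dir, "de.tsv")
      utils::write.table(de, f_de, sep = "\t", quote = FALSE, row.names = FALSE)
      cr <- chromosome_ratio(attr(de, "de_genes"), ds$gene2chrom)
      f_cr <- file.path(out_dir, "chrom_ratio.tsv")
      utils::write.table(cr$ratios, f_cr, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      outs <- c(f_de, f_cr)
      if (length(ds$sets)) {
        cls <- if (is.null(params$class)) unique(ds$classes) else params$class
        n_perm <- if (is.null(params$n_perm)) 10000L else as.integer(params$n_perm)
        results <- list()
        for (cl in cls) for (s in ds$sets)
          results[[length(results) + 1L]] <-
            permutation_heat_value(ds$expr, s$genes, ds$classes, cl,
                                   n_perm = n_perm, seed = st_seed,
                                   set_name = s$name)
        f_perm <- file.path(out_dir, "permutation.tsv")
        perm_df <- do.call(rbind, lapply(results, function(r)
          data.frame(set = r$set, class = r$class, observed = r$observed,
                     N = r$N, n_up = r$n_up, n_down = r$n_down,
                     heat = r$heat, mode = r$mode)))
        utils::write.table(perm_df, f_perm, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        ht <- heatmap_table(results)
        f_heat <- file.path(out_dir, "heatmap.tsv")
        utils::write.table(data.frame(set = rownames(ht$values), ht$values,
                                      check.names = FALSE),
                           f_heat, sep = "\t", quote = FALSE, row.names = FALSE)
        outs <- c(outs, f_perm, f_heat)
      }
      if (!is.null(params$gene2go)) {
        g2g <- read.delim(params$gene2go)
        enr <- go_enrichment(attr(de, "de_genes"), rownames(ds$expr), g2g)
        f_enr <- file.path(out_dir, "enrichment.tsv")
        utils::write.table(enr, f_enr, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        outs <- c(outs, f_enr)
      }
      outs
    },
    stop("unknown pipeline stage: ", name))
}
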