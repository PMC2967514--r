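#' Declare a planted gene set for the expression generator
#'
#' @param name set name (GMT-compatible, no tabs).
#' @param size number of member genes.
#' @param direction `"up"`, `"down"` or `"null"`.
#' @param delta absolute expression shift in log2 units applied to member
#'   genes in the affected class (ignored for `"null"`).
#' @param class affected class label (ignored for `"null"`).
#' @param genes optional explicit member gene ids; by default members are
#'   drawn at random (disjointly across sets) by the generator.
#' @return list describing the set.
#' @export
planted_set <- function(name, size, direction = c("null", "up", "down"),
                        delta = 0, class = NA_character_, genes = NULL) {
  direction <- match.arg(direction)
  if (!is.null(genes)) size <- length(genes)
  list(name = name, size = as.integer(size), direction = direction,
       delta = delta, class = class, genes = genes)
}

#' Generate a synthetic expression matrix with planted gene-set regulation
#'
#' Emulates the downstream product of a normalized microarray experiment: a
#' log2-scale genes x samples matrix over a multi-class design (default 3
#' classes - untreated control, receptor-blocking antibody, growth-factor
#' stimulation - with 3 independent replicates each). Per-gene baselines
#' are drawn once; genes of each planted set are shifted by +/- delta in
#' the affected class; i.i.d. Gaussian noise is added per cell. Chromosome
#' labels are assigned per gene with configurable density.
#'
#' @param n_genes number of genes.
#' @param classes class labels (character).
#' @param n_replicates replicates per class.
#' @param sets list of [planted_set()] declarations. Randomly drawn sets
#'   are disjoint by construction; sets with explicit `genes` may overlap,
#'   but overlapping planted effects must agree - conflicting directions
#'   raise an error.
#' @param noise_sd per-cell Gaussian noise sd in log2 units (default 0.25).
#' @param baseline_mean,baseline_sd distribution of per-gene baseline log2
#'   expression.
#' @param n_chromosomes number of chromosomes for the gene map (default 20,
#'   a mouse-like karyotype).
#' @param chromosome_weights optional relative gene densities per
#'   chromosome (default uniform).
#' @param seed integer seed; the dataset is deterministic given the
#'   arguments.
#' @return An object of class `expression_dataset`: `expr` (matrix, genes x
#'   samples, log2), `classes` (character vector named by sample),
#'   `gene2chrom` (data.frame `gene`, `chrom`), `sets` (list of
#'   `list(name, description, genes)`), and `truth` (list with per-set and
#'   per-gene data.frames of planted effects).
#' @export
generate_expression <- function(n_genes = 10000L,
                                classes = c("control", "antibody", "hgf"),
                                n_replicates = 3L,
                                sets = list(),
                                noise_sd = 0.25,
                                baseline_mean = 7, baseline_sd = 1.5,
                                n_chromosomes = 20L,
                                chromosome_weights = NULL,
                                seed = 1L) {
  stopifnot(n_genes >= 1L, n_replicates >= 2L, noise_sd > 0)
  set.seed(as.integer(seed))
  genes <- sprintf("g%05d", seq_len(n_genes))
  samples <- as.vector(t(outer(classes, seq_len(n_replicates),
                               function(cl, r) paste0(cl, "_", r))))
  cls <- setNames(rep(classes, each = n_replicates), samples)

  # planted effects per gene, with conflict detection
  effect_dir <- setNames(rep("null", n_genes), genes)
  effect_delta <- setNames(numeric(n_genes), genes)
  effect_class <- setNames(rep(NA_character_, n_genes), genes)
  set_defs <- list()
  truth_sets <- list()
  available <- genes
  for (s in sets) {
    if (s$size > n_genes) stop("set size exceeds number of genes: ", s$name)
    if (!is.null(s$genes)) {
      members <- s$genes
      if (!all(members %in% genes))
        stop("explicit set genes outside the gene universe: ", s$name)
    } else {
      if (s$size > length(available))
        stop("not enough unassigned genes left for set: ", s$name)
      members <- sample(available, s$size)
      available <- setdiff(available, members)
    }
    if (s$direction != "null") {
      shift <- if (s$direction == "up") s$delta else -s$delta
      clash <- members[effect_dir[members] != "null" &
                       (effect_dir[members] != s$direction |
                        effect_delta[members] != shift |
                        effect_class[members] != s$class)]
      if (length(clash))
        stop("overlapping planted sets assign conflicting effects to gene(s): ",
             paste(head(clash, 3), collapse = ", "))
      effect_dir[members] <- s$direction
      effect_delta[members] <- shift
      effect_class[members] <- s$class
    }
    set_defs[[length(set_defs) + 1L]] <-
      list(name = s$name, description = sprintf("planted_%s", s$direction),
           genes = members)
    truth_sets[[length(truth_sets) + 1L]] <-
      data.frame(set = s$name, size = s$size, direction = s$direction,
                 delta = s$delta, class = s$class)
  }

  baseline <- rnorm(n_genes, baseline_mean, baseline_sd)
  expr <- matrix(rep(baseline, length(samples)), nrow = n_genes,
                 dimnames = list(genes, samples))
  for (g in which(effect_dir != "null")) {
    affected <- cls == effect_class[g]
    expr[g, affected] <- expr[g, affected] + effect_delta[g]
  }
  expr <- expr + matrix(rnorm(length(expr), 0, noise_sd), nrow = n_genes)

  w <- if (is.null(chromosome_weights)) rep(1, n_chromosomes) else chromosome_weights
  stopifnot(length(w) == n_chromosomes, all(w > 0))
  chrom <- sample(paste0("chr", seq_len(n_chromosomes)), n_genes,
                  replace = TRUE, prob = w / sum(w))

  structure(list(
    expr = expr,
    classes = cls,
    gene2chrom = data.frame(gene = genes, chrom = chrom),
    sets = set_defs,
    truth = list(
      sets = if (length(truth_sets)) do.call(rbind, truth_sets) else
        data.frame(set = character(0), size = integer(0),
                   direction = character(0), delta = numeric(0),
                   class = character(0)),
      genes = data.frame(gene = genes, chrom = chrom,
                         direction = unname(effect_dir),
                         delta = unname(effect_delta),
                         class = unname(effect_class),
                         de = unname(effect_dir != "null")),
      noise_sd = noise_sd, seed = as.integer(seed))),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d genes x %d samples (%s), %d sets planted\n",
              nrow(x$expr), ncol(x$expr),
              paste(unique(x$classes), collapse = "/"), length(x$sets)))
  invisible(x)
}

#' Write an expression dataset to disk
#'
#' Writes `expr.tsv` (genes x samples, log2 values), `classes.tsv`
#' (sample, class), `sets.gmt`, `gene2chrom.tsv` and `truth.json`.
#'
#' @param dataset an `expression_dataset`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the files written.
#' @export
write_expression_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "expression_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f_expr <- file.path(dir, "expr.tsv")
  df <- data.frame(gene = rownames(dataset$expr), dataset$expr,
                   check.names = FALSE)
  utils::write.table(df, f_expr, sep = "\t", quote = FALSE, row.names = FALSE)
  f_cls <- file.path(dir, "classes.tsv")
  utils::write.table(data.frame(sample = names(dataset$classes),
                                class = unname(dataset$classes)),
                     f_cls, sep = "\t", quote = FALSE, row.names = FALSE)
  f_gmt <- file.path(dir, "sets.gmt")
  write_gmt(dataset$sets, f_gmt)
  f_map <- file.path(dir, "gene2chrom.tsv")
  utils::write.table(dataset$gene2chrom, f_map, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  f_truth <- file.path(dir, "truth.json")
  jsonlite::write_json(dataset$truth, f_truth, dataframe = "columns",
                       auto_unbox = FALSE, digits = NA, na = "null")
  invisible(c(f_expr, f_cls, f_gmt, f_map, f_truth))
}

#' Read an expression matrix and class labels from TSV files
#'
#' @param expr_path TSV with a `gene` column followed by one column per
#'   sample.
#' @param classes_path TSV with `sample` and `class` columns.
#' @return list with `expr` (matrix) and `classes` (named character).
#' @export
read_expression <- function(expr_path, classes_path) {
  df <- read.delim(expr_path, check.names = FALSE)
  expr <- as.matrix(df[, -1, drop = FALSE])
  rownames(expr) <- df[[1]]
  cl <- read.delim(classes_path)
  classes <- setNames(as.character(cl$class), cl$sample)
  classes <- classes[colnames(expr)]
  list(expr = expr, classes = classes)
}
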