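#' Per-gene differential expression test between two classes
#'
#' Two-sided pooled-variance Student t test per gene on log2 expression
#' values, uncorrected; genes with `p < alpha` form the differentially
#' expressed (DE) list. This is the stand-in per-gene test of the pipeline,
#' operating on an already-normalized matrix. The pooled form is used
#' because, at the design's three replicates per class, the
#' Welch-Satterthwaite approximation is markedly conservative (empirical
#' size ~3.5% at nominal 5%), while the pooled test is exactly calibrated
#' under homoscedastic noise. Genes with zero variance in both classes are
#' assigned `p = 1` and flagged.
#'
#' @param expr genes x samples matrix of log2 expression.
#' @param classes character vector of class labels, one per column.
#' @param class_a,class_b the two class labels to compare (each with >= 2
#'   samples).
#' @param alpha significance threshold for the DE list (default 0.05).
#' @return data.frame with one row per gene: `gene`, `mean_a`, `mean_b`,
#'   `t`, `df`, `p`, `flagged`, `de`; attribute `de_genes` holds the DE
#'   gene ids.
#' @export
gene_de_test <- function(expr, classes, class_a, class_b, alpha = 0.05) {
  stopifnot(is.matrix(expr), length(classes) == ncol(expr))
  ia <- which(classes == class_a); ib <- which(classes == class_b)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("each class needs at least two samples")
  na <- length(ia); nb <- length(ib)
  xa <- expr[, ia, drop = FALSE]; xb <- expr[, ib, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se2 <- sp2 * (1 / na + 1 / nb)
  flagged <- se2 == 0
  tstat <- ifelse(flagged, 0, (ma - mb) / sqrt(se2))
  df <- ifelse(flagged, NA_real_, na + nb - 2)
  p <- ifelse(flagged, 1, 2 * pt(-abs(tstat), df))
  if (any(flagged))
    message("gene_de_test: ", sum(flagged),
            " gene(s) with zero within-class variance set to p = 1")
  out <- data.frame(gene = rownames(expr), mean_a = ma, mean_b = mb,
                    t = tstat, df = df, p = p, flagged = flagged,
                    de = p < alpha, row.names = NULL)
  attr(out, "de_genes") <- out$gene[out$de]
  attr(out, "alpha") <- alpha
  out
}

#' Per-chromosome differential-expression density ratio
#'
#' For each chromosome, the number of DE genes mapping to it divided by the
#' total number of genes mapping to it; a flat profile indicates that
#' de-regulation is evenly distributed over the genome rather than driven
#' by gene density.
#'
#' @param de_genes character vector of DE gene ids.
#' @param gene2chrom data.frame with `gene` and `chrom` columns covering
#'   the gene universe.
#' @return list with `ratios` (data.frame `chrom`, `n_de`, `n_total`,
#'   `ratio`) and `unmapped` (DE genes absent from the map; reported, never
#'   silently dropped).
#' @export
chromosome_ratio <- function(de_genes, gene2chrom) {
  stopifnot(all(c("gene", "chrom") %in% names(gene2chrom)))
  unmapped <- setdiff(de_genes, gene2chrom$gene)
  mapped <- intersect(de_genes, gene2chrom$gene)
  tot <- table(gene2chrom$chrom)
  de <- table(factor(gene2chrom$chrom[gene2chrom$gene %in% mapped],
                     levels = names(tot)))
  ratios <- data.frame(chrom = names(tot),
                       n_de = as.integer(de),
                       n_total = as.integer(tot),
                       ratio = as.numeric(de / tot),
                       row.names = NULL)
  list(ratios = ratios, unmapped = unmapped)
}

# per-sample mean expression profile over the present set genes
.set_profile <- function(expr, genes) {
  present <- intersect(genes, rownames(expr))
  n_dropped <- length(setdiff(genes, present))
  if (length(present) == 0L)
    stop(structure(class = c("nucleoscape_empty_set", "error", "condition"),
                   list(message = "EmptySet: no set gene present in the matrix",
                        call = sys.call())))
  if (n_dropped > 0)
    message("set genes absent from matrix and dropped: ", n_dropped)
  list(profile = colMeans(expr[present, , drop = FALSE]),
       n_used = length(present), n_dropped = n_dropped)
}

#' Observed class-versus-rest score of a gene set
#'
#' The mean, over set genes present in the matrix, of (mean expression in
#' the tested class - mean expression in all other classes), in log2
#' units. Positive scores indicate up-regulation in the class.
#'
#' @param expr genes x samples matrix.
#' @param genes character vector of set gene ids (absent genes are dropped
#'   with a message; an entirely absent set raises a
#'   `nucleoscape_empty_set` error).
#' @param classes character vector of class labels, one per column.
#' @param class the class tested against the rest.
#' @return Numeric score.
#' @export
set_score <- function(expr, genes, classes, class) {
  stopifnot(length(classes) == ncol(expr))
  pr <- .set_profile(expr, genes)
  idx <- classes == class
  if (!any(idx) || all(idx)) stop("class must select a proper subset of samples")
  mean(pr$profile[idx]) - mean(pr$profile[!idx])
}

#' Permutation heat-plot value for a gene set
#'
#' Recomputes the class-versus-rest set score under permutations of the
#' class-versus-rest sample membership. With `n_up` the number of permuted
#' scores greater than or equal to the observed score and `n_down` the
#' number less than or equal (ties count in both tails), the heat value is
#' `1 - n_up/N` when the observed score is non-negative (up-regulation:
#' values near 1 are significant) and `n_down/N` when negative
#' (down-regulation: values near 0 are significant), so both directions
#' co-plot on one `[0, 1]` color scale. When the number of distinct
#' class-versus-rest splits is at most `n_perm`, all splits are enumerated
#' exactly instead of sampled.
#'
#' @inheritParams set_score
#' @param n_perm permutation budget N (default 10000).
#' @param seed integer seed for the sampled mode.
#' @param set_name optional label carried into the result.
#' @param mode `"auto"` (exhaustive when the number of distinct splits is
#'   at most `n_perm`, sampled otherwise), or force `"sampled"` /
#'   `"exhaustive"` (the latter errors if there are more splits than
#'   `n_perm` would ever enumerate sensibly; used mainly to validate the
#'   sampler against the exact enumeration).
#' @return An object of class `permutation_result`: `set`, `class`,
#'   `observed` (log2 units), `N`, `n_up`, `n_down`, `heat` in `[0, 1]`,
#'   `mode` (`"exhaustive"` or `"sampled"`), `seed`, `n_genes_used`,
#'   `n_genes_dropped`.
#' @export
permutation_heat_value <- function(expr, genes, classes, class,
                                   n_perm = 10000L, seed = NULL,
                                   set_name = NA_character_,
                                   mode = c("auto", "sampled", "exhaustive")) {
  mode <- match.arg(mode)
  stopifnot(length(classes) == ncol(expr))
  k <- sum(classes == class)
  n <- length(classes)
  if (k < 2L || n - k < 2L)
    stop("degenerate class sizes: need >= 2 samples in the class and >= 2 outside")
  pr <- .set_profile(expr, genes)
  g <- pr$profile
  gsum <- sum(g)
  score_of <- function(idx) {
    si <- sum(g[idx])
    si / k - (gsum - si) / (n - k)
  }
  obs <- score_of(which(classes == class))

  n_splits <- choose(n, k)
  if (mode == "auto")
    mode <- if (n_splits <= n_perm) "exhaustive" else "sampled"
  if (mode == "exhaustive") {
    if (n_splits > 1e6) stop("too many distinct splits for exhaustive enumeration")
    splits <- utils::combn(n, k)
    scores <- apply(splits, 2, score_of)
    N <- as.integer(n_splits)
  } else {
    if (!is.null(seed)) set.seed(as.integer(seed))
    scores <- vapply(seq_len(n_perm),
                     function(i) score_of(sample.int(n, k)), numeric(1))
    N <- as.integer(n_perm)
  }
  n_up <- sum(scores >= obs)
  n_down <- sum(scores <= obs)
  heat <- if (obs >= 0) 1 - n_up / N else n_down / N
  structure(list(set = set_name, class = class, observed = obs, N = N,
                 n_up = n_up, n_down = n_down, heat = heat, mode = mode,
                 seed = seed, n_genes_used = pr$n_used,
                 n_genes_dropped = pr$n_dropped),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> set %s vs class '%s': score %.4f, heat %.4f (%s, N = %d)\n",
              x$set, x$class, x$observed, x$heat, x$mode, x$N))
  invisible(x)
}

#' Hypergeometric GO over-representation with Holm correction
#'
#' For each GO category, the upper-tail hypergeometric probability of
#' observing at least the seen overlap between the DE list and the
#' category, given the annotated universe; raw p-values are adjusted across
#' all tested categories by the Holm step-down method. Genes without any
#' GO annotation are excluded from both the universe and the DE list (the
#' exclusion count is messaged).
#'
#' @param de_genes character vector of DE gene ids (must be a subset of
#'   `universe`).
#' @param universe character vector of all tested gene ids.
#' @param gene2go data.frame with `gene` and `go` columns.
#' @param min_size smallest category size tested (default 1).
#' @return data.frame ordered by raw p: `go_id`, `n_array` (category size
#'   in the annotated universe), `n_de` (DE genes in the category), `p`
#'   (raw hypergeometric), `p_holm`.
#' @export
go_enrichment <- function(de_genes, universe, gene2go, min_size = 1L) {
  if (length(universe) == 0L) stop("empty universe")
  if (!all(de_genes %in% universe))
    stop("`de_genes` must be a subset of `universe`")
  stopifnot(all(c("gene", "go") %in% names(gene2go)))
  covered <- intersect(universe, unique(gene2go$gene))
  n_excl <- length(universe) - length(covered)
  if (n_excl > 0)
    message("go_enrichment: ", n_excl, " unannotated gene(s) excluded from universe and DE list")
  if (length(covered) == 0L) stop("no annotated genes in universe")
  de <- intersect(de_genes, covered)
  M <- length(covered)
  n <- length(de)
  map <- gene2go[gene2go$gene %in% covered, c("gene", "go")]
  map <- unique(map)
  cats <- split(map$gene, map$go)
  cats <- cats[lengths(cats) >= min_size]
  if (length(cats) == 0L)
    return(data.frame(go_id = character(0), n_array = integer(0),
                      n_de = integer(0), p = numeric(0), p_holm = numeric(0)))
  m <- lengths(cats)
  kk <- vapply(cats, function(gs) length(intersect(gs, de)), integer(1))
  p <- phyper(kk - 1, m, M - m, n, lower.tail = FALSE)
  out <- data.frame(go_id = names(cats), n_array = as.integer(m),
                    n_de = as.integer(kk), p = as.numeric(p),
                    p_holm = p.adjust(p, method = "holm"), row.names = NULL)
  out[order(out$p), ]
}

#' Assemble permutation results into a heat-plot table
#'
#' @param results list of `permutation_result` objects (one per set x class
#'   pair; each must carry a `set` name).
#' @param sets,classes optional row/column orders; default: order of first
#'   appearance. Missing pairs are reported (message) and left `NA`.
#' @return An object of class `heat_table`: `values` (sets x classes matrix
#'   of heat values in `[0, 1]`) and `significant` (logical matrix; a cell
#'   with `0.05 < value < 0.95` is non-significant).
#' @export
heatmap_table <- function(results, sets = NULL, classes = NULL) {
  rsets <- vapply(results, function(r) as.character(r$set), character(1))
  rcls <- vapply(results, function(r) as.character(r$class), character(1))
  if (anyNA(rsets)) stop("every permutation_result needs a set name")
  if (is.null(sets)) sets <- unique(rsets)
  if (is.null(classes)) classes <- unique(rcls)
  values <- matrix(NA_real_, length(sets), length(classes),
                   dimnames = list(sets, classes))
  for (r in results) values[as.character(r$set), as.character(r$class)] <- r$heat
  missing <- which(is.na(values), arr.ind = TRUE)
  if (nrow(missing))
    message("heatmap_table: ", nrow(missing), " missing set x class cell(s)")
  significant <- values <= 0.05 | values >= 0.95
  structure(list(values = values, significant = significant),
            class = "heat_table")
}

#' @export
print.heat_table <- function(x, ...) {
  cat("<heat_table>", nrow(x$values), "sets x", ncol(x$values), "classes\n")
  print(round(x$values, 4))
  invisible(x)
}
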