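# Shared fixtures and independent oracles, all built in code.

# Render an axis-aligned ellipsoid indicator (value inside, bg outside) on a
# fresh grid; independent of the package's generator internals.
render_ellipsoid <- function(semi, voxel_size = c(0.2, 0.2, 0.25),
                             margin = 0.8, value = 100, bg = 0,
                             center = NULL, dims = NULL) {
  if (is.null(dims)) dims <- ceiling((2 * semi + 2 * margin) / voxel_size)
  if (is.null(center)) center <- dims * voxel_size / 2
  xs <- (seq_len(dims[1]) - 0.5) * voxel_size[1]
  ys <- (seq_len(dims[2]) - 0.5) * voxel_size[2]
  zs <- (seq_len(dims[3]) - 0.5) * voxel_size[3]
  inside <- outer(outer(((xs - center[1]) / semi[1])^2,
                        ((ys - center[2]) / semi[2])^2, "+"),
                  ((zs - center[3]) / semi[3])^2, "+") <= 1
  array(bg + (value - bg) * inside, dims)
}

# add a solid sphere to an existing array (independent re-implementation)
add_sphere_fixture <- function(img, voxel_size, center, radius, value = 100) {
  dims <- dim(img)
  xs <- (seq_len(dims[1]) - 0.5) * voxel_size[1]
  ys <- (seq_len(dims[2]) - 0.5) * voxel_size[2]
  zs <- (seq_len(dims[3]) - 0.5) * voxel_size[3]
  d2 <- outer(outer((xs - center[1])^2, (ys - center[2])^2, "+"),
              (zs - center[3])^2, "+")
  img + value * (d2 <= radius^2)
}

# O(n^2) two-sample KS statistic: max absolute ECDF difference over all
# pooled evaluation points
ks_D_bruteforce <- function(a, b) {
  pts <- c(a, b)
  max(vapply(pts, function(t) abs(mean(a <= t) - mean(b <= t)), numeric(1)))
}

# Brute-force upper-tail hypergeometric by enumerating every size-n draw
# from a universe of M genes of which the first m form the category.
phyper_bruteforce <- function(M, m, n, k) {
  draws <- utils::combn(M, n)
  overlap <- colSums(draws <= m)
  mean(overlap >= k)
}

# go_enrichment wrapper producing an exact (M, m, n, k) configuration:
# universe g1..gM, category A = first m genes, B = the rest (so the map
# covers the universe), DE list with overlap exactly k.
run_enrichment_case <- function(M, m, n, k) {
  genes <- sprintf("g%02d", seq_len(M))
  cat_a <- genes[seq_len(m)]
  map <- rbind(data.frame(gene = cat_a, go = "A"),
               if (m < M) data.frame(gene = genes[(m + 1):M], go = "B"))
  de <- c(cat_a[seq_len(k)], setdiff(genes, cat_a)[seq_len(n - k)])
  res <- go_enrichment(de, genes, map)
  res[res$go_id == "A", ]
}

# small noiseless 3-class expression matrix with a shifted gene set
make_shifted_expression <- function(n_genes = 50, set_size = 5, delta = 1,
                                    class = "antibody",
                                    classes = rep(c("control", "antibody", "hgf"), each = 3),
                                    baseline = 5) {
  genes <- sprintf("g%03d", seq_len(n_genes))
  expr <- matrix(baseline, n_genes, length(classes),
                 dimnames = list(genes, paste0(classes, "_", seq_along(classes))))
  set_genes <- genes[seq_len(set_size)]
  expr[set_genes, classes == class] <- baseline + delta
  list(expr = expr, classes = classes, set_genes = set_genes)
}
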