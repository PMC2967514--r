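test_that("a constant gene is flagged with p = 1", {
  expr <- rbind(flat = rep(5, 6), vary = c(1, 2, 3, 7, 8, 9))
  classes <- rep(c("a", "b"), each = 3)
  expect_message(res <- gene_de_test(expr, classes, "a", "b"), "zero within-class")
  expect_equal(res$p[res$gene == "flat"], 1)
  expect_true(res$flagged[res$gene == "flat"])
  expect_lt(res$p[res$gene == "vary"], 0.05)
})

test_that("planted shifts of 4 noise-sd are detected at >= 90% power with n = 3", {
  sets <- list(planted_set("UP", 500, "up", delta = 1, class = "antibody"))
  ds <- generate_expression(n_genes = 2000, sets = sets, noise_sd = 0.25, seed = 13)
  res <- gene_de_test(ds$expr, ds$classes, "antibody", "control")
  planted <- ds$sets[[1]]$genes
  expect_gte(mean(res$de[res$gene %in% planted]), 0.90)
})

test_that("chromosome ratios are exact on hand-counted maps", {
  map <- data.frame(gene = sprintf("g%02d", 1:30),
                    chrom = rep(c("chr1", "chr2"), c(20, 10)))
  de <- c(sprintf("g%02d", 1:4), "g21")   # chr1: 4/20, chr2: 1/10
  cr <- chromosome_ratio(de, map)
  expect_equal(cr$ratios$ratio[cr$ratios$chrom == "chr1"], 0.2)
  expect_equal(cr$ratios$ratio[cr$ratios$chrom == "chr2"], 0.1)
  expect_identical(cr$unmapped, character(0))
  # conservation: per-chromosome DE counts sum to the mapped DE total
  expect_equal(sum(cr$ratios$n_de), length(intersect(de, map$gene)))

  all_de <- chromosome_ratio(map$gene, map)
  expect_true(all(all_de$ratios$ratio == 1))
  none <- chromosome_ratio(character(0), map)
  expect_true(all(none$ratios$ratio == 0))
  um <- chromosome_ratio(c("g01", "gX"), map)
  expect_identical(um$unmapped, "gX")
})

test_that("set_score equals the hand-computed class-versus-rest difference", {
  expr <- matrix(5, 3, 4, dimnames = list(c("g1", "g2", "g3"), NULL))
  classes <- c("a", "a", "b", "b")
  expect_equal(set_score(expr, c("g1", "g2"), classes, "a"), 0)

  # noiseless construction: +delta in the class for all set genes
  mk <- make_shifted_expression(n_genes = 20, set_size = 4, delta = 1.5)
  expect_equal(set_score(mk$expr, mk$set_genes, mk$classes, "antibody"), 1.5)

  # hand-computed 3-gene, 4-sample oracle
  expr2 <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 2, 4, 4), g3 = c(0, 1, 1, 2))
  cls2 <- c("x", "x", "y", "y")
  hand <- mean(c(mean(c(3, 4)) - mean(c(1, 2)),
                 mean(c(4, 4)) - mean(c(2, 2)),
                 mean(c(1, 2)) - mean(c(0, 1))))
  expect_equal(set_score(expr2, c("g1", "g2", "g3"), cls2, "y"), hand)

  expect_error(set_score(expr2, c("nope"), cls2, "y"),
               class = "nucleoscape_empty_set")
  expect_message(set_score(expr2, c("g1", "nope"), cls2, "y"), "dropped")
})

test_that("an observed unique maximum over 84 splits gives heat 1 - 1/84", {
  mk <- make_shifted_expression(n_genes = 30, set_size = 5, delta = 2)
  # add tiny distinct noise so all 84 split scores are distinct
  set.seed(7)
  expr <- mk$expr + matrix(rnorm(length(mk$expr), 0, 1e-4), nrow(mk$expr))
  res <- permutation_heat_value(expr, mk$set_genes, mk$classes, "antibody",
                                set_name = "UP")
  expect_identical(res$mode, "exhaustive")
  expect_identical(res$N, 84L)
  expect_identical(res$n_up, 1L)
  expect_equal(res$heat, 1 - 1 / 84)
  # the tie convention keeps both tail counts covering every permutation
  expect_gte(res$n_up + res$n_down, res$N)
})

test_that("a planted down-set lands near 0 and ties count in both tails", {
  mk <- make_shifted_expression(n_genes = 30, set_size = 5, delta = -2)
  set.seed(8)
  expr <- mk$expr + matrix(rnorm(length(mk$expr), 0, 1e-4), nrow(mk$expr))
  res <- permutation_heat_value(expr, mk$set_genes, mk$classes, "antibody")
  expect_equal(res$heat, 1 / 84)
  # fully tied scores: constant matrix
  expr0 <- matrix(5, 10, 9, dimnames = list(sprintf("g%03d", 1:10), NULL))
  res0 <- permutation_heat_value(expr0, sprintf("g%03d", 1:3), mk$classes, "antibody")
  expect_identical(res0$n_up, 84L)
  expect_identical(res0$n_down, 84L)
  expect_equal(res0$heat, 0)
  expect_error(permutation_heat_value(expr0, sprintf("g%03d", 1:3),
                                      c(rep("a", 1), rep("b", 8)), "a"),
               "degenerate")
})

test_that("sampled and exhaustive modes agree and are seed-reproducible", {
  mk <- make_shifted_expression(n_genes = 40, set_size = 6, delta = 0.4)
  set.seed(21)
  expr <- mk$expr + matrix(rnorm(length(mk$expr), 0, 0.3), nrow(mk$expr))
  ex <- permutation_heat_value(expr, mk$set_genes, mk$classes, "antibody")
  sa1 <- permutation_heat_value(expr, mk$set_genes, mk$classes, "antibody",
                                n_perm = 4000, seed = 2, mode = "sampled")
  sa2 <- permutation_heat_value(expr, mk$set_genes, mk$classes, "antibody",
                                n_perm = 4000, seed = 2, mode = "sampled")
  expect_identical(sa1$heat, sa2$heat)
  expect_lt(abs(sa1$heat - ex$heat), 0.03)
})

test_that("hypergeometric enrichment matches the worked overlap example", {
  # universe 10, DE 5, category of 2 with overlap 2: p = 10/45
  res <- run_enrichment_case(M = 10, m = 2, n = 5, k = 2)
  expect_equal(res$p, 10 / 45, tolerance = 1e-12)
  expect_identical(res$n_array, 2L)
  expect_identical(res$n_de, 2L)

  # overlap 0: the upper tail P(X >= 0) is 1 by definition, and enumeration
  # agrees; an overlap of 1 in a singleton category gives p = n/M
  res2 <- run_enrichment_case(M = 8, m = 1, n = 3, k = 0)
  expect_equal(res2$p, phyper_bruteforce(8, 1, 3, 0), tolerance = 1e-12)
  expect_equal(res2$p, 1, tolerance = 1e-12)
  res3 <- run_enrichment_case(M = 8, m = 1, n = 3, k = 1)
  expect_equal(res3$p, 3 / 8, tolerance = 1e-12)
  expect_equal(res3$p, phyper_bruteforce(8, 1, 3, 1), tolerance = 1e-12)
})

test_that("with a single tested category the Holm-adjusted p equals the raw p", {
  genes <- sprintf("g%02d", 1:10)
  map <- rbind(data.frame(gene = genes[1:4], go = "A"),
               data.frame(gene = genes[5:10], go = "B"))
  # min_size filters B-sized.. use min_size above |B| to keep only one? B is
  # larger; instead keep only A by annotating B genes with singleton terms
  map2 <- rbind(data.frame(gene = genes[1:4], go = "A"),
                data.frame(gene = genes[5:10],
                           go = paste0("single_", 5:10)))
  res <- go_enrichment(genes[c(1, 2, 5)], genes, map2, min_size = 2)
  expect_identical(nrow(res), 1L)
  expect_equal(res$p_holm, res$p)
})

test_that("go_enrichment validates inputs and reports exclusions", {
  genes <- sprintf("g%02d", 1:6)
  map <- data.frame(gene = genes[1:4], go = "A")
  expect_error(go_enrichment("g01", character(0), map), "empty universe")
  expect_error(go_enrichment("zz", genes, map), "subset")
  expect_message(go_enrichment("g01", genes, map), "excluded")
})

test_that("heat tables assemble planted designs with the 0.05/0.95 flags", {
  mk <- make_shifted_expression(n_genes = 60, set_size = 5, delta = 2)
  set.seed(30)
  expr <- mk$expr + matrix(rnorm(length(mk$expr), 0, 1e-3), nrow(mk$expr))
  genes <- rownames(expr)
  # 2 up-sets (shifted genes split in two) and 2 down-sets planted by hand
  expr[genes[6:10], mk$classes == "antibody"] <-
    expr[genes[6:10], mk$classes == "antibody"] + 2
  expr[genes[11:20], mk$classes == "antibody"] <-
    expr[genes[11:20], mk$classes == "antibody"] - 2
  defs <- list(UP1 = genes[1:5], UP2 = genes[6:10],
               DN1 = genes[11:15], DN2 = genes[16:20],
               NUL = genes[21:30])
  results <- lapply(names(defs), function(nm)
    permutation_heat_value(expr, defs[[nm]], mk$classes, "antibody",
                           set_name = nm))
  ht <- heatmap_table(results)
  expect_identical(dim(ht$values), c(5L, 1L))
  expect_identical(sum(ht$significant[, 1]), 4L)
  expect_true(all(ht$values[c("UP1", "UP2"), 1] >= 0.95))
  expect_true(all(ht$values[c("DN1", "DN2"), 1] <= 0.05))

  # single set, single class: 1x1 table with that heat value
  one <- heatmap_table(results[1])
  expect_identical(dim(one$values), c(1L, 1L))
  expect_equal(one$values[1, 1], results[[1]]$heat)

  # missing pair reported
  r2 <- permutation_heat_value(expr, defs$UP1, mk$classes, "control",
                               set_name = "UP1")
  expect_message(ht2 <- heatmap_table(list(results[[1]], results[[2]], r2)),
                 "missing")
  expect_true(is.na(ht2$values["UP2", "control"]))
})
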