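# Single-cell QC filtering, gene scoring, ranking and preranked enrichment.

test_that("QC filter applies the strict inequalities and lists reasons", {
  rec <- data.frame(cell_id = c("a", "b", "c", "d", "e", "f"),
                    n_genes = c(500, 200, 500, 500, 500, 150),
                    n_molecules = c(5000, 5000, 1000, 50000, 5000, 500),
                    percent_mito = c(5, 5, 5, 5, 20, 30))
  r <- filter_cells_qc(rec)
  expect_equal(r$kept, "a")
  expect_equal(r$rejected$reasons[r$rejected$cell_id == "b"], "genes")
  expect_equal(r$rejected$reasons[r$rejected$cell_id == "c"], "molecules_low")
  expect_equal(r$rejected$reasons[r$rejected$cell_id == "d"], "molecules_high")
  expect_equal(r$rejected$reasons[r$rejected$cell_id == "e"], "mito")
  expect_equal(r$rejected$reasons[r$rejected$cell_id == "f"], "genes,molecules_low,mito")
})

test_that("QC filter recovers planted violations exactly and is order-equivariant", {
  tab <- gen_cell_qc_table(n = 100, n_violations = 37, seed = 2L)
  r <- filter_cells_qc(tab)
  expect_equal(sort(r$kept), sort(tab$cell_id[tab$true_keep]))
  expect_length(r$kept, 63L)
  perm <- sample(nrow(tab))
  r2 <- filter_cells_qc(tab[perm, ])
  expect_equal(sort(r2$kept), sort(r$kept))
  expect_equal(r2$kept, tab$cell_id[perm][tab$true_keep[perm]])
})

test_that("gene score follows -log10(p) * sign(log2fc)", {
  expect_equal(gene_score(0.01, 2), 2)
  expect_equal(gene_score(0.001, -1.5), -3)
  expect_equal(gene_score(1, 5), 0)
  expect_equal(gene_score(0.01, 0), 0)
  expect_error(gene_score(1.5, 1), "\\[0, 1\\]")
  expect_warning(s <- gene_score(0, 1), "clamped")
  expect_equal(s, 300)
  # antisymmetric in sign(fc), monotone decreasing in p for fc > 0
  p <- runif(20)
  expect_equal(gene_score(p, 1), -gene_score(p, -1))
  ps <- sort(p)
  expect_true(all(diff(gene_score(ps, 1)) <= 0))
})

test_that("ranking sorts by score with lexicographic tie-break and unique genes", {
  de <- data.frame(gene = c("A", "B"), pval = c(0.01, 0.1), log2fc = c(1, -1))
  rk <- rank_genes(de)
  expect_equal(rk$gene, c("A", "B"))
  expect_equal(rk$score, c(2, -1))
  ties <- data.frame(gene = c("Z", "M", "A"), pval = 0.1, log2fc = 1)
  expect_equal(rank_genes(ties)$gene, c("A", "M", "Z"))
  expect_error(rank_genes(data.frame(gene = c("A", "A"), pval = 0.5, log2fc = 1)),
               "duplicate")
  # independent sort oracle on random records
  set.seed(3)
  de2 <- data.frame(gene = sprintf("g%04d", sample(9999, 1000)),
                    pval = runif(1000), log2fc = rnorm(1000))
  rk2 <- rank_genes(de2)
  sc <- -log10(de2$pval) * sign(de2$log2fc)
  oracle <- de2$gene[order(sc, de2$gene, decreasing = c(TRUE, FALSE), method = "radix")]
  expect_equal(rk2$gene, oracle)
})

test_that("ES matches brute-force and fgsea oracles and scales invariantly", {
  set.seed(4)
  worst <- 0; worst_f <- 0
  for (i in 1:25) {
    N <- 400
    de <- data.frame(gene = sprintf("g%04d", 1:N), pval = runif(N), log2fc = rnorm(N))
    rk <- rank_genes(de)
    st <- sample(de$gene, sample(5:60, 1))
    es <- preranked_es(rk, st)$es
    worst <- max(worst, abs(es - brute_force_es(rk, st)))
    worst_f <- max(worst_f, abs(es - fgsea::calcGseaStat(
      stats::setNames(rk$score, rk$gene), which(rk$gene %in% st), gseaParam = 1)))
    # invariance under positive rescaling of all scores
    rk2 <- rk; rk2$score <- 3.7 * rk2$score
    expect_lt(abs(preranked_es(rk2, st)$es - es), 1e-12)
  }
  expect_lt(worst, 1e-12)
  expect_lt(worst_f, 1e-12)
})

test_that("ES of a top-k positive set peaks at position k", {
  de <- data.frame(gene = sprintf("g%03d", 1:100),
                   pval = seq(0.001, 0.999, length.out = 100), log2fc = 1)
  rk <- rank_genes(de)
  k <- 10
  r <- preranked_es(rk, rk$gene[1:k], return_curve = TRUE)
  expect_gt(r$es, 0)
  expect_equal(which.max(r$curve), k)
})

test_that("degenerate sets are handled: empty intersection, full universe", {
  de <- data.frame(gene = c("A", "B", "C"), pval = c(0.1, 0.2, 0.3), log2fc = 1)
  rk <- rank_genes(de)
  r <- preranked_es(rk, c("X", "Y"))
  expect_true(r$undefined)
  expect_true(is.na(r$es))
  expect_error(preranked_es(rk, c("A", "B", "C")), "universe")
  # near-full set still matches the brute-force oracle
  set.seed(8)
  de2 <- data.frame(gene = sprintf("g%03d", 1:50), pval = runif(50), log2fc = rnorm(50))
  rk2 <- rank_genes(de2)
  big <- rk2$gene[1:49]
  expect_lt(abs(preranked_es(rk2, big)$es - brute_force_es(rk2, big)), 1e-12)
})

test_that("planted enriched sets are significant; oversized sets are excluded", {
  spec <- de_sim_spec(n_genes = 2000, n_true_up = 50, n_true_down = 50,
                      planted_sets = list(
                        UP = list(genes = sprintf("G%05d", 1:40), direction = 1),
                        DOWN = list(genes = sprintf("G%05d", 101:140), direction = -1)),
                      seed = 2L)
  g <- gen_de_table(spec)
  rk <- rank_genes(g$de)
  set.seed(5)
  sets <- list(UP = sprintf("G%05d", 1:40), DOWN = sprintf("G%05d", 101:140),
               BIG = sample(g$de$gene, 1800), TINY = sample(g$de$gene, 2))
  for (i in 1:5) sets[[paste0("NULL", i)]] <- sample(g$de$gene, 50)
  res <- permutation_fdr(rk, sets, n_perm = 500, seed = 9L)
  expect_false("BIG" %in% res$set)
  excl <- attr(res, "excluded")
  expect_true("BIG" %in% excl$set)
  expect_equal(excl$reason[excl$set == "BIG"], "larger than max_size")
  expect_true("TINY" %in% excl$set)
  expect_gt(res$es[res$set == "UP"], 0)
  expect_lt(res$es[res$set == "DOWN"], 0)
  expect_lte(res$fdr_q[res$set == "UP"], 0.3)
  expect_lte(res$fdr_q[res$set == "DOWN"], 0.3)
  expect_error(permutation_fdr(rk, sets, n_perm = 5), "n_perm")
})

test_that("permutation results are reproducible under a fixed seed", {
  spec <- de_sim_spec(n_genes = 500, n_true_up = 20, n_true_down = 0, seed = 3L)
  g <- gen_de_table(spec)
  rk <- rank_genes(g$de)
  sets <- list(A = sprintf("G%05d", 1:30), B = sprintf("G%05d", 200:260))
  r1 <- permutation_fdr(rk, sets, n_perm = 200, seed = 11L)
  r2 <- permutation_fdr(rk, sets, n_perm = 200, seed = 11L)
  expect_identical(r1, r2)
})

test_that("DE generator: uniform null, guaranteed planted ordering, determinism", {
  spec0 <- de_sim_spec(n_genes = 10000, n_true_up = 0, n_true_down = 0, seed = 4L)
  g0 <- gen_de_table(spec0)
  frac <- mean(g0$de$pval < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 10000))
  # planted 50-gene up-set occupies the top 50 positive scores
  spec1 <- de_sim_spec(n_genes = 10000, n_true_up = 0, n_true_down = 0,
                       planted_sets = list(UP = list(genes = sprintf("G%05d", 1:50),
                                                     direction = 1)), seed = 5L)
  g1 <- gen_de_table(spec1)
  rk <- rank_genes(g1$de)
  expect_setequal(rk$gene[1:50], sprintf("G%05d", 1:50))
  # byte-identical regeneration under the same seed
  expect_identical(gen_de_table(spec1), g1)
  # member validation
  expect_error(de_sim_spec(n_genes = 10, n_true_up = 0, n_true_down = 0,
                           planted_sets = list(
    X = list(genes = "NOPE", direction = 1))), "universe")
})

test_that("RNK, GMT and DE TSV files round-trip", {
  dir <- withr::local_tempdir()
  de <- data.frame(gene = c("B", "A", "C"), pval = c(0.1, 0.01, 0.5),
                   log2fc = c(-1, 2, 1))
  rk <- rank_genes(de)
  p1 <- write_rnk(rk, file.path(dir, "x.rnk"))
  rk2 <- read_rnk(p1)
  expect_equal(rk2$gene, rk$gene)
  expect_equal(rk2$score, rk$score, tolerance = 1e-12)
  sets <- list(S1 = c("A", "B"), S2 = c("C"))
  p2 <- write_gmt(sets, file.path(dir, "x.gmt"))
  expect_equal(read_gmt(p2), sets)
  p3 <- write_de_tsv(de, file.path(dir, "x.tsv"))
  expect_equal(read_de_tsv(p3), de[, c("gene", "pval", "log2fc")])
})
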