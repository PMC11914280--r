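test_that("DE filter keeps genes passing both significance rules strictly", {
  tab <- toyDeTable()
  expect_setequal(filterSignificantGenes(tab), c("G1", "G2", "G6", "G9"))
  # boundary: adjusted p fine but |log2FC| at or below 0.6 is excluded
  one <- data.frame(gene = "X", cluster = "c", p_value = 0.001,
                    adjusted_p = 0.01, log2_fold_change = 0.5)
  expect_length(filterSignificantGenes(one), 0)
  one$log2_fold_change <- 0.7
  expect_equal(filterSignificantGenes(one), "X")
  # empty result allowed
  none <- data.frame(gene = "X", cluster = "c", p_value = 0.5,
                     adjusted_p = 0.9, log2_fold_change = 0.1)
  expect_length(filterSignificantGenes(none), 0)
})

test_that("signature construction selects top-k genes per cluster", {
  set.seed(7)
  genes <- sprintf("g%03d", 1:60)
  tab <- data.frame(gene = genes, cluster = rep(c("A", "B"), each = 30),
                    p_value = runif(60, 1e-6, 1),
                    adjusted_p = runif(60, 1e-4, 1),
                    log2_fold_change = rnorm(60))
  ref <- matrix(runif(120, 1, 10), 60, 2, dimnames = list(genes, c("A", "B")))
  sig <- buildMomacSignature(tab, ref, k = 20)
  expect_lte(nrow(sig), 40)
  # oracle: per-cluster sort by (p, -|lfc|, gene)
  for (cl in c("A", "B")) {
    d <- tab[tab$cluster == cl, ]
    oracle <- d$gene[order(d$p_value, -abs(d$log2_fold_change),
                           d$gene)][1:20]
    expect_true(all(oracle %in% rownames(sig)))
  }
  # degenerate cluster: fewer than k genes, all taken, with a warning
  small <- tab[c(1:12, 31:60), ]
  expect_warning(sigS <- buildMomacSignature(small, ref, k = 20),
                 "only 12")
  expect_true(all(small$gene[1:12] %in% rownames(sigS)))
  # missing cluster in the reference is an error
  expect_error(buildMomacSignature(tab, ref[, "A", drop = FALSE]), "B")
})

test_that("tie rule is deterministic: p, then |log2FC|, then symbol", {
  tab <- data.frame(gene = c("b", "a", "c"), cluster = "X",
                    p_value = c(0.01, 0.01, 0.01),
                    adjusted_p = 0.02,
                    log2_fold_change = c(1, 1, 2))
  ref <- matrix(1, 3, 1, dimnames = list(c("a", "b", "c"), "X"))
  sig <- buildMomacSignature(tab, ref, k = 2)
  expect_setequal(rownames(sig), c("c", "a"))  # c by |lfc|, then a < b
})

test_that("NNLS deconvolution recovers noiseless mixtures exactly", {
  sig <- defaultSignature()
  # identity: a sample equal to a signature column scores that type only
  f <- diag(ncol(sig)); dimnames(f) <- list(colnames(sig), colnames(sig))
  e <- simulateExpression(sig, f, dispersion = 0)
  res <- deconvolveLS(e, sig, sumToOne = TRUE)
  expect_equal(unname(diag(cellScores(res))), rep(1, ncol(sig)),
               tolerance = 1e-8)
  # random known fractions, noiseless: recovered to 1e-6
  fr <- toyFractions(6, sig)
  e2 <- simulateExpression(sig, fr, dispersion = 0)
  res2 <- deconvolveLS(e2, sig, sumToOne = TRUE)
  expect_lt(max(abs(cellScores(res2) - fr)), 1e-6)
  # orthogonal sample: disjoint gene support gives all-zero scores
  sigO <- matrix(c(5, 3, 0, 0, 0, 0, 2, 4), ncol = 2,
                 dimnames = list(paste0("g", 1:4), c("ctA", "ctB")))
  yO <- matrix(c(0, 0, 0, 0), ncol = 1, dimnames = list(paste0("g", 1:4), "S1"))
  yO[1:2, 1] <- 0; yO[3:4, 1] <- 0
  sigOnly12 <- sigO[, "ctA", drop = FALSE]      # support on g1, g2
  yOnly34 <- matrix(c(0, 0, 2, 1), ncol = 1,
                    dimnames = list(paste0("g", 1:4), "S1"))
  resO <- deconvolveLS(yOnly34, sigOnly12, sumToOne = FALSE)
  expect_true(all(cellScores(resO) == 0))
  expect_error(deconvolveLS(matrix(1, 2, 1, dimnames = list(c("zz1", "zz2"),
                                                            "S")), sig),
               "intersection")
})

test_that("weighted deconvolution reduces to NNLS under uniform weights", {
  sig <- defaultSignature()
  fr <- toyFractions(4, sig, seed = 3)
  e <- simulateExpression(sig, fr, dispersion = 0.2, seed = 5)
  w1 <- setNames(rep(2, nrow(sig)), rownames(sig))
  a <- deconvolveLS(e, sig)
  b <- deconvolveWeighted(e, sig, geneWeights = w1)
  expect_equal(cellScores(a), cellScores(b), tolerance = 1e-9)
  expect_error(deconvolveWeighted(e, sig, geneWeights = w1 * 0),
               "positive")
})

test_that("down-weighting a corrupted gene improves recovery", {
  sig <- defaultSignature()
  fr <- toyFractions(8, sig, seed = 10)
  e <- simulateExpression(sig, fr, dispersion = 0)
  e[1, ] <- e[1, ] + 500  # corrupt one marker gene
  w <- setNames(rep(1, nrow(sig)), rownames(sig))
  w[1] <- 1e-8
  uniform <- deconvolveLS(e, sig, sumToOne = TRUE)
  weighted <- deconvolveWeighted(e, sig, geneWeights = w, sumToOne = TRUE)
  errU <- mean(abs(cellScores(uniform) - fr))
  errW <- mean(abs(cellScores(weighted) - fr))
  expect_lt(errW, errU)
})

test_that("single gene, single cell type has the closed-form score", {
  sig <- matrix(4, 1, 1, dimnames = list("g", "ct"))
  e <- matrix(10, 1, 1, dimnames = list("g", "S1"))
  res <- deconvolveWeighted(e, sig, geneWeights = c(g = 3))
  expect_equal(unname(cellScores(res)[1, 1]), 10 / 4)
})

test_that("MDCLR formulas sum exactly the configured cell-type lists", {
  ct <- mdclrCellTypes()
  v <- setNames(rep(0.012, length(c(ct$myeloid, ct$lymphoid))),
                c(ct$myeloid, ct$lymphoid))
  # myeloid sum 0.06, lymphoid sum 0.048 -> hand ratio
  expect_equal(mdclrFull(v), sum(v[ct$myeloid]) / sum(v[ct$lymphoid]))
  v2 <- v; v2[ct$myeloid] <- 0
  expect_equal(mdclrFull(v2), 0)
  # invariance to cell types outside the lists
  v3 <- c(v, Fibroblasts = 99)
  expect_equal(mdclrFull(v3), mdclrFull(v))
  # arbitrary score map equals the hand-summed ratio
  set.seed(2)
  v4 <- setNames(runif(9), c(ct$myeloid, ct$lymphoid))
  expect_equal(mdclrFull(v4), sum(v4[ct$myeloid]) / sum(v4[ct$lymphoid]))
  v5 <- v; v5[ct$lymphoid] <- 0
  expect_error(mdclrFull(v5), "undefined")
})

test_that("compact MDCLR uses one macrophage score over four lymphoid types", {
  v <- c(Macrophages = 0.010, B_cells = 0.0025, T_CD4 = 0.0025,
         T_CD8 = 0.0025, NK = 0.0025)
  expect_equal(mdclrCompact(v), 1.0)
  v["Macrophages"] <- 0.010; v[c("B_cells", "T_CD4", "T_CD8", "NK")] <- 0.025
  expect_equal(mdclrCompact(v), 0.1)
  expect_error(mdclrCompact(v[setdiff(names(v), "NK")]), "NK")
})

test_that("IHC MonoLR is CD68 over CD3 + CD20 and scale invariant", {
  expect_equal(ihcMonoLR(5, 4, 1), 1.0)
  expect_equal(ihcMonoLR(0, 4, 1), 0)
  expect_equal(ihcMonoLR(5 * 3, 4 * 3, 1 * 3), ihcMonoLR(5, 4, 1))
  expect_error(ihcMonoLR(5, 0, 0), "undefined")
})

test_that("heatmap normalization is subgroup mean over grand mean", {
  m <- matrix(c(2, 2, 2, 2,   # ct1: all means equal
                4, 4, 0, 0),  # ct2: means 4 and 0
              ncol = 2, dimnames = list(paste0("S", 1:4), c("ct1", "ct2")))
  groups <- c("a", "a", "b", "b")
  h <- heatmapNormalize(m, groups = groups)
  expect_equal(unname(h["ct1", ]), c(1, 1))
  expect_equal(unname(h["ct2", ]), c(2, 0))
  # unequal subgroup sizes: weighted mean of normalized values is 1 exactly
  m2 <- matrix(runif(14, 1, 5), ncol = 2,
               dimnames = list(paste0("S", 1:7), c("x", "y")))
  g2 <- c("a", "a", "a", "a", "b", "b", "c")
  h2 <- heatmapNormalize(m2, groups = g2)
  n <- as.numeric(attr(h2, "n"))
  for (ct in rownames(h2))
    expect_equal(sum(h2[ct, ] * n) / sum(n), 1)
  # zero grand mean flags the marker as missing
  m3 <- cbind(m, ct3 = 0)
  h3 <- heatmapNormalize(m3, groups = groups)
  expect_true(all(is.na(h3["ct3", ])))
})

test_that("per-cell-type group tests match the shared KS routine", {
  set.seed(31)
  sc <- matrix(runif(40), ncol = 2,
               dimnames = list(paste0("S", 1:20), c("ct1", "ct2")))
  si <- data.frame(sample_id = rownames(sc),
                   timepoint = rep(c("baseline", "C3"), each = 10),
                   response_group = rep(c("Progressive", "StableElite"), 10))
  res <- new("DeconvResult", scores = sc, method = "nnls", sampleInfo = si)
  tab <- celltypeGroupTests(res)
  row <- tab[tab$cell_type == "ct1" & tab$timepoint == "baseline", ]
  sel <- si$timepoint == "baseline"
  ref <- groupCompareKS(sc[sel, "ct1"][si$response_group[sel] == "Progressive"],
                        sc[sel, "ct1"][si$response_group[sel] != "Progressive"])
  expect_equal(row$statistic, ref$statistic)
  expect_equal(row$p_value, ref$p_value)
  # star banding at the 0.01 boundary
  expect_equal(significanceStars(c(0.009, 0.01, 0.011, 0.0005, 0.2)),
               c("**", "**", "*", "***", ""))
  # an empty group at a timepoint is untestable
  si2 <- si; si2$response_group[si2$timepoint == "C3"] <- "Progressive"
  res2 <- new("DeconvResult", scores = sc, method = "nnls", sampleInfo = si2)
  tab2 <- celltypeGroupTests(res2)
  expect_false(any(tab2$testable[tab2$timepoint == "C3"]))
})

test_that("Kruskal-Wallis H matches the rank closed form; Dunn flags shifts", {
  # hand-computable 3x3 toy: ranks 1..9, no ties
  samples <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  out <- kruskalDunn(samples)
  n <- 9
  rbar <- c(2, 5, 8)
  h <- 12 / (n * (n + 1)) * sum(3 * (rbar - (n + 1) / 2)^2)
  expect_equal(out$h, h)
  expect_equal(out$h, unname(kruskal.test(samples)$statistic))
  # one group shifted by a large constant: its pairwise comparisons significant
  set.seed(5)
  g <- list(a = rnorm(50), b = rnorm(50), c = rnorm(50) + 10)
  res <- kruskalDunn(g)
  pw <- res$pairwise
  withC <- pw$group1 == "c" | pw$group2 == "c"
  expect_true(all(pw$p_adjusted[withC] < 0.001))
  expect_gt(pw$p_adjusted[!withC], 0.05)
  expect_error(kruskalDunn(list(a = 1:3, b = 1:3)), "two-sample")
})
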