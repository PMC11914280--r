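## Tumor-side scoring: marker-signature construction from a DE table,
## nonnegative least-squares deconvolution, myeloid/lymphoid ratio
## surrogates, IHC MonoLR, subgroup heatmap normalization and group tests.

#' Filter a differential-expression table for significant genes
#'
#' Retains genes with adjusted p-value below `alpha` and absolute log2
#' fold change above `lfc` (both strict, so a gene sitting exactly on
#' either threshold is excluded). Defaults are adjusted p < 0.05 and
#' |log2FC| > 0.6.
#'
#' @param table data.frame with columns gene, cluster, p_value,
#'   adjusted_p, log2_fold_change.
#' @param alpha,lfc positive thresholds.
#' @return character vector of retained gene symbols (possibly empty).
#' @export
filterSignificantGenes <- function(table, alpha = 0.05, lfc = 0.6) {
  .checkDeTable(table)
  if (alpha <= 0 || lfc <= 0) stop("thresholds must be positive")
  keep <- table$adjusted_p < alpha & abs(table$log2_fold_change) > lfc
  table$gene[keep]
}

.checkDeTable <- function(table) {
  need <- c("gene", "cluster", "p_value", "adjusted_p", "log2_fold_change")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("DE table missing columns: ", paste(miss, collapse = ", "))
  if (any(table$p_value <= 0 | table$p_value > 1) ||
      any(table$adjusted_p <= 0 | table$adjusted_p > 1))
    stop("p-values must lie in (0, 1]")
  if (anyDuplicated(paste(table$gene, table$cluster)))
    stop("duplicated gene-cluster pairs in DE table")
  invisible(TRUE)
}

#' Build a monocyte/macrophage marker signature from a DE table
#'
#' For each cluster, selects the `k` genes with the smallest differential
#' p-values (default 20); ties are broken by larger |log2FC|, then by
#' lexicographic gene symbol, so the construction is deterministic. The
#' signature rows are the union of selected genes, with values taken from
#' the supplied per-cluster reference expression profiles. Clusters with
#' fewer than `k` genes contribute all of them, with a warning.
#'
#' @param table DE marker table (see [filterSignificantGenes()]).
#' @param referenceProfiles genes x clusters nonnegative matrix of mean
#'   reference expression; must cover every cluster in `table`.
#' @param k genes to select per cluster (default 20).
#' @return genes x clusters signature matrix (see details on row union).
#' @export
buildMomacSignature <- function(table, referenceProfiles, k = 20) {
  .checkDeTable(table)
  clusters <- unique(table$cluster)
  absent <- setdiff(clusters, colnames(referenceProfiles))
  if (length(absent))
    stop("cluster(s) absent from referenceProfiles: ",
         paste(absent, collapse = ", "))
  selected <- lapply(clusters, function(cl) {
    d <- table[table$cluster == cl, , drop = FALSE]
    if (nrow(d) < k)
      warning(sprintf("cluster %s has only %d genes (< k = %d); taking all",
                      cl, nrow(d), k))
    ord <- order(d$p_value, -abs(d$log2_fold_change), d$gene)
    d$gene[ord][seq_len(min(k, nrow(d)))]
  })
  genes <- sort(unique(unlist(selected)))
  missingGenes <- setdiff(genes, rownames(referenceProfiles))
  if (length(missingGenes))
    stop("selected gene(s) absent from referenceProfiles: ",
         paste(head(missingGenes, 5), collapse = ", "))
  sig <- referenceProfiles[genes, clusters, drop = FALSE]
  if (any(sig < 0)) stop("referenceProfiles must be nonnegative")
  sig
}

.sharedGenes <- function(expr, sig) {
  genes <- intersect(rownames(expr), rownames(sig))
  if (!length(genes)) stop("empty gene intersection between expression and signature")
  genes
}

#' Nonnegative least-squares deconvolution of bulk expression
#'
#' Estimates per-sample cell-type scores by minimizing the squared
#' residual || y - S x || subject to x >= 0, where S is the signature
#' restricted to the genes shared (by identifier intersection) with the
#' expression matrix, both on a linear (TPM-like) scale. With
#' `sumToOne = TRUE` the scores of each sample are renormalized to sum to
#' one, turning them into fraction estimates. The solve is deterministic.
#'
#' @param expr genes x samples nonnegative matrix.
#' @param sig genes x cell-types signature matrix.
#' @param sumToOne renormalize scores to fractions (default FALSE).
#' @param sampleInfo optional data.frame (sample_id, timepoint,
#'   response_group) attached to the result.
#' @return a [DeconvResult-class] with samples x cell-types scores.
#' @export
deconvolveLS <- function(expr, sig, sumToOne = FALSE, sampleInfo = data.frame()) {
  deconvolveWeighted(expr, sig, geneWeights = NULL, sumToOne = sumToOne,
                     sampleInfo = sampleInfo, methodTag = "nnls")
}

#' Weighted nonnegative least-squares deconvolution
#'
#' As [deconvolveLS()] but minimizing the weighted residual
#' sum_g w_g (y_g - (S x)_g)^2 with one positive weight per shared gene
#' (e.g. inverse-variance weights that down-weight noisy genes). Uniform
#' weights reproduce [deconvolveLS()] exactly.
#'
#' @param expr,sig,sumToOne,sampleInfo as in [deconvolveLS()].
#' @param geneWeights named positive vector over (at least) the shared
#'   genes, or NULL for uniform weights.
#' @param methodTag tag stored in the result.
#' @return a [DeconvResult-class].
#' @export
deconvolveWeighted <- function(expr, sig, geneWeights = NULL,
                               sumToOne = FALSE, sampleInfo = data.frame(),
                               methodTag = "wnnls") {
  expr <- as.matrix(expr); sig <- as.matrix(sig)
  genes <- .sharedGenes(expr, sig)
  E <- expr[genes, , drop = FALSE]
  S <- sig[genes, , drop = FALSE]
  if (is.null(geneWeights)) {
    w <- rep(1, length(genes))
  } else {
    if (!all(genes %in% names(geneWeights)))
      stop("geneWeights must cover all shared genes")
    w <- as.numeric(geneWeights[genes])
    if (any(w <= 0)) stop("gene weights must be positive")
  }
  sw <- sqrt(w)
  Sw <- S * sw
  scores <- matrix(0, ncol(E), ncol(S),
                   dimnames = list(colnames(E), colnames(S)))
  for (j in seq_len(ncol(E))) {
    y <- E[, j]
    if (all(y == 0)) stop(sprintf("sample %s is all-zero", colnames(E)[j]))
    fit <- pracma::lsqnonneg(Sw, y * sw)
    scores[j, ] <- fit$x
  }
  if (sumToOne) {
    rs <- rowSums(scores)
    if (any(rs == 0)) stop("cannot renormalize an all-zero score vector")
    scores <- scores / rs
  }
  new("DeconvResult", scores = scores, method = methodTag,
      sampleInfo = sampleInfo)
}

.scoreVector <- function(scores) {
  if (is(scores, "DeconvResult")) cellScores(scores) else
    if (is.matrix(scores)) scores else t(as.matrix(scores))
}

.sumTypes <- function(m, types, role) {
  absent <- setdiff(types, colnames(m))
  if (length(absent))
    stop(sprintf("%s cell type(s) missing from scores: %s", role,
                 paste(absent, collapse = ", ")))
  rowSums(m[, types, drop = FALSE])
}

#' Default myeloid / lymphoid cell-type memberships
#'
#' The cell-type name lists behind the MDCLR ratios are configuration, not
#' code: the "full" formula sums monocytes, macrophages (any polarization)
#' and myeloid dendritic cells over the sum of T, B and NK scores; the
#' "compact" formula uses a single macrophage score over B + CD4 T + CD8 T
#' + NK. These defaults name the columns of [defaultSignature()].
#'
#' @return list with `myeloid`, `lymphoid`, `macrophage`,
#'   `lymphoidCompact` character vectors.
#' @export
mdclrCellTypes <- function() {
  list(myeloid = .MYELOID_TYPES,
       lymphoid = .LYMPHOID_TYPES,
       macrophage = "Macrophages",
       lymphoidCompact = c("B_cells", "T_CD4", "T_CD8", "NK"))
}

#' Tumor MDCLR, full myeloid formula
#'
#' Monocyte-derived-cell / lymphocyte ratio on deconvolution scores:
#' (sum of monocyte + macrophage + myeloid dendritic scores) divided by
#' (sum of T + B + NK scores). Cell types outside the two lists are
#' ignored. A zero lymphoid sum is an error, not infinity.
#'
#' @param scores a [DeconvResult-class], a samples x cell-types matrix, or
#'   a named score vector for one sample.
#' @param myeloid,lymphoid cell-type name lists (defaults from
#'   [mdclrCellTypes()]).
#' @return numeric vector of ratios, one per sample.
#' @export
mdclrFull <- function(scores, myeloid = mdclrCellTypes()$myeloid,
                      lymphoid = mdclrCellTypes()$lymphoid) {
  m <- .scoreVector(scores)
  num <- .sumTypes(m, myeloid, "myeloid")
  den <- .sumTypes(m, lymphoid, "lymphoid")
  if (any(den == 0)) stop("lymphoid score sum is 0: MDCLR undefined")
  num / den
}

#' Tumor MDCLR, compact macrophage formula
#'
#' Macrophage score divided by the sum of B-cell, CD4 T, CD8 T and NK
#' scores, for deconvolution outputs that report a single macrophage
#' population.
#'
#' @param scores as in [mdclrFull()].
#' @param macrophage single macrophage column name.
#' @param lymphoid the four denominator cell types.
#' @return numeric vector of ratios, one per sample.
#' @export
mdclrCompact <- function(scores, macrophage = mdclrCellTypes()$macrophage,
                         lymphoid = mdclrCellTypes()$lymphoidCompact) {
  m <- .scoreVector(scores)
  num <- .sumTypes(m, macrophage, "macrophage")
  den <- .sumTypes(m, lymphoid, "lymphoid")
  if (any(den == 0)) stop("lymphoid score sum is 0: MDCLR undefined")
  num / den
}

#' IHC-based tumor MonoLR
#'
#' CD68+ density divided by the sum of CD3+ and CD20+ densities, all in
#' cells/mm2; the IHC surrogate of the tumor myeloid/lymphoid balance.
#'
#' @param cd68,cd3,cd20 nonnegative densities (cells/mm2); vectorized.
#' @return numeric ratio(s).
#' @export
ihcMonoLR <- function(cd68, cd3, cd20) {
  if (any(c(cd68, cd3, cd20) < 0)) stop("densities must be nonnegative")
  den <- cd3 + cd20
  if (any(den == 0)) stop("CD3 + CD20 density is 0: ratio undefined")
  cd68 / den
}

#' Subgroup-normalized heatmap scores
#'
#' Per cell type, each (response group, timepoint) subgroup is summarized
#' as subgroup mean / grand mean, the normalization used for
#' response-by-timepoint score heatmaps. With this definition the
#' sample-count-weighted average of the normalized values equals 1 exactly
#' for every cell type. A cell type whose grand mean is 0 yields `NA`
#' (a missing marker) rather than an error.
#'
#' @param result a [DeconvResult-class] whose `sampleInfo` has
#'   response_group and timepoint columns, or a scores matrix plus
#'   `groups` explicitly.
#' @param groups optional character vector (one subgroup label per sample)
#'   overriding sampleInfo.
#' @return matrix, cell types x subgroups, of normalized values; attribute
#'   "n" carries the subgroup sample counts.
#' @export
heatmapNormalize <- function(result, groups = NULL) {
  m <- .scoreVector(result)
  if (is.null(groups)) {
    si <- sampleInfo(result)
    if (!nrow(si)) stop("no sampleInfo: supply `groups`")
    groups <- paste(si$response_group, si$timepoint, sep = ".")
  }
  if (length(groups) != nrow(m))
    stop("`groups` must have one label per sample")
  glev <- unique(groups)
  grand <- colMeans(m)
  out <- sapply(glev, function(g)
    colMeans(m[groups == g, , drop = FALSE]) / ifelse(grand > 0, grand, NA))
  out <- matrix(out, nrow = ncol(m), dimnames = list(colnames(m), glev))
  out[grand == 0, ] <- NA  # zero grand mean: missing marker, not an error
  attr(out, "n") <- table(factor(groups, levels = glev))
  out
}

#' Per-cell-type, per-timepoint group comparisons
#'
#' Runs the two-sided Kolmogorov-Smirnov comparison of Progressive versus
#' Stable+Elite scores separately for each cell type at each biopsy
#' timepoint, and assigns significance stars at p <= 0.05 / 0.01 / 0.001.
#' A (cell type, timepoint) with an empty group is marked untestable.
#'
#' @param result a [DeconvResult-class] with response_group and timepoint
#'   in its sampleInfo.
#' @return data.frame: cell_type, timepoint, n_progressive, n_stable_elite,
#'   statistic, p_value, stars, testable.
#' @export
celltypeGroupTests <- function(result) {
  m <- .scoreVector(result)
  si <- sampleInfo(result)
  if (!nrow(si)) stop("result carries no sampleInfo")
  rows <- list()
  for (tp in unique(si$timepoint)) {
    sel <- si$timepoint == tp
    isProg <- si$response_group[sel] == "Progressive"
    for (ct in colnames(m)) {
      a <- m[sel, ct][isProg]
      b <- m[sel, ct][!isProg]
      if (!length(a) || !length(b)) {
        rows[[length(rows) + 1L]] <- data.frame(
          cell_type = ct, timepoint = tp, n_progressive = length(a),
          n_stable_elite = length(b), statistic = NA_real_,
          p_value = NA_real_, stars = "", testable = FALSE,
          stringsAsFactors = FALSE)
        next
      }
      kt <- groupCompareKS(a, b)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_type = ct, timepoint = tp, n_progressive = length(a),
        n_stable_elite = length(b), statistic = kt$statistic,
        p_value = kt$p_value, stars = significanceStars(kt$p_value),
        testable = TRUE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Significance stars
#'
#' Banding rule used in the figure captions: `***` for p <= 0.001, `**`
#' for p <= 0.01, `*` for p <= 0.05, empty otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of star strings.
#' @export
significanceStars <- function(p) {
  ifelse(is.na(p), "",
    ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**",
      ifelse(p <= 0.05, "*", ""))))
}

#' Kruskal-Wallis omnibus test with Dunn's post-hoc comparisons
#'
#' Multigroup comparison: Kruskal-Wallis H (with tie correction) followed
#' by Dunn's pairwise z-tests on the mean ranks, with multiplicity
#' adjustment (Bonferroni by default). With fewer than three groups the
#' caller is directed to the two-sample comparison instead.
#'
#' @param samples named list of >= 3 nonempty numeric vectors.
#' @param adjust p-value adjustment method for the pairwise table
#'   (any method of [stats::p.adjust()]; default "bonferroni").
#' @return list with `h`, `df`, `p_value` (omnibus) and `pairwise`
#'   data.frame (group1, group2, z, p_value, p_adjusted).
#' @export
kruskalDunn <- function(samples, adjust = "bonferroni") {
  if (length(samples) < 3)
    stop("fewer than 3 groups: use groupCompareKS for two-sample comparison")
  if (any(!lengths(samples))) stop("every group must be nonempty")
  kw <- kruskal.test(samples)
  x <- unlist(samples, use.names = FALSE)
  g <- factor(rep(names(samples) %||% seq_along(samples), lengths(samples)))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tieCorr
  combs <- utils::combn(levels(g), 2)
  z <- apply(combs, 2, function(pr) {
    (rbar[pr[1]] - rbar[pr[2]]) /
      sqrt(s2 * (1 / n[pr[1]] + 1 / n[pr[2]]))
  })
  p <- 2 * pnorm(-abs(z))
  pairwise <- data.frame(group1 = combs[1, ], group2 = combs[2, ],
                         z = as.numeric(z), p_value = as.numeric(p),
                         p_adjusted = pmin(1, p.adjust(p, method = adjust)),
                         stringsAsFactors = FALSE)
  list(h = unname(kw$statistic), df = unname(kw$parameter),
       p_value = kw$p.value, pairwise = pairwise)
}
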