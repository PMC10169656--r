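# Two-condition differential statistics on log2 intensities, FDR control,
# replicate QC, significant-set comparison across contexts, and hierarchical
# clustering of modulated features.

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of raw p-values (via \code{stats::p.adjust}),
#' with input validation: every value must lie in [0, 1]. Adjusted values
#' are always >= the raw ones and monotone non-decreasing after sorting.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order as \code{p}.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p)) stopf("p must be numeric")
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# Row-wise group summaries with complete-case handling.
.rowGroupStats <- function(mat) {
  n <- rowSums(!is.na(mat))
  m <- rowMeans(mat, na.rm = TRUE)
  v <- rowSums((mat - m)^2, na.rm = TRUE) / pmax(n - 1L, 1L)
  v[n < 2L] <- NA_real_
  list(n = n, mean = m, var = v)
}

#' Per-feature two-sample differential statistics
#'
#' For every feature, a two-sided two-sample t-test of treated versus
#' control log2 intensities (Student pooled-variance by default, Welch
#' optionally), Benjamini-Hochberg FDR across retained features, and a
#' significance flag at \code{fdrThreshold} (default 0.1, the conventional
#' cut for this kind of screen). For phospho matrices the class-I filter is
#' applied first: sites with localization probability below
#' \code{classIThreshold} are removed (sites with no annotated probability
#' are kept). Missing values are handled complete-case per feature per
#' group; features with fewer than two complete values in either group are
#' excluded and listed in the \code{"excluded"} attribute. With zero pooled
#' variance the statistic is 0 (p = 1) for a zero mean difference and
#' signed infinite (p = 0) otherwise.
#'
#' @param x an \linkS4class{OmicsMatrix}.
#' @param treated,control levels of the \code{treatment} annotation to
#'   contrast (treated minus control).
#' @param genotype optional genotype to subset to before testing.
#' @param fdrThreshold FDR significance cut.
#' @param flavor \code{"student"} (equal-variance) or \code{"welch"}.
#' @param classIThreshold localization-probability floor for phospho
#'   features.
#' @return data.frame with columns \code{feature}, \code{log2fc},
#'   \code{t_stat}, \code{df}, \code{p_value}, \code{fdr},
#'   \code{significant}, \code{n_treated}, \code{n_control}; excluded
#'   features in \code{attr(, "excluded")}.
#' @examples
#' ex <- simulateStudy(nNodes = 30, nRegulators = 8, nActive = 2,
#'                     genotypes = "ITD-JMD", seed = 3)
#' dt <- differentialStats(ex@phospho, genotype = "ITD-JMD")
#' head(dt)
#' @export
differentialStats <- function(x, treated = "treated", control = "control",
                              genotype = NULL, fdrThreshold = 0.1,
                              flavor = c("student", "welch"),
                              classIThreshold = 0.75) {
  flavor <- match.arg(flavor)
  if (fdrThreshold <= 0 || fdrThreshold > 1)
    stopf("fdrThreshold must lie in (0, 1]")
  cd <- colData(x)
  if (!is.null(genotype)) {
    if (!genotype %in% cd$genotype)
      stopf("genotype \"%s\" absent from sample annotations", genotype)
    x <- x[, cd$genotype == genotype]
    cd <- colData(x)
  }
  for (lev in c(treated, control))
    if (!lev %in% cd$treatment)
      stopf("treatment level \"%s\" absent from sample annotations", lev)
  mat <- assay(x, "log2intensity")
  excluded <- character()
  if (omicsKind(x) == "phospho") {
    lp <- rowData(x)$loc_prob
    drop <- !is.na(lp) & lp < classIThreshold
    excluded <- rownames(mat)[drop]
    mat <- mat[!drop, , drop = FALSE]
  }
  g1 <- .rowGroupStats(mat[, cd$treatment == treated, drop = FALSE])
  g2 <- .rowGroupStats(mat[, cd$treatment == control, drop = FALSE])
  keep <- g1$n >= 2L & g2$n >= 2L
  excluded <- c(excluded, rownames(mat)[!keep])
  n1 <- g1$n[keep]; n2 <- g2$n[keep]
  d <- (g1$mean - g2$mean)[keep]
  v1 <- g1$var[keep]; v2 <- g2$var[keep]
  if (flavor == "student") {
    df <- n1 + n2 - 2
    se <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / df * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    df[se == 0] <- n1[se == 0] + n2[se == 0] - 2
  }
  t <- ifelse(se > 0, d / se, ifelse(d == 0, 0, sign(d) * Inf))
  p <- ifelse(is.finite(t), 2 * pt(-abs(t), df), ifelse(t == 0, 1, 0))
  p[t == 0] <- 1
  fdr <- bhAdjust(p)
  out <- data.frame(feature = rownames(mat)[keep], log2fc = d, t_stat = t,
                    df = df, p_value = p, fdr = fdr,
                    significant = fdr < fdrThreshold,
                    n_treated = n1, n_control = n2,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[corder(out$feature), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- csort(excluded)
  attr(out, "fdr_threshold") <- fdrThreshold
  out
}

#' Replicate correlation QC
#'
#' Pairwise Pearson correlations between samples on pairwise-complete
#' log2 intensities. Pairs with fewer than two overlapping non-missing
#' values get \code{NA}. Replicate pairs (same genotype and treatment)
#' whose correlation falls below \code{floor} are flagged in the QC table.
#'
#' @param x an \linkS4class{OmicsMatrix} with >= 2 samples.
#' @param floor QC floor for within-condition replicate correlations
#'   (default 0.75, the low end of what a well-behaved label-free
#'   experiment shows).
#' @return list with \code{correlation} (samples x samples matrix) and
#'   \code{qc} (data.frame of replicate pairs with \code{r} and
#'   \code{below_floor}).
#' @export
replicateCorrelation <- function(x, floor = 0.75) {
  mat <- assay(x, "log2intensity")
  if (ncol(mat) < 2L) stopf("need >= 2 samples")
  cc <- suppressWarnings(cor(mat, use = "pairwise.complete.obs"))
  overlap <- crossprod(!is.na(mat))
  cc[overlap < 2L] <- NA_real_
  cd <- colData(x)
  grp <- paste(cd$genotype, cd$treatment, sep = "|")
  pairs <- which(upper.tri(cc) & outer(grp, grp, "=="), arr.ind = TRUE)
  qc <- data.frame(
    sample_a = colnames(mat)[pairs[, 1L]],
    sample_b = colnames(mat)[pairs[, 2L]],
    r = cc[pairs],
    stringsAsFactors = FALSE
  )
  qc$below_floor <- !is.na(qc$r) & qc$r < floor
  qc <- qc[corder(qc$sample_a, qc$sample_b), , drop = FALSE]
  rownames(qc) <- NULL
  if (any(qc$below_floor))
    warnf("%d replicate pair(s) below the correlation floor %.2f",
          sum(qc$below_floor), floor)
  list(correlation = cc, qc = qc)
}

#' Compare significant feature sets across contexts
#'
#' Given differential tables for two or more contexts (e.g. genotypes),
#' reports the significant features common to all contexts (the "common
#' core"), the union, per-context counts, and a membership table.
#'
#' @param tables named list of [differentialStats()] outputs; >= 2
#'   entries.
#' @return list with \code{intersection}, \code{union} (character
#'   vectors), \code{n_intersection}, \code{n_union},
#'   \code{per_context} (named counts) and \code{membership}
#'   (feature x context logical data.frame).
#' @export
compareSignificantSets <- function(tables) {
  if (length(tables) < 2L || is.null(names(tables)))
    stopf("need a named list of >= 2 differential tables")
  sig <- lapply(tables, function(t) t$feature[t$significant])
  un <- csort(Reduce(union, sig))
  inter <- csort(Reduce(intersect, sig))
  membership <- data.frame(
    feature = un,
    lapply(sig, function(s) un %in% s),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  list(intersection = inter, union = un,
       n_intersection = length(inter), n_union = length(un),
       per_context = vapply(sig, length, 0L),
       membership = membership)
}

#' Hierarchical clustering of modulated features
#'
#' Rows are z-scored across samples, the distance is 1 minus the Pearson
#' correlation of feature profiles, trees are built with average-linkage
#' agglomeration and cut into \code{k} clusters. Features are processed in
#' lexicographic order and cluster labels are renumbered by first
#' appearance in that order, so the assignment is deterministic. Features
#' with zero variance across samples cannot be z-scored and are dropped
#' with a warning.
#'
#' @param x an \linkS4class{OmicsMatrix} or numeric matrix.
#' @param features optional feature subset (typically the significant
#'   features of a differential table).
#' @param k number of clusters (default 4), 1 <= k <= number of features.
#' @return data.frame with columns \code{feature} and \code{cluster}.
#' @export
clusterFeatures <- function(x, features = NULL, k = 4) {
  mat <- if (is(x, "OmicsMatrix")) assay(x, "log2intensity") else as.matrix(x)
  if (!is.null(features)) {
    miss <- setdiff(features, rownames(mat))
    if (length(miss))
      stopf("features absent from the matrix: %s", paste(miss, collapse = ", "))
    mat <- mat[features, , drop = FALSE]
  }
  mat <- mat[csort(rownames(mat)), , drop = FALSE]
  m <- rowMeans(mat, na.rm = TRUE)
  s <- sqrt(rowSums((mat - m)^2, na.rm = TRUE) /
              pmax(rowSums(!is.na(mat)) - 1L, 1L))
  flat <- s == 0 | !is.finite(s)
  if (any(flat)) {
    warnf("dropping %d zero-variance feature(s) before clustering", sum(flat))
    mat <- mat[!flat, , drop = FALSE]
    m <- m[!flat]; s <- s[!flat]
  }
  if (k < 1 || k > nrow(mat))
    stopf("k must lie in [1, number of clusterable features]")
  z <- (mat - m) / s
  d <- as.dist(1 - suppressWarnings(cor(t(z), use = "pairwise.complete.obs")))
  cl <- cutree(hclust(d, method = "average"), k = k)
  relabel <- match(cl, unique(cl))
  data.frame(feature = rownames(mat), cluster = relabel,
             stringsAsFactors = FALSE, row.names = NULL)
}
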