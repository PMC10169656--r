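# Footprint-based protein activity inference: regulon-level mean signed
# t-statistics against a permutation null, regulatory-phosphosite scoring,
# and the merge of the two evidence streams.

# nPerm draws of size n without replacement from seq_len(m), as an n x nPerm
# index matrix. Drawn with replacement first, then columns containing a
# duplicate are redrawn honestly (cheap: duplicates are rare for n << m).
.permIndex <- function(m, n, nPerm) {
  idx <- matrix(sample.int(m, n * nPerm, replace = TRUE), nrow = n)
  if (n > 1L) {
    bad <- rep(FALSE, nPerm)
    for (i in seq_len(n - 1L))
      for (j in seq.int(i + 1L, n))
        bad <- bad | idx[i, ] == idx[j, ]
    for (k in which(bad)) idx[, k] <- sample.int(m, n)
  }
  idx
}

#' Footprint activity from regulon target statistics
#'
#' A regulator's footprint score is the mean of sign-weighted
#' t-statistics over its measured regulon targets: \eqn{score(R) = (1/n)
#' \sum_i sign_i t_i}. Significance comes from a permutation null: the same
#' statistic recomputed on \code{nPerm} random draws of \eqn{n} measured
#' features, giving a two-sided p-value
#' \eqn{(1 + \#\{|null| \ge |score|\}) / (nPerm + 1)} and a z-score against
#' the null mean and standard deviation. FDR is Benjamini-Hochberg across
#' scored regulators. Regulators with fewer than \code{minTargets} measured
#' targets are skipped and listed in the \code{"skipped"} attribute.
#'
#' Kinase/phosphatase regulons should be scored against the phospho-layer
#' differential table and TF regulons against the proteome layer; the
#' \code{classes} argument selects which regulators of a mixed
#' \linkS4class{RegulonSet} to score here (see [inferActivities()] for the
#' two-layer routing).
#'
#' @param diff a [differentialStats()] table carrying \code{t_stat}.
#' @param regulons a \linkS4class{RegulonSet}.
#' @param classes regulator classes to score (default: all present).
#' @param minTargets minimum measured targets per regulator (default 3;
#'   set to 2 to let very small regulons, e.g. phosphatases, survive).
#' @param nPerm permutation draws; >= 100 (smaller nulls are unstable).
#' @param seed integer seed for the permutation draws, or \code{NULL}.
#' @return ActivityTable data.frame: \code{protein}, \code{class},
#'   \code{method} (\code{"footprint"}), \code{score}, \code{z},
#'   \code{sign}, \code{p_value}, \code{fdr}, \code{n_evidence}.
#' @examples
#' ex <- simulateStudy(nNodes = 40, nRegulators = 10, nActive = 3,
#'                     genotypes = "ITD-JMD", seed = 11)
#' dp <- differentialStats(ex@phospho, genotype = "ITD-JMD")
#' footprintActivity(dp, ex@regulons, classes = c("kinase", "phosphatase"),
#'                   nPerm = 200, seed = 1)
#' @export
footprintActivity <- function(diff, regulons, classes = NULL,
                              minTargets = 3, nPerm = 1000, seed = NULL) {
  if (nPerm < 100) stopf("nPerm must be >= 100 (unstable null below that)")
  if (!all(c("feature", "t_stat") %in% colnames(diff)))
    stopf("diff must carry feature and t_stat columns")
  if (!is.null(seed)) set.seed(seed)
  tvec <- setNames(diff$t_stat, diff$feature)
  e <- regulonTable(regulons)
  if (!is.null(classes)) e <- e[e$class %in% classes, , drop = FALSE]
  e <- e[e$target %in% names(tvec), , drop = FALSE]
  regs <- csort(unique(regulonTable(regulons)$regulator[
    if (is.null(classes)) TRUE else regulonTable(regulons)$class %in% classes]))
  split_e <- split(e[c("target", "sign", "class")], e$regulator)
  m <- length(tvec)
  rows <- list(); skipped <- character()
  for (r in regs) {
    er <- split_e[[r]]
    if (is.null(er) || nrow(er) < minTargets) {
      skipped <- c(skipped, r)
      next
    }
    s <- er$sign
    tt <- tvec[er$target]
    score <- mean(s * tt)
    null <- colSums(matrix(tvec[.permIndex(m, length(s), nPerm)],
                           nrow = length(s)) * s) / length(s)
    mu <- mean(null[is.finite(null)])
    sdv <- sd(null[is.finite(null)])
    rows[[r]] <- data.frame(
      protein = r, class = er$class[1L], method = "footprint",
      score = score,
      z = if (is.finite(score) && isTRUE(sdv > 0)) (score - mu) / sdv else NA_real_,
      sign = if (is.nan(score)) 0 else sign(score),
      p_value = if (is.nan(score)) NA_real_ else
        (1 + sum(abs(null) >= abs(score), na.rm = TRUE)) / (nPerm + 1),
      n_evidence = length(s), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein = character(), class = character(),
               method = character(), score = numeric(), z = numeric(),
               sign = numeric(), p_value = numeric(), n_evidence = integer(),
               stringsAsFactors = FALSE)
  out$fdr <- rep(NA_real_, nrow(out))
  ok <- !is.na(out$p_value)
  out$fdr[ok] <- bhAdjust(out$p_value[ok])
  out <- out[c("protein", "class", "method", "score", "z", "sign",
               "p_value", "fdr", "n_evidence")]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Activity from regulatory phosphosites
#'
#' Scores a protein by its own regulatory sites: the mean over measured
#' sites of log2 fold change times the annotated effect (+1 activating,
#' -1 inhibiting). An up-shifted activating site therefore argues for
#' activation; exact cancellation gives score 0 and sign 0. By default only
#' sites flagged significant in the differential table contribute; proteins
#' with no contributing site are absent from the result.
#'
#' @param diffPhospho a [differentialStats()] table for the phospho layer.
#' @param regSites data.frame with columns \code{protein}, \code{site},
#'   \code{effect} in \{+1, -1\} (or activating/inhibiting strings).
#' @param onlySignificant use only significant sites (default TRUE).
#' @param classes optional named character vector protein -> class used to
#'   annotate the result (unannotated proteins get \code{"other"}).
#' @return ActivityTable data.frame (method \code{"phosphoscore"};
#'   \code{p_value}/\code{fdr} are \code{NA}: this evidence stream carries
#'   direction and magnitude, not a calibrated test).
#' @export
phosphoScore <- function(diffPhospho, regSites, onlySignificant = TRUE,
                         classes = NULL) {
  rs <- as.data.frame(regSites)
  if (!all(c("protein", "site", "effect") %in% colnames(rs)))
    stopf("regSites needs columns protein/site/effect")
  eff <- normalizeSign(rs$effect)
  if (any(is.na(eff))) stopf("unrecognized regulatory-site effect(s)")
  rs$effect <- eff
  d <- diffPhospho
  if (onlySignificant) d <- d[d$significant, , drop = FALSE]
  rs <- rs[rs$site %in% d$feature, , drop = FALSE]
  if (!nrow(rs))
    return(data.frame(protein = character(), class = character(),
                      method = character(), score = numeric(), z = numeric(),
                      sign = numeric(), p_value = numeric(), fdr = numeric(),
                      n_evidence = integer(), stringsAsFactors = FALSE))
  fc <- setNames(d$log2fc, d$feature)
  contrib <- fc[rs$site] * rs$effect
  agg <- tapply(contrib, rs$protein, mean)
  nev <- tapply(contrib, rs$protein, length)
  prot <- csort(names(agg))
  out <- data.frame(
    protein = prot,
    class = if (is.null(classes)) "other" else
      ifelse(prot %in% names(classes), unname(classes[prot]), "other"),
    method = "phosphoscore",
    score = as.numeric(agg[prot]), z = NA_real_,
    sign = sign(as.numeric(agg[prot])),
    p_value = NA_real_, fdr = NA_real_,
    n_evidence = as.integer(nev[prot]),
    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Merge footprint and phospho-score activities
#'
#' One row per protein: a protein covered by a single method keeps that
#' row; when both methods agree in sign the footprint score and p-value are
#' kept under method \code{"combined"}; when the two non-zero signs
#' conflict the protein is dropped and listed in the \code{"conflicts"}
#' attribute (a conservative policy: contradictory evidence is not
#' resolved by fiat). A zero phospho-score sign is treated as
#' non-directional and does not veto the footprint call.
#'
#' @param footprint,phosphoscore ActivityTable data.frames from
#'   [footprintActivity()] and [phosphoScore()].
#' @return Combined ActivityTable, sorted by protein.
#' @export
combineActivities <- function(footprint, phosphoscore) {
  prots <- csort(union(footprint$protein, phosphoscore$protein))
  conflicts <- character()
  rows <- lapply(prots, function(p) {
    f <- footprint[footprint$protein == p, , drop = FALSE]
    s <- phosphoscore[phosphoscore$protein == p, , drop = FALSE]
    if (!nrow(f)) return(s)
    if (!nrow(s) || s$sign == 0) return(f)
    if (f$sign == s$sign) {
      f$method <- "combined"
      f$n_evidence <- f$n_evidence + s$n_evidence
      return(f)
    }
    if (f$sign == 0) return(s)
    conflicts <<- c(conflicts, p)
    NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- footprint[0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "conflicts") <- conflicts
  out
}

#' Correlate two activity profiles
#'
#' Pearson and Spearman correlation of activity scores over the proteins
#' shared by two tables, plus the fraction of shared proteins on which the
#' inferred signs agree. With fewer than three shared proteins the
#' correlations are undefined and reported as \code{NA}.
#'
#' @param a,b ActivityTable data.frames.
#' @return list: \code{n_shared}, \code{pearson}, \code{spearman},
#'   \code{sign_agreement}.
#' @export
compareActivityProfiles <- function(a, b) {
  shared <- intersect(a$protein, b$protein)
  sa <- setNames(a$score, a$protein)[shared]
  sb <- setNames(b$score, b$protein)[shared]
  if (length(shared) < 3L)
    return(list(n_shared = length(shared), pearson = NA_real_,
                spearman = NA_real_, sign_agreement = NA_real_))
  list(n_shared = length(shared),
       pearson = cor(sa, sb),
       spearman = cor(sa, sb, method = "spearman"),
       sign_agreement = mean(sign(sa) == sign(sb)))
}

#' Two-layer activity inference
#'
#' The standard routing: kinase and phosphatase regulons are scored by
#' [footprintActivity()] against the phospho-layer differential table, TF
#' regulons against the proteome layer, regulatory phosphosites by
#' [phosphoScore()], and the streams merged with [combineActivities()].
#'
#' @param diffProteome,diffPhospho [differentialStats()] tables for the two
#'   layers.
#' @param regulons a \linkS4class{RegulonSet}.
#' @param regSites regulatory-site annotations.
#' @param classes optional named protein -> class vector for phospho-score
#'   annotation (e.g. from \code{networkNodes()}).
#' @inheritParams footprintActivity
#' @inheritParams phosphoScore
#' @return Combined ActivityTable; the per-method tables are attached as
#'   attributes \code{"footprint"} and \code{"phosphoscore"}, skipped
#'   regulators and sign conflicts as \code{"skipped"}/\code{"conflicts"}.
#' @export
inferActivities <- function(diffProteome, diffPhospho, regulons, regSites,
                            classes = NULL, minTargets = 3, nPerm = 1000,
                            onlySignificant = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fpPh <- footprintActivity(diffPhospho, regulons,
                            classes = c("kinase", "phosphatase"),
                            minTargets = minTargets, nPerm = nPerm)
  fpTf <- footprintActivity(diffProteome, regulons, classes = "TF",
                            minTargets = minTargets, nPerm = nPerm)
  fp <- rbind(fpPh, fpTf)
  fdrAll <- rep(NA_real_, nrow(fp))
  ok <- !is.na(fp$p_value) & nrow(fp) > 0
  fdrAll[ok] <- bhAdjust(fp$p_value[ok])
  fp$fdr <- fdrAll
  ps <- phosphoScore(diffPhospho, regSites,
                     onlySignificant = onlySignificant, classes = classes)
  out <- combineActivities(fp, ps)
  attr(out, "footprint") <- fp
  attr(out, "phosphoscore") <- ps
  attr(out, "skipped") <- c(attr(fpPh, "skipped"), attr(fpTf, "skipped"))
  out
}
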