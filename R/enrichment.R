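# Over-representation analysis, kinase-substrate set enrichment, and the
# phenotype arithmetic (relative apoptosis, Bliss-independence excess).

#' Over-representation analysis
#'
#' One-sided hypergeometric upper-tail test of each gene set against a
#' query, both intersected with the measured universe (the defensible
#' background: features the experiment could have seen, not the whole
#' genome). P-values are Benjamini-Hochberg adjusted across the tested
#' sets and reported alongside the enrichment score \eqn{-log10(adjusted
#' p)}; by the usual convention an enrichment score above 3 corresponds to
#' an adjusted p below 0.001.
#'
#' @param query character vector of feature IDs; members outside the
#'   universe are dropped with a warning.
#' @param collection named list of character vectors (e.g. from
#'   [readGMT()]).
#' @param universe character vector of measured feature IDs; must be
#'   non-empty.
#' @param adjustThreshold adjusted-p cut for the \code{significant} flag
#'   (default 0.05).
#' @param esThreshold enrichment-score cut for the \code{high_score} flag
#'   (default 3).
#' @return data.frame with one row per set: \code{set_name},
#'   \code{overlap}, \code{set_size}, \code{query_size},
#'   \code{universe_size}, \code{fold_enrichment}, \code{p_value},
#'   \code{adjusted_p}, \code{enrichment_score}, \code{significant},
#'   \code{high_score}, plus a \code{members} column with the overlapping
#'   IDs (comma-separated).
#' @examples
#' ora(query = c("a", "b", "c"),
#'     collection = list(s1 = c("a", "b", "x"), s2 = "y"),
#'     universe = c(letters[1:10], "x", "y"))
#' @export
ora <- function(query, collection, universe, adjustThreshold = 0.05,
                esThreshold = 3) {
  universe <- unique(universe)
  if (!length(universe)) stopf("universe must be non-empty")
  query <- unique(query)
  out <- setdiff(query, universe)
  if (length(out)) {
    warnf("dropping %d query ID(s) outside the universe", length(out))
    query <- intersect(query, universe)
  }
  N <- length(universe); n <- length(query)
  nm <- csort(names(collection))
  rows <- lapply(nm, function(s) {
    set <- intersect(unique(collection[[s]]), universe)
    K <- length(set)
    hit <- intersect(set, query)
    k <- length(hit)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = s, overlap = k, set_size = K, query_size = n,
               universe_size = N,
               fold_enrichment = if (K > 0 && n > 0) (k / n) / (K / N)
                 else NA_real_,
               p_value = p,
               members = paste(csort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(set_name = character(), overlap = integer(),
                      set_size = integer(), query_size = integer(),
                      universe_size = integer(), fold_enrichment = numeric(),
                      p_value = numeric(), adjusted_p = numeric(),
                      enrichment_score = numeric(), significant = logical(),
                      high_score = logical(), members = character()))
  res$adjusted_p <- bhAdjust(res$p_value)
  res$enrichment_score <- -log10(res$adjusted_p)
  res$significant <- res$adjusted_p < adjustThreshold
  res$high_score <- res$enrichment_score > esThreshold
  res <- res[c("set_name", "overlap", "set_size", "query_size",
               "universe_size", "fold_enrichment", "p_value", "adjusted_p",
               "enrichment_score", "significant", "high_score", "members")]
  rownames(res) <- NULL
  res
}

#' Kinase-substrate set enrichment
#'
#' Tests whether each regulator's target-site set is over-represented
#' among the significantly up- (or down-) regulated phosphosites:
#' [ora()] with query = significant sites changed in the requested
#' direction, sets = each regulator's regulon targets, and universe = all
#' measured (class-I filtered) sites of the differential table.
#'
#' @param diffPhospho a [differentialStats()] table for the phospho layer.
#' @param regulons a \linkS4class{RegulonSet}.
#' @param direction \code{"up"} or \code{"down"}.
#' @param classes regulator classes whose sets are tested (default kinase
#'   and phosphatase).
#' @inheritParams ora
#' @return An [ora()] result data.frame, one row per regulator set.
#' @export
kinaseSetEnrichment <- function(diffPhospho, regulons,
                                direction = c("up", "down"),
                                classes = c("kinase", "phosphatase"),
                                adjustThreshold = 0.05, esThreshold = 3) {
  direction <- match.arg(direction)
  e <- regulonTable(regulons)
  if (!nrow(e)) stopf("regulons is empty")
  e <- e[e$class %in% classes, , drop = FALSE]
  sets <- split(e$target, e$regulator)
  sig <- diffPhospho[diffPhospho$significant, , drop = FALSE]
  query <- if (direction == "up") sig$feature[sig$log2fc > 0]
    else sig$feature[sig$log2fc < 0]
  ora(query, sets, universe = diffPhospho$feature,
      adjustThreshold = adjustThreshold, esThreshold = esThreshold)
}

#' Treatment-induced relative apoptosis
#'
#' The standard flow-cytometry normalization for treatment-induced cell
#' death: \code{100 * (deadTreated - deadControl) / viableControl}. Equal
#' dead fractions give 0; a negative value indicates protection.
#'
#' @param deadTreated,deadControl,viableControl percentages (>= 0;
#'   \code{viableControl} must be positive). Vectorised.
#' @return Relative apoptosis (percentage points).
#' @examples
#' relativeApoptosis(30, 10, 50)  # 40
#' @export
relativeApoptosis <- function(deadTreated, deadControl, viableControl) {
  if (any(deadTreated < 0) || any(deadControl < 0))
    stopf("dead-cell percentages must be >= 0")
  if (any(viableControl <= 0))
    stopf("viableControl must be > 0")
  100 * (deadTreated - deadControl) / viableControl
}

#' Bliss-independence excess of a drug combination
#'
#' Under Bliss independence two non-interacting drugs with kill fractions
#' \code{fA} and \code{fB} combine to \code{fA + fB - fA*fB}; the excess
#' \code{fAB} minus that expectation is positive for synergy,
#' approximately zero for additivity, negative for antagonism.
#'
#' @param fA,fB,fAB kill fractions in [0, 1] (single agents and
#'   combination). Vectorised.
#' @return Bliss excess.
#' @examples
#' blissExcess(0.5, 0.5, 0.75)  # 0: exactly Bliss-additive
#' @export
blissExcess <- function(fA, fB, fAB) {
  v <- c(fA, fB, fAB)
  if (any(v < 0 | v > 1)) stopf("kill fractions must lie in [0, 1]")
  fAB - (fA + fB - fA * fB)
}
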