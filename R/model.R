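# Context-specific mechanistic models: sign-consistent induced subgraphs,
# causal path enumeration to a phenotype node, circuit extraction, model
# comparison and validation.

# Adjacency list of a PriorNetwork edge table: per source node, a data.frame
# of (target, sign, mechanism). Self-loops are dropped (they only create
# trivial sign-flipping cycles).
.adjacency <- function(edges) {
  e <- edges[edges$source != edges$target, , drop = FALSE]
  split(e[c("target", "sign", "mechanism")], e$source)
}

#' Sign-consistent induced subgraph of modulated proteins
#'
#' Restricts the prior network to proteins with a non-zero inferred
#' activity sign and keeps only edges whose sign is consistent with both
#' endpoint activities, i.e. \eqn{sign(u) \times edge\_sign = sign(v)}:
#' an active node activating an active node, an active node inhibiting an
#' inactivated one, and so on. Self-loops are removed. Node rows carry the
#' activity \code{score} and \code{sign}.
#'
#' @param activities ActivityTable data.frame (columns \code{protein},
#'   \code{sign}, \code{score}).
#' @param prior a \linkS4class{PriorNetwork}.
#' @return A \linkS4class{PriorNetwork} subgraph (empty, with a warning,
#'   when no scored protein occurs in the prior).
#' @export
buildNaiveNetwork <- function(activities, prior) {
  if (!nrow(activities)) stopf("activities is empty")
  act <- activities[activities$sign != 0, , drop = FALSE]
  nd <- networkNodes(prior)
  keep <- intersect(act$protein, nd$node)
  if (!length(keep))
    warnf("no scored protein occurs in the prior network")
  sgn <- setNames(act$sign, act$protein)
  sco <- setNames(act$score, act$protein)
  ed <- networkEdges(prior)
  ed <- ed[ed$source %in% keep & ed$target %in% keep &
             ed$source != ed$target, , drop = FALSE]
  ed <- ed[sgn[ed$source] * ed$sign == sgn[ed$target], , drop = FALSE]
  nodes <- nd[nd$node %in% keep, , drop = FALSE]
  nodes$score <- unname(sco[nodes$node])
  nodes$sign <- unname(sgn[nodes$node])
  out <- PriorNetwork(ed, nodes = nodes[c("node", "class")])
  # PriorNetwork() rebuilds the node table; reattach scores in its order
  ond <- out@nodes
  ond <- merge(ond, nodes[c("node", "score", "sign")], by = "node",
               all.x = TRUE, sort = FALSE)
  ond <- ond[corder(ond$node), , drop = FALSE]
  rownames(ond) <- NULL
  out@nodes <- ond
  out
}

# Depth-first enumeration of simple sign-consistent paths from one scored
# source to the phenotype. `signMap` maps scored nodes to their +1/-1
# activity sign; a path is extended through edge (u, v, s) only if the
# implied sign at v (source sign times the edge-sign product) matches
# sign(v) whenever v is scored, and a path ending at the phenotype is kept
# only if the implied sign equals `direction`.
.dfsPaths <- function(source, adj, signMap, phenotype, direction, maxLen) {
  res <- list()
  srcSign <- signMap[[source]]
  recurse <- function(node, visited, signs) {
    if (length(signs) >= maxLen) return()
    out <- adj[[node]]
    if (is.null(out)) return()
    for (i in seq_len(nrow(out))) {
      v <- out$target[i]; s <- out$sign[i]
      implied <- srcSign * prod(signs) * s
      if (v == phenotype) {
        if (implied == direction)
          res[[length(res) + 1L]] <<- list(nodes = c(visited, v),
                                           edgeSigns = c(signs, s))
        next
      }
      if (v %in% visited) next
      if (!is.null(signMap[[v]]) && signMap[[v]] != implied) next
      recurse(v, c(visited, v), c(signs, s))
    }
  }
  recurse(source, source, numeric(0))
  res
}

#' Connect modulated proteins to a phenotype node
#'
#' Enumerates simple directed paths of length at most \code{maxLen} edges
#' from every activity-scored node of \code{subgraph} to the phenotype
#' through the full prior network. A path is kept when the sign implied by
#' the running edge-sign product matches the inferred activity sign at
#' every scored node it traverses and equals \code{direction} at the
#' phenotype; unscored intermediate nodes are unconstrained. The model is
#' the union of all kept paths plus the sign-consistent subgraph edges
#' among retained nodes. Where the prior carries both an activating and an
#' inhibiting edge for the same node pair, each parallel edge is a separate
#' candidate and a path commits to one of them.
#'
#' @param subgraph scored subgraph from [buildNaiveNetwork()].
#' @param prior the full \linkS4class{PriorNetwork}.
#' @param phenotype phenotype node ID; must exist in the prior.
#' @param direction +1 or -1: required net effect on the phenotype.
#' @param maxLen maximum path length in edges; >= 1 (default 4 — causal
#'   chains worth interpreting are shallow, and enumeration stays bounded).
#' @return A \linkS4class{MechanisticModel}. The result is independent of
#'   node iteration order (nodes, edges and paths are sorted).
#' @examples
#' act <- data.frame(protein = "CHEK1", sign = 1, score = 2)
#' pr <- PriorNetwork(data.frame(source = "CHEK1", target = "DNA_damage",
#'                               sign = 1), phenotype = "DNA_damage")
#' m <- connectToPhenotype(buildNaiveNetwork(act, pr), pr)
#' networkEdges(m)
#' @export
connectToPhenotype <- function(subgraph, prior, phenotype = "DNA_damage",
                               direction = 1, maxLen = 4) {
  if (maxLen < 1) stopf("maxLen must be >= 1")
  if (!direction %in% c(-1, 1)) stopf("direction must be +1 or -1")
  nd <- networkNodes(prior)
  if (!phenotype %in% nd$node)
    stopf("phenotype node \"%s\" absent from the prior network", phenotype)
  snd <- networkNodes(subgraph)
  scored <- snd[!is.na(snd$sign) & snd$sign != 0 & !snd$is_phenotype, ,
                drop = FALSE]
  signMap <- as.list(setNames(scored$sign, scored$node))
  adj <- .adjacency(networkEdges(prior))
  paths <- list()
  for (src in csort(scored$node)) {
    if (src == phenotype) next
    paths <- c(paths, .dfsPaths(src, adj, signMap, phenotype, direction,
                                maxLen))
  }
  pathKey <- vapply(paths, function(p)
    paste(paste(p$nodes, collapse = ">"),
          paste(p$edgeSigns, collapse = ","), sep = "|"), "")
  ord <- corder(pathKey)
  paths <- paths[ord]

  retained <- csort(unique(as.character(unlist(lapply(paths, `[[`, "nodes")))))
  edF <- function(p) data.frame(
    source = p$nodes[-length(p$nodes)], target = p$nodes[-1L],
    sign = p$edgeSigns, stringsAsFactors = FALSE)
  pathEdges <- if (length(paths)) unique(do.call(rbind, lapply(paths, edF)))
    else data.frame(source = character(), target = character(),
                    sign = numeric())
  sed <- networkEdges(subgraph)
  sed <- sed[sed$source %in% retained & sed$target %in% retained,
             c("source", "target", "sign"), drop = FALSE]
  edges <- unique(rbind(pathEdges, sed))
  pe <- networkEdges(prior)
  mech <- setNames(pe$mechanism, edgeKey(pe$source, pe$target, pe$sign))
  edges$mechanism <- unname(mech[edgeKey(edges$source, edges$target,
                                         edges$sign)])
  edges$mechanism[is.na(edges$mechanism)] <- ""
  edges <- edges[corder(edges$source, edges$target, edges$sign), ,
                 drop = FALSE]
  rownames(edges) <- NULL

  nodes <- data.frame(node = retained, stringsAsFactors = FALSE)
  nodes$class <- nd$class[match(nodes$node, nd$node)]
  nodes$score <- snd$score[match(nodes$node, snd$node)]
  nodes$sign <- snd$sign[match(nodes$node, snd$node)]
  nodes$is_phenotype <- nodes$node == phenotype
  new("MechanisticModel", nodes = nodes, edges = edges,
      phenotype = phenotype, direction = as.numeric(direction),
      paths = paths, maxLen = as.integer(maxLen))
}

#' Extract a functional circuit from a model
#'
#' Restricts a mechanistic model to the causal paths whose source protein
#' belongs to \code{geneSet} (for example, the members of one enriched GO
#' term), plus the model edges among the retained nodes. All model
#' invariants are preserved; with \code{geneSet} covering every path
#' source, the circuit equals the model.
#'
#' @param model a \linkS4class{MechanisticModel}.
#' @param geneSet character vector of protein IDs.
#' @return A \linkS4class{MechanisticModel} (empty when no path source is
#'   in the set).
#' @export
extractCircuit <- function(model, geneSet) {
  keep <- vapply(model@paths, function(p) p$nodes[1L] %in% geneSet, TRUE)
  paths <- model@paths[keep]
  retained <- csort(unique(as.character(unlist(lapply(paths, `[[`, "nodes")))))
  nodes <- model@nodes[model@nodes$node %in% retained, , drop = FALSE]
  rownames(nodes) <- NULL
  ed <- model@edges
  ed <- ed[ed$source %in% retained & ed$target %in% retained, , drop = FALSE]
  # keep only edges justified by a retained path or consistent among
  # retained scored nodes (all model edges between retained nodes qualify)
  rownames(ed) <- NULL
  new("MechanisticModel", nodes = nodes, edges = ed,
      phenotype = model@phenotype, direction = model@direction,
      paths = paths, maxLen = model@maxLen)
}

#' Compare two mechanistic models
#'
#' Node and edge sets unique to each model and shared by both, in
#' deterministic (lexicographic) order. Edges are compared as
#' (source, sign, target) triples.
#'
#' @param a,b \linkS4class{MechanisticModel} objects.
#' @return list with \code{nodes_only_a}, \code{nodes_only_b},
#'   \code{nodes_shared}, \code{edges_only_a}, \code{edges_only_b},
#'   \code{edges_shared}.
#' @export
modelDiff <- function(a, b) {
  na <- a@nodes$node; nb <- b@nodes$node
  ea <- edgeKey(a@edges$source, a@edges$target, a@edges$sign)
  eb <- edgeKey(b@edges$source, b@edges$target, b@edges$sign)
  list(nodes_only_a = csort(setdiff(na, nb)),
       nodes_only_b = csort(setdiff(nb, na)),
       nodes_shared = csort(intersect(na, nb)),
       edges_only_a = csort(setdiff(ea, eb)),
       edges_only_b = csort(setdiff(eb, ea)),
       edges_shared = csort(intersect(ea, eb)))
}

#' Validate a mechanistic model
#'
#' Asserts the model invariants: every edge connects retained nodes with a
#' sign in \{+1, -1\}; every edge between two activity-scored nodes is
#' sign-consistent (\eqn{sign(u) \times edge\_sign = sign(v)}); every
#' non-phenotype node lies on at least one stored causal path; every
#' stored path is simple, at most \code{maxLen} edges long, sign-consistent
#' at each scored node it traverses, ends at the phenotype, and its total
#' sign equals the phenotype direction.
#'
#' @param model a \linkS4class{MechanisticModel}.
#' @return \code{TRUE} if all invariants hold, otherwise \code{FALSE} with
#'   the failures in \code{attr(, "failures")}.
#' @export
validateModel <- function(model) {
  fail <- character()
  nd <- model@nodes; ed <- model@edges
  sgn <- setNames(nd$sign, nd$node)
  if (nrow(ed)) {
    if (!all(ed$sign %in% c(-1, 1))) fail <- c(fail, "edge sign outside {-1,+1}")
    if (!all(c(ed$source, ed$target) %in% nd$node))
      fail <- c(fail, "edge endpoint outside the model")
    su <- sgn[ed$source]; sv <- sgn[ed$target]
    both <- !is.na(su) & su != 0 & !is.na(sv) & sv != 0
    if (any(su[both] * ed$sign[both] != sv[both]))
      fail <- c(fail, "sign-inconsistent edge between scored nodes")
  }
  onPath <- unique(unlist(lapply(model@paths, `[[`, "nodes")))
  off <- setdiff(nd$node[!nd$is_phenotype], onPath)
  if (nrow(nd) && length(off))
    fail <- c(fail, paste0("node(s) on no causal path: ",
                           paste(off, collapse = ", ")))
  for (p in model@paths) {
    k <- length(p$edgeSigns)
    if (k < 1L || k > model@maxLen) fail <- c(fail, "path length out of bounds")
    if (anyDuplicated(p$nodes)) fail <- c(fail, "non-simple path")
    if (p$nodes[length(p$nodes)] != model@phenotype)
      fail <- c(fail, "path does not end at the phenotype")
    src <- p$nodes[1L]
    if (is.na(sgn[src]) || sgn[src] == 0) {
      fail <- c(fail, "path source is unscored")
      next
    }
    run <- sgn[[src]]
    for (i in seq_len(k)) {
      run <- run * p$edgeSigns[i]
      v <- p$nodes[i + 1L]
      if (v != model@phenotype && !is.na(sgn[v]) && sgn[v] != 0 &&
          sgn[v] != run)
        fail <- c(fail, sprintf("path sign mismatch at %s", v))
    }
    if (run != model@direction)
      fail <- c(fail, "path sign does not match the phenotype direction")
  }
  ok <- !length(fail)
  if (!ok) attr(ok, "failures") <- unique(fail)
  ok
}
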