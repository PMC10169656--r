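# Small fixtures built in code, shared across test files.

# A tiny omics matrix: two conditions x `nrep` replicates, values supplied
# per feature as treated/control group means plus optional per-column noise.
tinyOmics <- function(features, control, treated, nrep = 3,
                      kind = "proteome", genotype = "ITD-JMD",
                      locProb = NULL) {
  stopifnot(length(control) == length(features),
            length(treated) == length(features))
  mat <- cbind(matrix(rep(control, nrep), ncol = nrep),
               matrix(rep(treated, nrep), ncol = nrep))
  ids <- c(paste0(genotype, "_control_r", seq_len(nrep)),
           paste0(genotype, "_treated_r", seq_len(nrep)))
  dimnames(mat) <- list(features, ids)
  sd <- data.frame(sample_id = ids, genotype = genotype,
                   treatment = rep(c("control", "treated"), each = nrep),
                   replicate = rep(seq_len(nrep), 2), row.names = ids)
  OmicsMatrix(mat, sd, kind = kind, locProb = locProb)
}

# Omics matrix from an explicit feature x sample matrix with parsed IDs.
omicsFromMatrix <- function(mat, kind = "proteome", locProb = NULL) {
  rx <- "^(.+)_([^_]+)_r([0-9]+)$"
  ids <- colnames(mat)
  sd <- data.frame(sample_id = ids, genotype = sub(rx, "\\1", ids),
                   treatment = sub(rx, "\\2", ids),
                   replicate = as.integer(sub(rx, "\\3", ids)),
                   row.names = ids)
  OmicsMatrix(mat, sd, kind = kind, locProb = locProb)
}

# Sample annotation data.frame for bare matrices.
sampleAnn <- function(ids) {
  rx <- "^(.+)_([^_]+)_r([0-9]+)$"
  data.frame(sample_id = ids, genotype = sub(rx, "\\1", ids),
             treatment = sub(rx, "\\2", ids),
             replicate = as.integer(sub(rx, "\\3", ids)), row.names = ids)
}

# Differential-table stub with the columns downstream stages consume.
diffStub <- function(feature, t_stat = 0, log2fc = 0, significant = TRUE,
                     fdr = 0.05) {
  data.frame(feature = feature, log2fc = log2fc, t_stat = t_stat,
             df = 4, p_value = 0.01, fdr = fdr, significant = significant,
             n_treated = 3L, n_control = 3L, stringsAsFactors = FALSE)
}

# Random signed prior over `n` signaling nodes + phenotype, with unique
# (source, target) pairs so an igraph-based oracle can look up edge signs.
randomPrior <- function(n, pEdge = 0.25, phenotype = "PHEN") {
  nodes <- sprintf("n%02d", seq_len(n))
  all <- c(nodes, phenotype)
  pairs <- expand.grid(source = nodes, target = all,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  keep <- runif(nrow(pairs)) < pEdge
  ed <- pairs[keep, ]
  ed$sign <- sample(c(-1, 1), nrow(ed), replace = TRUE)
  if (!any(ed$target == phenotype))
    ed <- rbind(ed, data.frame(source = nodes[1], target = phenotype,
                               sign = 1))
  PriorNetwork(ed, phenotype = phenotype)
}

# Random activity table over a subset of a prior's signaling nodes.
randomActivities <- function(prior, nScored) {
  nd <- networkNodes(prior)
  prot <- sample(nd$node[!nd$is_phenotype], nScored)
  data.frame(protein = prot, class = "kinase", method = "footprint",
             score = rnorm(nScored),
             sign = sample(c(-1, 1), nScored, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Independent path-search oracle: enumerate simple paths with
# igraph::all_simple_paths (cutoff in edges), apply the sign rule over the
# node sequence, and return the kept paths as "a>b>c" strings. Requires
# unique (source, target) pairs in the prior.
oraclePaths <- function(prior, activities, phenotype, direction, maxLen) {
  ed <- networkEdges(prior)
  ed <- ed[ed$source != ed$target, ]
  g <- igraph::graph_from_data_frame(ed[c("source", "target")],
                                     directed = TRUE,
                                     vertices = networkNodes(prior)$node)
  signLut <- setNames(ed$sign, paste(ed$source, ed$target))
  act <- setNames(activities$sign, activities$protein)
  act <- act[act != 0 & names(act) %in% networkNodes(prior)$node]
  kept <- character()
  for (src in names(act)) {
    if (src == phenotype) next
    ps <- igraph::all_simple_paths(g, from = src, to = phenotype,
                                   mode = "out", cutoff = maxLen)
    for (p in ps) {
      nodes <- names(p)
      ok <- TRUE
      run <- act[[src]]
      for (i in seq_len(length(nodes) - 1L)) {
        run <- run * signLut[[paste(nodes[i], nodes[i + 1L])]]
        v <- nodes[i + 1L]
        isLast <- i == length(nodes) - 1L
        want <- if (isLast) direction else act[v]
        if (isLast && run != direction) { ok <- FALSE; break }
        if (!isLast && !is.na(want) && run != want) { ok <- FALSE; break }
      }
      if (ok) kept <- c(kept, paste(nodes, collapse = ">"))
    }
  }
  sort(kept)
}
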