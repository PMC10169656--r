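# Readers and writers for the plain-text formats the pipeline touches:
# TSV matrices, SIF-like signed networks, GMT gene sets, model exports.
# All writers order rows lexicographically so output is byte-deterministic.

#' Read a log2 intensity matrix from TSV
#'
#' Expects a TSV whose header row holds sample IDs and whose first column
#' holds feature IDs (protein symbols, or phosphosite strings such as
#' \code{"CDK7_T170"} for \code{kind = "phospho"}). A phospho file may carry
#' an optional \code{loc_prob} column (localization probability in [0, 1]).
#' Sample annotations come either from \code{annotations} (a data.frame or a
#' TSV path with columns \code{sample_id}, \code{genotype},
#' \code{treatment}, \code{replicate}) or, failing that, are parsed from
#' sample IDs of the form \code{"<genotype>_<treatment>_r<replicate>"}.
#'
#' Duplicate feature IDs and unparseable phosphosite strings are format
#' errors naming the offending rows; empty cells and \code{NA} become
#' missing values.
#'
#' @param path TSV file path.
#' @param kind \code{"proteome"} or \code{"phospho"}.
#' @param annotations sample annotation data.frame or TSV path, or
#'   \code{NULL} to parse sample IDs.
#' @return An \linkS4class{OmicsMatrix}.
#' @seealso [writeOmicsMatrix()]
#' @export
readOmicsMatrix <- function(path, kind = c("proteome", "phospho"),
                            annotations = NULL) {
  kind <- match.arg(kind)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  if (ncol(df) < 2L) stopf("%s: need a feature column plus >=1 sample", path)
  feat <- as.character(df[[1L]])
  dup <- unique(feat[duplicated(feat)])
  if (length(dup))
    stopf("%s: duplicated feature IDs: %s", path, paste(dup, collapse = ", "))
  lp <- NULL
  if ("loc_prob" %in% colnames(df)[-1L]) {
    lp <- as.numeric(df[["loc_prob"]])
    df <- df[setdiff(colnames(df), "loc_prob")]
  }
  mat <- as.matrix(df[-1L])
  storage.mode(mat) <- "double"
  rownames(mat) <- feat
  if (is.character(annotations)) {
    annotations <- read.delim(annotations, stringsAsFactors = FALSE)
  }
  if (is.null(annotations)) {
    rx <- "^(.+)_([^_]+)_r([0-9]+)$"
    ids <- colnames(mat)
    if (!all(grepl(rx, ids)))
      stopf("%s: sample IDs not of the form genotype_treatment_rN and no annotation table given", path)
    annotations <- data.frame(sample_id = ids,
                              genotype = sub(rx, "\\1", ids),
                              treatment = sub(rx, "\\2", ids),
                              replicate = as.integer(sub(rx, "\\3", ids)),
                              row.names = ids, stringsAsFactors = FALSE)
  }
  OmicsMatrix(mat, annotations, kind = kind,
              locProb = if (kind == "phospho") lp else NULL)
}

#' Write an OmicsMatrix to TSV
#'
#' Inverse of [readOmicsMatrix()]: features sorted lexicographically, one
#' \code{feature} column, one column per sample, plus \code{loc_prob} for
#' phospho matrices that carry localization probabilities. Sample
#' annotations are written alongside when \code{annotationPath} is given.
#'
#' @param x an \linkS4class{OmicsMatrix}.
#' @param path output TSV path.
#' @param annotationPath optional path for the sample annotation TSV.
#' @return \code{path}, invisibly.
#' @export
writeOmicsMatrix <- function(x, path, annotationPath = NULL) {
  mat <- assay(x, "log2intensity")
  ord <- csort(rownames(mat))
  out <- data.frame(feature = ord, mat[ord, , drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (x@kind == "phospho") {
    lp <- rowData(x)$loc_prob
    if (!all(is.na(lp))) out$loc_prob <- lp[match(ord, rownames(x))]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotationPath)) {
    si <- sampleInfo(x)
    si <- si[corder(si$sample_id), , drop = FALSE]
    write.table(si, annotationPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Read a signed prior-knowledge network
#'
#' Reads a SIF-like TSV with columns \code{source}, \code{target},
#' \code{sign} and optionally \code{mechanism}. Signs may be numeric
#' (\code{+1}/\code{-1}) or SIGNOR-style verbs (\code{"activates"},
#' \code{"inhibits"}, \code{"up-regulates..."}, \code{"down-regulates..."});
#' anything else is a format error naming the offending rows. Node classes
#' and phenotype flags come from an optional node table (columns
#' \code{node}, \code{class}, \code{is_phenotype}) or the \code{phenotype}
#' argument.
#'
#' @param path edge TSV path.
#' @param nodePath optional node annotation TSV path.
#' @param phenotype phenotype node IDs to flag (ignored when
#'   \code{nodePath} carries an \code{is_phenotype} column).
#' @return A \linkS4class{PriorNetwork}. An empty file yields an empty
#'   network with a warning.
#' @seealso [writeNetwork()]
#' @export
readPriorNetwork <- function(path, nodePath = NULL, phenotype = character()) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!nrow(df)) {
    warnf("%s: empty network file", path)
    return(PriorNetwork(df[0, c("source", "target", "sign")], phenotype = phenotype))
  }
  if (!all(c("source", "target", "sign") %in% colnames(df)))
    stopf("%s: need columns source/target/sign", path)
  sg <- normalizeSign(df$sign)
  if (any(is.na(sg)))
    stopf("%s: unrecognized sign on row(s) %s", path,
          paste(which(is.na(sg)), collapse = ", "))
  nodes <- NULL
  if (!is.null(nodePath)) {
    nodes <- read.delim(nodePath, stringsAsFactors = FALSE)
    if ("is_phenotype" %in% colnames(nodes))
      phenotype <- nodes$node[as.logical(nodes$is_phenotype)]
  }
  PriorNetwork(df, nodes = nodes, phenotype = phenotype)
}

#' Write a PriorNetwork
#'
#' Writes the edge table as TSV (columns source/target/sign/mechanism,
#' sorted) and, optionally, the node table.
#'
#' @param x a \linkS4class{PriorNetwork}.
#' @param path edge TSV path.
#' @param nodePath optional node TSV path.
#' @return \code{path}, invisibly.
#' @export
writeNetwork <- function(x, path, nodePath = NULL) {
  write.table(networkEdges(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(nodePath))
    write.table(networkNodes(x), nodePath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}

#' Read and write GMT gene-set collections
#'
#' GMT is one set per line: name, description, then tab-separated member
#' IDs. Lines with fewer than three fields are format errors naming the
#' line. Duplicate members within a set are collapsed.
#'
#' @param path GMT file path.
#' @return \code{readGMT}: a named list of character vectors with a
#'   \code{"descriptions"} attribute. \code{writeGMT}: \code{path},
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeGMT(list(cellcycle = c("CDK2", "CCNA2")), f)
#' readGMT(f)
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stopf("%s: GMT line(s) with fewer than 3 fields: %s", path,
          paste(bad, collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "descriptions") <- setNames(vapply(parts, `[[`, "", 2L),
                                         names(sets))
  sets
}

#' @rdname readGMT
#' @param sets named list of character vectors.
#' @param descriptions optional named character vector of set descriptions
#'   (\code{"na"} where absent).
#' @export
writeGMT <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  nm <- csort(names(sets))
  lines <- vapply(nm, function(n) {
    d <- if (!is.null(descriptions) && n %in% names(descriptions))
      descriptions[[n]] else "na"
    paste(c(n, d, csort(sets[[n]])), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Export a mechanistic model
#'
#' Writes a node table (\code{<base>_nodes.tsv}: node, class, score, sign,
#' is_phenotype), an edge table (\code{<base>_edges.tsv}: source, target,
#' sign, mechanism) and a graph file: SIF (\code{u activates v} /
#' \code{u inhibits v}) and/or GraphML (via \pkg{igraph}, with node
#' \code{score}/\code{sign} and edge \code{sign} attributes).
#'
#' @param model a \linkS4class{MechanisticModel} (or scored
#'   \linkS4class{PriorNetwork} subgraph).
#' @param base output path prefix; files get \code{_nodes.tsv},
#'   \code{_edges.tsv}, \code{.sif}, \code{.graphml} suffixes.
#' @param formats subset of \code{c("tsv", "sif", "graphml")}.
#' @return Character vector of the files written, invisibly.
#' @export
writeModel <- function(model, base, formats = c("tsv", "sif", "graphml")) {
  formats <- match.arg(formats, several.ok = TRUE)
  nd <- networkNodes(model)
  ed <- networkEdges(model)
  nd <- nd[corder(nd$node), , drop = FALSE]
  ed <- ed[corder(ed$source, ed$target, ed$sign), , drop = FALSE]
  files <- character()
  if ("tsv" %in% formats) {
    nf <- paste0(base, "_nodes.tsv"); ef <- paste0(base, "_edges.tsv")
    write.table(nd, nf, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(ed, ef, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, nf, ef)
  }
  if ("sif" %in% formats) {
    sf <- paste0(base, ".sif")
    writeLines(edgeKey(ed$source, ed$target, ed$sign), sf)
    files <- c(files, sf)
  }
  if ("graphml" %in% formats) {
    gf <- paste0(base, ".graphml")
    g <- igraph::graph_from_data_frame(
      ed[c("source", "target", "sign", "mechanism")],
      directed = TRUE, vertices = nd)
    igraph::write_graph(g, gf, format = "graphml")
    files <- c(files, gf)
  }
  invisible(files)
}

#' Write a synthetic experiment bundle to a directory
#'
#' Emits \code{proteome.tsv}, \code{phospho.tsv}, \code{samples.tsv},
#' \code{network.sif}, \code{network_nodes.tsv}, \code{regulons.tsv},
#' \code{reg_sites.tsv} and \code{truth.json} under \code{dir} — the same
#' layout [readExperiment()] loads. Exports are byte-deterministic for a
#' given experiment.
#'
#' @param x a \linkS4class{SyntheticExperiment}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeExperiment <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  writeOmicsMatrix(x@proteome, fp("proteome.tsv"), fp("samples.tsv"))
  writeOmicsMatrix(x@phospho, fp("phospho.tsv"))
  writeNetwork(x@network, fp("network.sif"), fp("network_nodes.tsv"))
  write.table(regulonTable(x@regulons), fp("regulons.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  rs <- x@regSites[corder(x@regSites$protein, x@regSites$site), , drop = FALSE]
  write.table(rs, fp("reg_sites.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  tr <- x@truth
  jsonlite::write_json(
    list(phenotype = tr@phenotype, direction = tr@direction,
         seed = x@seed, activities = tr@activities),
    fp("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a synthetic experiment bundle
#'
#' Loads the file layout written by [writeExperiment()].
#'
#' @param dir directory containing the bundle.
#' @return A \linkS4class{SyntheticExperiment}.
#' @export
readExperiment <- function(dir) {
  fp <- function(f) file.path(dir, f)
  tr <- jsonlite::read_json(fp("truth.json"), simplifyVector = TRUE)
  act <- as.data.frame(tr$activities)
  if (!nrow(act)) act <- data.frame(genotype = character(),
                                    regulator = character(),
                                    activity = numeric())
  new("SyntheticExperiment",
      proteome = readOmicsMatrix(fp("proteome.tsv"), "proteome",
                                 fp("samples.tsv")),
      phospho = readOmicsMatrix(fp("phospho.tsv"), "phospho",
                                fp("samples.tsv")),
      network = readPriorNetwork(fp("network.sif"), fp("network_nodes.tsv")),
      regulons = RegulonSet(read.delim(fp("regulons.tsv"),
                                       stringsAsFactors = FALSE)),
      regSites = read.delim(fp("reg_sites.tsv"), stringsAsFactors = FALSE),
      truth = GroundTruth(act, tr$phenotype, tr$direction),
      seed = as.integer(tr$seed))
}
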