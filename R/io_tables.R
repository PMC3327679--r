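#' Construct an expression matrix with sample metadata
#'
#' The central container for one omics layer: a features-by-samples matrix of
#' log2 intensities (single-channel data, two conditions among the columns) or
#' log2 ratios (two-color data, one contrast column per array), together with
#' per-sample metadata.
#'
#' @param values Numeric matrix, rows = features, columns = samples. Row names
#'   are taken as feature ids; missing values allowed.
#' @param samples Data frame with one row per column of `values` and columns
#'   `sample_id`, `condition` ("sensitive"/"resistant"), `bio_rep`, `tech_rep`,
#'   `dye` ("Cy3", "Cy5" or "none"). For ratio matrices `dye` is the dye of the
#'   resistant-condition channel and is used to undo dye swaps.
#' @param layer One of "mRNA", "miRNA", "protein".
#' @param value_type "intensity" (per-sample log2 values, both conditions
#'   present) or "ratio" (per-array log2 resistant/sensitive contrasts).
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `samples`, `layer`, `value_type`.
#' @export
expression_matrix <- function(values, samples, layer = c("mRNA", "miRNA", "protein"),
                              value_type = c("intensity", "ratio")) {
  layer <- match.arg(layer)
  value_type <- match.arg(value_type)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) stop("values must have feature ids as row names")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "condition", "bio_rep", "tech_rep", "dye")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop("sample metadata missing columns: ", paste(miss, collapse = ", "))
  if (nrow(samples) != ncol(values))
    stop("sample metadata has ", nrow(samples), " rows but values has ", ncol(values), " columns")
  if (is.null(colnames(values))) colnames(values) <- samples$sample_id
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup)) stop("duplicate feature ids: ", paste(dup, collapse = ", "))
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  bad <- setdiff(samples$condition, c("sensitive", "resistant"))
  if (length(bad)) stop("unknown condition: ", paste(bad, collapse = ", "))
  if (value_type == "intensity") {
    if (length(unique(samples$condition)) < 2)
      stop("intensity matrix must contain samples from both conditions")
  } else {
    if (!all(samples$dye %in% c("Cy3", "Cy5")))
      stop("ratio matrix requires dye annotation (Cy3/Cy5) for every array")
  }
  structure(list(values = values, samples = samples, layer = layer,
                 value_type = value_type),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s, %s]: %d features x %d samples\n",
              x$layer, x$value_type, nrow(x$values), ncol(x$values)))
  tab <- table(x$samples$condition)
  cat("  conditions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read a delimited expression table
#'
#' Reads a tab-delimited table whose first column holds feature ids and whose
#' remaining columns are samples, matched by name against `meta`.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param layer Omics layer of the data.
#' @param meta Sample metadata data frame (see [expression_matrix()]); must
#'   cover every sample column present in the file.
#' @param value_type Passed to [expression_matrix()].
#' @return An `expr_matrix`. Empty cells and "NA" are read as missing.
#' @export
read_expression_table <- function(path, layer, meta, value_type = "intensity") {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           na.strings = c("", "NA"), stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression table needs a feature-id column plus samples: ", path)
  ids <- as.character(tab[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate feature ids in ", path, ": ", paste(dup, collapse = ", "))
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  unknown <- setdiff(colnames(vals), meta$sample_id)
  if (length(unknown))
    stop("samples in file absent from metadata: ", paste(unknown, collapse = ", "))
  meta <- meta[match(colnames(vals), meta$sample_id), , drop = FALSE]
  expression_matrix(vals, meta, layer = layer, value_type = value_type)
}

# Write a data frame as TSV with doubles rendered at full (%.17g) precision
# so that write -> read round trips are numerically exact.
.write_tsv <- function(df, path) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      v <- df[[j]]
      s <- sprintf("%.17g", v)
      s[is.na(v)] <- NA_character_
      df[[j]] <- s
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
}

#' Write an expression matrix to a delimited table
#'
#' @param mat An `expr_matrix`.
#' @param path Output path; missing values written as "NA".
#' @return Invisibly, `path`.
#' @export
write_expression_table <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat$values), mat$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
  invisible(path)
}

#' Read a scored miRNA-to-gene target prediction table
#'
#' Expects three tab-delimited columns: miRNA id, gene id, prediction score
#' (mirSVR-style, more negative = stronger). Duplicate (miRNA, gene) rows are
#' collapsed keeping the most negative score.
#'
#' @param path Path to the table (header row required).
#' @return A data frame of class `target_map` with columns `mirna_id`,
#'   `gene_id`, `score`.
#' @export
read_target_map <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(tab) == 0) {
    return(target_map(data.frame(mirna_id = character(), gene_id = character(),
                                 score = numeric(), stringsAsFactors = FALSE)))
  }
  if (ncol(tab) < 3) stop("target map needs columns (miRNA, gene, score): ", path)
  score <- suppressWarnings(as.numeric(tab[[3]]))
  bad <- which(is.na(score) & !is.na(tab[[3]]) & tab[[3]] != "NA")
  if (length(bad))
    stop("non-numeric score in ", path, " at row ", paste(bad, collapse = ", "))
  target_map(data.frame(mirna_id = tab[[1]], gene_id = tab[[2]], score = score,
                        stringsAsFactors = FALSE))
}

#' Construct a target map, collapsing duplicate pairs
#'
#' @param df Data frame with columns `mirna_id`, `gene_id`, `score`.
#' @return A `target_map` data frame; duplicated pairs keep the most negative
#'   (strongest) score, rows ordered canonically by (miRNA, gene).
#' @export
target_map <- function(df) {
  stopifnot(all(c("mirna_id", "gene_id", "score") %in% names(df)))
  if (any(!is.finite(df$score) & !is.na(df$score))) stop("target scores must be finite")
  if (nrow(df)) {
    df <- df[order(df$mirna_id, df$gene_id, df$score), , drop = FALSE]
    df <- df[!duplicated(df[c("mirna_id", "gene_id")]), , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("target_map", "data.frame")
  df
}

#' Write a target map
#' @param tm A `target_map`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_target_map <- function(tm, path) {
  .write_tsv(as.data.frame(tm), path)
  invisible(path)
}

#' Read an annotation catalog (category to gene-set mapping)
#'
#' Expects tab-delimited columns `category_id`, `gene_id` and optionally
#' `name`; one row per (category, gene) membership.
#'
#' @param path Path to the table (header row required).
#' @return A named list of character vectors (gene ids per category), with a
#'   `category_names` attribute; class `annotation_catalog`.
#' @export
read_catalog <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2) stop("catalog needs columns (category_id, gene_id): ", path)
  annotation_catalog(split(tab[[2]], tab[[1]]),
                     names = if (ncol(tab) >= 3) {
                       nm <- tapply(tab[[3]], tab[[1]], `[`, 1)
                       stats::setNames(as.character(nm), names(nm))
                     })
}

#' Construct an annotation catalog
#' @param sets Named list of character vectors of gene ids.
#' @param names Optional named character vector of human-readable category names.
#' @return An `annotation_catalog`.
#' @export
annotation_catalog <- function(sets, names = NULL) {
  sets <- lapply(sets, function(g) sort(unique(as.character(g))))
  if (any(lengths(sets) == 0)) stop("catalog categories must be non-empty")
  sets <- sets[order(base::names(sets))]
  structure(sets, category_names = names, class = "annotation_catalog")
}

#' Read a two-column gene-gene interaction edge list
#' @param path Tab-delimited file with header and two gene-id columns.
#' @return Data frame with columns `gene_a`, `gene_b`.
#' @export
read_edge_list <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(tab) == 0) return(data.frame(gene_a = character(), gene_b = character(),
                                        stringsAsFactors = FALSE))
  if (ncol(tab) < 2) stop("edge list needs two gene-id columns: ", path)
  data.frame(gene_a = tab[[1]], gene_b = tab[[2]], stringsAsFactors = FALSE)
}

#' Construct an annotated interaction network
#'
#' Nodes carry the layer-wise expression directions used for display (the fill
#' vs border colouring of miRNA-target network figures); edges are either
#' predicted miRNA-target relations or gene-gene pathway interactions.
#'
#' @param nodes Data frame with columns `id`, `node_kind` ("gene", "miRNA",
#'   "protein"), `mrna_direction` and `protein_direction` ("up"/"down"/"none").
#' @param edges Data frame with columns `source`, `target`, `edge_kind`
#'   ("mirna_target" or "gene_gene").
#' @return An object of class `omics_network` with canonically ordered rows.
#' @export
omics_network <- function(nodes, edges) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(nodes) == 0)
    nodes <- data.frame(id = character(), node_kind = character(),
                        mrna_direction = character(), protein_direction = character(),
                        stringsAsFactors = FALSE)
  if (nrow(edges) == 0)
    edges <- data.frame(source = character(), target = character(),
                        edge_kind = character(), stringsAsFactors = FALSE)
  stopifnot(all(c("id", "node_kind", "mrna_direction", "protein_direction") %in% names(nodes)),
            all(c("source", "target", "edge_kind") %in% names(edges)))
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (!all(nodes$node_kind %in% c("gene", "miRNA", "protein"))) stop("bad node_kind")
  if (!all(edges$edge_kind %in% c("mirna_target", "gene_gene"))) stop("bad edge_kind")
  missing_ep <- setdiff(c(edges$source, edges$target), nodes$id)
  if (length(missing_ep))
    stop("edge endpoints absent from nodes: ", paste(missing_ep, collapse = ", "))
  key <- paste(edges$source, edges$target, edges$edge_kind)
  edges <- edges[!duplicated(key), , drop = FALSE]
  nodes <- nodes[order(nodes$id), c("id", "node_kind", "mrna_direction", "protein_direction")]
  edges <- edges[order(edges$source, edges$target, edges$edge_kind),
                 c("source", "target", "edge_kind")]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "omics_network")
}

#' @export
print.omics_network <- function(x, ...) {
  cat(sprintf("omics_network: %d nodes, %d edges\n", nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Export a network in Cytoscape SIF format
#'
#' Writes one `source<TAB>edge_kind<TAB>target` line per edge, and a companion
#' node-attribute table (`id`, `node_kind`, `mrna_direction`,
#' `protein_direction`) alongside. [read_sif()] on the pair reproduces the
#' network exactly.
#'
#' @param network An `omics_network`.
#' @param path SIF output path.
#' @param attr_path Node-attribute table path; defaults to `path` with a
#'   `_nodes.tsv` suffix.
#' @return Invisibly, `c(path, attr_path)`.
#' @export
write_sif <- function(network, path, attr_path = NULL) {
  if (is.null(attr_path))
    attr_path <- paste0(sub("\\.sif$", "", path), "_nodes.tsv")
  lines <- if (nrow(network$edges)) {
    paste(network$edges$source, network$edges$edge_kind, network$edges$target, sep = "\t")
  } else character()
  writeLines(lines, path)
  utils::write.table(network$nodes, attr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, attr_path))
}

#' Read a network back from SIF plus node-attribute table
#' @param path SIF file written by [write_sif()].
#' @param attr_path Node-attribute table path (same default as [write_sif()]).
#' @return An `omics_network`.
#' @export
read_sif <- function(path, attr_path = NULL) {
  if (is.null(attr_path))
    attr_path <- paste0(sub("\\.sif$", "", path), "_nodes.tsv")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  edges <- if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) != 3)) stop("malformed SIF line in ", path)
    data.frame(source = vapply(parts, `[`, "", 1),
               edge_kind = vapply(parts, `[`, "", 2),
               target = vapply(parts, `[`, "", 3),
               stringsAsFactors = FALSE)[, c("source", "target", "edge_kind")]
  } else data.frame(source = character(), target = character(), edge_kind = character(),
                    stringsAsFactors = FALSE)
  nodes <- utils::read.delim(attr_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, colClasses = "character")
  omics_network(nodes, edges)
}
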