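#' Assemble a miRNA-target network with expression-annotated nodes
#'
#' Builds the network whose nodes are miRNAs and genes from a set of pair
#' links, with predicted miRNA-target edges and gene-gene pathway edges
#' restricted to genes present in the network. Node attributes carry the mRNA
#' direction (node fill in the published figures) and the protein direction
#' (node border).
#'
#' @param pairs Pair-link data frame from [pair_links()] (typically the `anti`
#'   subset for the post-transcriptional network).
#' @param gene_gene_edges Optional data frame (`gene_a`, `gene_b`) of pathway
#'   interactions; edges touching a gene outside the network are dropped (a
#'   message reports the count).
#' @param de_genes,de_proteins Optional `de_result` tables supplying node
#'   direction annotations.
#' @param de_mirnas Optional miRNA `de_result` for miRNA node directions
#'   (stored in `mrna_direction`).
#' @return An `omics_network`.
#' @export
build_network <- function(pairs, gene_gene_edges = NULL, de_genes = NULL,
                          de_proteins = NULL, de_mirnas = NULL) {
  genes <- unique(pairs$gene_id)
  mirnas <- unique(pairs$mirna_id)
  dir_of <- function(ids, de) {
    if (is.null(de)) return(rep("none", length(ids)))
    st <- de$status[match(ids, de$feature_id)]
    ifelse(is.na(st) | st == "ns", "none", st)
  }
  nodes <- rbind(
    data.frame(id = mirnas, node_kind = rep("miRNA", length(mirnas)),
               mrna_direction = dir_of(mirnas, de_mirnas),
               protein_direction = rep("none", length(mirnas)),
               stringsAsFactors = FALSE),
    data.frame(id = genes, node_kind = rep("gene", length(genes)),
               mrna_direction = dir_of(genes, de_genes),
               protein_direction = dir_of(genes, de_proteins),
               stringsAsFactors = FALSE))
  edges <- data.frame(source = pairs$mirna_id, target = pairs$gene_id,
                      edge_kind = rep("mirna_target", nrow(pairs)),
                      stringsAsFactors = FALSE)
  if (!is.null(gene_gene_edges) && nrow(gene_gene_edges)) {
    keep <- gene_gene_edges$gene_a %in% genes & gene_gene_edges$gene_b %in% genes
    if (any(!keep))
      message(sum(!keep), " gene-gene edge(s) dropped (endpoint outside network)")
    if (any(keep))
      edges <- rbind(edges,
                     data.frame(source = gene_gene_edges$gene_a[keep],
                                target = gene_gene_edges$gene_b[keep],
                                edge_kind = "gene_gene", stringsAsFactors = FALSE))
  }
  omics_network(nodes, edges)
}

#' Extract the pathway subnetwork induced by a gene set
#'
#' Keeps the genes of the selection plus any miRNA adjacent to at least one
#' retained gene; all surviving edges join retained nodes.
#'
#' @param network An `omics_network`.
#' @param gene_ids Character vector of genes defining the module (e.g. a
#'   pathway such as negative regulation of apoptosis or cell cycle).
#' @return An `omics_network` (possibly empty).
#' @export
extract_subnetwork <- function(network, gene_ids) {
  nodes <- network$nodes
  keep_genes <- nodes$id[nodes$node_kind != "miRNA" & nodes$id %in% gene_ids]
  e <- network$edges
  mir_adj <- e$source[e$edge_kind == "mirna_target" & e$target %in% keep_genes]
  keep <- c(keep_genes, intersect(nodes$id[nodes$node_kind == "miRNA"], mir_adj))
  nodes <- nodes[nodes$id %in% keep, , drop = FALSE]
  e <- e[e$source %in% keep & e$target %in% keep, , drop = FALSE]
  omics_network(nodes, e)
}
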