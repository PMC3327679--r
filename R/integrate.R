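#' Classify a miRNA-mRNA-protein sign pattern into a regulatory loop type
#'
#' With signs on the log fold changes of a differentially expressed miRNA, a
#' predicted target mRNA and its protein:
#' type A (coherent) has mRNA opposite to the miRNA with the protein following
#' the mRNA — the degradation scenario, where the miRNA's action propagates to
#' the protein; type B (incoherent) has mRNA co-expressed with the miRNA but
#' protein opposite — translational repression without mRNA decay; type C
#' (incoherent) has all three co-directional — the expression pattern does not
#' support a miRNA action on the target. The remaining pattern (mRNA opposite,
#' protein back at the miRNA's sign) is left unclassified.
#'
#' @param s_mirna,s_mrna,s_protein Signs in `{-1, +1}` (vectors recycle).
#' @return Data frame with columns `loop_type` ("A"/"B"/"C"/"unclassified")
#'   and `coherence` ("coherent"/"incoherent"/"none").
#' @export
classify_loop <- function(s_mirna, s_mrna, s_protein) {
  n <- max(length(s_mirna), length(s_mrna), length(s_protein))
  s_mirna <- rep_len(s_mirna, n); s_mrna <- rep_len(s_mrna, n)
  s_protein <- rep_len(s_protein, n)
  if (any(!c(s_mirna, s_mrna, s_protein) %in% c(-1, 1)))
    stop("signs must be -1 or +1")
  type <- ifelse(s_mrna == -s_mirna & s_protein == s_mrna, "A",
          ifelse(s_mrna == s_mirna & s_protein == -s_mirna, "B",
          ifelse(s_mrna == s_mirna & s_protein == s_mirna, "C", "unclassified")))
  coherence <- c(A = "coherent", B = "incoherent", C = "incoherent",
                 unclassified = "none")[type]
  data.frame(loop_type = unname(type), coherence = unname(coherence),
             stringsAsFactors = FALSE)
}

#' Pair differentially expressed miRNAs with predicted targets
#'
#' Restricts the target-prediction map to pairs in which both the miRNA and
#' the target are differentially expressed, and labels each pair as `anti`
#' (inverse relationship) or `co` (co-expressed). In `sign` mode the label
#' compares the signs of the log fold changes; in `correlation` mode it is
#' based on the Pearson correlation of the matched biological-replicate
#' profiles.
#'
#' @param de_mirnas,de_targets `de_result` tables for the miRNA layer and the
#'   target layer (mRNA or protein); only `status != "ns"` rows are used.
#' @param target_map A `target_map`.
#' @param mode "sign" (default) or "correlation".
#' @param target_layer "mRNA" or "protein", recorded in the output.
#' @param score_max Keep predictions with score <= this cutoff (mirSVR-style,
#'   more negative = stronger).
#' @param mirna_mat,target_mat Collapsed `expr_matrix` objects, required in
#'   correlation mode (>= 4 matched biological replicates).
#' @param r_min Anti-correlation threshold: `anti` when `r <= -r_min`.
#' @return Data frame of pair links: `mirna_id`, `gene_id`, `relation`,
#'   `layer_of_target`, `score`, plus the two log fold changes.
#' @export
pair_links <- function(de_mirnas, de_targets, target_map, mode = c("sign", "correlation"),
                       target_layer = "mRNA", score_max = -0.1,
                       mirna_mat = NULL, target_mat = NULL, r_min = 0.7) {
  mode <- match.arg(mode)
  mir <- de_mirnas[de_mirnas$status != "ns", , drop = FALSE]
  tgt <- de_targets[de_targets$status != "ns", , drop = FALSE]
  tm <- target_map[target_map$score <= score_max, , drop = FALSE]
  tm <- tm[tm$mirna_id %in% mir$feature_id & tm$gene_id %in% tgt$feature_id, , drop = FALSE]
  empty <- data.frame(mirna_id = character(), gene_id = character(),
                      relation = character(), layer_of_target = character(),
                      score = numeric(), mirna_logfc = numeric(),
                      target_logfc = numeric(), stringsAsFactors = FALSE)
  if (!nrow(tm)) return(empty)
  mfc <- mir$logFC[match(tm$mirna_id, mir$feature_id)]
  tfc <- tgt$logFC[match(tm$gene_id, tgt$feature_id)]
  if (mode == "sign") {
    relation <- ifelse(sign(mfc) != sign(tfc), "anti", "co")
  } else {
    if (is.null(mirna_mat) || is.null(target_mat))
      stop("correlation mode requires mirna_mat and target_mat")
    r <- .pair_correlation(tm, mirna_mat, target_mat)
    relation <- ifelse(r <= -r_min, "anti", "co")
  }
  out <- data.frame(mirna_id = tm$mirna_id, gene_id = tm$gene_id,
                    relation = relation, layer_of_target = target_layer,
                    score = tm$score, mirna_logfc = mfc, target_logfc = tfc,
                    stringsAsFactors = FALSE)
  out <- out[order(out$mirna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Pearson correlation of contrast-comparable replicate profiles. Intensity
# matrices contribute per-bio-rep resistant-sensitive differences so that the
# profiles are matched across layers by biological replicate.
.pair_correlation <- function(tm, mirna_mat, target_mat) {
  pm <- .bio_profile(mirna_mat)
  pt <- .bio_profile(target_mat)
  common <- intersect(colnames(pm), colnames(pt))
  if (length(common) < 4)
    stop("correlation mode needs at least 4 matched biological replicates")
  vapply(seq_len(nrow(tm)), function(i) {
    x <- pm[tm$mirna_id[i], common]; y <- pt[tm$gene_id[i], common]
    suppressWarnings(stats::cor(x, y, use = "complete.obs"))
  }, 0)
}

.bio_profile <- function(mat) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (mat$value_type == "ratio") {
    x <- mat$values
    flip <- mat$samples$dye == "Cy3"
    x[, flip] <- -x[, flip, drop = FALSE]
    colnames(x) <- paste0("bio", mat$samples$bio_rep)
    x
  } else {
    s <- mat$samples
    bios <- sort(unique(s$bio_rep))
    out <- sapply(bios, function(b) {
      r <- rowMeans(mat$values[, s$condition == "resistant" & s$bio_rep == b,
                               drop = FALSE], na.rm = TRUE)
      sn <- rowMeans(mat$values[, s$condition == "sensitive" & s$bio_rep == b,
                                drop = FALSE], na.rm = TRUE)
      r - sn
    })
    colnames(out) <- paste0("bio", bios)
    rownames(out) <- rownames(mat$values)
    out
  }
}

#' Genes altered at both the mRNA and the protein level
#'
#' Intersects the differentially expressed gene and protein lists (proteins
#' mapped to gene ids) and reports whether the two log fold changes agree in
#' sign.
#'
#' @param de_genes,de_proteins `de_result` tables.
#' @param protein_map Optional data frame (`protein_id`, `gene_id`) mapping
#'   protein features to genes; by default protein feature ids are taken as
#'   gene ids. One-to-many mappings expand.
#' @return Data frame with `gene_id`, `mrna_logfc`, `protein_logfc`,
#'   `concordant`.
#' @export
mrna_protein_core <- function(de_genes, de_proteins, protein_map = NULL) {
  g <- de_genes[de_genes$status != "ns", , drop = FALSE]
  p <- de_proteins[de_proteins$status != "ns", , drop = FALSE]
  if (is.null(protein_map))
    protein_map <- data.frame(protein_id = p$feature_id, gene_id = p$feature_id,
                              stringsAsFactors = FALSE)
  pm <- protein_map[protein_map$protein_id %in% p$feature_id, , drop = FALSE]
  pm <- pm[pm$gene_id %in% g$feature_id, , drop = FALSE]
  out <- data.frame(
    gene_id = pm$gene_id,
    mrna_logfc = g$logFC[match(pm$gene_id, g$feature_id)],
    protein_logfc = p$logFC[match(pm$protein_id, p$feature_id)],
    stringsAsFactors = FALSE)
  out <- out[!duplicated(out$gene_id), , drop = FALSE]
  out$concordant <- sign(out$mrna_logfc) == sign(out$protein_logfc)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate and classify miRNA-mRNA-protein regulatory loops
#'
#' For every predicted (miRNA, gene) pair whose miRNA, mRNA and protein are
#' all differentially expressed, emits a loop with signs taken from the log
#' fold changes and a type from [classify_loop()].
#'
#' @param de_mirnas,de_genes,de_proteins `de_result` tables.
#' @param target_map A `target_map`.
#' @param score_max Prediction-score cutoff (keep score <= cutoff).
#' @param protein_map Optional protein-to-gene mapping as in
#'   [mrna_protein_core()].
#' @return Data frame of class `loop_table`: `mirna_id`, `gene_id`, `s_mirna`,
#'   `s_mrna`, `s_protein`, `loop_type`, `coherence`; canonically ordered, no
#'   duplicate (miRNA, gene) triplets. Per-type counts via [loop_counts()].
#' @export
enumerate_loops <- function(de_mirnas, de_genes, de_proteins, target_map,
                            score_max = -0.1, protein_map = NULL) {
  mir <- de_mirnas[de_mirnas$status != "ns", , drop = FALSE]
  gen <- de_genes[de_genes$status != "ns", , drop = FALSE]
  pro <- de_proteins[de_proteins$status != "ns", , drop = FALSE]
  if (is.null(protein_map))
    protein_map <- data.frame(protein_id = pro$feature_id, gene_id = pro$feature_id,
                              stringsAsFactors = FALSE)
  pm <- protein_map[protein_map$protein_id %in% pro$feature_id, , drop = FALSE]
  tm <- target_map[target_map$score <= score_max, , drop = FALSE]
  tm <- tm[tm$mirna_id %in% mir$feature_id & tm$gene_id %in% gen$feature_id &
             tm$gene_id %in% pm$gene_id, , drop = FALSE]
  empty <- data.frame(mirna_id = character(), gene_id = character(),
                      s_mirna = numeric(), s_mrna = numeric(), s_protein = numeric(),
                      loop_type = character(), coherence = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(tm)) { class(empty) <- c("loop_table", "data.frame"); return(empty) }
  tm <- merge(tm, pm, by = "gene_id")
  s_mir <- sign(mir$logFC[match(tm$mirna_id, mir$feature_id)])
  s_mrna <- sign(gen$logFC[match(tm$gene_id, gen$feature_id)])
  s_pro <- sign(pro$logFC[match(tm$protein_id, pro$feature_id)])
  cls <- classify_loop(s_mir, s_mrna, s_pro)
  out <- data.frame(mirna_id = tm$mirna_id, gene_id = tm$gene_id,
                    s_mirna = s_mir, s_mrna = s_mrna, s_protein = s_pro,
                    loop_type = cls$loop_type, coherence = cls$coherence,
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[c("mirna_id", "gene_id")]), , drop = FALSE]
  out <- out[order(out$mirna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("loop_table", "data.frame")
  out
}

#' Per-type loop counts
#' @param loops A `loop_table`.
#' @return Named integer vector over A, B, C, unclassified.
#' @export
loop_counts <- function(loops) {
  vapply(c(A = "A", B = "B", C = "C", unclassified = "unclassified"),
         function(t) sum(loops$loop_type == t), 0L)
}

#' @export
print.loop_table <- function(x, ...) {
  cnt <- loop_counts(x)
  cat(sprintf("loop_table: %d loops (A=%d coherent, B=%d, C=%d incoherent, %d unclassified)\n",
              nrow(x), cnt["A"], cnt["B"], cnt["C"], cnt["unclassified"]))
  invisible(x)
}

#' Single-linkage genomic clustering of miRNAs
#'
#' Groups miRNAs on the same chromosome whose consecutive sorted positions are
#' separated by strictly less than `max_gap_kb` kilobases.
#'
#' @param coords Data frame with columns `mirna_id`, `chromosome`, `position`
#'   (bp, non-negative).
#' @param max_gap_kb Gap threshold in kb (strict; a gap of exactly this size
#'   splits clusters).
#' @return Data frame with one row per cluster: `cluster_id`, `chromosome`,
#'   `n_members`, `members` (comma-separated in position order), `span_kb`.
#' @export
cluster_mirnas <- function(coords, max_gap_kb = 1000) {
  stopifnot(all(c("mirna_id", "chromosome", "position") %in% names(coords)))
  if (anyDuplicated(coords$mirna_id))
    stop("duplicate mirna_id: ",
         paste(unique(coords$mirna_id[duplicated(coords$mirna_id)]), collapse = ", "))
  if (any(coords$position < 0)) stop("positions must be non-negative")
  out <- list()
  for (chr in sort(unique(coords$chromosome))) {
    cc <- coords[coords$chromosome == chr, , drop = FALSE]
    cc <- cc[order(cc$position), , drop = FALSE]
    gap <- c(Inf, diff(cc$position))
    cl <- cumsum(gap >= max_gap_kb * 1000)
    for (k in unique(cl)) {
      mem <- cc[cl == k, , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        chromosome = chr, n_members = nrow(mem),
        members = paste(mem$mirna_id, collapse = ","),
        span_kb = (max(mem$position) - min(mem$position)) / 1000,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chromosome = character(), n_members = integer(),
                      members = character(), span_kb = numeric(),
                      stringsAsFactors = FALSE)
  res <- cbind(cluster_id = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}
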