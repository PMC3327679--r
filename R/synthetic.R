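#' Configuration for the synthetic three-layer array generator
#'
#' Defaults emulate the study design: two-color 44K-class gene arrays scaled
#' to 10,000 probes, an 800-feature single-channel miRNA platform and a
#' 725-antibody panel, with 3 biological x 4 technical replicates per
#' condition, dye swaps on the two-color platforms, 47 differentially
#' expressed miRNAs, 336 differential proteins, and planted regulatory loops
#' in the published 38/34/28 type proportions.
#'
#' @param n_genes,n_mirnas,n_proteins Platform sizes (`n_proteins <= n_genes`;
#'   antibodies are mapped to gene ids).
#' @param n_bio,n_tech Biological and technical replicates per condition.
#' @param dye_swap Swap dye assignment on even technical replicates.
#' @param n_de_genes,n_de_mirnas,n_de_proteins Differentially expressed
#'   feature counts (loop members included).
#' @param logfc_magnitude Absolute planted log2 fold change.
#' @param noise_sd Total Gaussian noise sd on the log2 scale, split equally
#'   between the biological and technical components.
#' @param loops_per_type Named integer vector over `A`, `B`, `C`,
#'   `unclassified`.
#' @param n_decoy_targets Decoy target-prediction edges in addition to the
#'   planted pairs.
#' @param target_score_range Range of mirSVR-style prediction scores.
#' @param background_mu,background_sd Local-background distribution of the
#'   two-color platforms.
#' @param signal_alpha Mean of the exponential per-feature brightness.
#' @param low_signal_fraction Fraction of null mRNA probes planted below the
#'   local background (removed by the 60% filter).
#' @param seed RNG seed; generation is fully reproducible from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 10000, n_mirnas = 800, n_proteins = 725,
                       n_bio = 3, n_tech = 4, dye_swap = TRUE,
                       n_de_genes = 700, n_de_mirnas = 47, n_de_proteins = 336,
                       logfc_magnitude = 1.5, noise_sd = 0.25,
                       loops_per_type = c(A = 38, B = 34, C = 28, unclassified = 0),
                       n_decoy_targets = 2000,
                       target_score_range = c(-1.2, -0.1),
                       background_mu = 100, background_sd = 20, signal_alpha = 500,
                       low_signal_fraction = 0.05, seed = 1) {
  lp <- c(A = 0, B = 0, C = 0, unclassified = 0)
  lp[names(loops_per_type)] <- loops_per_type
  total_loops <- sum(lp)
  if (n_proteins > n_genes) stop("n_proteins must be <= n_genes")
  if (noise_sd < 0 || background_sd < 0) stop("noise/background sd must be >= 0")
  if (signal_alpha <= 0) stop("signal_alpha must be > 0")
  if (low_signal_fraction < 0 || low_signal_fraction > 1)
    stop("low_signal_fraction must be in [0, 1]")
  if (total_loops > min(n_de_genes, n_de_proteins, n_proteins))
    stop("infeasible loop counts: need <= min(n_de_genes, n_de_proteins, n_proteins)")
  if (total_loops > 0 && n_de_mirnas < 1)
    stop("infeasible loop counts: no differentially expressed miRNAs")
  if (n_de_genes > n_genes || n_de_mirnas > n_mirnas || n_de_proteins > n_proteins)
    stop("more DE features requested than platform features")
  structure(list(n_genes = n_genes, n_mirnas = n_mirnas, n_proteins = n_proteins,
                 n_bio = n_bio, n_tech = n_tech, dye_swap = dye_swap,
                 n_de_genes = n_de_genes, n_de_mirnas = n_de_mirnas,
                 n_de_proteins = n_de_proteins,
                 logfc_magnitude = logfc_magnitude, noise_sd = noise_sd,
                 loops_per_type = lp, n_decoy_targets = n_decoy_targets,
                 target_score_range = target_score_range,
                 background_mu = background_mu, background_sd = background_sd,
                 signal_alpha = signal_alpha,
                 low_signal_fraction = low_signal_fraction, seed = seed),
            class = "sim_config")
}

#' Generate a synthetic three-layer bundle with known ground truth
#'
#' Produces raw two-color mRNA and protein array sets, a raw single-channel
#' miRNA matrix, a scored target map covering every planted loop pair plus
#' decoys, miRNA genomic coordinates containing a 5-member and a 3-member
#' cluster, a small annotation catalog and gene-gene edge list, and the
#' planted truth (per-layer DE status, true log fold changes, planted loops
#' and low-signal probes).
#'
#' Biological-replicate effects of a planted loop's mRNA and protein are
#' coupled to the miRNA's (with the sign of their planted relation), so that
#' anti-correlated pairs really are anti-correlated across replicates; decoy
#' target edges emulate predicted targets that are not differentially
#' expressed and never connect a DE miRNA to a gene altered at both layers.
#'
#' @param config A `sim_config`.
#' @return List of class `sim_bundle` with elements `mrna` (`two_color_set`),
#'   `mirna` (raw intensity `expr_matrix`), `protein` (`two_color_set`),
#'   `target_map`, `mirna_coords`, `catalog`, `gene_edges`, `truth`, `config`.
#' @export
generate_omics <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cf <- config
  genes <- sprintf("G%05d", seq_len(cf$n_genes))
  mirnas <- sprintf("miR-%04d", seq_len(cf$n_mirnas))
  protein_panel <- sort(sample(genes, cf$n_proteins))

  ## ---- planted truth -------------------------------------------------
  de_mirnas <- sort(sample(mirnas, cf$n_de_mirnas))
  s_mir_all <- stats::setNames(sample(c(-1, 1), cf$n_de_mirnas, replace = TRUE), de_mirnas)
  lp <- cf$loops_per_type
  total_loops <- sum(lp)
  loop_genes <- sort(sample(protein_panel, total_loops))
  loop_mirs <- sample(de_mirnas, total_loops, replace = TRUE)
  loop_type <- rep(names(lp), lp)
  s_m <- s_mir_all[loop_mirs]
  s_g <- ifelse(loop_type %in% c("A", "unclassified"), -s_m, s_m)
  s_p <- ifelse(loop_type == "A", -s_m,
         ifelse(loop_type == "B", -s_m,
         ifelse(loop_type == "C", s_m, s_m)))
  loops <- data.frame(mirna_id = loop_mirs, gene_id = loop_genes,
                      s_mirna = unname(s_m), s_mrna = unname(s_g),
                      s_protein = unname(s_p), stringsAsFactors = FALSE)
  cls <- classify_loop(loops$s_mirna, loops$s_mrna, loops$s_protein)
  loops$loop_type <- cls$loop_type
  loops$coherence <- cls$coherence
  stopifnot(identical(unname(loop_counts(loops)[names(lp)]), unname(as.integer(lp))))

  lfc_gene <- stats::setNames(numeric(cf$n_genes), genes)
  lfc_gene[loops$gene_id] <- loops$s_mrna * cf$logfc_magnitude
  extra_g <- sample(setdiff(genes, loops$gene_id), cf$n_de_genes - total_loops)
  lfc_gene[extra_g] <- sample(c(-1, 1), length(extra_g), TRUE) * cf$logfc_magnitude

  lfc_prot <- stats::setNames(numeric(cf$n_proteins), protein_panel)
  lfc_prot[loops$gene_id] <- loops$s_protein * cf$logfc_magnitude
  extra_p <- sample(setdiff(protein_panel, loops$gene_id),
                    cf$n_de_proteins - total_loops)
  lfc_prot[extra_p] <- sample(c(-1, 1), length(extra_p), TRUE) * cf$logfc_magnitude

  lfc_mir <- stats::setNames(numeric(cf$n_mirnas), mirnas)
  lfc_mir[de_mirnas] <- s_mir_all * cf$logfc_magnitude

  null_genes <- setdiff(genes, c(names(lfc_gene)[lfc_gene != 0],
                                 names(lfc_prot)[lfc_prot != 0]))
  low_signal <- sort(sample(null_genes,
                            round(cf$low_signal_fraction * length(null_genes))))

  ## bio-replicate effects, drawn per condition so that the
  ## resistant-vs-sensitive contrast has variance noise_sd^2/2; loop targets
  ## inherit the miRNA's effect with the sign of the planted relation
  sd_bio <- cf$noise_sd / 2
  rel_g <- loops$s_mrna * loops$s_mirna
  rel_p <- loops$s_protein * loops$s_mirna
  draw_bio <- function() {
    bm <- matrix(stats::rnorm(cf$n_mirnas * cf$n_bio, 0, sd_bio),
                 cf$n_mirnas, cf$n_bio, dimnames = list(mirnas, NULL))
    bg <- matrix(stats::rnorm(cf$n_genes * cf$n_bio, 0, sd_bio),
                 cf$n_genes, cf$n_bio, dimnames = list(genes, NULL))
    bp <- matrix(stats::rnorm(cf$n_proteins * cf$n_bio, 0, sd_bio),
                 cf$n_proteins, cf$n_bio, dimnames = list(protein_panel, NULL))
    bg[loops$gene_id, ] <- rel_g * bm[loops$mirna_id, , drop = FALSE]
    bp[loops$gene_id, ] <- rel_p * bm[loops$mirna_id, , drop = FALSE]
    list(mir = bm, gene = bg, prot = bp)
  }
  bio_s <- draw_bio()
  bio_r <- draw_bio()

  ## ---- two-color layers ----------------------------------------------
  make_two_color <- function(ids, lfc, bio_sens, bio_res, low = character()) {
    n <- length(ids)
    base <- stats::runif(n, 6, 12)
    ## exponential brightness with a floor at 0.2*alpha so that expressed
    ## features sit clear of the additive background
    amp <- cf$signal_alpha * (0.2 + stats::rexp(n, 1))
    arrays <- list(); meta <- list(); k <- 0
    for (b in seq_len(cf$n_bio)) for (t in seq_len(cf$n_tech)) {
      k <- k + 1
      swap <- cf$dye_swap && (t %% 2 == 0)
      xs <- base + unname(bio_sens[ids, b]) + stats::rnorm(n, 0, cf$noise_sd)
      xr <- base + unname(lfc[ids]) + unname(bio_res[ids, b]) +
        stats::rnorm(n, 0, cf$noise_sd)
      sig_s <- amp * 2^(xs - base)
      sig_r <- amp * 2^(xr - base)
      bg_true_s <- stats::rnorm(n, cf$background_mu, cf$background_sd)
      bg_true_r <- stats::rnorm(n, cf$background_mu, cf$background_sd)
      bg_meas_s <- pmax(stats::rnorm(n, cf$background_mu, cf$background_sd), 0)
      bg_meas_r <- pmax(stats::rnorm(n, cf$background_mu, cf$background_sd), 0)
      fg_s <- pmax(bg_true_s, 0) + sig_s
      fg_r <- pmax(bg_true_r, 0) + sig_r
      if (length(low)) {
        idx <- match(low, ids)
        fg_s[idx] <- bg_meas_s[idx] * stats::runif(length(idx), 0.3, 0.8)
        fg_r[idx] <- bg_meas_r[idx] * stats::runif(length(idx), 0.3, 0.8)
      }
      ## channel 1 is always Cy3; conditions swap on dye-swapped replicates
      if (!swap) {
        arrays[[k]] <- list(fg1 = fg_s, bg1 = bg_meas_s, fg2 = fg_r, bg2 = bg_meas_r)
        meta[[k]] <- data.frame(array_id = sprintf("b%dt%d", b, t), bio_rep = b,
                                tech_rep = t, dye_of_channel1 = "Cy3",
                                condition_ch1 = "sensitive",
                                condition_ch2 = "resistant",
                                stringsAsFactors = FALSE)
      } else {
        arrays[[k]] <- list(fg1 = fg_r, bg1 = bg_meas_r, fg2 = fg_s, bg2 = bg_meas_s)
        meta[[k]] <- data.frame(array_id = sprintf("b%dt%d", b, t), bio_rep = b,
                                tech_rep = t, dye_of_channel1 = "Cy3",
                                condition_ch1 = "resistant",
                                condition_ch2 = "sensitive",
                                stringsAsFactors = FALSE)
      }
    }
    two_color_set(ids, arrays, do.call(rbind, meta))
  }
  mrna_set <- make_two_color(genes, lfc_gene, bio_s$gene, bio_r$gene, low_signal)
  prot_set <- make_two_color(protein_panel, lfc_prot, bio_s$prot, bio_r$prot)

  ## ---- single-channel miRNA layer ------------------------------------
  n_m <- cf$n_mirnas
  base_m <- stats::runif(n_m, 6, 12)
  amp_m <- cf$signal_alpha * (0.2 + stats::rexp(n_m, 1))
  cols <- list(); smeta <- list(); k <- 0
  for (cond in c("sensitive", "resistant")) for (b in seq_len(cf$n_bio))
    for (t in seq_len(cf$n_tech)) {
      k <- k + 1
      bio_b <- if (cond == "resistant") bio_r$mir[, b] else bio_s$mir[, b]
      x <- base_m + unname(bio_b) + (cond == "resistant") * unname(lfc_mir) +
        stats::rnorm(n_m, 0, cf$noise_sd)
      cols[[k]] <- pmax(stats::rnorm(n_m, cf$background_mu, cf$background_sd), 0) +
        amp_m * 2^(x - base_m + 4)
      smeta[[k]] <- data.frame(sample_id = sprintf("%s_b%dt%d", substr(cond, 1, 3), b, t),
                               condition = cond, bio_rep = b, tech_rep = t,
                               dye = "none", stringsAsFactors = FALSE)
    }
  mir_vals <- do.call(cbind, cols)
  rownames(mir_vals) <- mirnas
  smeta <- do.call(rbind, smeta)
  colnames(mir_vals) <- smeta$sample_id
  mirna_mat <- expression_matrix(mir_vals, smeta, layer = "miRNA",
                                 value_type = "intensity")

  ## ---- target map -----------------------------------------------------
  sc <- sort(cf$target_score_range)
  planted <- data.frame(mirna_id = loops$mirna_id, gene_id = loops$gene_id,
                        score = stats::runif(total_loops, sc[1], sc[2]),
                        stringsAsFactors = FALSE)
  both_de <- intersect(names(lfc_gene)[lfc_gene != 0], names(lfc_prot)[lfc_prot != 0])
  decoys <- data.frame(mirna_id = sample(mirnas, cf$n_decoy_targets, TRUE),
                       gene_id = sample(genes, cf$n_decoy_targets, TRUE),
                       score = stats::runif(cf$n_decoy_targets, sc[1], sc[2]),
                       stringsAsFactors = FALSE)
  bad <- (decoys$mirna_id %in% de_mirnas & decoys$gene_id %in% both_de) |
    paste(decoys$mirna_id, decoys$gene_id) %in% paste(planted$mirna_id, planted$gene_id)
  decoys <- decoys[!bad, , drop = FALSE]
  tmap <- target_map(rbind(planted, decoys))

  ## ---- miRNA coordinates: one 5-member and one 3-member cluster --------
  chr <- paste0("chr", (seq_len(n_m) - 1) %% 22 + 1)
  pos <- 100e6 + ((seq_len(n_m) - 1) %/% 22) * 3e6
  chr[1:5] <- "chr13"; pos[1:5] <- 50e3 + (0:4) * 5e3
  chr[6:8] <- "chr19"; pos[6:8] <- 1e6 + (0:2) * 40e3
  coords <- data.frame(mirna_id = mirnas, chromosome = chr, position = pos,
                       stringsAsFactors = FALSE)

  ## ---- annotation catalog and gene-gene edges -------------------------
  up_g <- names(lfc_gene)[lfc_gene > 0]; down_g <- names(lfc_gene)[lfc_gene < 0]
  n_bg <- min(40, cf$n_genes)
  sets <- list(
    CAT01 = sample(c(up_g, sample(genes, n_bg)), min(60, length(up_g) + n_bg)),
    CAT02 = sample(c(down_g, sample(genes, n_bg)), min(60, length(down_g) + n_bg)))
  for (i in 3:8) sets[[sprintf("CAT%02d", i)]] <- sample(genes, min(50, cf$n_genes))
  catalog <- annotation_catalog(sets,
    names = stats::setNames(c("upregulated module", "downregulated module",
                              sprintf("random set %d", 3:8)), names(sets)))
  eg <- unique(c(loops$gene_id, sample(genes, min(150, cf$n_genes))))
  gene_edges <- data.frame(gene_a = sample(eg, 120, TRUE),
                           gene_b = sample(eg, 120, TRUE),
                           stringsAsFactors = FALSE)
  gene_edges <- gene_edges[gene_edges$gene_a != gene_edges$gene_b, , drop = FALSE]

  truth <- list(
    de_status = list(
      mRNA = stats::setNames(ifelse(lfc_gene > 0, "up", ifelse(lfc_gene < 0, "down", "ns")), genes),
      miRNA = stats::setNames(ifelse(lfc_mir > 0, "up", ifelse(lfc_mir < 0, "down", "ns")), mirnas),
      protein = stats::setNames(ifelse(lfc_prot > 0, "up", ifelse(lfc_prot < 0, "down", "ns")),
                                protein_panel)),
    true_logfc = list(mRNA = lfc_gene, miRNA = lfc_mir, protein = lfc_prot),
    planted_loops = loops,
    planted_low_signal = low_signal,
    protein_panel = protein_panel)

  structure(list(mrna = mrna_set, mirna = mirna_mat, protein = prot_set,
                 target_map = tmap, mirna_coords = coords, catalog = catalog,
                 gene_edges = gene_edges, truth = truth, config = config),
            class = "sim_bundle")
}

#' Write a synthetic bundle as a pipeline-ready fixture directory
#'
#' All files use the package's delimited formats; the truth tables and a YAML
#' echo of the configuration are written alongside.
#'
#' @param bundle A `sim_bundle`.
#' @param out_dir Output directory (created if needed).
#' @param overwrite Allow writing into a non-empty directory.
#' @return Invisibly, `out_dir`.
#' @export
write_fixture <- function(bundle, out_dir, overwrite = FALSE) {
  stopifnot(inherits(bundle, "sim_bundle"))
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite)
    stop("directory ", out_dir, " is not empty (use overwrite = TRUE)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  write_two_color(bundle$mrna, fp("mrna.tsv"), fp("mrna_arrays.tsv"))
  write_two_color(bundle$protein, fp("protein.tsv"), fp("protein_arrays.tsv"))
  write_expression_table(bundle$mirna, fp("mirna_raw.tsv"))
  utils::write.table(bundle$mirna$samples, fp("mirna_samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_target_map(bundle$target_map, fp("target_map.tsv"))
  .write_tsv(bundle$mirna_coords, fp("mirna_coords.tsv"))
  cat_df <- do.call(rbind, lapply(names(bundle$catalog), function(id)
    data.frame(category_id = id, gene_id = bundle$catalog[[id]],
               name = unname(attr(bundle$catalog, "category_names")[id]),
               stringsAsFactors = FALSE)))
  utils::write.table(cat_df, fp("catalog.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(bundle$gene_edges, fp("gene_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- bundle$truth
  de_df <- do.call(rbind, lapply(names(tr$de_status), function(layer)
    data.frame(layer = layer, feature_id = names(tr$de_status[[layer]]),
               status = unname(tr$de_status[[layer]]),
               true_logfc = unname(tr$true_logfc[[layer]]),
               stringsAsFactors = FALSE)))
  .write_tsv(de_df, fp("truth_de.tsv"))
  .write_tsv(tr$planted_loops, fp("truth_loops.tsv"))
  writeLines(tr$planted_low_signal, fp("truth_low_signal.txt"))
  cfg_out <- unclass(bundle$config)
  cfg_out$loops_per_type <- as.list(cfg_out$loops_per_type)
  yaml::write_yaml(cfg_out, fp("config.yaml"))
  invisible(out_dir)
}

#' Read a fixture directory back into a bundle
#' @param dir Directory written by [write_fixture()].
#' @return A `sim_bundle`.
#' @export
read_fixture <- function(dir) {
  fp <- function(f) file.path(dir, f)
  smeta <- utils::read.delim(fp("mirna_samples.tsv"), stringsAsFactors = FALSE)
  cfg <- yaml::read_yaml(fp("config.yaml"))
  cfg$loops_per_type <- unlist(cfg$loops_per_type)
  cfg$target_score_range <- unlist(cfg$target_score_range)
  config <- do.call(sim_config, cfg)
  de <- utils::read.delim(fp("truth_de.tsv"), stringsAsFactors = FALSE)
  tr <- list(
    de_status = lapply(split(de, de$layer), function(d)
      stats::setNames(d$status, d$feature_id))[c("mRNA", "miRNA", "protein")],
    true_logfc = lapply(split(de, de$layer), function(d)
      stats::setNames(d$true_logfc, d$feature_id))[c("mRNA", "miRNA", "protein")],
    planted_loops = utils::read.delim(fp("truth_loops.tsv"), stringsAsFactors = FALSE),
    planted_low_signal = readLines(fp("truth_low_signal.txt")))
  tr$protein_panel <- names(tr$de_status$protein)
  cat_df <- utils::read.delim(fp("catalog.tsv"), stringsAsFactors = FALSE)
  structure(list(
    mrna = read_two_color(fp("mrna.tsv"), fp("mrna_arrays.tsv")),
    mirna = read_expression_table(fp("mirna_raw.tsv"), "miRNA", smeta),
    protein = read_two_color(fp("protein.tsv"), fp("protein_arrays.tsv")),
    target_map = read_target_map(fp("target_map.tsv")),
    mirna_coords = utils::read.delim(fp("mirna_coords.tsv"), stringsAsFactors = FALSE),
    catalog = read_catalog(fp("catalog.tsv")),
    gene_edges = read_edge_list(fp("gene_edges.tsv")),
    truth = tr, config = config), class = "sim_bundle")
}
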