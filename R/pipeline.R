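#' Pipeline options
#'
#' Collects the tunable constants of the full analysis. Defaults are the
#' study's: mRNA selection at FDR <= 0.01 with |logFC| >= 1, miRNA and protein
#' at FDR <= 0.1, the 60% below-background filter, sign-based miRNA-target
#' pairing with a mirSVR-style score cutoff of -0.1, and 1000 kb miRNA
#' clustering.
#'
#' @param mrna_thresholds,mirna_thresholds,protein_thresholds Selection
#'   thresholds per layer (see [de_thresholds()]).
#' @param filter_max_fraction Below-background fraction above which a feature
#'   is removed.
#' @param pairing_mode "sign" or "correlation".
#' @param score_max Target-prediction score cutoff (keep score <= cutoff).
#' @param r_min Anti-correlation threshold for correlation mode.
#' @param cluster_gap_kb miRNA cluster gap threshold in kb.
#' @param lowess_span Span for lowess normalization.
#' @param normexp_offset Offset for normexp background correction.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(mrna_thresholds = de_thresholds("mRNA"),
                            mirna_thresholds = de_thresholds("miRNA"),
                            protein_thresholds = de_thresholds("protein"),
                            filter_max_fraction = 0.6,
                            pairing_mode = "sign", score_max = -0.1, r_min = 0.7,
                            cluster_gap_kb = 1000, lowess_span = 0.3,
                            normexp_offset = 16) {
  for (th in list(mrna_thresholds, mirna_thresholds, protein_thresholds))
    if (th$fdr_max <= 0 || th$fdr_max > 1) stop("invalid fdr_max")
  structure(list(mrna_thresholds = mrna_thresholds,
                 mirna_thresholds = mirna_thresholds,
                 protein_thresholds = protein_thresholds,
                 filter_max_fraction = filter_max_fraction,
                 pairing_mode = pairing_mode, score_max = score_max, r_min = r_min,
                 cluster_gap_kb = cluster_gap_kb, lowess_span = lowess_span,
                 normexp_offset = normexp_offset),
            class = "pipeline_config")
}

#' Run the full three-layer integration pipeline on a fixture directory
#'
#' Executes preprocess -> differential expression per layer -> enrichment ->
#' miRNA-target pairing -> mRNA-protein core -> loop enumeration -> network
#' export on a directory laid out as written by [write_fixture()], writing all
#' result tables plus a YAML run manifest into `out_dir`. Reruns on identical
#' inputs produce byte-identical outputs.
#'
#' @param input_dir Directory with `mrna.tsv`/`mrna_arrays.tsv`,
#'   `protein.tsv`/`protein_arrays.tsv`, `mirna_raw.tsv`/`mirna_samples.tsv`,
#'   `target_map.tsv`, and optionally `mirna_coords.tsv`, `catalog.tsv`,
#'   `gene_edges.tsv`, `gene_sets.tsv` (columns set_name, gene_id).
#' @param out_dir Output directory (created).
#' @param config A [pipeline_config()].
#' @return The run manifest (list), invisibly written to
#'   `out_dir/manifest.yaml`.
#' @export
run_pipeline <- function(input_dir, out_dir, config = pipeline_config()) {
  t0 <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp_in <- function(f) file.path(input_dir, f)
  fp_out <- function(f) file.path(out_dir, f)
  stage <- "load_inputs"
  manifest <- list(input_dir = normalizePath(input_dir), stages = list())
  res <- try({
    need <- c("mrna.tsv", "mrna_arrays.tsv", "protein.tsv", "protein_arrays.tsv",
              "mirna_raw.tsv", "mirna_samples.tsv", "target_map.tsv")
    missing <- need[!file.exists(fp_in(need))]
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "))
    mrna_set <- read_two_color(fp_in("mrna.tsv"), fp_in("mrna_arrays.tsv"))
    prot_set <- read_two_color(fp_in("protein.tsv"), fp_in("protein_arrays.tsv"))
    smeta <- utils::read.delim(fp_in("mirna_samples.tsv"), stringsAsFactors = FALSE)
    mirna_raw <- read_expression_table(fp_in("mirna_raw.tsv"), "miRNA", smeta)
    tmap <- read_target_map(fp_in("target_map.tsv"))

    stage <- "preprocess_mrna"
    sig <- two_color_signal_matrices(mrna_set)
    filt <- filter_low_signal(sig$fg, sig$bg, config$filter_max_fraction)
    utils::write.table(
      data.frame(feature_id = names(filt$fraction),
                 below_background_fraction = filt$fraction,
                 removed = names(filt$fraction) %in% filt$removed),
      fp_out("mrna_filter_report.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    mrna_ratios <- process_two_color(mrna_set, background = "subtract",
                                     normalization = "lowess", layer = "mRNA",
                                     keep_features = filt$kept,
                                     span = config$lowess_span)
    mrna_col <- collapse_replicates(mrna_ratios)
    write_expression_table(mrna_col, fp_out("mrna_normalized.tsv"))

    stage <- "preprocess_protein"
    prot_ratios <- process_two_color(prot_set, background = "normexp",
                                     normalization = "rank_invariant",
                                     layer = "protein",
                                     offset = config$normexp_offset)
    prot_col <- collapse_replicates(prot_ratios)
    write_expression_table(prot_col, fp_out("protein_normalized.tsv"))

    stage <- "preprocess_mirna"
    mirna_norm <- vsn_like_normalize(mirna_raw)
    mirna_col <- collapse_replicates(mirna_norm)
    write_expression_table(mirna_col, fp_out("mirna_normalized.tsv"))

    stage <- "differential_expression"
    de_mrna <- de_analysis(mrna_col, config$mrna_thresholds)
    de_mirna <- de_analysis(mirna_col, config$mirna_thresholds)
    de_prot <- de_analysis(prot_col, config$protein_thresholds)
    write_de_table(de_mrna, fp_out("de_mrna.tsv"))
    write_de_table(de_mirna, fp_out("de_mirna.tsv"))
    write_de_table(de_prot, fp_out("de_protein.tsv"))

    stage <- "enrichment"
    n_enrich <- 0L
    if (file.exists(fp_in("catalog.tsv"))) {
      catalog <- read_catalog(fp_in("catalog.tsv"))
      universe <- de_mrna$feature_id[!is.na(de_mrna$p)]
      for (dir in c("up", "down")) {
        sel <- de_mrna$feature_id[de_mrna$status == dir]
        tab <- enrich(catalog, sel, universe, direction = dir)
        utils::write.table(tab, fp_out(sprintf("enrichment_mrna_%s.tsv", dir)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        n_enrich <- n_enrich + nrow(tab)
      }
    }

    stage <- "integration"
    links_mrna <- pair_links(de_mirna, de_mrna, tmap, mode = config$pairing_mode,
                             target_layer = "mRNA", score_max = config$score_max,
                             mirna_mat = mirna_col, target_mat = mrna_col,
                             r_min = config$r_min)
    links_prot <- pair_links(de_mirna, de_prot, tmap, mode = config$pairing_mode,
                             target_layer = "protein", score_max = config$score_max,
                             mirna_mat = mirna_col, target_mat = prot_col,
                             r_min = config$r_min)
    .write_tsv(rbind(links_mrna, links_prot), fp_out("pair_links.tsv"))
    core <- mrna_protein_core(de_mrna, de_prot)
    .write_tsv(core, fp_out("core_genes.tsv"))

    stage <- "loops"
    loops <- enumerate_loops(de_mirna, de_mrna, de_prot, tmap,
                             score_max = config$score_max)
    .write_tsv(as.data.frame(loops), fp_out("loops.tsv"))
    cnt <- loop_counts(loops)
    utils::write.table(data.frame(loop_type = names(cnt), n = as.integer(cnt)),
                       fp_out("loop_counts.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)

    stage <- "mirna_clusters"
    n_clusters <- NA_integer_
    if (file.exists(fp_in("mirna_coords.tsv"))) {
      coords <- utils::read.delim(fp_in("mirna_coords.tsv"), stringsAsFactors = FALSE)
      cl <- cluster_mirnas(coords, max_gap_kb = config$cluster_gap_kb)
      .write_tsv(cl, fp_out("mirna_clusters.tsv"))
      n_clusters <- sum(cl$n_members > 1)
    }

    stage <- "networks"
    gg <- if (file.exists(fp_in("gene_edges.tsv"))) read_edge_list(fp_in("gene_edges.tsv"))
    anti <- links_mrna[links_mrna$relation == "anti", , drop = FALSE]
    net <- build_network(anti, gg, de_genes = de_mrna, de_proteins = de_prot,
                         de_mirnas = de_mirna)
    write_sif(net, fp_out("post_transcriptional.sif"))
    anti_p <- links_prot[links_prot$relation == "anti", , drop = FALSE]
    net_p <- build_network(anti_p, NULL, de_genes = de_mrna, de_proteins = de_prot,
                           de_mirnas = de_mirna)
    write_sif(net_p, fp_out("pre_translational.sif"))
    n_subnets <- 0L
    if (file.exists(fp_in("gene_sets.tsv"))) {
      gs <- utils::read.delim(fp_in("gene_sets.tsv"), stringsAsFactors = FALSE)
      for (nm in unique(gs[[1]])) {
        sub <- extract_subnetwork(net, gs[[2]][gs[[1]] == nm])
        write_sif(sub, fp_out(sprintf("subnetwork_%s.sif", gsub("[^A-Za-z0-9]+", "_", nm))))
        n_subnets <- n_subnets + 1L
      }
    }

    stage <- "manifest"
    list(filter = filt, de = list(mRNA = de_mrna, miRNA = de_mirna, protein = de_prot),
         links = list(mRNA = links_mrna, protein = links_prot),
         core = core, loops = loops, counts = cnt,
         rows = list(
           features_in = length(mrna_set$feature_ids),
           features_kept = length(filt$kept),
           de_mrna = sum(de_mrna$status != "ns"),
           de_mirna = sum(de_mirna$status != "ns"),
           de_protein = sum(de_prot$status != "ns"),
           pair_links = nrow(links_mrna) + nrow(links_prot),
           core_genes = nrow(core), loops = nrow(loops),
           enrichment_rows = n_enrich, mirna_clusters = n_clusters,
           subnetworks = n_subnets))
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    stop("pipeline failed at stage '", stage, "': ",
         attr(res, "condition")$message, call. = FALSE)
  manifest$stages <- c("load_inputs", "preprocess_mrna", "preprocess_protein",
                       "preprocess_mirna", "differential_expression", "enrichment",
                       "integration", "loops", "mirna_clusters", "networks")
  manifest$row_counts <- res$rows
  manifest$loop_counts <- as.list(res$counts)
  cfg_file <- fp_out("config_used.yaml")
  yaml::write_yaml(unclass(config), cfg_file)
  manifest$config_md5 <- unname(tools::md5sum(cfg_file))
  manifest$elapsed_s <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
  out_manifest <- manifest
  out_manifest$elapsed_s <- NULL  # keep manifest file byte-stable across reruns
  out_manifest$input_dir <- basename(manifest$input_dir)
  yaml::write_yaml(out_manifest, fp_out("manifest.yaml"))
  invisible(c(manifest, res[c("filter", "de", "links", "core", "loops", "counts")]))
}

#' One-command synthetic demonstration run
#'
#' Generates a synthetic fixture from `sim` (seeded with `seed`), writes it
#' under `dir/fixture`, runs the full pipeline into `dir/results`, and returns
#' the manifest augmented with a recovery report comparing called loops with
#' the planted truth.
#'
#' @param seed RNG seed for the generator.
#' @param dir Working directory (default: a fresh temporary directory).
#' @param sim A `sim_config`; its seed is replaced by `seed`.
#' @param config A `pipeline_config`.
#' @return Manifest list with an extra `recovery` element: per-type planted
#'   and recovered counts, the fraction of planted loops recovered with the
#'   correct type, and the fraction of reported loops that were not planted.
#' @export
demo_pipeline <- function(seed = 1, dir = tempfile("loopomics_demo"),
                          sim = sim_config(), config = pipeline_config()) {
  sim$seed <- seed
  bundle <- generate_omics(sim)
  fix_dir <- file.path(dir, "fixture")
  write_fixture(bundle, fix_dir, overwrite = TRUE)
  manifest <- run_pipeline(fix_dir, file.path(dir, "results"), config)
  manifest$recovery <- loop_recovery(manifest$loops, bundle$truth$planted_loops)
  manifest
}

#' Compare called loops against a planted truth table
#'
#' @param called A `loop_table` (or data frame with `mirna_id`, `gene_id`,
#'   `loop_type`).
#' @param planted The planted loop table.
#' @return List with `n_planted`, `n_called`, `recovered_correct_type`
#'   (fraction of planted loops called with the right type), `spurious_rate`
#'   (fraction of called loops that are unplanted), and per-type planted vs
#'   called counts.
#' @export
loop_recovery <- function(called, planted) {
  key <- function(d) paste(d$mirna_id, d$gene_id)
  hit <- match(key(planted), key(called))
  correct <- !is.na(hit) & called$loop_type[hit] == planted$loop_type
  list(n_planted = nrow(planted), n_called = nrow(called),
       recovered_correct_type = mean(correct),
       spurious_rate = if (nrow(called)) mean(!key(called) %in% key(planted)) else 0,
       per_type = data.frame(
         loop_type = c("A", "B", "C", "unclassified"),
         planted = as.integer(loop_counts(planted)),
         called = as.integer(loop_counts(called))))
}
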