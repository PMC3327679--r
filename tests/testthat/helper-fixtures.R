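# Shared fixture builders and independent oracles.

# Small sample-metadata table for intensity matrices.
meta_intensity <- function(n_bio = 2, n_tech = 1) {
  grid <- expand.grid(tech_rep = seq_len(n_tech), bio_rep = seq_len(n_bio),
                      condition = c("sensitive", "resistant"),
                      stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("%s_b%dt%d", substr(grid$condition, 1, 3),
                            grid$bio_rep, grid$tech_rep)
  grid$dye <- "none"
  grid[, c("sample_id", "condition", "bio_rep", "tech_rep", "dye")]
}

# Intensity expr_matrix from a plain matrix (columns ordered as meta).
toy_intensity <- function(values, layer = "mRNA", n_bio = ncol(values) / 2,
                          n_tech = 1) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("F%05d", seq_len(nrow(values)))
  meta <- meta_intensity(n_bio, n_tech)
  colnames(values) <- meta$sample_id
  expression_matrix(values, meta, layer = layer, value_type = "intensity")
}

# Ratio expr_matrix: one column per array, dye = dye of resistant channel.
toy_ratio <- function(values, bio_rep, tech_rep, dye, layer = "mRNA") {
  meta <- data.frame(sample_id = sprintf("a%02d", seq_len(ncol(values))),
                     condition = "resistant", bio_rep = bio_rep,
                     tech_rep = tech_rep, dye = dye, stringsAsFactors = FALSE)
  colnames(values) <- meta$sample_id
  expression_matrix(values, meta, layer = layer, value_type = "ratio")
}

# Minimal de_result-like table for integration tests.
toy_de <- function(ids, logfc, status = ifelse(logfc > 0, "up",
                                               ifelse(logfc < 0, "down", "ns"))) {
  data.frame(feature_id = ids, logFC = logfc, status = status,
             stringsAsFactors = FALSE)
}

small_sim <- function(seed = 1, ...) {
  args <- list(n_genes = 500, n_mirnas = 60, n_proteins = 80,
               n_de_genes = 50, n_de_mirnas = 10, n_de_proteins = 30,
               loops_per_type = c(A = 4, B = 3, C = 2, unclassified = 1),
               n_decoy_targets = 60, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# --- independent oracles ---------------------------------------------------

# Brute-force BH step-up: q_(i) = min over j >= i of p_(j) * m / j, capped.
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- numeric(0)
    for (j in i:m) vals <- c(vals, p[ord[j]] * m / j)
    q_sorted[i] <- min(1, min(vals))
  }
  out <- numeric(m)
  out[ord] <- q_sorted
  out
}

# Exhaustive hypergeometric upper tail by enumerating all selections.
hypergeom_enum <- function(overlap, selected_n, category_n, universe_n) {
  universe <- seq_len(universe_n)
  category <- seq_len(category_n)
  picks <- utils::combn(universe, selected_n)
  mean(colSums(matrix(picks %in% category, nrow = selected_n)) >= overlap)
}

# Numerical-quadrature oracle for E[S | X = x] under X = N(mu, sigma^2) + Exp(alpha).
# The integrand is a narrow Gaussian spike at s = x - mu, so integrate over its
# actual support rather than (0, Inf).
normexp_conditional_mean_quad <- function(x, mu, sigma, alpha) {
  joint <- function(s) stats::dexp(s, 1 / alpha) * stats::dnorm(x - s, mu, sigma)
  lo <- max(0, x - mu - 12 * sigma)
  hi <- max(x - mu + 12 * sigma, 12 * sigma)
  num <- stats::integrate(function(s) s * joint(s), lo, hi, rel.tol = 1e-10)$value
  den <- stats::integrate(joint, lo, hi, rel.tol = 1e-10)$value
  num / den
}
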