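#' Upper-tail hypergeometric probability for a category overlap
#'
#' Probability of drawing at least `overlap` members of a category of size
#' `category_n` when `selected_n` features are drawn without replacement from
#' a universe of `universe_n`.
#'
#' @param overlap Observed overlap count.
#' @param selected_n Size of the selected list.
#' @param category_n Size of the category within the universe.
#' @param universe_n Size of the universe.
#' @return `P(X >= overlap)`.
#' @export
hypergeom_p <- function(overlap, selected_n, category_n, universe_n) {
  if (any(overlap < 0 | overlap > pmin(selected_n, category_n)))
    stop("overlap must lie in [0, min(selected_n, category_n)]")
  if (any(universe_n < pmax(selected_n, category_n)))
    stop("universe_n must be >= max(selected_n, category_n)")
  stats::phyper(overlap - 1, category_n, universe_n - category_n, selected_n,
                lower.tail = FALSE)
}

#' Hypergeometric over-representation of catalog categories
#'
#' Tests each category of an annotation catalog for over-representation in a
#' selected gene list relative to a universe, with Benjamini-Hochberg
#' correction across the tested categories. Counts are restricted to the
#' universe; categories with no universe member are not tested; zero overlaps
#' are reported with p = 1 so the correction denominator is stable.
#'
#' @param catalog An `annotation_catalog`.
#' @param selected Character vector of selected gene ids (must be a subset of
#'   `universe`).
#' @param universe Character vector of background gene ids.
#' @param direction Label ("up" or "down") carried into the output.
#' @return Data frame with columns `category_id`, `name`, `overlap`,
#'   `selected_n`, `category_n`, `universe_n`, `p`, `fdr`, `direction`,
#'   ordered by p.
#' @export
enrich <- function(catalog, selected, universe, direction = "up") {
  selected <- unique(as.character(selected))
  universe <- unique(as.character(universe))
  outside <- setdiff(selected, universe)
  if (length(outside))
    stop("selected genes outside the universe: ", paste(outside, collapse = ", "))
  cat_in <- lapply(catalog, intersect, universe)
  tested <- which(lengths(cat_in) > 0)
  if (!length(tested))
    return(data.frame(category_id = character(), name = character(),
                      overlap = integer(), selected_n = integer(),
                      category_n = integer(), universe_n = integer(),
                      p = numeric(), fdr = numeric(), direction = character(),
                      stringsAsFactors = FALSE))
  nm <- attr(catalog, "category_names")
  rows <- data.frame(
    category_id = names(catalog)[tested],
    name = if (is.null(nm)) names(catalog)[tested] else
      ifelse(is.na(nm[names(catalog)[tested]]), names(catalog)[tested],
             nm[names(catalog)[tested]]),
    overlap = vapply(cat_in[tested], function(g) length(intersect(g, selected)), 0L),
    selected_n = length(selected),
    category_n = lengths(cat_in[tested]),
    universe_n = length(universe),
    direction = direction,
    stringsAsFactors = FALSE)
  rows$p <- hypergeom_p(rows$overlap, rows$selected_n, rows$category_n, rows$universe_n)
  rows$fdr <- bh_fdr(rows$p)
  rows <- rows[order(rows$p, rows$category_id),
               c("category_id", "name", "overlap", "selected_n", "category_n",
                 "universe_n", "p", "fdr", "direction")]
  rownames(rows) <- NULL
  rows
}
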