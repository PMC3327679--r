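#' Construct a two-color array set
#'
#' Raw foreground/background intensities for a set of two-color arrays sharing
#' one feature list. Each array is a resistant-vs-sensitive co-hybridization;
#' `dye_of_channel1` records the label of channel 1 and `condition_ch1` /
#' `condition_ch2` which condition each channel carries (dye swaps exchange
#' them).
#'
#' @param feature_ids Character vector of unique feature ids.
#' @param arrays List of arrays; each a list with non-negative numeric vectors
#'   `fg1`, `bg1`, `fg2`, `bg2` of length `length(feature_ids)`.
#' @param array_meta Data frame with one row per array: `array_id`, `bio_rep`,
#'   `tech_rep`, `dye_of_channel1` ("Cy3"/"Cy5"), `condition_ch1`,
#'   `condition_ch2` ("sensitive"/"resistant").
#' @return An object of class `two_color_set`.
#' @export
two_color_set <- function(feature_ids, arrays, array_meta) {
  feature_ids <- as.character(feature_ids)
  if (anyDuplicated(feature_ids)) stop("duplicate feature ids")
  array_meta <- as.data.frame(array_meta, stringsAsFactors = FALSE)
  req <- c("array_id", "bio_rep", "tech_rep", "dye_of_channel1",
           "condition_ch1", "condition_ch2")
  miss <- setdiff(req, names(array_meta))
  if (length(miss)) stop("array metadata missing columns: ", paste(miss, collapse = ", "))
  if (length(arrays) != nrow(array_meta)) stop("arrays and array_meta disagree in length")
  n <- length(feature_ids)
  for (i in seq_along(arrays)) {
    a <- arrays[[i]]
    if (!all(c("fg1", "bg1", "fg2", "bg2") %in% names(a)))
      stop("array ", i, " lacks fg1/bg1/fg2/bg2")
    if (any(lengths(a[c("fg1", "bg1", "fg2", "bg2")]) != n))
      stop("array ", i, ": channel vectors must match feature count")
    if (any(unlist(a[c("fg1", "bg1", "fg2", "bg2")]) < 0, na.rm = TRUE))
      stop("array ", i, ": intensities must be non-negative")
  }
  if (!all(array_meta$dye_of_channel1 %in% c("Cy3", "Cy5"))) stop("bad dye_of_channel1")
  if (!all(c(array_meta$condition_ch1, array_meta$condition_ch2) %in%
           c("sensitive", "resistant"))) stop("bad channel condition")
  if (any(array_meta$condition_ch1 == array_meta$condition_ch2))
    stop("the two channels of an array must carry different conditions")
  names(arrays) <- array_meta$array_id
  structure(list(feature_ids = feature_ids, arrays = arrays, array_meta = array_meta),
            class = "two_color_set")
}

#' @export
print.two_color_set <- function(x, ...) {
  cat(sprintf("two_color_set: %d features x %d arrays (%d dye-swapped)\n",
              length(x$feature_ids), length(x$arrays),
              sum(x$array_meta$condition_ch1 == "resistant")))
  invisible(x)
}

#' Write a two-color array set as a pair of delimited tables
#'
#' Intensities go to `path` (columns `<array_id>.fg1` etc.), array metadata to
#' `meta_path`.
#'
#' @param set A `two_color_set`.
#' @param path Intensity table path.
#' @param meta_path Array metadata path; defaults to `path` with `_arrays.tsv`.
#' @return Invisibly, the two paths.
#' @export
write_two_color <- function(set, path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- paste0(sub("\\.tsv$", "", path), "_arrays.tsv")
  cols <- lapply(set$arrays, function(a) a[c("fg1", "bg1", "fg2", "bg2")])
  flat <- do.call(cbind, lapply(cols, function(a) do.call(cbind, a)))
  colnames(flat) <- as.vector(t(outer(names(set$arrays),
                                      c("fg1", "bg1", "fg2", "bg2"), paste, sep = ".")))
  df <- data.frame(feature_id = set$feature_ids, flat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
  utils::write.table(set$array_meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, meta_path))
}

#' Read a two-color array set written by [write_two_color()]
#' @param path Intensity table path.
#' @param meta_path Array metadata path (same default as [write_two_color()]).
#' @return A `two_color_set`.
#' @export
read_two_color <- function(path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- paste0(sub("\\.tsv$", "", path), "_arrays.tsv")
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           na.strings = c("", "NA"), stringsAsFactors = FALSE)
  meta <- utils::read.delim(meta_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  meta$array_id <- as.character(meta$array_id)
  ids <- as.character(tab[[1]])
  arrays <- lapply(meta$array_id, function(aid) {
    lapply(stats::setNames(c("fg1", "bg1", "fg2", "bg2"),
                           c("fg1", "bg1", "fg2", "bg2")),
           function(ch) as.numeric(tab[[paste(aid, ch, sep = ".")]]))
  })
  two_color_set(ids, arrays, meta)
}
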