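# Diversity indexes computed from OTU abundance tables.
#
# Four per-sample indexes summarise a community: richness (number of OTUs
# observed), Shannon entropy H' = -sum p_i ln p_i, evenness J' = H' /
# ln(richness), and the inverse Simpson concentration 1/D = 1 / sum p_i^2.
# Index computation is delegated to vegan; this module adds the richness /
# evenness bookkeeping, input validation and table-level plumbing.

#' Diversity profile of a single sample
#'
#' @param counts nonnegative per-OTU abundances (zero-count OTUs are
#'   ignored); need not be integers, e.g. expected compositions.
#' @param base logarithm base for H' and J' (natural log by default).
#' @return one-row data frame with `richness`, `shannon_h`, `evenness_j`
#'   (`NA` when richness is 1, where evenness is undefined) and
#'   `inv_simpson`.
#' @export
#' @examples
#' diversity_profile(c(25, 25, 25, 25))
diversity_profile <- function(counts, base = exp(1)) {
  if (any(counts < 0, na.rm = TRUE))
    cmin_abort("negative abundance", "data")
  counts <- counts[!is.na(counts) & counts > 0]
  if (!length(counts))
    cmin_abort("sample has no positive counts", "empty_sample")
  richness <- length(counts)
  h <- as.numeric(vegan::diversity(counts, index = "shannon", base = base))
  invd <- as.numeric(vegan::diversity(counts, index = "invsimpson"))
  j <- if (richness > 1) h / log(richness, base = base) else NA_real_
  data.frame(richness = richness, shannon_h = h, evenness_j = j,
             inv_simpson = invd)
}

#' Diversity profiles for every sample of an OTU table
#'
#' @param otu matrix or data frame, samples in rows and OTUs in columns
#'   (wide layout), with sample identifiers as row names or in a
#'   `sample_id` column.
#' @param base logarithm base for H' and J'.
#' @return data frame with one row per sample: `sample_id` plus the four
#'   index columns of [diversity_profile()].
#' @export
diversity_table <- function(otu, base = exp(1)) {
  if (is.data.frame(otu) && "sample_id" %in% names(otu)) {
    ids <- otu$sample_id
    otu <- as.matrix(otu[setdiff(names(otu), "sample_id")])
  } else {
    otu <- as.matrix(otu)
    ids <- rownames(otu) %||% as.character(seq_len(nrow(otu)))
  }
  profs <- do.call(rbind, lapply(seq_len(nrow(otu)), function(i)
    diversity_profile(otu[i, ], base = base)))
  cbind(data.frame(sample_id = ids), profs)
}

#' Read an OTU abundance table from CSV
#'
#' Accepts either a wide layout (one row per sample, one column per OTU,
#' first column `sample_id`) or a long layout with columns `sample_id`,
#' `otu_id`, `count`.
#'
#' @param path CSV file.
#' @return numeric matrix, samples in rows (named), OTUs in columns.
#' @export
read_otu_table <- function(path) {
  if (!file.exists(path)) cmin_abort(paste("file not found:", path), "io")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("sample_id", "otu_id", "count") %in% names(df))) {
    wide <- stats::xtabs(count ~ sample_id + otu_id, data = df)
    m <- matrix(as.numeric(wide), nrow = nrow(wide),
                dimnames = dimnames(wide))
  } else {
    if (!"sample_id" %in% names(df))
      cmin_abort("OTU table needs a sample_id column", "schema",
                 columns = "sample_id", table = "otu")
    m <- as.matrix(df[setdiff(names(df), "sample_id")])
    rownames(m) <- df$sample_id
  }
  if (any(m < 0)) cmin_abort("negative OTU count", "data")
  m
}
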