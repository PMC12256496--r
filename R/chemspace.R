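# Chemical-space pipeline: descriptor filtering by cross-correlation and
# diversity, PCA to a variance target, and 2-D t-SNE embedding.

#' Chemical-space configuration
#'
#' @param r2_max maximum tolerated pairwise Pearson r-squared between
#'   retained descriptors (default 0.8).
#' @param diversity_min minimum accepted descriptor diversity (default
#'   0.3), where diversity is `1 - (modal value frequency)/n`: 0 for a
#'   constant column, approaching 1 when all values differ.
#' @param pca_variance_target cumulative explained-variance target for the
#'   PCA stage (default 0.95).
#' @param tsne_perplexity,tsne_seed t-SNE parameters.
#' @return list of class `chemspace_config`.
#' @export
chemspace_config <- function(r2_max = 0.8, diversity_min = 0.3,
                             pca_variance_target = 0.95,
                             tsne_perplexity = 30, tsne_seed = 42L) {
  stopifnot(r2_max > 0, r2_max < 1, diversity_min >= 0, diversity_min <= 1,
            pca_variance_target > 0, pca_variance_target <= 1)
  structure(list(r2_max = r2_max, diversity_min = diversity_min,
                 pca_variance_target = pca_variance_target,
                 tsne_perplexity = tsne_perplexity,
                 tsne_seed = as.integer(tsne_seed)),
            class = "chemspace_config")
}

descriptor_diversity <- function(col) {
  1 - max(table(col)) / length(col)
}

#' Filter a descriptor matrix by diversity and cross-correlation
#'
#' Removes descriptors that are nearly constant (diversity below
#' `diversity_min`) and then greedily removes cross-correlated descriptors:
#' columns are visited in order of descending diversity and a column is
#' kept only if its squared Pearson correlation with every already-retained
#' column is at most `r2_max`. Filtering is idempotent.
#'
#' @param x numeric matrix (chemicals x descriptors) with column names.
#' @param config a [chemspace_config()].
#' @return the filtered matrix, with attributes `removed_low_diversity` and
#'   `removed_correlated` naming the dropped columns.
#' @export
filter_descriptors <- function(x, config = chemspace_config()) {
  x <- as.matrix(x)
  stopifnot(ncol(x) >= 2, !anyNA(x))
  if (is.null(colnames(x))) colnames(x) <- paste0("d", seq_len(ncol(x)))

  div <- apply(x, 2, descriptor_diversity)
  low <- names(div)[div < config$diversity_min]
  keep_div <- setdiff(colnames(x), low)
  if (length(keep_div) == 0L) stop("all descriptors removed by diversity")

  ord <- keep_div[order(div[keep_div], decreasing = TRUE)]
  retained <- character(0); corr_removed <- character(0)
  for (nm in ord) {
    if (length(retained) == 0L) { retained <- nm; next }
    r2 <- suppressWarnings(
      stats::cor(x[, nm], x[, retained, drop = FALSE]))^2
    r2[is.na(r2)] <- 0
    if (any(r2 > config$r2_max)) corr_removed <- c(corr_removed, nm)
    else retained <- c(retained, nm)
  }
  if (length(retained) == 0L) stop("all descriptors removed")
  out <- x[, colnames(x)[colnames(x) %in% retained], drop = FALSE]
  attr(out, "removed_low_diversity") <- low
  attr(out, "removed_correlated") <- corr_removed
  out
}

#' Reduce a filtered descriptor matrix to a 2-D embedding
#'
#' Standardizes the columns, keeps the smallest number of principal
#' components whose cumulative explained variance reaches the target, and
#' embeds the component scores in two dimensions with t-SNE under a fixed
#' seed (same input and seed give identical coordinates).
#'
#' @param x filtered descriptor matrix (>= 3 rows).
#' @param config a [chemspace_config()].
#' @return data.frame with `id` (rownames of `x` or row indices), `x`, `y`;
#'   attribute `provenance` records retained descriptors, components kept
#'   and the seed.
#' @export
reduce_embed <- function(x, config = chemspace_config()) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("at least 3 chemicals required")
  sds <- apply(x, 2, stats::sd)
  xz <- scale(x[, sds > 0, drop = FALSE])
  pc <- stats::prcomp(xz, center = FALSE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- which(cum >= config$pca_variance_target - 1e-12)[1]
  if (is.na(k)) k <- length(cum)
  scores <- pc$x[, seq_len(k), drop = FALSE]

  if (nrow(x) >= 4) {
    emb <- tsne_embed(scores, perplexity = config$tsne_perplexity,
                      seed = config$tsne_seed)
  } else {
    emb <- cbind(scores[, 1], if (k >= 2) scores[, 2] else 0)
  }
  ids <- if (!is.null(rownames(x))) rownames(x) else
    as.character(seq_len(nrow(x)))
  out <- data.frame(id = ids, x = emb[, 1], y = emb[, 2])
  attr(out, "provenance") <- list(descriptors = colnames(x),
                                  components = k,
                                  variance_explained = cum[k],
                                  seed = config$tsne_seed)
  out
}

#' SMILES to descriptor-matrix adapter
#'
#' Thin adapter from a SMILES list to the numeric descriptor matrix the
#' chemical-space pipeline consumes, using \pkg{ChemmineR}/\pkg{ChemmineOB}
#' (OpenBabel) physicochemical properties. SMILES are curated first: the
#' largest fragment of a multi-fragment (salt) entry is kept. The pipeline
#' itself is adapter-agnostic and is exercised on synthetic matrices in the
#' package tests.
#'
#' @param smiles character vector of SMILES, optionally named by chemical
#'   id.
#' @return numeric matrix (chemicals x descriptors).
#' @export
smiles_descriptors <- function(smiles) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE))
    stop("smiles_descriptors() needs ChemmineR and ChemmineOB")
  desalted <- vapply(smiles, function(s) {
    frags <- strsplit(s, ".", fixed = TRUE)[[1]]
    frags[which.max(nchar(frags))]
  }, "")
  sdf <- ChemmineR::smiles2sdf(desalted)
  props <- ChemmineR::propOB(sdf)
  m <- as.matrix(props[vapply(props, is.numeric, TRUE)])
  rownames(m) <- if (!is.null(names(smiles))) names(smiles) else
    as.character(seq_along(smiles))
  m
}
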