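# Expression-matrix processing: quantile normalization, detection-failure
# masking, presence filtering, per-gene Student-t differential expression,
# hierarchical clustering (Pearson/complete for signatures, Euclidean for
# patient integration) and k-nearest-neighbour imputation.
#
# Matrices are genes x samples on the log2 scale; masked (detection-failed)
# entries are NA and excluded from every statistic.

#' Read or write an expression matrix as TSV
#'
#' Interchange format: first column the gene id, remaining columns one per
#' sample. An optional companion mask TSV in the same layout marks
#' detection-failed entries with 1; masked entries become `NA` on read.
#'
#' @param path expression TSV path.
#' @param mask_path optional mask TSV path.
#' @param m genes x samples matrix to write.
#' @return `read_expression_tsv()` returns a genes x samples matrix with
#'   `NA` at masked entries; `write_expression_tsv()` returns `path`
#'   invisibly.
#' @export
read_expression_tsv <- function(path, mask_path = NULL) {
  tab <- read_tsv_table(path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  if (!is.null(mask_path)) {
    mt <- read_tsv_table(mask_path)
    mask <- as.matrix(mt[, -1, drop = FALSE]) == 1
    blx_assert(identical(dim(mask), dim(m)), "invalid_input",
               "mask and expression tables have different shapes")
    m[mask[match(rownames(m), mt[[1]]), , drop = FALSE]] <- NA_real_
  }
  m
}

#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(m, path) {
  m <- as_expr_matrix(m)
  write_tsv_table(data.frame(gene_id = rownames(m), m, check.names = FALSE),
                  path)
}

as_expr_matrix <- function(m) {
  if (inherits(m, "expression_sim")) m <- m$values
  blx_assert(is.matrix(m) && is.numeric(m), "invalid_input",
             "expression data must be a numeric genes x samples matrix")
  if (is.null(rownames(m))) rownames(m) <- sprintf("G%05d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("S%03d", seq_len(ncol(m)))
  m
}

#' Quantile normalization across samples
#'
#' Forces every sample (column) to the same intensity distribution: each
#' sample's sorted values are replaced by the across-sample mean of the
#' order statistics, preserving within-sample ranks (ties averaged). Masked
#' entries stay missing; samples with differing numbers of observed values
#' are mapped through interpolated quantiles. Delegates to
#' \code{limma::normalizeQuantiles}. The operation is idempotent.
#'
#' @param m genes x samples numeric matrix (`NA` = masked) or an
#'   `expression_sim`.
#' @return normalized matrix of the same shape.
#' @export
quantile_normalize <- function(m) {
  m <- as_expr_matrix(m)
  blx_assert(ncol(m) >= 2, "invalid_input",
             "quantile normalization needs >= 2 samples")
  if (any(colSums(!is.na(m)) == 0))
    blx_error("degenerate_sample", "a sample has no observed values")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Filter genes by presence across samples
#'
#' Keeps genes observed (not detection-masked) in at least `min_presence` of
#' the samples; the standard filter is 80% presence. Values are never
#' altered, only rows dropped.
#'
#' @param m genes x samples matrix (`NA` = masked) or `expression_sim`.
#' @param min_presence minimum observed fraction per gene, inclusive.
#' @return the filtered matrix.
#' @export
presence_filter <- function(m, min_presence = 0.8) {
  m <- as_expr_matrix(m)
  blx_assert(min_presence >= 0 && min_presence <= 1, "invalid_config",
             "min_presence must lie in [0, 1]")
  keep <- rowMeans(!is.na(m)) >= min_presence
  m[keep, , drop = FALSE]
}

# per-gene pooled two-sample Student t on the unmasked values; returns NA
# rows for genes failing the per-class minimum or with zero pooled variance
gene_t_table <- function(m, labels) {
  classes <- sort(unique(labels))
  res <- data.frame(gene = rownames(m), t = NA_real_, df = NA_real_,
                    p = NA_real_, mean_diff = NA_real_,
                    skipped = NA_character_, stringsAsFactors = FALSE)
  a_idx <- labels == classes[1]
  b_idx <- labels == classes[2]
  for (i in seq_len(nrow(m))) {
    a <- m[i, a_idx]; a <- a[!is.na(a)]
    b <- m[i, b_idx]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) {
      res$skipped[i] <- "fewer than 2 observed values in a class"
      next
    }
    sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
      (length(a) + length(b) - 2)
    if (sp2 == 0) {
      res$skipped[i] <- "zero variance in both classes"
      next
    }
    t_stat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    df <- length(a) + length(b) - 2
    res$t[i] <- t_stat
    res$df[i] <- df
    res$p[i] <- 2 * pt(-abs(t_stat), df)
    res$mean_diff[i] <- mean(a) - mean(b)
  }
  res
}

#' Differentially expressed genes by per-gene Student's t test
#'
#' Tests every gene between the two label classes on its unmasked values
#' with the pooled-variance Student t test; genes with `p < alpha` are
#' returned sorted by p. Benjamini-Hochberg adjusted values are reported
#' alongside so selection can be tightened; the default selection itself is
#' on the unadjusted p. Genes with fewer than two observed values in a class
#' or zero variance in both are skipped and reported in the `skipped`
#' attribute.
#'
#' @param m genes x samples matrix (`NA` = masked) or `expression_sim`.
#' @param labels sample class labels (exactly two classes).
#' @param alpha selection level on the raw p-value.
#' @param all return the full per-gene table instead of the selection.
#' @return data frame `gene`, `t`, `df`, `p`, `p_bh`, `mean_diff`, sorted by
#'   p; attribute `skipped` lists untestable genes with reasons.
#' @export
de_genes <- function(m, labels, alpha = 0.05, all = FALSE) {
  m <- as_expr_matrix(m)
  if (inherits(labels, "expression_sim")) labels <- labels$labels
  labels <- as.character(labels)
  blx_assert(length(labels) == ncol(m), "labeling",
             "one label per sample required")
  if (length(unique(labels)) != 2)
    blx_error("labeling", "exactly two label classes required")
  tab <- gene_t_table(m, labels)
  skipped <- tab[!is.na(tab$skipped), c("gene", "skipped")]
  tested <- tab[is.na(tab$skipped), , drop = FALSE]
  tested$p_bh <- p.adjust(tested$p, method = "BH")
  tested <- tested[order(tested$p),
                   c("gene", "t", "df", "p", "p_bh", "mean_diff")]
  out <- if (all) tested else tested[tested$p < alpha, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

# pairwise-complete distance matrix between columns
expr_distance <- function(m, distance) {
  if (distance == "euclidean") return(dist(t(m)))
  n <- ncol(m)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- sum(!is.na(m[, i]) & !is.na(m[, j]))
    if (shared < 3)
      blx_error("undefined_distance",
                sprintf("samples %s and %s share only %d observed values (need >= 3)",
                        colnames(m)[i], colnames(m)[j], shared))
  }
  r <- cor(m, use = "pairwise.complete.obs")
  if (anyNA(r)) blx_error("undefined_distance",
                          "constant sample makes a Pearson distance undefined")
  as.dist(1 - r)
}

#' Hierarchical clustering of samples
#'
#' Complete-linkage agglomeration on either `1 - Pearson correlation`
#' (pairwise-complete over unmasked values; the signature-clustering
#' distance) or Euclidean distance (the patient-integration distance).
#' Merges are deterministic; ties are resolved by the stable lexicographic
#' item order.
#'
#' @param m genes x samples matrix (`NA` = masked) or `expression_sim`;
#'   columns are clustered.
#' @param distance `"pearson"` or `"euclidean"`.
#' @param linkage agglomeration method, default `"complete"`.
#' @param k optional number of clusters to cut the tree at.
#' @return list of class `expr_clust`: `hclust` (the merge tree), `labels`
#'   (k-cut cluster id per sample, `NULL` when `k` is missing), `distance`.
#' @export
hierarchical_cluster <- function(m, distance = c("pearson", "euclidean"),
                                 linkage = "complete", k = NULL) {
  m <- as_expr_matrix(m)
  distance <- match.arg(distance)
  blx_assert(ncol(m) >= 2, "invalid_input", "need >= 2 items to cluster")
  d <- expr_distance(m, distance)
  hc <- hclust(d, method = linkage)
  labels <- if (!is.null(k)) cutree(hc, k = k) else NULL
  structure(list(hclust = hc, labels = labels, distance = distance),
            class = "expr_clust")
}

#' Export a clustering as a Newick tree
#'
#' @param clust an `expr_clust` from [hierarchical_cluster()].
#' @param path optional file to write to.
#' @return the Newick string, invisibly when written to `path`.
#' @export
cluster_newick <- function(clust, path = NULL) {
  blx_assert(inherits(clust, "expr_clust"), "invalid_input",
             "clust must come from hierarchical_cluster()")
  phy <- ape::as.phylo(clust$hclust)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' k-nearest-neighbour imputation of masked entries
#'
#' Each missing entry of a gene is replaced by the mean of the `k` nearest
#' genes' values at that sample, nearness being root-mean-square Euclidean
#' distance over the samples both genes observe. Neighbours must themselves
#' be observed at the target sample. Entries with no eligible neighbour are
#' left masked and reported in the `unimputed` attribute.
#'
#' @param m genes x samples matrix (`NA` = masked) or `expression_sim`.
#' @param k number of neighbours.
#' @return the matrix with imputed values; attribute `unimputed` is a data
#'   frame of entries that could not be filled.
#' @export
knn_impute <- function(m, k = 10) {
  m <- as_expr_matrix(m)
  blx_assert(k >= 1 && k == round(k), "invalid_config",
             "k must be a positive integer")
  out <- m
  holes <- which(is.na(m), arr.ind = TRUE)
  if (nrow(holes) == 0) return(out)
  unimputed <- list()
  for (g in unique(holes[, "row"])) {
    target <- m[g, ]
    obs_t <- !is.na(target)
    # rms distance over shared observed samples, candidates = all other genes
    d <- vapply(seq_len(nrow(m)), function(j) {
      if (j == g) return(Inf)
      shared <- obs_t & !is.na(m[j, ])
      if (!any(shared)) return(Inf)
      sqrt(mean((target[shared] - m[j, shared])^2))
    }, 0)
    for (s in holes[holes[, "row"] == g, "col"]) {
      eligible <- which(is.finite(d) & !is.na(m[, s]))
      if (length(eligible) < k) {
        unimputed[[length(unimputed) + 1]] <-
          data.frame(gene = rownames(m)[g], sample = colnames(m)[s],
                     stringsAsFactors = FALSE)
        next
      }
      nn <- eligible[order(d[eligible], eligible)][seq_len(k)]
      out[g, s] <- mean(m[nn, s])
    }
  }
  attr(out, "unimputed") <- if (length(unimputed))
    do.call(rbind, unimputed) else NULL
  out
}
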