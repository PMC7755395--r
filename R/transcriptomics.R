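#' Select brain-specific genes from a tissue expression table
#'
#' Keeps genes whose mean expression across brain tissues is strictly more
#' than four times the median expression across all tissue types. Genes with
#' a zero all-tissue median are kept iff their brain expression is positive
#' (and counted in the attached log).
#'
#' @param tissue_expression Genes x tissues numeric matrix with gene-id
#'   rownames.
#' @param brain_tissue_ids Column names (or indices) of the brain tissues.
#' @param ratio Enrichment multiple required (default 4).
#' @return Character vector of selected gene ids; the number of zero-median
#'   genes handled by the fallback rule is attached as attribute
#'   `n_zero_median`.
#' @export
select_brain_specific <- function(tissue_expression, brain_tissue_ids,
                                  ratio = 4) {
  X <- as.matrix(tissue_expression)
  if (ncol(X) < 2L) stop_ts("need at least 2 tissues")
  brain <- X[, brain_tissue_ids, drop = FALSE]
  if (ncol(brain) < 1L) stop_ts("no brain tissues identified")
  brain_mean <- rowMeans(brain)
  med_all <- apply(X, 1L, median)
  sel <- ifelse(med_all > 0, brain_mean > ratio * med_all, brain_mean > 0)
  out <- rownames(X)[sel]
  attr(out, "n_zero_median") <- sum(med_all == 0)
  out
}

#' Normalize an expression matrix across parcels
#'
#' Per-gene mean 0, variance 1 across parcels — the variance-normalized form
#' expected by [expression_pca()] and [pls1_weights()].
#'
#' @param X Genes x parcels matrix.
#' @return Matrix of the same shape with attribute `normalized = TRUE`.
#' @export
normalize_expression <- function(X) {
  mu <- rowMeans(X)
  s <- apply(X, 1L, sd)
  if (any(s == 0)) stop_ts("zero-variance gene(s); remove before normalizing")
  out <- (X - mu) / s
  attr(out, "normalized") <- TRUE
  out
}

#' Principal component analysis of gene expression
#'
#' Factorizes the variance-normalized genes x parcels matrix `X = U S V'`;
#' the columns of `V` (parcels space) are the principal components, and the
#' dominant axis of expression is the first column. Explained variance
#' ratios come from the squared singular values. The sign of each component
#' is fixed by making it positively correlated with the expression of its
#' highest-loading gene, so results are deterministic.
#'
#' @param X Genes x parcels matrix, normalized per gene
#'   (see [normalize_expression()]).
#' @param k Number of components to retain.
#' @return An object of class `pc_result`: `components` (parcels x k),
#'   `singular_values`, `explained_variance_ratio`, `loadings` (genes x k).
#' @export
expression_pca <- function(X, k = 5L) {
  X <- as.matrix(X)
  if (k > min(dim(X))) stop_ts("k exceeds min(genes, parcels)")
  s <- svd(X, nu = k, nv = k)
  evr <- s$d^2 / sum(s$d^2)
  V <- s$v
  U <- s$u
  for (j in seq_len(k)) {
    top_gene <- which.max(abs(U[, j]))
    if (cor(X[top_gene, ], V[, j]) < 0) {
      V[, j] <- -V[, j]
      U[, j] <- -U[, j]
    }
  }
  structure(list(components = V, singular_values = s$d[seq_len(k)],
                 explained_variance_ratio = evr[seq_len(k)],
                 loadings = U, all_singular_values = s$d),
            class = "pc_result")
}

#' @export
print.pc_result <- function(x, ...) {
  cat(sprintf("<pc_result> %d components; explained variance: %s\n",
              ncol(x$components),
              paste(sprintf("%.3f", x$explained_variance_ratio),
                    collapse = ", ")))
  invisible(x)
}

#' Per-gene Spearman correlation with a map, SA-corrected
#'
#' Correlates every gene's expression profile with a parcel map and computes
#' SA-corrected p-values by reusing one shared null ensemble of the map
#' (rather than per-gene nulls).
#'
#' @param X Genes x parcels matrix with gene-id rownames.
#' @param map A [parcel_map()] or numeric vector over the same parcels.
#' @param nulls A [msr_nulls()] ensemble of `map`.
#' @param alpha Significance level for the `significant` flag.
#' @return data.frame `gene_id`, `rho`, `p_sa`, `significant`.
#' @export
correlate_genes_with_map <- function(X, map, nulls, alpha = 0.05) {
  v <- if (inherits(map, "parcel_map")) map$values else as.numeric(map)
  keep <- is.finite(v)
  v <- v[keep]
  Xk <- as.matrix(X)[, keep, drop = FALSE]
  rv <- rank(v)
  RX <- t(apply(Xk, 1L, rank))              # genes x parcels ranks
  rho <- as.numeric(cor(t(RX), rv))
  RN <- apply(nulls$nulls[, keep, drop = FALSE], 1L, rank)  # parcels x n_null
  null_rho <- abs(cor(t(RX), RN))           # genes x n_null, |rho|
  n_null <- ncol(null_rho)
  p_sa <- (1 + rowSums(null_rho >= abs(rho))) / (n_null + 1)
  data.frame(gene_id = rownames(Xk), rho = rho, p_sa = p_sa,
             significant = p_sa < alpha, stringsAsFactors = FALSE)
}

#' Regress one map out of another
#'
#' Ordinary least squares of `y` on `[1, x]`; returns the residuals, which
#' are exactly uncorrelated with `x`. Used to remove the anatomical
#' (T1w/T2w-like) gradient from timescale and gene expression maps before
#' PLS.
#'
#' @param y_map,x_map [parcel_map()]s or numeric vectors on shared parcels.
#' @return Numeric residual vector (NA at parcels invalid in either input).
#' @export
residualize <- function(y_map, x_map) {
  pr <- map_values_pair(y_map, x_map)
  if (sd(pr$y) == 0) stop_ts("covariate map is constant")
  fit <- lm(pr$x ~ pr$y)
  out <- rep(NA_real_, length(pr$keep))
  out[pr$keep] <- as.numeric(fit$residuals)
  out
}

# residualize every row of a genes x parcels matrix against one covariate
residualize_matrix <- function(X, x_map) {
  v <- if (inherits(x_map, "parcel_map")) x_map$values else as.numeric(x_map)
  keep <- is.finite(v)
  Xk <- as.matrix(X)[, keep, drop = FALSE]
  M <- cbind(1, v[keep])
  # hat-matrix complement applied to all genes at once
  beta <- solve(crossprod(M), t(M))          # 2 x n_parcels
  t(t(Xk) - M %*% (beta %*% t(Xk)))
}

#' One-component PLS weights
#'
#' First-component PLS1 x-weights: the unit-norm vector proportional to the
#' per-gene covariance with the response map, `w ∝ X_c y_c` (rows of `X`
#' centered across parcels, `y` centered). With orthonormal predictors this
#' reduces to the univariate covariances. Invariant to gene ordering and to
#' positive rescaling of `y`.
#'
#' @param X Genes x parcels matrix (typically residualized, see
#'   [residualize_matrix()]).
#' @param y Response vector over parcels (typically the residual timescale
#'   map).
#' @return Named numeric vector of per-gene weights, unit Euclidean norm.
#' @export
pls1_weights <- function(X, y) {
  y <- as.numeric(y)
  keep <- is.finite(y)
  y <- y[keep]
  if (sd(y) == 0) stop_ts("response map has zero variance")
  Xk <- as.matrix(X)[, keep, drop = FALSE]
  Xc <- Xk - rowMeans(Xk)
  w <- as.numeric(Xc %*% (y - mean(y)))
  w <- w / sqrt(sum(w^2))
  names(w) <- rownames(X)
  w
}

#' Null-map PLS gene selection
#'
#' Refits the one-component PLS weights against each SA-preserving null of
#' the response map and selects genes whose absolute empirical weight
#' exceeds the 95th percentile of their own null absolute-weight
#' distribution.
#'
#' @param X Genes x parcels (residualized) expression matrix.
#' @param y (Residual) response map over parcels.
#' @param null_y A [msr_nulls()] ensemble of `y` (or of its residual map).
#' @param percentile Selection percentile (default 0.95).
#' @return data.frame `gene_id`, `weight`, `null_q` (the per-gene null
#'   percentile threshold), `significant`.
#' @export
null_pls_gene_selection <- function(X, y, null_y, percentile = 0.95) {
  stopifnot(inherits(null_y, "null_ensemble"))
  if (null_y$n_null < 100L)
    warning("fewer than 100 nulls; the selection percentile is unstable")
  w_emp <- pls1_weights(X, y)
  yk <- as.numeric(y)
  keep <- is.finite(yk)
  Xk <- as.matrix(X)[, keep, drop = FALSE]
  Xc <- Xk - rowMeans(Xk)
  Yn <- t(null_y$nulls[, keep, drop = FALSE])     # parcels x n_null
  Yc <- t(t(Yn) - colMeans(Yn))
  Wn <- Xc %*% Yc                                  # genes x n_null
  norms <- sqrt(colSums(Wn^2))
  Wn <- abs(t(t(Wn) / norms))
  thr <- apply(Wn, 1L, quantile, probs = percentile, names = FALSE)
  data.frame(gene_id = rownames(X), weight = as.numeric(w_emp),
             null_q = thr, significant = abs(w_emp) > thr,
             stringsAsFactors = FALSE)
}

#' Gene ontology enrichment analysis
#'
#' Per-term two-sided Fisher's exact test of the 2x2 table (study vs.
#' reference, in-term vs. out-of-term), Benjamini-Hochberg adjustment across
#' all tested terms, and the enrichment ratio `(b/n) / (B/N)` where `N` is
#' the reference size, `n` the study size, `B` the term size within the
#' reference, and `b` the study-term overlap. Terms with `b = 0` have ratio
#' 0 (purification candidates). Annotation genes outside the reference are
#' ignored; terms are tested independently (no ontology-graph propagation).
#'
#' @param study_genes Character vector, the significant gene set.
#' @param reference_genes Character vector, the universe (study is
#'   intersected into it; an empty study set is an error).
#' @param annotation data.frame with columns `term_id`, `gene_id`.
#' @param terms Optional term metadata (`term_id`, `name`, `namespace`)
#'   merged into the output.
#' @return data.frame `term_id`, `N`, `n`, `B`, `b`, `enrichment_ratio`,
#'   `p`, `q`, ordered by `p` (plus `name`, `namespace` when supplied).
#' @export
go_enrichment <- function(study_genes, reference_genes, annotation,
                          terms = NULL) {
  reference_genes <- unique(reference_genes)
  study_genes <- unique(intersect(study_genes, reference_genes))
  if (length(study_genes) == 0L) stop_ts("study set is empty")
  N <- length(reference_genes)
  n <- length(study_genes)
  ann <- annotation[annotation$gene_id %in% reference_genes, , drop = FALSE]
  by_term <- split(ann$gene_id, ann$term_id)
  rows <- lapply(names(by_term), function(tid) {
    genes_t <- unique(by_term[[tid]])
    B <- length(genes_t)
    b <- length(intersect(genes_t, study_genes))
    p <- fisher.test(matrix(c(b, B - b, n - b, N - B - n + b), 2L))$p.value
    data.frame(term_id = tid, N = N, n = n, B = B, b = b,
               enrichment_ratio = (b / n) / (B / N), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  if (!is.null(terms)) out <- merge(terms, out, by = "term_id")
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-scale comparison of gene-timescale associations
#'
#' Correlates per-gene single-cell association statistics (e.g. membrane
#' time-constant correlations from patch-seq data) with the macroscale
#' map-correlation coefficients of the same genes, overall and within
#' quantiles of the absolute macroscale correlation. By default the
#' macroscale set is restricted to genes with `p_sa < 0.05`.
#'
#' @param micro data.frame `gene_id`, `statistic` (single-cell association).
#' @param macro data.frame `gene_id`, `rho` (macroscale Spearman), and
#'   optionally `p_sa` used by the restriction.
#' @param n_quantiles Number of |macro rho| quantile bins (default 5,
#'   quintiles).
#' @param restrict_significant Restrict to macroscale `p_sa < 0.05`?
#' @return List with `overall_rho`, `overall_p`, `by_quantile` (data.frame
#'   `quantile`, `rho`, `n`), `n_genes`.
#' @export
cross_scale_comparison <- function(micro, macro, n_quantiles = 5L,
                                   restrict_significant = TRUE) {
  if (restrict_significant && !is.null(macro$p_sa))
    macro <- macro[macro$p_sa < 0.05, , drop = FALSE]
  j <- merge(micro, macro, by = "gene_id")
  if (nrow(j) < 10L) stop_ts("fewer than 10 genes joined across scales")
  ct <- cor.test(j$statistic, j$rho, method = "spearman", exact = FALSE)
  qs <- cut(rank(abs(j$rho), ties.method = "first"),
            breaks = n_quantiles, labels = FALSE)
  byq <- do.call(rbind, lapply(seq_len(n_quantiles), function(q) {
    sub <- j[qs == q, , drop = FALSE]
    data.frame(quantile = q,
               rho = if (nrow(sub) >= 3L)
                 cor(sub$statistic, sub$rho, method = "spearman")
               else NA_real_,
               n = nrow(sub))
  }))
  list(overall_rho = unname(ct$estimate), overall_p = ct$p.value,
       by_quantile = byq, n_genes = nrow(j))
}
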