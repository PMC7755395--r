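test_that("brain-specific gene selection applies the strict 4x rule", {
  X <- rbind(boundary = c(8, 2, 2, 2),   # brain = 8 = 4 x median -> excluded
             included = c(9, 2, 2, 2),
             flat = c(2, 2, 2, 2),
             zero_med = c(1, 0, 0, 0))
  colnames(X) <- c("brain", "t1", "t2", "t3")
  sel <- select_brain_specific(X, "brain")
  expect_setequal(as.character(sel), c("included", "zero_med"))
  expect_equal(attr(sel, "n_zero_median"), 1L)
})

test_that("expression PCA recovers planted structure deterministically", {
  geom <- test_geom
  grad <- generate_sa_map(geom, 25, seed = 81)

  # rank-1 matrix: first component explains everything
  X1 <- outer(runif(40, 0.5, 2), grad$values)
  rownames(X1) <- sprintf("g%02d", 1:40)
  p1 <- expression_pca(normalize_expression(X1), k = 3)
  expect_equal(p1$explained_variance_ratio[1L], 1, tolerance = 1e-10)

  # planted single gradient + noise: PC1 tracks it
  ex <- generate_expression_matrix(geom, grad, n_genes = 300,
                                   n_associated = 300, effect_size = 1,
                                   noise_sd = 0.3, seed = 82)
  pc <- expression_pca(normalize_expression(ex$X), k = 4)
  expect_gte(abs(cor(pc$components[, 1L], grad$values)), 0.95)
  expect_true(all(diff(pc$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(pc$explained_variance_ratio), 1 + 1e-8)

  # gene order must not matter
  perm <- sample(nrow(ex$X))
  pc2 <- expression_pca(normalize_expression(ex$X[perm, ]), k = 4)
  expect_equal(abs(cor(pc$components[, 1L], pc2$components[, 1L])), 1,
               tolerance = 1e-8)

  # full SVD reconstructs the matrix
  Xn <- normalize_expression(ex$X)
  s <- svd(Xn)
  expect_lt(max(abs(Xn - s$u %*% diag(s$d) %*% t(s$v))), 1e-8)
})

test_that("per-gene map correlations separate planted from background genes", {
  geom <- test_geom
  target <- generate_sa_map(geom, 25, seed = 91)
  ex <- generate_expression_matrix(geom, target, n_genes = 400,
                                   n_associated = 40, effect_size = 1,
                                   noise_sd = 0.5, seed = 92)
  W <- test_W
  nulls <- msr_nulls(target, W, n_null = 200, seed = 93)
  assoc <- correlate_genes_with_map(ex$X, target, nulls)
  planted <- assoc$gene_id %in% ex$truth$associated_genes
  expect_gt(median(abs(assoc$rho[planted])),
            median(abs(assoc$rho[!planted])))
  expect_gt(mean(assoc$significant[planted]),
            mean(assoc$significant[!planted]))

  # a gene identical to the map correlates perfectly
  Xid <- rbind(ex$X, target = target$values)
  assoc_id <- correlate_genes_with_map(Xid, target, nulls)
  expect_equal(assoc_id$rho[assoc_id$gene_id == "target"], 1)

  # noiseless planted genes hit |rho| = 1
  ex0 <- generate_expression_matrix(geom, target, n_genes = 20,
                                    n_associated = 5, effect_size = 1,
                                    noise_sd = 0, seed = 94)
  assoc0 <- correlate_genes_with_map(ex0$X, target, nulls)
  pl <- assoc0$gene_id %in% ex0$truth$associated_genes
  expect_true(all(abs(assoc0$rho[pl]) == 1))
})

test_that("residualization removes the covariate exactly", {
  geom <- test_geom
  x <- generate_sa_map(geom, 25, seed = 101)
  y_perfect <- 2 * x$values + 3
  expect_lt(max(abs(residualize(y_perfect, x))), 1e-10)

  noise <- generate_sa_map(geom, 25, seed = 102)
  y <- x$values + noise$values
  r <- residualize(y, x)
  expect_lt(abs(cor(r, x$values)), 1e-10)
  expect_gt(cor(r, noise$values), 0.5)

  # orthogonal input: residual is the centered input
  y_orth <- noise$values - mean(noise$values) -
    cov(noise$values, x$values) / var(x$values) *
      (x$values - mean(x$values))
  expect_equal(residualize(y_orth, x), y_orth, tolerance = 1e-10)

  expect_error(residualize(y, rep(1, length(y))), "constant")

  # matrix version agrees with row-wise calls
  X <- rbind(a = y, b = noise$values)
  R <- tauspec:::residualize_matrix(X, x)
  expect_equal(unname(R[1L, ]), residualize(y, x), tolerance = 1e-10)
})

test_that("PLS1 weights equal normalized covariances with the response", {
  set.seed(7)
  n <- 40
  y <- rnorm(n)
  X <- matrix(rnorm(10 * n), 10, n)
  rownames(X) <- letters[1:10]
  w <- pls1_weights(X, y)
  Xc <- X - rowMeans(X)
  covs <- as.numeric(Xc %*% (y - mean(y)))
  expect_equal(unname(w), covs / sqrt(sum(covs^2)), tolerance = 1e-12)
  expect_equal(sum(w^2), 1)

  # invariant to positive rescaling of y and to gene order
  expect_equal(pls1_weights(X, 3.7 * y), w)
  perm <- sample(10)
  expect_equal(pls1_weights(X[perm, ], y), w[perm])

  # the response inserted as a predictor dominates
  X2 <- rbind(X, yy = y)
  w2 <- pls1_weights(X2, y)
  expect_equal(names(which.max(abs(w2))), "yy")

  expect_error(pls1_weights(X, rep(1, n)), "zero variance")
})

test_that("null-map PLS selection recovers planted genes at scale", {
  geom <- test_geom
  target <- generate_sa_map(geom, 25, seed = 111)
  ex <- generate_expression_matrix(geom, target, n_genes = 400,
                                   n_associated = 30, effect_size = 1,
                                   noise_sd = 0.5, seed = 112)
  W <- test_W
  nulls <- msr_nulls(target, W, n_null = 200, seed = 113)
  sel <- null_pls_gene_selection(ex$X, target$values, nulls)
  planted <- sel$gene_id %in% ex$truth$associated_genes
  sens <- mean(sel$significant[planted])
  fpr <- mean(sel$significant[!planted])
  expect_gte(sens, 0.8)
  expect_lte(fpr, 0.1)

  expect_warning(
    null_pls_gene_selection(ex$X, target$values,
                            msr_nulls(target, W, 50, seed = 1)),
    "100 nulls")
})

test_that("Fisher enrichment matches the hypergeometric oracle", {
  # the toy table: N = 20, n = 5, B = 4, b = 3
  ref <- sprintf("g%02d", 1:20)
  study <- ref[1:5]
  ann <- data.frame(term_id = "T1", gene_id = ref[c(1, 2, 3, 6)])
  res <- go_enrichment(study, ref, ann)
  expect_equal(res$enrichment_ratio, 3.0)
  expect_equal(res$b, 3L)
  expect_equal(res$p, fisher_p_oracle(3, 4, 5, 20), tolerance = 1e-12)

  # random tables up to N = 60 against brute-force enumeration
  set.seed(21)
  for (i in 1:60) {
    N <- sample(10:60, 1)
    n <- sample(1:(N - 1), 1)
    B <- sample(1:N, 1)
    bs <- max(0, n + B - N):min(n, B)
    b <- bs[sample.int(length(bs), 1)]
    ref <- sprintf("g%03d", 1:N)
    study <- ref[seq_len(n)]
    genes_t <- c(ref[seq_len(b)], setdiff(ref, study)[seq_len(B - b)])
    res <- go_enrichment(study, ref, data.frame(term_id = "T", gene_id = genes_t))
    expect_equal(res$p, fisher_p_oracle(b, B, n, N), tolerance = 1e-12)
    expect_equal(res$enrichment_ratio, (b / n) / (B / N), tolerance = 1e-12)
  }
})

test_that("enrichment edge cases and BH adjustment behave", {
  ref <- sprintf("g%02d", 1:20)
  ann <- data.frame(term_id = rep(c("T1", "T2", "T3"), times = c(20, 4, 6)),
                    gene_id = c(ref, ref[17:20], ref[15:20]))
  # saturating term: ratio 1, p = 1
  res <- go_enrichment(ref, ref, ann)
  expect_true(all(res$enrichment_ratio == 1))
  expect_true(all(res$p == 1))

  # disjoint term: ratio 0 (purification direction)
  res2 <- go_enrichment(ref[1:5], ref, ann)
  t2 <- res2[res2$term_id == "T2", ]
  expect_equal(t2$b, 0L)
  expect_equal(t2$enrichment_ratio, 0)

  # q monotone non-decreasing in p
  expect_true(all(diff(res2$q[order(res2$p)]) >= -1e-12))
  expect_true(all(res2$q >= res2$p - 1e-12))

  expect_error(go_enrichment(character(0), ref, ann), "empty")
})

test_that("a term equal to the planted gene set attains the smallest p", {
  geom <- test_geom
  target <- generate_sa_map(geom, 25, seed = 121)
  ex <- generate_expression_matrix(geom, target, n_genes = 300,
                                   n_associated = 25, effect_size = 1,
                                   noise_sd = 0.4, seed = 122)
  nulls <- msr_nulls(target, test_W, n_null = 200, seed = 123)
  sel <- null_pls_gene_selection(ex$X, target$values, nulls)
  onto <- generate_toy_ontology(ex$gene_ids, 20, seed = 124)
  ann <- rbind(onto$annotation,
               data.frame(term_id = "PLANTED",
                          gene_id = ex$truth$associated_genes))
  res <- go_enrichment(sel$gene_id[sel$significant], ex$gene_ids, ann)
  expect_equal(res$term_id[which.min(res$p)], "PLANTED")
})

test_that("cross-scale comparison handles identity, null, and gradients", {
  set.seed(31)
  genes <- sprintf("g%03d", 1:200)
  rho_macro <- runif(200, -0.9, 0.9)
  macro <- data.frame(gene_id = genes, rho = rho_macro,
                      p_sa = runif(200, 0, 0.04))

  # identity: rho 1 overall and in every quantile
  micro <- data.frame(gene_id = genes, statistic = rho_macro)
  cs <- cross_scale_comparison(micro, macro)
  expect_equal(cs$overall_rho, 1)
  expect_true(all(abs(cs$by_quantile$rho - 1) < 1e-12))

  # independent: near zero
  micro0 <- data.frame(gene_id = genes, statistic = rnorm(200))
  cs0 <- cross_scale_comparison(micro0, macro)
  expect_lt(abs(cs0$overall_rho), 0.2)

  # noise shrinking with |macro rho|: per-quantile rho increases
  noise_sd <- 1.2 - abs(rho_macro)
  micro2 <- data.frame(gene_id = genes,
                       statistic = rho_macro + rnorm(200, 0, noise_sd))
  cs2 <- cross_scale_comparison(micro2, macro)
  q <- cs2$by_quantile$rho
  expect_gt(cor(seq_along(q), q, method = "spearman"), 0.5)

  expect_error(cross_scale_comparison(micro[1:5, ], macro[1:5, ]), "10 genes")
})
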