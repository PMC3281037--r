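test_that("variant-overlap probe filter uses half-open intervals", {
  feats <- data.frame(feature_id = c("p1", "p2", "p3"), gene_id = "gA",
                      exon_index = 1:3, chrom = "chrT",
                      start = c(100, 100, 300), end = c(125, 125, 350),
                      platform = "test")
  # SNP at 110 inside [100,125) drops p1/p2; SNP at 125 (boundary) retains
  expect_setequal(
    filter_probes_overlapping_variants(feats,
                                       data.frame(chrom = "chrT", pos = 110)),
    "p3")
  expect_setequal(
    filter_probes_overlapping_variants(feats,
                                       data.frame(chrom = "chrT", pos = 125)),
    c("p1", "p2", "p3"))
  # empty variant list: all retained, order preserved
  expect_identical(
    filter_probes_overlapping_variants(feats, NULL),
    c("p1", "p2", "p3"))
  # interval variant overlapping p3
  expect_setequal(
    filter_probes_overlapping_variants(
      feats, data.frame(chrom = "chrT", pos = 340, end = 360)),
    c("p1", "p2"))
  # missing intervals are an error naming the feature
  feats$start[2] <- NA
  expect_error(filter_probes_overlapping_variants(
    feats, data.frame(chrom = "chrT", pos = 1)), "p2")
})

test_that("non-expressed filters follow the platform rules", {
  v <- rbind(c(0, 0, 0, 0, 0, 0),       # zero everywhere
             c(5, 6, 5, 0, 0, 0),       # expressed in pop 1 only
             c(3, 3, 3, 3, 3, 3),       # constant (MAD 0)
             c(1, 9, 2, 8, 3, 7))
  ex <- toy_expr(v, populations = rep(c("A", "B"), each = 3))
  # count rule: dropped iff median 0 in every population
  expect_setequal(filter_non_expressed(ex, "zero_median_count"),
                  c("f2", "f3", "f4"))
  # median-level rule with ALL-populations logic
  expect_setequal(filter_non_expressed(ex, "median_level", threshold = 1),
                  c("f2", "f3", "f4"))
  # constant feature dropped under mad with positive threshold
  expect_false("f3" %in% filter_non_expressed(ex, "mad", threshold = 0.5))
  expect_error(filter_non_expressed(ex, "median_level"), "threshold")
})

test_that("quantile normalization produces exact normal scores", {
  ex <- toy_expr(matrix(c(5, 2, 9), 1, 3))
  qn <- quantile_normalize(ex)
  # ranks 2,1,3 of n=3 -> qnorm(c(.5,.25,.75))
  expect_equal(as.vector(qn$values),
               qnorm(c(2, 1, 3) / 4), tolerance = 1e-12)

  # rank invariance under strictly monotone transforms
  set.seed(7)
  v <- matrix(rnorm(60), 4, 15)
  ex2 <- toy_expr(v)
  expect_equal(quantile_normalize(ex2)$values,
               quantile_normalize(toy_expr(exp(3 * v)))$values)

  # all-tied vector maps to zeros (average rank = middle)
  ex3 <- toy_expr(matrix(2, 1, 5))
  expect_true(all(quantile_normalize(ex3)$values == 0))

  # idempotence (no ties)
  qn2 <- quantile_normalize(quantile_normalize(ex2))
  expect_equal(qn2$values, quantile_normalize(ex2)$values, tolerance = 1e-12)

  # group of size 1 rejected
  ex4 <- toy_expr(matrix(1:4, 2, 2), populations = c("A", "B"))
  expect_error(quantile_normalize(ex4), "fewer than 2")

  # normalization is within population
  ex5 <- toy_expr(matrix(c(1, 2, 3, 10, 20, 30), 1, 6),
                  populations = rep(c("A", "B"), each = 3))
  qn5 <- quantile_normalize(ex5)
  expect_equal(unname(qn5$values[1, 1:3]), unname(qn5$values[1, 4:6]))
})

test_that("population centering zeroes group means and is idempotent", {
  ex <- toy_expr(matrix(c(1, 2, 3, 10, 20, 30), 1, 6),
                 populations = rep(c("A", "B"), each = 3))
  ct <- center_by_population(ex)
  expect_equal(as.vector(ct$values), c(-1, 0, 1, -10, 0, 10))
  expect_equal(center_by_population(ct)$values, ct$values)
  # single group equals global centering
  ex2 <- toy_expr(matrix(1:5, 1, 5))
  expect_equal(as.vector(center_by_population(ex2)$values),
               as.vector(scale(1:5, scale = FALSE)))
})

test_that("PC selection separates planted factors from iid noise", {
  # defaults follow the published recipe
  expect_equal(formals(select_num_pcs)$n_perm, 100)
  expect_equal(formals(select_num_pcs)$upper_quantile, 0.975)

  noise_k <- planted_k <- integer(20)
  for (s in 1:20) {
    set.seed(s)
    noise <- matrix(rnorm(50 * 40), 50, 40)
    ex_n <- toy_expr(noise)
    noise_k[s] <- select_num_pcs(ex_n, n_perm = 40, seed = s)$K
    fac <- matrix(rnorm(3 * 40), 3, 40)
    load <- matrix(rnorm(50 * 3, 0, 3), 50, 3)
    ex_f <- toy_expr(load %*% fac + noise)
    planted_k[s] <- select_num_pcs(ex_f, n_perm = 40, seed = s)$K
  }
  expect_gte(mean(noise_k == 0), 0.9)
  expect_gte(mean(planted_k == 3), 0.9)
  expect_error(select_num_pcs(toy_expr(matrix(1:4, 2, 2))), "3 samples")
})

test_that("elastic-net residualization matches its contract", {
  # K = 0 and no covariates: output equals centered input
  set.seed(11)
  v <- matrix(rnorm(200), 10, 20)
  ex <- toy_expr(v)
  r0 <- regress_out_factors(ex, K = 0, covariates = character(0))
  expect_equal(r0$values, v - rowMeans(v), ignore_attr = TRUE)

  # exact low-rank matrix: residuals vanish (perfect predictors)
  fac <- matrix(rnorm(3 * 30), 3, 30)
  load <- matrix(rnorm(20 * 3), 20, 3)
  exr <- toy_expr(load %*% fac)
  rr <- regress_out_factors(exr, K = 3, covariates = character(0))
  expect_lt(max(abs(rr$values)), 1e-6)

  # independent features keep ~all of their variance
  set.seed(12)
  n <- 60
  fac2 <- matrix(rnorm(2 * n), 2, n)
  conf <- matrix(rnorm(30 * 2, 0, 3), 30, 2) %*% fac2 +
    matrix(rnorm(30 * n), 30, n)
  indep <- matrix(rnorm(10 * n), 10, n)
  ex2 <- toy_expr(rbind(conf, indep))
  r2 <- regress_out_factors(ex2, K = 2, covariates = character(0))
  vr <- apply(r2$values[31:40, ], 1, var) / apply(indep, 1, var)
  expect_true(all(vr > 0.9 & vr < 1.1))

  expect_error(regress_out_factors(ex, K = 50), "K exceeds")
})

test_that("the compiled elastic net solves the glmnet objective", {
  skip_if_not_installed("glmnet")
  set.seed(2)
  n <- 60; p <- 5
  X <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(X %*% c(1, -0.5, 0, 0, 0.2) + rnorm(n, 0, 0.5))
  for (pen in list(c(0.05, 0.3), c(0.2, 0.01), c(0.01, 2))) {
    l1 <- pen[1]; l2 <- pen[2]
    fit <- eqtnpos:::elnet_fit_cpp(X, y, l1, l2)
    # glmnet standardizes y internally, which rescales the ridge term:
    # lambda * alpha = l1, lambda * (1 - alpha) = l2 * sd_n(y)
    sdy <- sqrt(mean((y - mean(y))^2))
    lam <- l1 + l2 * sdy; al <- l1 / lam
    gf <- glmnet::glmnet(X, y, alpha = al,
                         lambda = exp(seq(log(lam * 20), log(lam),
                                          length.out = 40)),
                         standardize = FALSE, thresh = 1e-14)
    b <- as.numeric(stats::coef(gf, s = lam))[-1]
    expect_equal(fit$beta, b, tolerance = 1e-6)
  }
})

test_that("factor removal restores nominal type-I error", {
  # planted confounders, null genetics: association tests on corrected
  # expression should reject at ~alpha
  set.seed(30)
  n <- 60; m <- 60
  fac <- matrix(rnorm(3 * n), 3, n)
  load <- matrix(rnorm(m * 3, 0, 2), m, 3)
  v <- load %*% fac + matrix(rnorm(m * n), m, n)
  ex <- toy_expr(v, populations = rep(c("A", "B"), each = n / 2))
  pp <- preprocess_expression(ex, n_perm = 40, seed = 5)
  G <- matrix(rbinom(40 * n, 2, 0.3), 40, n)
  p <- unlist(lapply(seq_len(nrow(pp$expr$values)), function(r)
    vapply(seq_len(nrow(G)), function(i)
      test_association(pp$expr$values[r, ], G[i, ])$p, numeric(1))))
  expect_gt(mean(p < 0.01), 0.003)
  expect_lt(mean(p < 0.01), 0.022)
})
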