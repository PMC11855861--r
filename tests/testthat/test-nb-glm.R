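test_that("NB fit agrees with an independent ML implementation", {
  skip_if_not_installed("MASS")
  set.seed(7)
  for (i in 1:3) {
    x <- runif(11, 0, 4)
    y <- rnbinom(11, mu = exp(3 + 0.5 * x), size = 10)
    f <- fit_nb_glm(y, x)
    m <- MASS::glm.nb(y ~ x)
    expect_equal(c(f$intercept, f$slope), unname(coef(m)), tolerance = 1e-6)
    expect_equal(f$theta, m$theta, tolerance = 1e-5)
    expect_equal(f$se, sqrt(diag(vcov(m)))[[2]], tolerance = 1e-5)
  }
})

test_that("NB fit attains the maximum of the likelihood surface", {
  # independent oracle: coarse lattice over slope x log(theta), intercept
  # profiled, likelihood evaluated with dnbinom
  set.seed(17)
  for (i in 1:3) {
    x <- runif(9, 0, 3)
    y <- rnbinom(9, mu = exp(2 + 0.4 * x), size = 5)
    f <- fit_nb_glm(y, x)
    ll <- function(b0, b1, th)
      sum(dnbinom(y, size = th, mu = exp(b0 + b1 * x), log = TRUE))
    ll_fit <- ll(f$intercept, f$slope, f$theta)
    lattice <- expand.grid(b1 = seq(f$slope - 1.5, f$slope + 1.5, length.out = 21),
                           lth = seq(log(0.5), log(200), length.out = 21))
    ll_best <- max(apply(lattice, 1, function(r)
      optimize(function(b0) -ll(b0, r[["b1"]], exp(r[["lth"]])),
               c(-10, 15), tol = 1e-8)$objective) * -1)
    expect_gte(ll_fit, ll_best - 0.02)
  }
})

test_that("the Poisson limit reproduces a Poisson GLM", {
  set.seed(19)
  x <- runif(12, 0, 3)
  y <- rpois(12, exp(1 + 0.3 * x))
  f <- fit_nb_glm(y, x)
  g <- glm(y ~ x, family = poisson)
  expect_equal(c(f$intercept, f$slope), unname(coef(g)), tolerance = 1e-6)
  expect_gte(f$theta, 1e4)
})

test_that("null slopes stay within three standard errors", {
  set.seed(43)
  evs <- ev_design_11()
  within <- replicate(400, {
    y <- rpois(11, exp(1))
    f <- tryCatch(fit_nb_glm(y, evs), error = function(e) NULL)
    if (is.null(f)) NA else abs(f$slope) <= 3 * f$se
  })
  expect_gte(mean(within, na.rm = TRUE), 0.95)
})

test_that("NB fit rejects degenerate inputs", {
  expect_error(fit_nb_glm(c(1, 2, 3, 4), rep(1, 4)), "zero variance")
  expect_error(fit_nb_glm(rep(0, 6), 1:6), "all-zero")
  expect_error(fit_nb_glm(c(1, 2, 3), c(1, 2, 3)), ">= 4")
  expect_error(fit_nb_glm(c(1, -2, 3, 4), 1:4), ">= 0")
})

test_that("BH adjustment reproduces the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # independent step-up oracle on random vectors
  set.seed(23)
  for (i in 1:10) {
    p <- runif(sample(2:40, 1))
    m <- length(p); o <- order(p)
    q <- pmin(1, m * p[o] / seq_len(m))
    q <- rev(cummin(rev(q)))
    oracle <- numeric(m); oracle[o] <- q
    adj <- bh_adjust(p)
    expect_equal(adj, oracle, tolerance = 1e-12)
    # monotone non-decreasing in the sorted order of the raw p
    expect_true(all(diff(adj[o]) >= -1e-12))
    expect_true(all(adj >= p - 1e-12))
  }
})

test_that("DEG filtering applies strict thresholds and direction", {
  tab <- data.frame(
    gene_id = c("Pex5", "flat", "boundary_fc", "boundary_p", "up_ok"),
    log2_fc = c(-14.82, 0.0, 1.0, 2.0, 1.5),
    p_value = c(0.01, 0.001, 0.01, 0.05, 0.049))
  out <- filter_degs(tab)
  expect_setequal(out$gene_id, c("Pex5", "up_ok"))
  expect_equal(out$direction[out$gene_id == "Pex5"], "down")
  expect_equal(out$direction[out$gene_id == "up_ok"], "up")
  expect_error(filter_degs(data.frame(gene_id = "g", log2_fc = Inf,
                                      p_value = 0.01)), "finite")
})

test_that("group contrast recovers planted fold changes and flips sign", {
  set.seed(41)
  x_groups <- rep(c("SAL", "METH"), each = 6)
  hits <- replicate(200, {
    y <- rnbinom(12, mu = exp(3 + log(4) * (x_groups == "METH")), size = 10)
    mat <- matrix(y, nrow = 1, dimnames = list("g1", paste0("s", 1:12)))
    meta <- data.frame(sample_id = colnames(mat), group = x_groups)
    de <- nb_group_contrast(mat, meta, groups = c("SAL", "METH"))
    abs(de$log2_fc - 2) <= 0.5
  })
  expect_gte(mean(hits), 0.90)
  # exact sign symmetry under group reversal
  set.seed(44)
  mat <- matrix(rnbinom(24, mu = 20, size = 10), nrow = 2,
                dimnames = list(c("g1", "g2"), paste0("s", 1:12)))
  meta <- data.frame(sample_id = colnames(mat), group = x_groups)
  d1 <- nb_group_contrast(mat, meta, groups = c("SAL", "METH"))
  d2 <- nb_group_contrast(mat, meta, groups = c("METH", "SAL"))
  expect_equal(d1$log2_fc, -d2$log2_fc, tolerance = 1e-8)
})

test_that("null group contrasts rarely pass the DEG rule", {
  set.seed(42)
  n_g <- 2000
  mu0 <- exp(rnorm(n_g, 3.5, 1))
  mat <- matrix(rnbinom(n_g * 12, mu = rep(mu0, 12), size = 10), nrow = n_g,
                dimnames = list(paste0("g", seq_len(n_g)), paste0("s", 1:12)))
  meta <- data.frame(sample_id = colnames(mat),
                     group = rep(c("SAL", "METH"), each = 6))
  de <- nb_group_contrast(mat, meta, groups = c("SAL", "METH"))
  ok <- complete.cases(de[c("log2_fc", "p_value")])
  expect_lt(nrow(filter_degs(de[ok, ])) / sum(ok), 0.01)
})
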