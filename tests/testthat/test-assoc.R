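# independent IRLS oracle used in several tests: plain Newton-Raphson on the
# full design, no shortcuts shared with the package implementation
oracle_logistic <- function(X, y, iter = 50) {
  b <- rep(0, ncol(X))
  for (i in seq_len(iter)) {
    mu <- 1 / (1 + exp(-drop(X %*% b)))
    W <- mu * (1 - mu)
    grad <- drop(t(X) %*% (y - mu))
    H <- t(X) %*% (X * W)
    b <- b + solve(H, grad)
  }
  mu <- 1 / (1 + exp(-drop(X %*% b)))
  H <- t(X) %*% (X * (mu * (1 - mu)))
  list(beta = b, se = sqrt(diag(solve(H))),
       ll = sum(y * log(mu) + (1 - y) * log(1 - mu)))
}

woolf_study <- function() {
  # printed 2x2 table: dosage 0/1 cells resilient (20, 10), cases (10, 20)
  dos <- c(rep(0, 20), rep(1, 10), rep(0, 10), rep(1, 20))
  status <- c(rep("control", 30), rep("case", 30))
  st <- toy_study(n = 60, m = 1, dosages = dos,
                  samples = toy_samples(60, status = status))
  ch <- toy_cohort(st$samples$sample_id[1:30], st$samples$sample_id[31:60])
  list(st = st, ch = ch)
}

test_that("GWAS beta/SE equal the closed-form Woolf estimator on a 2x2 table", {
  f <- woolf_study()
  out <- run_resilience_gwas(f$st, f$ch, covariates = character(0))
  # Woolf oracle: logOR and SE from the four cells
  a <- 10; b <- 20; c <- 20; d <- 10   # resilient d1, resilient d0, case d0, case d1... cells below
  # odds(resilient | d=1) = 10/20, odds(resilient | d=0) = 20/10
  lor <- log((10 / 20) / (20 / 10))
  se <- sqrt(1 / 20 + 1 / 10 + 1 / 10 + 1 / 20)
  expect_equal(out$beta, lor, tolerance = 1e-7)
  expect_equal(out$se, se, tolerance = 1e-7)
  expect_equal(out$p, 2 * pnorm(-abs(lor / se)), tolerance = 1e-7)
})

test_that("GWAS matches the independent IRLS oracle with covariates", {
  set.seed(55)
  n <- 120
  status <- rep(c("control", "case"), each = n / 2)
  st <- toy_study(n = n, m = 8, seed = 55, n_pcs = 2,
                  samples = toy_samples(n, status = status, n_pcs = 2,
                                        seed = 55))
  ch <- toy_cohort(st$samples$sample_id[status == "control"],
                   st$samples$sample_id[status == "case"])
  out <- run_resilience_gwas(st, ch, covariates = c("age", "sex", "PC1", "PC2"))
  y <- as.numeric(c(rep(1, n / 2), rep(0, n / 2)))
  for (j in which(st$variants$snp_id %in% out$snp_id)) {
    X <- cbind(1, st$samples$age, st$samples$sex, st$samples$PC1,
               st$samples$PC2, st$dosages[, j])
    o <- oracle_logistic(X, y)
    k <- match(st$variants$snp_id[j], out$snp_id)
    expect_equal(out$beta[k], o$beta[6], tolerance = 1e-6)
    expect_equal(out$se[k], o$se[6], tolerance = 1e-6)
  }
})

test_that("monomorphic variants are skipped with a reason", {
  st <- toy_study(n = 30, m = 3, dosages = cbind(rep(1, 30), rbinom(30, 2, .4),
                                                 rbinom(30, 2, .4)))
  ch <- toy_cohort(st$samples$sample_id[1:15], st$samples$sample_id[16:30])
  out <- run_resilience_gwas(st, ch, covariates = character(0))
  expect_false("v001" %in% out$snp_id)
  expect_equal(unname(attr(out, "skipped")["monomorphic"]), 1)
})

test_that("null GWAS P-values are uniform (permutation null)", {
  set.seed(66)
  n <- 200
  st <- toy_study(n = n, m = 300, seed = 66,
                  samples = toy_samples(n, status = sample(rep(c("control", "case"),
                                                               each = n / 2))))
  ch <- toy_cohort(st$samples$sample_id[st$samples$status == "control"],
                   st$samples$sample_id[st$samples$status == "case"])
  out <- run_resilience_gwas(st, ch, covariates = character(0))
  ks <- suppressWarnings(stats::ks.test(out$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("score evaluation matches an independent maximum-likelihood fit", {
  set.seed(77)
  n <- 40
  status <- rep(c("control", "case"), each = 20)
  st <- toy_study(n = n, m = 2, seed = 77,
                  samples = toy_samples(n, status = status, seed = 77))
  ch <- toy_cohort(st$samples$sample_id[1:20], st$samples$sample_id[21:40])
  sc <- setNames(rnorm(n) + 0.8 * (status == "control"),
                 st$samples$sample_id)
  fit <- evaluate_score(st, ch, sc, covariates = "age")
  z <- (sc - mean(sc)) / sd(sc)   # evaluate_score standardizes internally
  X <- cbind(1, z, st$samples$age)
  o <- oracle_logistic(X, as.numeric(status == "control"))
  expect_equal(fit$lnor, unname(o$beta[2]), tolerance = 1e-6)
  expect_equal(fit$se, unname(o$se[2]), tolerance = 1e-6)
  expect_equal(fit$ll_full, o$ll, tolerance = 1e-6)
  o0 <- oracle_logistic(cbind(1, st$samples$age),
                        as.numeric(status == "control"))
  expect_equal(fit$ll_null, o0$ll, tolerance = 1e-6)
})

test_that("OR direction: higher scores favour the resilient group", {
  set.seed(88)
  n <- 400
  status <- rep(c("control", "case"), each = n / 2)
  st <- toy_study(n = n, m = 2, seed = 88,
                  samples = toy_samples(n, status = status))
  ch <- toy_cohort(st$samples$sample_id[1:(n / 2)],
                   st$samples$sample_id[(n / 2 + 1):n])
  up <- setNames(rnorm(n) + (status == "control"), st$samples$sample_id)
  expect_gt(evaluate_score(st, ch, up, covariates = character(0))$lnor, 0)
  # independent score, large n: lnOR near zero
  null_sc <- setNames(rnorm(n), st$samples$sample_id)
  fit0 <- evaluate_score(st, ch, null_sc, covariates = character(0))
  expect_lt(abs(fit0$lnor / fit0$se), 4)
  # zero variance is fatal
  expect_error(evaluate_score(st, ch, setNames(rep(1, n), st$samples$sample_id),
                              covariates = character(0)), "zero score variance")
})

test_that("evaluation is invariant to affine rescaling of the score", {
  set.seed(99)
  n <- 60
  status <- rep(c("control", "case"), each = 30)
  st <- toy_study(n = n, m = 2, seed = 99,
                  samples = toy_samples(n, status = status))
  ch <- toy_cohort(st$samples$sample_id[1:30], st$samples$sample_id[31:60])
  sc <- setNames(rnorm(n), st$samples$sample_id)
  f1 <- evaluate_score(st, ch, sc, covariates = "age")
  f2 <- evaluate_score(st, ch, 5 + 3 * sc, covariates = "age")
  expect_equal(f1$lnor, f2$lnor, tolerance = 1e-9)
  expect_equal(nagelkerke_r2(f1), nagelkerke_r2(f2), tolerance = 1e-9)
})

test_that("Nagelkerke pseudo-R2 follows its formula and limits", {
  expect_equal(nagelkerke_r2(list(ll_full = -12.3, ll_null = -12.3, n = 50)), 0)
  expect_error(nagelkerke_r2(list(ll_full = -1, ll_null = -2, n = 0)),
               "n = 0")
  # arithmetic oracle on a 10-sample fixture
  y <- c(1, 1, 1, 0, 1, 0, 0, 1, 0, 0)
  x <- c(2.1, 1.6, 1.4, 0.2, 1.9, -0.3, 0.4, 0.9, -0.1, 0.5)
  full <- suppressWarnings(glm(y ~ x, family = binomial()))
  null <- glm(y ~ 1, family = binomial())
  fit <- list(ll_full = as.numeric(logLik(full)),
              ll_null = as.numeric(logLik(null)), n = 10)
  cs <- 1 - exp(2 * (fit$ll_null - fit$ll_full) / 10)
  expect_equal(nagelkerke_r2(fit), cs / (1 - exp(2 * fit$ll_null / 10)))
  # a perfectly predictive score saturates toward 1
  ysep <- rep(c(0, 1), each = 20)
  xsep <- c(rnorm(20, -4), rnorm(20, 4))
  fullsep <- suppressWarnings(glm(ysep ~ xsep, family = binomial()))
  nullsep <- glm(ysep ~ 1, family = binomial())
  expect_gt(nagelkerke_r2(list(ll_full = as.numeric(logLik(fullsep)),
                               ll_null = as.numeric(logLik(nullsep)),
                               n = 40)), 0.95)
})

test_that("liability-scale conversion is exact at zero, monotone and validated", {
  expect_equal(liability_scale_r2(0, 0.1, 0.3), 0)
  r <- vapply(c(0.01, 0.05, 0.1), liability_scale_r2, 0, K = 0.1, P = 0.3)
  expect_true(all(diff(r) > 0))
  expect_error(liability_scale_r2(0.1, 0, 0.5), "in \\(0,1\\)")
  expect_error(liability_scale_r2(0.1, 0.5, 1), "in \\(0,1\\)")
  # without ascertainment at K = P the correction drops the sampling term
  expect_equal(liability_scale_r2(0.02, 0.5, 0.5, ascertained = FALSE),
               liability_scale_r2(0.02, 0.5, 0.5, ascertained = TRUE))
})

test_that("liability conversion agrees with a threshold-model simulation", {
  # brute force: liability y* = sqrt(h2) g + e, dichotomized at the median
  # (K = P = 0.5); the observed-scale R2 times the conversion factor must
  # recover h2
  set.seed(123)
  n <- 50000; h2 <- 0.2
  g <- rnorm(n)
  ystar <- sqrt(h2) * g + rnorm(n, 0, sqrt(1 - h2))
  y <- as.numeric(ystar > 0)
  obs <- cor(y, g)^2
  expect_equal(liability_scale_r2(obs, K = 0.5, P = 0.5), h2,
               tolerance = 0.02)
  # and the factor itself equals K(1-K)/z^2 = pi/2 at K = P = 0.5
  expect_equal(liability_scale_r2(0.1, 0.5, 0.5) / 0.1, pi / 2,
               tolerance = 1e-9)
})
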