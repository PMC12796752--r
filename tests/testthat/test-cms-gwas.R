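test_that("standard regression equals the closed-form least-squares solution", {
  # 5-point worked dataset, hand linear-algebra oracle
  y <- c(1.2, 0.7, 2.9, 2.1, 3.3)
  g <- c(0, 1, 2, 1, 2)
  X <- cbind(1, g)
  oracle <- solve(t(X) %*% X, t(X) %*% y)[2]
  rec <- stdRegression(y, g, snpId = "s1", biomarker = "b1")
  expect_equal(rec$beta, oracle, tolerance = 1e-10)
  # and with confounders against lm()
  set.seed(2)
  C <- data.frame(age = rnorm(60), sex = rbinom(60, 1, 0.5))
  g2 <- rbinom(60, 2, 0.4)
  y2 <- 0.3 * g2 + 0.2 * C$age + rnorm(60)
  ref <- summary(lm(y2 ~ g2 + age + sex, data = C))$coefficients["g2", ]
  rec2 <- stdRegression(y2, g2, C)
  expect_equal(rec2$beta, unname(ref[1]), tolerance = 1e-10)
  expect_equal(rec2$se, unname(ref[2]), tolerance = 1e-10)
  expect_equal(rec2$p, unname(ref[4]), tolerance = 1e-10)
})

test_that("standard regression recovers a strong signal and errors cleanly", {
  set.seed(4)
  g <- rbinom(500, 2, 0.3)
  y <- 2 * g + rnorm(500, sd = 0.01)
  expect_true(abs(stdRegression(y, g)$beta - 2) < 0.01)
  expect_error(stdRegression(y, rep(1, 500)), "monomorphic")
  C <- data.frame(c1 = g, c2 = rnorm(500))   # c1 collinear with g
  expect_error(stdRegression(y, g, C), "collinear.*c1")
})

test_that("null p-values are uniform (type-I error calibrated)", {
  set.seed(8)
  hits <- 0L
  for (i in 1:1000) {
    g <- rbinom(120, 2, 0.3)
    if (var(g) == 0) next
    if (stdRegression(rnorm(120), g)$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 1000, 0.035)
  expect_lte(hits / 1000, 0.065)
})

test_that("candidate covariates obey the variance rule, AIC order and cap", {
  set.seed(10)
  n <- 300L
  y <- rnorm(n)
  vals <- sapply(seq(0.05, 0.6, length.out = 40), function(r)
    r * y + sqrt(1 - r^2) * rnorm(n))
  tooStrong <- 0.95 * y + sqrt(1 - 0.95^2) * rnorm(n)   # R2 ~ 0.9
  v <- cbind(out = y, s = tooStrong, vals)
  colnames(v) <- c("out", "strong", sprintf("c%02d", 1:40))
  panel <- BiomarkerPanel(v)
  mask <- biomarkerCorrelationMask(panel)
  sel <- selectCandidateCovariates("out", panel, mask)
  expect_length(sel, 30L)                 # cap at top 30
  expect_false("strong" %in% sel)        # R2 > 0.70 excluded (also masked)
  expect_false("out" %in% sel)
  # ascending AIC = strongest candidates first
  r2 <- sapply(sel, function(l) summary(lm(v[, "out"] ~ v[, l]))$r.squared)
  expect_true(all(diff(r2) <= 1e-12))
  # empty admissible set
  noneMask <- mask & FALSE
  expect_identical(selectCandidateCovariates("out", panel, noneMask),
                   character(0))
})

test_that("the genotype-association screen removes variant proxies only", {
  set.seed(12)
  removed <- 0L
  for (i in 1:10) {
    g <- rbinom(1000, 2, 0.3)
    proxy <- 0.7 * scale(g)[, 1] + sqrt(1 - 0.49) * rnorm(1000)
    indep <- rnorm(1000)
    panel <- BiomarkerPanel(cbind(proxy = proxy, indep = indep))
    kept <- filterGenotypeAssociatedCovariates(c("proxy", "indep"), g, panel)
    if (!"proxy" %in% kept) removed <- removed + 1L
  }
  expect_gte(removed, 9L)
  # type-I control: independent candidates rarely removed
  dropped <- 0L
  for (i in 1:300) {
    g <- rbinom(300, 2, 0.3)
    panel <- BiomarkerPanel(cbind(a = rnorm(300), b = rnorm(300)))
    kept <- filterGenotypeAssociatedCovariates(c("a", "b"), g, panel)
    if (length(kept) < 2L) dropped <- dropped + 1L
  }
  expect_lte(dropped / 300, 2 * 0.05 + 0.02)
  expect_identical(filterGenotypeAssociatedCovariates(character(0),
                                                      rbinom(50, 2, 0.3),
                                                      NULL), character(0))
})

test_that("CMS reduces to STD with no covariates and shrinks the SE with them", {
  set.seed(14)
  g <- rbinom(400, 2, 0.3)
  y <- 0.2 * g + rnorm(400)
  panel <- BiomarkerPanel(cbind(y = y, c1 = rnorm(400)))
  std <- stdRegression(y, g, snpId = "s", biomarker = "y")
  cms <- cmsRegression(y, g, selectedCovariates = character(0),
                       panel = panel, snpId = "s", biomarker = "y")
  expect_equal(cms[, c("beta", "se", "p", "n")], std[, c("beta", "se", "p", "n")])
  wins <- 0L
  for (i in 1:50) {
    g <- rbinom(800, 2, 0.3)
    shared <- rnorm(800)
    y <- 0.1 * g + shared + rnorm(800)
    panel <- BiomarkerPanel(cbind(y = y, c1 = shared + rnorm(800, sd = 0.3)))
    if (cmsRegression(y, g, selectedCovariates = "c1", panel = panel)$se <
        stdRegression(y, g)$se) wins <- wins + 1L
  }
  expect_gte(wins, 45L)
})

test_that("CMS estimates a planted effect without bias", {
  set.seed(16)
  betas <- numeric(200)
  for (i in 1:200) {
    g <- rbinom(400, 2, 0.3)
    shared <- rnorm(400)
    y <- 0.3 * g + shared + rnorm(400)
    cov1 <- shared + rnorm(400, sd = 0.5)     # independent of g
    panel <- BiomarkerPanel(cbind(y = y, c1 = cov1))
    betas[i] <- cmsRegression(y, g, selectedCovariates = "c1",
                              panel = panel)$beta
  }
  expect_lt(abs(mean(betas) - 0.3), 0.02)
})

test_that("the association scan covers all pairs and respects the mask", {
  cfg <- demoConfig(seed = 21L, nCases = 80L, nControls = 400L)
  cfg@nSnps <- 10L; cfg@nBlocks <- 2L
  cfg@plantedEffects <- plantedEffect(3L, 1L, 0.4)
  co <- simulateCohort(cfg, "control")
  panel <- transformPanel(co@biomarkers)
  tab <- runMGWAS(co@genotypes, panel, co@confounders, method = "CMS")
  expect_equal(nrow(tab), 10L * 12L)
  mask <- biomarkerCorrelationMask(panel)
  for (i in seq_len(nrow(tab))) {
    covs <- strsplit(tab$covariates[i], ",")[[1]]
    bmCovs <- intersect(covs, biomarkerIds(panel))
    expect_false(tab$biomarker[i] %in% bmCovs)
    if (length(bmCovs))
      expect_true(all(mask[tab$biomarker[i], bmCovs]))
  }
  # stored p consistent with beta/se under the t reference
  ok <- !is.na(tab$p)
  dfres <- tab$n - 2L - vapply(tab$covariates, function(s)
    if (!nzchar(s)) 0L else length(strsplit(s, ",")[[1]]), integer(1))
  pRecomp <- 2 * pt(-abs(tab$beta / tab$se), dfres)
  expect_equal(pRecomp[ok], tab$p[ok], tolerance = 1e-6)
})

test_that("swapping allele coding flips beta and leaves se and p unchanged", {
  set.seed(23)
  g <- rbinom(300, 2, 0.4)
  C <- data.frame(age = rnorm(300))
  y <- 0.25 * g + 0.1 * C$age + rnorm(300)
  a <- stdRegression(y, g, C)
  b <- stdRegression(y, 2 - g, C)
  expect_equal(b$beta, -a$beta, tolerance = 1e-12)
  expect_equal(b$se, a$se, tolerance = 1e-12)
  expect_equal(b$p, a$p, tolerance = 1e-12)
})

test_that("genomic inflation follows its definition and null calibration", {
  expect_equal(genomicInflation(rep(0.5, 7)), 1, tolerance = 1e-6)
  set.seed(25)
  p <- runif(10000)
  expect_gt(genomicInflation(p), 0.97)
  expect_lt(genomicInflation(p), 1.03)
  expect_gt(genomicInflation(p / 2), 1)
  expect_error(genomicInflation(numeric(0)), "no p-values")
  expect_error(genomicInflation(c(0.5, 0)), "in \\(0, 1\\]")
})
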