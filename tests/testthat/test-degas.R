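test_that("Z-matrix construction censors, collapses and standardizes", {
  # symmetric z row: the censored cell stays 0 after fill + standardization
  rec <- rbind(zRecords(c(6, -6, 4), se = 0.04, biomarker = "bm1"),
               zRecords(c(5, -4, 6), se = 0.04, biomarker = "bm2"))
  rec$p[3] <- 0.5                      # bm1/snp003 censored by the p filter
  zm <- buildZMatrix(rec, pMax = 0.001, seMax = 0.08)
  W <- zm@W
  expect_equal(ncol(W), 3L)
  expect_equal(unname(W["bm1", "snp003"]), 0)
  expect_equal(rowMeans(W)[["bm1"]], 0, tolerance = 1e-12)
  expect_equal(apply(W, 1, var)[["bm1"]], 1, tolerance = 1e-8)
  # raw z = beta/se before standardization: symmetric pair stays symmetric
  expect_equal(unname(W["bm1", "snp001"]), -unname(W["bm1", "snp002"]))

  # a variant censored in every biomarker drops out entirely
  rec2 <- rbind(zRecords(c(5, 0.1, -6), se = 0.04, biomarker = "bm1"),
                zRecords(c(4, 0.2, 7), se = 0.04, biomarker = "bm2"))
  zm2 <- buildZMatrix(rec2, pMax = 0.001, seMax = 0.08)
  expect_false("snp002" %in% colnames(zm2@W))
  # the se filter censors too
  rec3 <- rbind(zRecords(c(5, -6, 4.5), se = 0.04),
                zRecords(8, se = 0.2, ids = "snp009"))
  zm3 <- buildZMatrix(rec3, pMax = 0.001, seMax = 0.08)
  expect_false("snp009" %in% colnames(zm3@W))
})

test_that("lead-variant collapse keeps one variant per block", {
  rec <- rbind(zRecords(c(6, 8, 5, 9), se = 0.04, biomarker = "bm1"),
               zRecords(c(5, 5, 7, 4), se = 0.04, biomarker = "bm2"))
  bm <- ldBlockMap(chrom = c("chr1", "chr1"), start = c(0, 250),
                   end = c(250, 500), blockId = c("L", "R"))
  zm <- buildZMatrix(rec, blockMap = bm)
  # positions 100,200 in L; 300,400 in R; leads: snp002 (z=8), snp004 (z=9)
  expect_identical(sort(colnames(zm@W)), c("snp002", "snp004"))
})

test_that("truncated SVD matches an independent spectral oracle", {
  set.seed(61)
  # exact recovery at full rank
  A <- matrix(rnorm(8), 4, 2) %*% matrix(rnorm(10), 2, 5)
  d2 <- tsvd(A, 2)
  expect_lt(norm(A - d2@U %*% diag(d2@S) %*% t(d2@V), "F"), 1e-8)
  dI <- tsvd(diag(5), 5)
  expect_equal(dI@S, rep(1, 5))
  # top-5 singular values of a random 20 x 200 matrix vs the spectral
  # oracle sqrt(eigenvalues(W W^T))
  W <- matrix(rnorm(4000), 20, 200)
  d5 <- tsvd(W, 5)
  oracle <- sqrt(sort(eigen(W %*% t(W), symmetric = TRUE,
                            only.values = TRUE)$values,
                      decreasing = TRUE)[1:5])
  expect_equal(d5@S, oracle, tolerance = 1e-8)
  expect_error(tsvd(W, 21), "exceeds")
  # reconstruction error is non-increasing in k
  errs <- sapply(1:8, function(k) {
    dk <- tsvd(W, k)
    norm(W - dk@U %*% diag(dk@S, k) %*% t(dk@V), "F")
  })
  expect_true(all(diff(errs) <= 1e-10))
  # deterministic sign convention
  expect_true(all(apply(d5@U, 2, function(u) u[which.max(abs(u))] > 0)))
})

test_that("scale equivariance: c*W scales S and preserves directions", {
  set.seed(63)
  W <- matrix(rnorm(300), 10, 30)
  a <- tsvd(W, 4)
  b <- tsvd(-2.5 * W, 4)
  expect_equal(b@S, 2.5 * a@S, tolerance = 1e-10)
  expect_equal(abs(b@U), abs(a@U), tolerance = 1e-8)
  expect_equal(contributionScores(b, "variant"),
               contributionScores(a, "variant"), tolerance = 1e-8)
  expect_equal(squaredCosines(b), squaredCosines(a), tolerance = 1e-8)
})

test_that("factor scores, contributions and cosines obey their identities", {
  set.seed(65)
  W <- matrix(rnorm(200), 8, 25)
  d <- tsvd(W, 4)
  FS <- factorScores(d)
  expect_equal(FS, d@U %*% diag(d@S), tolerance = 1e-12)
  # one nonzero singular value -> one nonzero factor-score column
  W1 <- outer(rnorm(6), rnorm(9))
  d1 <- tsvd(W1, 2)
  expect_lt(max(abs(factorScores(d1)[, 2])), 1e-8)
  # contributions sum to 1 per component, on both axes
  for (axis in c("biomarker", "variant"))
    expect_equal(unname(colSums(contributionScores(d, axis))), rep(1, 4),
                 tolerance = 1e-8)
  # a component loading a single biomarker concentrates its contribution
  dDiag <- tsvd(diag(c(3, 2, 1)), 3)
  expect_equal(max(contributionScores(dDiag, "biomarker")[, 1]), 1,
               tolerance = 1e-12)
  expect_equal(factorScores(dDiag)[1, 1], 3, tolerance = 1e-12)
  # squared cosines sum to 1 per biomarker
  expect_equal(unname(rowSums(squaredCosines(d))), rep(1, 8),
               tolerance = 1e-8)
  # worked 2-component example f = (3, 4) -> (0.36, 0.64)
  U <- cbind(c(3, -4) / 5, c(4, 3) / 5)
  hand <- new("DegasDecomposition", U = U, S = c(5, 5), V = diag(2),
              k = 2L, variantInfo = data.frame(snp_id = c("a", "b"),
                                               chrom = "chr1", pos = 1:2))
  expect_equal(unname(squaredCosines(hand)[1, ]), c(0.36, 0.64))
  # equal |factor scores| -> cosines 1/k
  eq <- new("DegasDecomposition", U = cbind(c(1, 1) / sqrt(2),
                                            c(1, -1) / sqrt(2)),
            S = c(1, 1), V = diag(2), k = 2L,
            variantInfo = data.frame(snp_id = c("a", "b"), chrom = "chr1",
                                     pos = 1:2))
  expect_equal(unname(squaredCosines(eq)[1, ]), c(0.5, 0.5))
})

test_that("variance explained follows the singular spectrum", {
  # S = (2, 1), ||W||_F^2 = 5
  U <- qr.Q(qr(matrix(rnorm(9), 3, 3)))[, 1:2]
  V <- qr.Q(qr(matrix(rnorm(16), 4, 4)))[, 1:2]
  W <- U %*% diag(c(2, 1)) %*% t(V)
  d <- tsvd(W, 2)
  ve <- varianceExplained(d, W)
  expect_equal(ve$proportion, c(0.8, 0.2), tolerance = 1e-10)
  expect_equal(ve$cumulative[2], 1, tolerance = 1e-10)
  set.seed(67)
  Wr <- matrix(rnorm(600), 10, 60)
  dr <- tsvd(Wr, 3)
  expect_lt(varianceExplained(dr, Wr)$cumulative[3], 1)
  expect_error(varianceExplained(dr, Wr * 0), "zero matrix")
})

test_that("top contributors are ranked with a partial-sum identity", {
  set.seed(69)
  W <- matrix(rnorm(400), 8, 50)
  d <- tsvd(W, 3)
  top <- topContributors(d, 1, 10)
  expect_equal(nrow(top), 10L)
  expect_true(all(diff(top$score) <= 1e-15))
  cntr <- contributionScores(d, "variant")[, 1]
  names(cntr) <- rownames(d@V)
  expect_equal(sum(top$score), unname(sum(cntr[top$snp_id])),
               tolerance = 1e-12)
  expect_message(all50 <- topContributors(d, 1, 100), "returning all")
  expect_equal(nrow(all50), 50L)
  # BED export: single-base half-open intervals with scores
  fix <- twoClusterRecords(seed = 73)
  db <- tsvd(buildZMatrix(fix$records), 2)
  path <- withr::local_tempfile(fileext = ".bed")
  writeTopContributorsBed(topContributors(db, 1, 5), path)
  bed <- read.table(path, sep = "\t")
  expect_equal(bed[[3]], bed[[2]] + 1)
  expect_equal(nrow(bed), 5L)
})

test_that("planted two-cluster structure is recovered by two components", {
  fix <- twoClusterRecords(seed = 71)
  zm <- buildZMatrix(fix$records, pMax = 0.001, seMax = 0.08)
  d <- tsvd(zm, 2)
  cos2 <- squaredCosines(d)
  argmax <- apply(cos2, 1, which.max)
  # every biomarker's dominant component agrees with its planted cluster
  comp1 <- argmax[fix$bmCluster == 1]
  comp2 <- argmax[fix$bmCluster == 2]
  expect_equal(length(unique(comp1)), 1L)
  expect_equal(length(unique(comp2)), 1L)
  expect_false(unique(comp1) == unique(comp2))
  # >= 90% of each cluster's contribution mass concentrates there
  cntr <- contributionScores(d, "biomarker")
  expect_gt(sum(cntr[fix$bmCluster == 1, unique(comp1)]), 0.9)
  expect_gt(sum(cntr[fix$bmCluster == 2, unique(comp2)]), 0.9)
})
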