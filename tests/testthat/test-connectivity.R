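test_that("pearsonFC matches the sum-formula oracle and handles exact cases", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6)
  fc <- pearsonFC(cbind(x, y))
  expect_equal(fc$r[1, 2], oracle_pearson(x, y), tolerance = 1e-12)
  expect_equal(fc$p[1, 2], oracle_pearson_p(oracle_pearson(x, y), 5),
               tolerance = 1e-12)

  # identical columns and a negated copy
  fc2 <- pearsonFC(cbind(x, x, -x))
  expect_equal(fc2$r[1, 2], 1)
  expect_equal(fc2$r[1, 3], -1)
  expect_true(all(abs(fc2$r - t(fc2$r)) == 0))
  expect_equal(diag(fc2$r), rep(1, 3), ignore_attr = TRUE)

  # random 20 x 5 inputs agree with the oracle to 1e-12
  set.seed(5)
  for (rep in 1:10) {
    m <- matrix(rnorm(100), 20, 5)
    fc3 <- pearsonFC(m)
    for (i in 1:4) for (j in (i + 1):5) {
      expect_equal(fc3$r[i, j], oracle_pearson(m[, i], m[, j]),
                   tolerance = 1e-12)
      expect_equal(fc3$p[i, j],
                   oracle_pearson_p(oracle_pearson(m[, i], m[, j]), 20),
                   tolerance = 1e-12)
    }
  }
})

test_that("zero-variance columns yield r = 0, p = 1 with a warning", {
  m <- cbind(a = rnorm(10), b = rep(2, 10), c = rnorm(10))
  expect_warning(fc <- pearsonFC(m), "zero-variance")
  expect_equal(fc$r[2, c(1, 3)], c(0, 0), ignore_attr = TRUE)
  expect_equal(fc$p[2, c(1, 3)], c(1, 1), ignore_attr = TRUE)
  expect_equal(diag(fc$r), rep(1, 3), ignore_attr = TRUE)
})

test_that("fdrEdges implements BH step-up over the upper triangle", {
  # four edges with p .01/.02/.03/.04 at q = .05: largest k with
  # p_(k) <= k q / m is k = 4, so all pass
  p <- matrix(0, 4, 4)
  p[1, 2] <- 0.01; p[1, 3] <- 0.02; p[1, 4] <- 0.03; p[2, 3] <- 0.04
  p[2, 4] <- 1; p[3, 4] <- 1
  p <- p + t(p)
  # make the remaining two pairs clearly null
  p[2, 4] <- p[4, 2] <- 1; p[3, 4] <- p[4, 3] <- 1
  mask <- fdrEdges(p, q = 0.05)
  ut <- upper.tri(p)
  expect_identical(unname(mask[ut]), oracle_bh(p[ut], 0.05))
  expect_false(any(diag(mask)))
  expect_identical(mask, t(mask))

  # all p = 1 -> empty mask
  p1 <- matrix(1, 5, 5); diag(p1) <- 0
  expect_false(any(fdrEdges(p1, 0.05)))

  # single edge, m = 1
  p2 <- matrix(c(0, 0.04, 0.04, 0), 2, 2)
  expect_true(fdrEdges(p2, 0.05)[1, 2])

  expect_error(fdrEdges(p1, 0), "strictly between")
})

test_that("fdrEdges equals the brute-force BH definition on random p-sets", {
  set.seed(9)
  for (rep in 1:25) {
    n <- sample(3:14, 1)          # up to 91 pairwise tests
    p <- matrix(0, n, n)
    p[upper.tri(p)] <- runif(n * (n - 1) / 2)^sample(1:3, 1)
    p <- p + t(p)
    q <- runif(1, 0.01, 0.3)
    mask <- fdrEdges(p, q)
    expect_identical(unname(mask[upper.tri(mask)]),
                     oracle_bh(p[upper.tri(p)], q))
  }
})

test_that("buildStack assembles the 4-D design with validated slices", {
  s <- small_sim(seed = 21, nSubjects = 3L, nRois = 8L, nTime = 20L,
                 instanceSizes = c(2L, 3L, 2L, 1L))
  stack <- s$stack
  expect_identical(dim(stack@matrices), c(2L, 3L, 8L, 8L))
  expect_identical(conditions(stack), c("cond1", "cond2"))
  expect_identical(subjects(stack), c("sub01", "sub02", "sub03"))
  # condition/subject order from first appearance; slices match pearsonFC
  fc <- pearsonFC(s$sim$series[[1]]@data)
  expect_equal(connMatrix(stack, conditions(s$sim$series[[1]]),
                          subjects(s$sim$series[[1]])), fc$r)

  # 1 x 1 design
  one <- buildStack(s$sim$series[1],
                    combineInstances(s$sim$instances))
  expect_identical(dim(one@matrices), c(1L, 1L, 8L, 8L))

  # duplicate cell and missing cell are rejected
  expect_error(buildStack(c(s$sim$series, s$sim$series[1]),
                          combineInstances(s$sim$instances)),
               "duplicate design cell")
  expect_error(buildStack(s$sim$series[-2],
                          combineInstances(s$sim$instances)),
               "missing cell")
})

test_that("time-series directories and stacks round-trip through TSV", {
  s <- small_sim(seed = 4, nSubjects = 2L, nRois = 6L, nTime = 15L,
                 instanceSizes = c(2L, 2L, 1L, 1L))
  dir <- withr::local_tempdir()
  writeTimeSeriesDir(s$sim$series, file.path(dir, "ts"))
  back <- readTimeSeriesDir(file.path(dir, "ts"))
  expect_length(back, length(s$sim$series))
  key <- function(l) sprintf("%s__%s", conditions(l), subjects(l))
  back <- back[match(vapply(s$sim$series, key, character(1)),
                     vapply(back, key, character(1)))]
  for (i in seq_along(back))
    expect_equal(back[[i]]@data, s$sim$series[[i]]@data, tolerance = 1e-12)

  stack <- s$stack
  saveStack(stack, file.path(dir, "stack"))
  stack2 <- loadStack(file.path(dir, "stack"))
  expect_identical(conditions(stack2), conditions(stack))
  expect_equal(stack2@matrices, stack@matrices, tolerance = 1e-12)
  expect_equal(stack2@pvals, stack@pvals, tolerance = 1e-12)
  expect_equal(roiTable(stack2), roiTable(stack))
})

test_that("every stored slice is symmetric with unit diagonal", {
  s <- small_sim(seed = 31, nSubjects = 3L, nRois = 10L, nTime = 25L,
                 instanceSizes = c(3L, 3L, 2L, 2L))
  for (ci in 1:2) for (si in 1:3) {
    M <- connMatrix(s$stack, ci, si)
    expect_equal(M, t(M))
    expect_equal(diag(M), rep(1, 10), ignore_attr = TRUE)
    expect_true(all(M >= -1 & M <= 1))
  }
})
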