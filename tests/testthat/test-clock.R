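test_that("z-score normalization centers, scales and round-trips", {
  x <- rbind(a = c(0.2, 0.4, 0.6), b = c(0.5, 0.5, 0.5))
  rownames(x) <- c("chr1:1", "chr1:2")
  norm <- normalize_sites(x)
  expect_equal(unname(norm$values[1, ]), c(-1, 0, 1))
  # constant site: scale 1, all zeros after centering
  expect_equal(unname(norm$values[2, ]), c(0, 0, 0))
  expect_equal(unname(norm$scale[2]), 1)

  # invert with the stored constants
  back <- norm$values * norm$scale + norm$center
  expect_equal(max(abs(back - x)), 0, tolerance = 1e-12)

  # reapplying constants to held-out data uses training center/scale
  held <- matrix(c(0.4, 0.5), 2, 1,
                 dimnames = list(c("chr1:1", "chr1:2"), "new"))
  reap <- normalize_sites(held, constants = norm)
  expect_equal(unname(reap$values[, 1]), c(0, 0))

  missing_site <- matrix(0.4, 1, 1, dimnames = list("chr1:1", "new"))
  expect_error(normalize_sites(missing_site, constants = norm), "missing")
})

test_that("unpenalized single-predictor fit equals closed-form OLS", {
  set.seed(31)
  x <- matrix(runif(40, 0.2, 0.8), 1, 40,
              dimnames = list("chr1:10", sprintf("s%d", 1:40)))
  age <- 5 + 20 * (x[1, ] - 0.5) + rnorm(40, 0, 0.5)
  fit <- epiclock(x, age, lambda = 0)
  z <- (x[1, ] - mean(x[1, ])) / sd(x[1, ])
  beta <- bf_ols(cbind(z), age)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-6)
  expect_equal(unname(fit$weights[1]), beta[2], tolerance = 1e-6)
  expect_equal(unname(predict(fit, x)), beta[1] + beta[2] * z,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("full shrinkage yields an intercept-only clock at the age mean", {
  set.seed(32)
  x <- matrix(runif(200), 10, 20)
  rownames(x) <- sprintf("chr1:%d", 1:10)
  colnames(x) <- sprintf("s%d", 1:20)
  age <- runif(20, 1, 20)
  fit <- epiclock(x, age, lambda = 1e6)
  expect_equal(fit$n_nonzero, 0)
  expect_equal(fit$intercept, mean(age))
  expect_equal(unname(predict(fit, x)), rep(mean(age), 20),
               ignore_attr = TRUE)
})

test_that("weight count is non-increasing along the penalty path", {
  set.seed(33)
  x <- matrix(runif(50 * 30), 50, 30)
  rownames(x) <- sprintf("chr1:%d", 1:50)
  colnames(x) <- sprintf("s%d", 1:30)
  age <- 2 + 30 * colMeans(x[1:5, ]) + rnorm(30, 0, 0.5)
  nz <- vapply(c(0.01, 0.05, 0.2, 1, 5),
               function(l) epiclock(x, age, lambda = l)$n_nonzero,
               integer(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("a single noiseless age site is recovered almost perfectly", {
  ages <- seq(1, 20, length.out = 30)
  x <- matrix(0.2 + 0.01 * ages, 1, 30,
              dimnames = list("chr1:5", sprintf("s%d", 1:30)))
  fit <- epiclock(x, ages, lambda = 0.001)
  pred <- predict(fit, x)
  expect_gt(cor(pred, ages), 0.99)
})

test_that("prediction is the stored linear form and checks its sites", {
  model <- structure(list(intercept = 10,
                          weights = c("chr1:1" = 2),
                          center = c("chr1:1" = 0.5),
                          scale = c("chr1:1" = 0.2),
                          alpha = 0.5, lambda = 0.1, n_nonzero = 1L),
                     class = "epiclock")
  # normalized value (0.8 - 0.5) / 0.2 = 1.5 -> 10 + 2 * 1.5 = 13
  x <- matrix(0.8, 1, 1, dimnames = list("chr1:1", "s1"))
  expect_equal(unname(predict(model, x)), 13)
  bad <- matrix(0.8, 1, 1, dimnames = list("chr1:9", "s1"))
  expect_error(predict(model, bad), "weighted site")

  # random-model agreement with an explicit matrix-product oracle
  set.seed(34)
  p <- 6; n <- 9
  w <- rnorm(p); ctr <- runif(p); sc <- runif(p, 0.5, 1.5)
  ids <- sprintf("chr2:%d", 1:p)
  m2 <- structure(list(intercept = 3, weights = setNames(w, ids),
                       center = setNames(ctr, ids),
                       scale = setNames(sc, ids),
                       alpha = 0.5, lambda = 0.1, n_nonzero = p),
                  class = "epiclock")
  xx <- matrix(runif(p * n), p, n, dimnames = list(ids, sprintf("s%d", 1:n)))
  oracle <- 3 + as.numeric(t((xx - ctr) / sc) %*% w)
  expect_equal(unname(predict(m2, xx)), oracle, tolerance = 1e-12)
})

test_that("constant ages produce a warned intercept-only model", {
  x <- matrix(runif(20), 4, 5)
  rownames(x) <- sprintf("chr1:%d", 1:4)
  colnames(x) <- sprintf("s%d", 1:5)
  expect_warning(fit <- epiclock(x, rep(7, 5)), "constant ages")
  expect_equal(fit$intercept, 7)
  expect_equal(fit$n_nonzero, 0)
})

test_that("leave-one-out refits exclude the held-out subject entirely", {
  set.seed(35)
  x <- matrix(runif(20 * 12), 20, 12)
  rownames(x) <- sprintf("chr1:%d", 1:20)
  colnames(x) <- sprintf("s%d", 1:12)
  age <- runif(12, 1, 20)
  cv1 <- loocv_clock(x, age, lambda = 0.3, seed = 1)
  # changing the held-out subject's recorded age cannot move its estimate
  age2 <- age
  age2[5] <- age2[5] + 100
  cv2 <- loocv_clock(x, age2, lambda = 0.3, seed = 1)
  expect_equal(cv2$epigenetic_age[5], cv1$epigenetic_age[5])

  # explicit leakage check: refit without subject 5 by hand
  fit <- epiclock(x[, -5], age[-5], lambda = 0.3)
  expect_equal(unname(predict(fit, x[, 5, drop = FALSE])),
               cv1$epigenetic_age[5])

  # full-shrinkage regime at n = 3: each estimate is the other two's mean
  cv3 <- loocv_clock(x[, 1:3], age[1:3], lambda = 1e6)
  expect_equal(cv3$epigenetic_age,
               vapply(1:3, function(i) mean(age[1:3][-i]), numeric(1)))
})

test_that("clock serialization round-trips and validates its format", {
  set.seed(36)
  x <- matrix(runif(30 * 25), 30, 25)
  rownames(x) <- sprintf("chr%d:%d", rep(1:3, 10), 1:30)
  colnames(x) <- sprintf("s%d", 1:25)
  age <- 1 + 25 * colMeans(x[1:4, ]) + rnorm(25, 0, 0.3)
  fit <- epiclock(x, age, lambda = 0.05)
  expect_gt(fit$n_nonzero, 0)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clock(fit, path)
  back <- read_clock(path)
  expect_equal(back$intercept, fit$intercept)
  expect_equal(back$weights, fit$weights)
  expect_equal(predict(back, x), predict(fit, x), tolerance = 1e-12)

  # empty-weight model round-trips
  empty <- epiclock(x, age, lambda = 1e6)
  write_clock(empty, path)
  back2 <- read_clock(path)
  expect_equal(back2$n_nonzero, 0)
  expect_equal(back2$intercept, mean(age))

  # hand-written two-site fixture
  writeLines(c("#epiage_clock\tversion=1",
               "#intercept\t4.5", "#alpha\t0.5", "#lambda\t0.02",
               "#seed\tNA",
               "site\tweight\tcenter\tscale",
               "chr1:100\t1.25\t0.4\t0.1",
               "chr2:7\t-0.5\t0.6\t0.2"), path)
  hand <- read_clock(path)
  expect_equal(hand$intercept, 4.5)
  expect_equal(hand$weights, c("chr1:100" = 1.25, "chr2:7" = -0.5))

  writeLines(c("#epiage_clock\tversion=99",
               "site\tweight\tcenter\tscale"), path)
  expect_error(read_clock(path), "version")
  writeLines("not a clock", path)
  expect_error(read_clock(path), "not a clock file")
})
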