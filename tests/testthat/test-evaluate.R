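test_that("the expected additive surface is standardized and symmetric", {
  E <- expectedMatrix()
  expect_equal(E[1, 1], 0)
  expect_equal(E[8, 8], 1)
  expect_equal(E, t(E), ignore_attr = TRUE)
  expect_true(all(diff(diag(E)) > 0))
})

test_that("observed surfaces are cell means rescaled to [0, 1]", {
  df <- data.frame(p_bin = c(1, 1, 3, 8), s_bin = c(1, 1, 5, 8))
  risk <- c(0.2, 0.3, 0.45, 0.7)
  O <- observedMatrix(risk, df)
  expect_equal(O[1, 1], 0)            # min cell (mean 0.25)
  expect_equal(O[8, 8], 1)            # max cell
  expect_equal(O[3, 5], (0.45 - 0.25) / (0.7 - 0.25))
  expect_equal(sum(!is.na(O)), 3)
  expect_equal(attr(O, "counts")[1, 1], 2)
  # brute-force group means
  m <- matrix(NA_real_, 8, 8)
  for (i in seq_len(nrow(df)))
    m[df$p_bin[i], df$s_bin[i]] <- mean(risk[df$p_bin == df$p_bin[i] &
                                             df$s_bin == df$s_bin[i]])
  m <- (m - min(m, na.rm = TRUE)) / diff(range(m, na.rm = TRUE))
  expect_equal(unname(unclass(O))[!is.na(m)], m[!is.na(m)])
  # constant surface: all zeros, flagged
  Oc <- observedMatrix(rep(0.4, 4), df)
  expect_true(attr(Oc, "degenerate"))
  expect_equal(unique(as.vector(Oc[!is.na(Oc)])), 0)
})

test_that("Frobenius distance equals the elementwise sum of squares", {
  E <- expectedMatrix()
  expect_equal(frobeniusDistance(E, E), 0)
  expect_equal(frobeniusDistance(matrix(1, 8, 8), matrix(0, 8, 8)), 8)
  withr::local_seed(5)
  for (i in 1:10) {
    A <- matrix(runif(64), 8); B <- matrix(runif(64), 8)
    expect_equal(frobeniusDistance(A, B), sqrt(sum((A - B)^2)))
    # definition via trace(M M*)
    M <- A - B
    expect_equal(frobeniusDistance(A, B), sqrt(sum(diag(M %*% t(M)))))
  }
  expect_error(frobeniusDistance(matrix(0, 2, 2), matrix(0, 3, 3)))
})

test_that("similarity is anchored at identical (1) and random-average (0)", {
  expect_equal(similarityScore(0, seed = 7), 1)
  s <- similarityScore(2, seed = 7)
  mean_random <- 2 / (1 - s)                    # invert the linear map
  expect_equal(similarityScore(mean_random, seed = 7), 0, tolerance = 1e-12)
  expect_equal(similarityScore(mean_random / 2, seed = 7), 0.5,
               tolerance = 1e-12)
  # strictly decreasing in the observed distance
  expect_gt(similarityScore(1, seed = 7), similarityScore(1.5, seed = 7))
})

test_that("an exactly additive risk pattern scores similarity near 1", {
  d <- buildDesign("sPSA", "additive", n_per_cell = 10L, seed = 2L)
  df <- designScores(d)
  risk <- (df$P + df$S - 2) / 4
  O <- observedMatrix(risk, d)
  expect_gt(similarityScore(O, seed = 3), 0.9)
})

test_that("LMG shares sum to R2 and match closed forms", {
  withr::local_seed(31)
  # single predictor: share equals the model R2
  x <- matrix(rnorm(100), dimnames = list(NULL, "a"))
  y <- 2 * x[, 1] + rnorm(100)
  li <- relativeImportance(x, y)
  expect_equal(unname(li$shares), li$R2)
  expect_equal(li$R2, summary(lm(y ~ x))$r.squared)
  # orthogonal predictors: shares equal the marginal R2s
  # exactly orthogonal, mean-centered predictors
  X <- qr.Q(qr(scale(matrix(rnorm(200 * 3), 200), scale = FALSE)))[, 1:3]
  colnames(X) <- letters[1:3]
  y <- X %*% c(1, 2, 3) + rnorm(200, sd = 0.5)
  li <- relativeImportance(X, y)
  marg <- vapply(1:3, function(j) summary(lm(y ~ X[, j]))$r.squared,
                 numeric(1))
  expect_equal(unname(li$shares), marg, tolerance = 1e-8)
  expect_equal(sum(li$shares), li$R2, tolerance = 1e-10)
})

test_that("LMG matches explicit ordering enumeration on 4 predictors", {
  withr::local_seed(13)
  n <- 80
  X <- matrix(rnorm(n * 4), n, dimnames = list(NULL, letters[1:4]))
  X[, 2] <- X[, 1] * 0.6 + X[, 2] * 0.8          # correlated pair
  y <- X %*% c(1, 0.5, -0.7, 0.2) + rnorm(n)
  r2 <- function(cols) if (length(cols) == 0) 0 else
    summary(lm(y ~ X[, cols, drop = FALSE]))$r.squared
  perms <- expand.grid(rep(list(1:4), 4))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  shares <- numeric(4)
  for (i in seq_len(nrow(perms))) {
    ord <- as.integer(perms[i, ])
    for (k in seq_along(ord))
      shares[ord[k]] <- shares[ord[k]] +
        r2(ord[seq_len(k)]) - r2(ord[seq_len(k - 1)])
  }
  shares <- shares / nrow(perms)
  li <- relativeImportance(X, y)
  expect_equal(unname(li$shares), shares, tolerance = 1e-8)
  expect_true(all(li$shares >= 0))
  expect_error(relativeImportance(cbind(X, e = 1), y), "constant")
})

test_that("interaction grids are direct group means with infeasible gaps", {
  df <- data.frame(A = c(1, 1, 2, 3, 3), B = c(1, 1, 2, 3, 3))
  risk <- c(0.1, 0.3, 0.5, 0.8, 0.6)
  g <- interactionGrid(risk, df, "A", "B")
  expect_equal(g[1, 1], 0.2)
  expect_equal(g[3, 3], 0.7)
  expect_true(is.na(g[1, 3]))
  expect_equal(attr(g, "counts")[2, 2], 1)
  expect_equal(interactionGrid(rep(0.5, 5), df, "A", "B")[1, 1], 0.5)
})

test_that("classification statistics follow the confusion-matrix identities", {
  perfect <- classificationStats(c(2, 3, 4), c(0.1, 0.5, 0.9))
  expect_equal(perfect$accuracy, 1)
  expect_equal(unname(perfect$sensitivity), c(1, 1, 1))
  # constructed counts [[10,0,0],[0,5,5],[0,5,5]]
  pred <- factor(rep(c("Low", "Medium", "Medium", "High", "High"),
                     c(10, 5, 5, 5, 5)), levels = c("Low", "Medium", "High"))
  true_risk <- rep(c(0.1, 0.5, 0.9, 0.5, 0.9), c(10, 5, 5, 5, 5))
  cs <- classificationStats(pred, true_risk)
  expect_equal(cs$accuracy, 20 / 30)
  expect_equal(unname(cs$sensitivity["Medium"]), 5 / 10)
  expect_equal(sum(cs$counts), 30)
  # boundary values go to the lower risk category
  b <- classificationStats(factor("Low", levels = c("Low", "Medium", "High")),
                           0.33)
  expect_equal(b$counts["Low", "Low"], 1L)
  # total conserved under category relabeling
  expect_equal(sum(classificationStats(rev(pred), true_risk)$counts), 30)
})

test_that("subset re-scoring reduces to the full scoring on all attributes", {
  d <- buildDesign("sPSA", "additive", n_per_cell = 2L, seed = 9L)
  df <- designScores(d)
  withr::local_seed(1)
  risk <- runif(nrow(df))
  full <- subsetRescoring(d, risk, psaAttributes("sPSA")$name)
  direct <- classificationStats(df$V, risk)
  expect_equal(full$counts, direct$counts)
  expect_equal(full$V, df$V)
  # one attribute per axis still spans the full V range in principle
  one <- subsetRescoring(d, risk, c("Steepness", "Selectivity"))
  expect_true(all(one$V >= sqrt(2) - 1e-9 & one$V <= sqrt(18) + 1e-9))
  expect_error(subsetRescoring(d, risk, c("Steepness", "MaxAge")), "axis")
})

test_that("leaner scoring systems of 3 to 5 attributes can be evaluated", {
  de <- buildDesign("ePSA", "additive", n_per_cell = 1L, seed = 21L)
  withr::local_seed(2)
  risk <- runif(nrow(designScores(de)))
  s3 <- c("RateIncrease", "Selectivity", "Discard")
  subsets <- list(s3, c(s3, "Steepness"), c(s3, "Steepness", "Encounterability"))
  for (sub in subsets) {
    cs <- subsetRescoring(de, risk, sub)
    expect_equal(cs$n, nrow(designScores(de)))
    expect_true(all(cs$V >= sqrt(2) - 1e-9 & cs$V <= sqrt(18) + 1e-9))
    expect_identical(cs$attributes, sub)
  }
})
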