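test_that("productivity and susceptibility aggregation follow their means", {
  expect_equal(aggregateProductivity(c(1, 1, 1, 1, 1)), 1)
  expect_equal(aggregateProductivity(rep(3, 7)), 3)
  expect_equal(aggregateProductivity(c(1, 2, 3, 2, 1)), 1.8)
  expect_equal(aggregateSusceptibility(c(2, 2, 2, 2), "additive"), 2)
  expect_equal(aggregateSusceptibility(c(1, 1, 1, 1), "multiplicative"), 1)
  expect_equal(aggregateSusceptibility(c(1, 3, 3, 3), "multiplicative"),
               27^(1 / 4), tolerance = 1e-12)
  expect_error(aggregateProductivity(numeric(0)))
  expect_error(aggregateSusceptibility(c(1, 4), "additive"))
})

test_that("additive aggregation dominates multiplicative (AM-GM)", {
  withr::local_seed(42)
  for (i in 1:50) {
    sc <- sample(1:3, sample(2:12, 1), replace = TRUE)
    am <- aggregateSusceptibility(sc, "additive")
    gm <- aggregateSusceptibility(sc, "multiplicative")
    expect_gte(am, gm)
    if (length(unique(sc)) > 1) expect_gt(am, gm) else expect_equal(am, gm)
  }
})

test_that("vulnerability spans 1.41 to 4.24 and increases in both scores", {
  expect_equal(round(vulnerability(1, 1), 2), 1.41)
  expect_equal(round(vulnerability(3, 3), 2), 4.24)
  expect_equal(vulnerability(3, 1, formula = "reversed"), 0)
  expect_error(vulnerability(0.5, 2))
  g <- seq(1, 3, by = 0.25)
  V <- outer(g, g, vulnerability)
  expect_true(all(diff(V) > 0))        # increasing in P
  expect_true(all(t(diff(t(V))) > 0))  # increasing in S
})

test_that("vulnerability categories partition the score range", {
  expect_equal(as.character(classifyVulnerability(c(2, 3, 4))),
               c("Low", "Medium", "High"))
  # boundary values fall in the lower category
  expect_equal(as.character(classifyVulnerability(c(2.64, 3.18))),
               c("Low", "Medium"))
  v <- seq(sqrt(2), sqrt(18), length.out = 400)
  tab <- table(classifyVulnerability(v))
  expect_true(all(tab > 0))
})

test_that("Monte-Carlo terciles match the uniform-density integration oracle", {
  th <- tercileThresholds(2e5, seed = 11)
  exact <- tercileOracle(c(1 / 3, 2 / 3))
  expect_equal(unname(th), exact, tolerance = 0.01)
  expect_true(all(th > sqrt(2) & th < sqrt(18)))
  expect_identical(th, tercileThresholds(2e5, seed = 11))  # reproducible
})

test_that("batch scoring appends P, S, V, category and round-trips CSV", {
  sc <- enumerateScores("sPSA")[c(1, 100, 19683), ]
  out <- scorePsa(sc, "sPSA", "multiplicative")
  expect_equal(out$P, unname(rowMeans(sc[, 1:5])))
  expect_equal(out$V, sqrt(out$P^2 + out$S^2))
  f <- tempfile(fileext = ".csv")
  scorePsa(sc, "sPSA", file = f)
  rt <- utils::read.csv(f)
  expect_equal(rt$V, scorePsa(sc, "sPSA")$V, tolerance = 1e-12)
  # missing-score policies
  sc$Discard[1] <- NA
  expect_error(scorePsa(sc, "sPSA"))
  hi <- scorePsa(sc, "sPSA", missing = "high")
  dr <- scorePsa(sc, "sPSA", missing = "drop")
  expect_gte(hi$S[1], dr$S[1])
})

test_that("attribute registry obeys its structural invariants", {
  for (variant in c("sPSA", "ePSA")) {
    atts <- psaAttributes(variant)
    expect_equal(nrow(atts), if (variant == "sPSA") 9L else 12L)
    expect_equal(sum(atts$axis == "productivity"),
                 if (variant == "sPSA") 5L else 7L)
    # intervals tile the sampling domain
    for (i in seq_len(nrow(atts))) {
      if (atts$composite[i]) next
      b <- sort(unlist(atts[i, c("lo1", "hi1", "lo2", "hi2", "lo3", "hi3")]))
      expect_equal(length(unique(round(b, 10))), 4L)
      expect_true(all(is.finite(b)))
    }
  }
  expect_equal(attributeInterval("Steepness", 3), c(0.21, 0.4))
  expect_equal(attributeInterval("Discard", 1, what = "mortality"),
               c(0, 0.25))
  expect_error(attributeInterval("Depletion", 1, "sPSA"))
})

test_that("a modified registry can be written, re-read and used", {
  reg <- readAttributeRegistry(system.file("extdata", "attributes.yaml",
                                           package = "psasim"))
  f <- tempfile(fileext = ".yaml")
  writeAttributeRegistry(reg, f)
  reg2 <- readAttributeRegistry(f)
  expect_equal(psaAttributes("ePSA", reg2), psaAttributes("ePSA", reg))
  # invalid: overlapping intervals rejected
  reg$attributes[[1]]$ranges[["2"]] <- c(4, 15)
  expect_error(writeAttributeRegistry(reg, f), "tile")
})
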