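test_that("regime classification applies the boundary rule", {
  tb <- tibble::tibble(r_realized = c(0.01, 0.039, 0.2))
  out <- classify_regimes(tb)
  expect_equal(as.character(out$regime), c("low", "high", "high"))
  all_low <- classify_regimes(tibble::tibble(r_realized = c(0.001, 0.01)))
  expect_true(all(all_low$regime == "low"))
  expect_error(classify_regimes(tb[0, ]), "empty")
})

test_that("mixture antimode recovers a cut between planted modes", {
  set.seed(33)
  r <- c(10^rnorm(300, log10(0.01), 0.15), 10^rnorm(300, log10(0.2), 0.15))
  cut <- mixture_antimode(r)
  expect_gt(cut, 0.02)
  expect_lt(cut, 0.12)
  out <- classify_regimes(tibble::tibble(r_realized = r), method = "mixture")
  expect_equal(attr(out, "threshold"), cut)
})

test_that("BP-BR scaling recovers exact and noisy power laws", {
  BR <- 10^seq(-3, 0, length.out = 50)
  exact <- tibble::tibble(BP = BR^0.6, BR = BR)
  fit <- bp_br_scaling(exact)
  g <- suppressWarnings(glance(fit))
  expect_equal(g$slope, 0.6, tolerance = 1e-10)
  expect_lt(g$conf_high - g$conf_low, 1e-8)
  # proportional data (noisy identity) accepts unity
  set.seed(34)
  ident <- tibble::tibble(BR = BR, BP = BR * 10^rnorm(50, 0, 0.05))
  g2 <- glance(bp_br_scaling(ident))
  expect_equal(g2$slope, 1, tolerance = 0.05)
  expect_gt(g2$p_vs_null, 0.05)
  expect_lt(g2$conf_low, 1); expect_gt(g2$conf_high, 1)
  # noisy Monte-Carlo construction
  set.seed(35)
  lBR <- runif(400, -3, 0)
  noisy <- tibble::tibble(BR = 10^lBR, BP = 10^(0.6 * lBR + rnorm(400, 0, 0.1)))
  g3 <- glance(bp_br_scaling(noisy))
  expect_gt(0.6, g3$conf_low)
  expect_lt(0.6, g3$conf_high)
  expect_lt(g3$p_vs_null, 1e-6) # slope clearly below one
  # non-positive rows are filtered with a warning
  bad <- rbind(noisy, tibble::tibble(BR = -1, BP = 1))
  expect_warning(bp_br_scaling(bad), "non-positive")
})

test_that("rate-yield regression works on class medians", {
  tb <- tibble::tibble(
    class = rep(c("sugar", "amino_acid", "organic_acid", "fatty_acid",
                  "nucleotide"), each = 4),
    r_realized = rep(c(0.4, 0.3, 0.2, 0.1, 0.05), each = 4) +
      rep(c(-0.001, 0, 0.001, 0), 5),
    CUE = rep(c(0.2, 0.3, 0.4, 0.5, 0.6), each = 4)
  )
  g <- suppressWarnings(glance(rate_yield_regression(tb)))
  expect_lt(g$slope, 0)
  expect_gt(g$r_squared, 0.95)
  # constant CUE: zero slope
  tb$CUE <- 0.5
  g2 <- suppressWarnings(glance(rate_yield_regression(tb)))
  expect_equal(g2$slope, 0, tolerance = 1e-12)
  expect_equal(g2$r_squared, 0)
})

test_that("preference differences against a brute-force oracle", {
  set.seed(37)
  led <- tidyr::expand_grid(isolate = sprintf("i%02d", 1:10),
                            substrate = letters[1:6])
  led$class <- "sugar"
  led$fraction <- runif(nrow(led))
  led$response_group <- rep(c("positive", "negative"), each = 30)
  pd <- preference_differences(led)
  # brute force means
  for (s in letters[1:6]) {
    pos <- mean(led$fraction[led$substrate == s &
                               led$response_group == "positive"]) * 100
    neg <- mean(led$fraction[led$substrate == s &
                               led$response_group == "negative"]) * 100
    expect_equal(pd$delta_pp[pd$substrate == s], pos - neg,
                 tolerance = 1e-12)
  }
  expect_true(all(pd$positive >= 0 & pd$positive <= 100))
  # identical groups: all differences zero
  led2 <- led
  led2$fraction <- rep(led$fraction[led$response_group == "positive"], 2)
  pd2 <- preference_differences(led2)
  expect_true(all(abs(pd2$delta_pp) < 1e-12))
  # complete separation gives 100 points
  led3 <- led
  led3$fraction <- ifelse(led3$response_group == "positive", 1, 0)
  pd3 <- preference_differences(led3)
  expect_true(all(pd3$delta_pp == 100))
  expect_error(preference_differences(led, groups = c("positive", "zzz")),
               "no consumers")
})

test_that("Levins index spans specialist to generalist", {
  expect_equal(levins_index(rep(1 / 82, 82)), 82)
  expect_equal(levins_index(c(1, 0, 0)), 1)
  expect_equal(levins_index(c(0.5, 0.5, 0)), 2)
  expect_true(is.na(levins_index(c(0, 0))))
  expect_error(levins_index(c(-0.1, 1)), "non-negative")
})

test_that("variance explained recovers planted structure", {
  set.seed(39)
  n <- 400
  tb <- tibble::tibble(rrn_copies = sample(1:15, n, TRUE),
                       genome_size = runif(n, 2e6, 1e7))
  # exact linear function: r^2 = 1
  tb$r_realized <- 0.02 * tb$rrn_copies + 0.1
  expect_equal(suppressWarnings(variance_explained(tb))$r_squared, 1,
               tolerance = 1e-12)
  # independent response: r^2 near 0
  tb$r_realized <- rnorm(n)
  expect_lt(variance_explained(tb)$r_squared, 0.05)
  # planted r^2 = 0.3, averaged over replicates to tame sampling noise
  r2s <- replicate(20, {
    x <- scale(tb$rrn_copies)[, 1]
    tb$r_realized <- sqrt(0.3) * x + sqrt(0.7) * rnorm(n)
    variance_explained(tb)$r_squared
  })
  expect_equal(mean(r2s), 0.3, tolerance = 0.05)
})

test_that("summary operations are pure functions of their inputs", {
  set.seed(41)
  tb <- tibble::tibble(BP = 10^runif(50, -3, 0))
  tb$BR <- tb$BP^1.4 * 10^rnorm(50, 0, 0.02)
  g1 <- glance(bp_br_scaling(tb))
  g2 <- glance(bp_br_scaling(tb))
  expect_identical(g1, g2)
  expect_identical(levins_index(c(0.2, 0.8)), levins_index(c(0.2, 0.8)))
})
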