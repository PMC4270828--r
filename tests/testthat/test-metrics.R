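test_that("entropy handles the standard cases in bits", {
  expect_equal(shannon_entropy(c(1000, 1000)), 1)
  expect_equal(shannon_entropy(2000), 0)
  expect_equal(shannon_entropy(c(750, 250)), -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
  expect_error(shannon_entropy(c(0, 0)), "positive total")
  expect_error(shannon_entropy(c(-1, 2)), "non-negative")
})

test_that("plug-in mutual information matches the brute-force double loop", {
  withr::with_seed(21, {
    for (i in 1:10) {
      n <- 80
      d <- tibble::tibble(
        A = sample(0:2, n, TRUE),
        B = sample(0:1, n, TRUE),
        Class = sample(0:1, n, TRUE)
      )
      expect_equal(mutual_information(d, "A"), brute_mi(d$A, d$Class),
                   tolerance = 1e-12)
      expect_equal(
        mutual_information(d, c("A", "B")),
        brute_mi(paste(d$A, d$B), d$Class),
        tolerance = 1e-12
      )
      # bounds: 0 <= I(X;Y) <= min(H(X), H(Y))
      hx <- shannon_entropy(table(d$A))
      hy <- shannon_entropy(table(d$Class))
      expect_gte(mutual_information(d, "A") + 1e-12, 0)
      expect_lte(mutual_information(d, "A"), min(hx, hy) + 1e-12)
    }
  })
})

test_that("the parity fixture is pure three-way epistasis: 1 bit of synergy, no lower-order signal", {
  d <- parity_dataset()
  ig <- interaction_information(d, c("TF1", "TF2", "enhancer"))
  expect_equal(unname(ig$main_ig), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(ig$pairwise_ig), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(ig$threeway_ig, 1, tolerance = 1e-12)
  expect_length(ig$degenerate, 0)
  td <- tidy(ig)
  expect_equal(nrow(td), 7)
  expect_equal(td$ig[td$order == 3], 1, tolerance = 1e-12)
})

test_that("a class label independent of the loci carries no exact information", {
  # every genotype combination paired with both class labels equally often
  g <- parity_dataset()[, 1:3]
  d <- dplyr::bind_rows(g, g)
  d$Class <- rep(0:1, each = nrow(g))
  ig <- interaction_information(d, c("TF1", "TF2", "enhancer"))
  expect_equal(unname(ig$main_ig), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(ig$threeway_ig, 0, tolerance = 1e-12)
})

test_that("degenerate loci are flagged but still computed", {
  d <- parity_dataset()
  d$TF2 <- 1L
  ig <- interaction_information(d, c("TF1", "TF2", "enhancer"))
  expect_equal(ig$degenerate, "TF2")
  expect_true(is.finite(ig$threeway_ig))
})

test_that("MDR separates a perfectly patterned dataset and reports its cells", {
  fit <- mdr(parity_dataset(), c("TF1", "TF2", "enhancer"))
  expect_equal(fit$accuracy, 1)
  expect_equal(nrow(fit$cells), 27)
  expect_equal(fit$threshold_ratio, 1)
  # each cell is pure, so high-risk cells are exactly the case cells
  expect_equal(fit$cells$risk == "high", fit$cells$n_cases > 0)
  expect_equal(glance(fit)$n, 64)
  # prediction recovers the class on the training data
  expect_equal(predict(fit, parity_dataset()), parity_dataset()$Class)
  # unseen genotype combinations are low-risk
  unseen <- tibble::tibble(TF1 = 9L, TF2 = 9L, enhancer = 9L)
  expect_equal(predict(fit, unseen), 0L)
})

test_that("MDR training accuracy is at least the majority-class rate, ~0.5 on permuted labels", {
  d <- sim_dataset(catalog_model(1), 250, 250, pop = 10000, seed = 31)
  accs <- withr::with_seed(32, vapply(1:100, function(i) {
    dp <- d
    dp$Class <- sample(dp$Class)
    mdr(dp, c("TF1", "TF2", "enhancer"))$accuracy
  }, numeric(1)))
  expect_true(all(accs >= 0.5)) # training-accuracy lower bound, balanced data
  # no systematic signal: only the small-cell overfitting bias above 0.5
  expect_lt(mean(accs), 0.62)
})

test_that("tie cells (ratio equal to overall) are labeled high-risk and empty cells low-risk", {
  d <- tibble::tibble(
    A = c(0, 0, 1, 1, 2, 2),
    Class = c(1, 0, 1, 0, 1, 0)
  )
  fit <- mdr(d, "A")
  expect_true(all(fit$cells$risk == "high")) # every cell ties the 1:1 ratio
  expect_equal(fit$accuracy, 0.5)
  expect_equal(predict(fit, tibble::tibble(A = 3)), 0L)
})

test_that("the standard permutation test flags association and uses the add-one estimator", {
  p <- mdr_permutation_test(parity_dataset(), c("TF1", "TF2", "enhancer"),
                            n_perm = 199, seed = 41)
  expect_equal(p$p.value, 1 / 200)
  expect_equal(p$statistic, 1)
  # n_perm = 1 with observed above the permuted value gives (1+0)/2
  d <- parity_dataset()
  p1 <- mdr_permutation_test(d, c("TF1", "TF2", "enhancer"), n_perm = 1,
                             seed = 42)
  expect_equal(p1$p.value, 0.5)
})

test_that("permutation p-values are approximately uniform under the null", {
  null_d <- make_fixtures(seed = 77, n_null = 120)$null
  pvals <- withr::with_seed(43, vapply(1:200, function(i) {
    d <- null_d
    d$Class <- sample(d$Class)
    mdr_permutation_test(d, c("TF1", "TF2", "enhancer"), n_perm = 59)$p.value
  }, numeric(1)))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the explicit epistasis test preserves per-class genotype counts and kills interaction signal", {
  d <- parity_dataset()
  p <- mdr_permutation_test(d, c("TF1", "TF2", "enhancer"), n_perm = 199,
                            type = "epistasis", seed = 44)
  expect_equal(p$p.value, 1 / 200) # parity signal is purely interactive
  # main-effect-only data: association survives the shuffle, test stays null
  main_d <- withr::with_seed(45, {
    tf1 <- sample(0:2, 600, TRUE, prob = c(0.25, 0.5, 0.25))
    tibble::tibble(
      TF1 = tf1,
      TF2 = sample(0:2, 600, TRUE, prob = c(0.25, 0.5, 0.25)),
      enhancer = sample(0:2, 600, TRUE, prob = c(0.25, 0.5, 0.25)),
      Class = rbinom(600, 1, c(0.2, 0.5, 0.8)[tf1 + 1])
    )
  })
  p_std <- mdr_permutation_test(main_d, c("TF1", "TF2", "enhancer"),
                                n_perm = 199, seed = 46)
  p_epi <- mdr_permutation_test(main_d, c("TF1", "TF2", "enhancer"),
                                n_perm = 199, type = "epistasis", seed = 47)
  expect_lte(p_std$p.value, 0.005) # strong marginal association
  expect_gt(p_epi$p.value, 0.05) # but no epistasis
})
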