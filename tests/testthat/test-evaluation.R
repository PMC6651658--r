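# Metrics: kappa, sensitivities, cross-validation, Shannon entropy.

test_that("perfect prediction scores kappa 1 and full sensitivity", {
  lv <- activity_levels()
  truth <- sample(rep(lv, times = 5))
  sc <- score(truth, truth)
  expect_equal(sc$kappa, 1)
  expect_equal(sc$total_sensitivity, 100)
  expect_equal(unname(diag(sc$confusion)), rep(5L, 6))
})

test_that("kappa matches the hand-computed two-class contingency", {
  truth <- c(rep("standing", 50), rep("sedentary", 50))
  pred <- c(rep("standing", 40), rep("sedentary", 10),
            rep("standing", 20), rep("sedentary", 30))
  sc <- score(truth, pred, levels = c("standing", "sedentary"))
  # TP=40 FN=10 FP=20 TN=30: po=0.7, pe=0.5
  expect_equal(sc$kappa, 0.4)
  expect_equal(sc$per_class$sensitivity, c(80, 60))
  expect_equal(sc$per_class$specificity, c(60, 80))
})

test_that("kappa agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(701)
  lv <- activity_levels()
  truth <- sample(lv, 500, replace = TRUE, prob = c(3, 3, 2, 1, 1, 1) / 11)
  pred <- ifelse(stats::runif(500) < 0.7, truth, sample(lv, 500, replace = TRUE))
  sc <- score(truth, pred)
  ext <- e1071::classAgreement(sc$confusion)
  expect_equal(sc$kappa, ext$kappa, tolerance = 1e-12)
})

test_that("chance-level prediction gives kappa near zero", {
  set.seed(702)
  lv <- activity_levels()
  truth <- sample(lv, 1e5, replace = TRUE)
  pred <- sample(lv, 1e5, replace = TRUE)
  expect_lt(abs(score(truth, pred)$kappa), 0.01)
})

test_that("kappa is invariant under a simultaneous relabelling", {
  set.seed(703)
  lv <- activity_levels()
  truth <- sample(lv, 300, replace = TRUE)
  pred <- ifelse(stats::runif(300) < 0.6, truth, sample(lv, 300, replace = TRUE))
  perm <- sample(lv)
  truth2 <- perm[match(truth, lv)]
  pred2 <- perm[match(pred, lv)]
  expect_equal(score(truth2, pred2)$kappa, score(truth, pred)$kappa)
})

test_that("degenerate inputs are rejected", {
  expect_error(score(rep("standing", 10), rep("standing", 10)), "two classes")
  expect_error(score(c("standing", "walking"), "standing"), "length")
})

cv_table <- function(n_per = 25, seed = 704, sep = TRUE) {
  set.seed(seed)
  lv <- activity_levels()
  lab <- rep(lv, each = n_per)
  n <- length(lab)
  centers <- setNames(seq(0, 50,, 6), lv)
  f <- tibble::tibble(
    window_start = seq_len(n) * 1.25,
    f1 = 0, f2 = 0, f3 = 0, f4 = 0,
    f5 = centers[lab] + stats::rnorm(n, 0, if (sep) 0.5 else 30),
    f6 = 0, f7 = 0, f8 = 0, cold_start = FALSE,
    label = factor(lab, levels = lv)
  )
  # give the tree usable structure on all nodes
  f$f6[lab == "sedentary"] <- 1.5
  f$f5[lab %in% c("sedentary", "standing")] <- stats::rnorm(2 * n_per, 0, 0.05)
  f$f7[lab == "postural_transition"] <- 0.6
  f$f8[lab == "walking_downstairs"] <- -0.3
  f$f8[lab == "walking_upstairs"] <- 0.3
  f$f5[!lab %in% c("sedentary", "standing")] <-
    stats::rnorm(4 * n_per, 8, if (sep) 0.5 else 6)
  f
}

test_that("cross-validation is deterministic and perfect on separable data", {
  f <- cv_table()
  r1 <- cross_validate(f, config = "new", seed = 42, boot = 50)
  r2 <- cross_validate(f, config = "new", seed = 42, boot = 50)
  expect_equal(r1$kappa, 1)
  expect_equal(glance(r1), glance(r2))
  r3 <- cross_validate(f, config = "new", seed = 7, boot = 50)
  expect_equal(r3$kappa, 1)   # separable: fold assignment does not matter
  expect_error(cross_validate(f[1:30, ], config = "new", folds = 10), "fewer")
})

test_that("bootstrap CI covers the estimate and shrinks like 1/sqrt(n)", {
  f <- cv_table(sep = FALSE, seed = 705)
  r <- cross_validate(f, config = "new", seed = 1, boot = 2000)
  expect_lt(r$kappa, 1)
  expect_gte(r$kappa, r$ci$kappa[1])
  expect_lte(r$kappa, r$ci$kappa[2])
  f4 <- dplyr::bind_rows(f, f, f, f)
  r4 <- cross_validate(f4, config = "new", seed = 1, boot = 2000)
  ratio <- diff(r4$ci$kappa) / diff(r$ci$kappa)
  expect_gt(ratio, 0.4)
  expect_lt(ratio, 0.6)
})

test_that("Shannon entropy reproduces closed-form cases and the sum oracle", {
  expect_equal(shannon_entropy(rep(1, 50), rep("a", 50), bins = 8), 0)
  # two classes, each filling one distinct bin, equal sizes: 1 bit
  v <- c(rep(0, 50), rep(1, 50))
  l <- c(rep("a", 50), rep("b", 50))
  expect_equal(shannon_entropy(v, l, bins = 2), 1)
  set.seed(706)
  vals <- stats::rnorm(500)
  labs <- sample(c("x", "y", "z"), 500, replace = TRUE)
  bins <- 16
  h <- shannon_entropy(vals, labs, bins = bins)
  br <- seq(min(vals), max(vals), length.out = bins + 1)
  bi <- findInterval(vals, br, rightmost.closed = TRUE, all.inside = TRUE)
  p <- as.numeric(table(paste(bi, labs))) / 500
  expect_equal(h, -sum(p * log2(p)), tolerance = 1e-12)
})

test_that("joint entropy falls as classes separate at fixed marginals", {
  # same feature marginal, increasingly class-pure bins
  v <- rep(c(0, 1), each = 100)
  mixed <- rep(c("a", "b"), 100)                       # both classes in both bins
  pure <- c(rep("a", 100), rep("b", 100))              # one class per bin
  expect_lt(shannon_entropy(v, pure, bins = 2),
            shannon_entropy(v, mixed, bins = 2))
})

test_that("feature/class entropies reflect orientation robustness", {
  f0 <- std_features()
  fr <- preset_features()
  pool <- dplyr::bind_rows(c(list(f0), fr))
  pool <- pool[!is.na(pool$label) & !is.na(pool$f6), ]
  act <- ifelse(pool$label %in% c("sedentary", "standing"), "inactive", "active")
  # angular-velocity pair: both members are built from rotation-invariant
  # magnitudes, so remounting must leave their entropies unchanged
  base <- f0[!is.na(f0$label) & !is.na(f0$f6), ]
  act0 <- ifelse(base$label %in% c("sedentary", "standing"), "inactive", "active")
  for (nm in c("f1", "f5")) {
    h_train <- shannon_entropy(base[[nm]], act0, range = range(pool[[nm]]))
    h_test <- shannon_entropy(pool[[nm]], act, range = range(pool[[nm]]))
    expect_lt(abs(h_train - h_test), 0.25)
  }
  # tilt pair: the quaternion-derived tilt keeps the posture classes
  # separated across remounts while the fixed-axis inclination scrambles
  inact <- pool[act == "inactive", ]
  expect_lt(shannon_entropy(inact$f6, as.character(inact$label)),
            shannon_entropy(inact$f2, as.character(inact$label)))
})
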