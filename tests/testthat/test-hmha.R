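# Stump training, the fixed hierarchy, and classification.

# exhaustive-enumeration oracle for a single stump, uniform priors
oracle_split <- function(values, labels) {
  w <- 1 / table(labels)
  sv <- sort(unique(values))
  cands <- (sv[-1] + sv[-length(sv)]) / 2
  best <- Inf; thr <- NA
  for (cand in cands) {
    left <- values <= cand
    imp <- 0
    for (side in list(left, !left)) {
      ws <- as.numeric(w[labels[side]])
      tot <- sum(ws)
      if (tot > 0) {
        p <- vapply(names(w), function(cl) sum(ws[labels[side] == cl]) / tot,
                    numeric(1))
        imp <- imp + tot * (1 - sum(p^2))
      }
    }
    if (imp < best - 1e-12) { best <- imp; thr <- cand }
  }
  thr
}

test_that("stump training finds the separating midpoint", {
  fit <- train_node(c(1, 2, 9, 10), c("A", "A", "B", "B"))
  expect_equal(fit$threshold, 5.5)
  expect_equal(fit$impurity, 0)
  expect_error(train_node(c(1, 2), c("A", "A")), "one class")
  expect_error(train_node(rep(3, 4), c("A", "A", "B", "B")), "no candidate")
})

test_that("uniform priors neutralize class imbalance", {
  vals <- c(1, seq(4, 12, length.out = 100))
  labs <- c("A", rep("B", 100))
  fit <- train_node(vals, labs)
  # same split as the balanced case: in the gap between the lone A and the Bs
  expect_equal(fit$threshold, (1 + 4) / 2)
})

test_that("training matches exhaustive enumeration on random instances", {
  set.seed(601)
  for (i in seq_len(400)) {
    n <- sample(5:25, 1)
    vals <- round(stats::rnorm(n), 2)
    labs <- sample(c("L", "R"), n, replace = TRUE)
    if (length(unique(labs)) < 2 || length(unique(vals)) < 2) next
    expect_equal(train_node(vals, labs)$threshold, oracle_split(vals, labs))
  }
})

make_margin_table <- function(n_per = 30, seed = 602) {
  # synthetic feature table generated from known per-node thresholds with
  # clear margins; features not routed at a node are noise
  set.seed(seed)
  lv <- activity_levels()
  lab <- rep(lv, each = n_per)
  n <- length(lab)
  f <- tibble::tibble(
    window_start = seq_len(n) * 1.25,
    f1 = stats::runif(n, 0, 0.5), f2 = stats::runif(n, 0, 0.2),
    f3 = stats::runif(n, 0, 5), f4 = stats::rnorm(n, 0, 0.01),
    f5 = stats::runif(n, 0, 0.5), f6 = stats::runif(n, 0, 0.2),
    f7 = stats::runif(n, 0, 0.05), f8 = stats::rnorm(n, 0, 0.02),
    cold_start = FALSE,
    label = factor(lab, levels = lv)
  )
  active <- !lab %in% c("sedentary", "standing")
  f$f5[active] <- stats::runif(sum(active), 2, 12)       # threshold ~1.25
  f$f6[lab == "sedentary"] <- stats::runif(n_per, 1.3, 1.6)  # vs < 0.2
  f$f7[lab == "postural_transition"] <- stats::runif(n_per, 0.4, 0.8)
  walkish <- lab %in% c("walking", "walking_upstairs", "walking_downstairs")
  f$f8[lab == "walking_downstairs"] <- stats::rnorm(n_per, -0.3, 0.02)
  f$f8[lab == "walking_upstairs"] <- stats::rnorm(n_per, 0.3, 0.02)
  # original features mirror the structure so both configs are trainable
  f$f1[active] <- f$f5[active] * stats::runif(sum(active), 0.9, 1.1)
  f$f2[lab == "sedentary"] <- f$f6[lab == "sedentary"]
  f$f3[lab == "postural_transition"] <- stats::runif(n_per, 30, 60)
  f$f4[lab == "walking_downstairs"] <- stats::rnorm(n_per, -0.1, 0.005)
  f$f4[lab == "walking_upstairs"] <- stats::rnorm(n_per, 0.1, 0.005)
  f
}

test_that("the fitted hierarchy recovers generating thresholds within the gap", {
  f <- make_margin_table()
  m <- hmha(f, config = "new")
  td <- tidy(m)
  expect_equal(td$feature, c("f5", "f6", "f7", "f8", "f8"))
  thr <- setNames(td$threshold, td$node)
  expect_gt(thr[["active"]], 0.5); expect_lt(thr[["active"]], 2)
  expect_gt(thr[["posture"]], 0.2); expect_lt(thr[["posture"]], 1.3)
  expect_gt(thr[["transition"]], 0.05); expect_lt(thr[["transition"]], 0.4)
  expect_gt(thr[["down"]], -0.3); expect_lt(thr[["down"]], -0.1)
  expect_gt(thr[["up"]], 0.1); expect_lt(thr[["up"]], 0.3)
  # perfect recovery on its own training data
  pred <- predict(m, f)
  expect_equal(as.character(pred), as.character(f$label))
})

test_that("feature-set configuration contracts hold", {
  f <- make_margin_table()
  mo <- hmha(f, config = "original")
  expect_equal(tidy(mo)$feature, c("f1", "f2", "f3", "f4", "f4"))
  # best selects the cleanly-separating member when the other is scrambled
  f_scr <- f
  f_scr$f2 <- sample(f_scr$f2)          # scrambled tilt angle
  mb <- hmha(f_scr, config = "best")
  expect_equal(tidy(mb)$feature[tidy(mb)$node == "posture"], "f6")
  expect_error(hmha(f[f$label != "walking", ], config = "new"), "walking")
})

test_that("classification reproduces the published decision-rule examples", {
  # thresholds as printed for the pooled-cohort 100 Hz model
  m <- structure(list(nodes = list(
    active = list(feature = "f5", threshold = 0.230,
                  left = c("sedentary", "standing")),
    posture = list(feature = "f6", threshold = 0.640, left = "standing"),
    transition = list(feature = "f3", threshold = 46.7,
                      left = c("walking", "walking_upstairs", "walking_downstairs")),
    down = list(feature = "f4", threshold = -0.062, left = "walking_downstairs"),
    up = list(feature = "f4", threshold = 0.092, left = "walking")
  ), config = "best", fs = 100, n_train = 0L), class = "hmha")
  fv <- function(f5, f6 = 0, f3 = 0, f4 = 0) {
    tibble::tibble(f1 = 0, f2 = 0, f3 = f3, f4 = f4,
                   f5 = f5, f6 = f6, f7 = 0, f8 = 0)
  }
  expect_equal(as.character(predict(m, fv(f5 = 0.10, f6 = 0.30))), "standing")
  expect_equal(as.character(predict(m, fv(f5 = 0.10, f6 = 0.80))), "sedentary")
  expect_equal(as.character(predict(m, fv(f5 = 1.0, f3 = 100))),
               "postural_transition")
  expect_equal(as.character(predict(m, fv(f5 = 1.0, f3 = 10, f4 = -0.2))),
               "walking_downstairs")
  expect_equal(as.character(predict(m, fv(f5 = 1.0, f3 = 10, f4 = 0.2))),
               "walking_upstairs")
  expect_equal(as.character(predict(m, fv(f5 = 1.0, f3 = 10, f4 = 0.05))),
               "walking")
})

test_that("classification is monotone at each node boundary", {
  f <- make_margin_table()
  m <- hmha(f, config = "new")
  thr <- setNames(tidy(m)$threshold, tidy(m)$node)
  base <- tibble::tibble(f1 = 0, f2 = 0, f3 = 0, f4 = 0,
                         f5 = 0, f6 = 0, f7 = 0, f8 = 0)
  eps <- 1e-9
  # crossing the active threshold flips inactive -> active subtree only
  lo <- base; lo$f5 <- thr[["active"]] - eps
  hi <- base; hi$f5 <- thr[["active"]] + eps
  expect_equal(as.character(predict(m, lo)), "standing")
  expect_true(as.character(predict(m, hi)) %in%
                c("walking", "walking_upstairs", "walking_downstairs",
                  "postural_transition"))
  # crossing the posture threshold flips standing -> sedentary
  hi2 <- base; hi2$f6 <- thr[["posture"]] + eps
  expect_equal(as.character(predict(m, hi2)), "sedentary")
})

test_that("cold-start windows default to standing and are flagged", {
  f <- make_margin_table()
  m <- hmha(f, config = "new")
  cold <- f[1, ]
  cold$f6 <- NA_real_
  p <- predict(m, cold)
  expect_equal(as.character(p), "standing")
  expect_true(attr(p, "cold_start"))
})

test_that("a serialized model round-trips to identical classifications", {
  f <- make_margin_table()
  m <- hmha(f, config = "best")
  path <- tempfile(fileext = ".txt")
  write_hmha(m, path)
  m2 <- read_hmha(path)
  expect_equal(tidy(m2)$threshold, tidy(m)$threshold)
  expect_identical(predict(m2, f), predict(m, f))
  expect_equal(glance(m2)$config, glance(m)$config)
})
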