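# The hierarchical model of human activity: a fixed tree of five binary
# CART stumps, one leaf per class, trained with uniform prior class
# probabilities. The tree structure never changes; only the per-node
# feature choice (within a designated pair) and threshold are learned.
#
#   node        data reaching it          "<= threshold" branch   pair
#   active      everything                inactive (sed, stand)   f1 / f5
#   posture     inactive windows          standing                f2 / f6
#   transition  active windows            any walking             f3 / f7
#   down        walking-group windows     walking downstairs      f4 / f8
#   up          walking + upstairs        walking                 f4 / f8

#' The six activity classes
#'
#' @return Character vector of the class labels in canonical order.
#' @export
activity_levels <- function() {
  c("sedentary", "standing", "walking", "walking_upstairs",
    "walking_downstairs", "postural_transition")
}

hmha_node_defs <- function() {
  list(
    active = list(
      subset = activity_levels(),
      left = c("sedentary", "standing"),
      pair = c(original = "f1", new = "f5")
    ),
    posture = list(
      subset = c("sedentary", "standing"),
      left = "standing",
      pair = c(original = "f2", new = "f6")
    ),
    transition = list(
      subset = c("walking", "walking_upstairs", "walking_downstairs",
                 "postural_transition"),
      left = c("walking", "walking_upstairs", "walking_downstairs"),
      pair = c(original = "f3", new = "f7")
    ),
    down = list(
      subset = c("walking", "walking_upstairs", "walking_downstairs"),
      left = "walking_downstairs",
      pair = c(original = "f4", new = "f8")
    ),
    up = list(
      subset = c("walking", "walking_upstairs"),
      left = "walking",
      pair = c(original = "f4", new = "f8")
    )
  )
}

#' Train a single CART stump threshold with uniform class priors
#'
#' Finds the scalar threshold minimizing the class-weighted Gini impurity of
#' the partition \code{value <= threshold} vs \code{value > threshold}.
#' Per-sample weights are inversely proportional to class frequency, which
#' is equivalent to uniform prior class probabilities: class imbalance does
#' not move the split. Candidate thresholds are the midpoints between
#' adjacent distinct sorted values; ties in impurity break toward the
#' smaller threshold.
#'
#' @param values Numeric feature values.
#' @param labels Two-level factor/character labels, same length.
#' @param weights Optional per-sample weights. The default weights each
#'   sample by the inverse frequency of its (binary) label; the hierarchy
#'   passes weights derived from the six activity classes instead, so that
#'   a rare class grouped with common ones on one branch still counts as a
#'   full class.
#' @return A list with \code{threshold}, the achieved weighted
#'   \code{impurity}, and the \code{margin} (gap width at the split).
#' @export
train_node <- function(values, labels, weights = NULL) {
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]
  labels <- as.character(labels)[ok]
  if (!is.null(weights)) weights <- weights[ok]
  cls <- unique(labels)
  if (length(cls) < 2) {
    stop("degenerate node: only one class present", call. = FALSE)
  }
  if (length(cls) > 2) {
    stop("train_node expects binary labels", call. = FALSE)
  }
  if (is.null(weights)) {
    wtab <- 1 / table(labels)        # uniform priors over the binary labels
    weights <- as.numeric(wtab[labels])
  }
  w <- weights
  o <- order(values)
  v <- values[o]; lb <- labels[o]; w <- w[o]
  is1 <- lb == cls[1]
  cw1 <- cumsum(w * is1)
  cw2 <- cumsum(w * !is1)
  W1 <- cw1[length(cw1)]; W2 <- cw2[length(cw2)]
  # split points between adjacent *distinct* values
  cut <- which(diff(v) > 0)
  if (!length(cut)) {
    stop("degenerate node: no candidate split (all values identical)", call. = FALSE)
  }
  wl <- cw1[cut] + cw2[cut]
  wr <- (W1 + W2) - wl
  gini_l <- 1 - (cw1[cut] / wl)^2 - (cw2[cut] / wl)^2
  gini_r <- 1 - ((W1 - cw1[cut]) / wr)^2 - ((W2 - cw2[cut]) / wr)^2
  imp <- (wl * gini_l + wr * gini_r) / (W1 + W2)
  best <- which(imp <= min(imp) + 1e-12)[1]   # tie -> smaller threshold
  thr <- (v[cut[best]] + v[cut[best] + 1]) / 2
  list(threshold = thr,
       impurity = imp[best],
       margin = v[cut[best] + 1] - v[cut[best]])
}

#' Fit the hierarchical activity model
#'
#' Trains the five stumps of the fixed hierarchy on a labelled feature
#' table. Each node sees only the windows whose true label reaches it under
#' the tree routing. With \code{config = "original"} the nodes use features
#' f1-f4, with \code{"new"} features f5-f8, and with \code{"best"} each node
#' trains a stump on both members of its feature pair and keeps the one
#' with lower uniform-prior Gini impurity; when the impurities tie (the
#' training data cannot distinguish the splits) the quaternion-derived
#' member is preferred, since it is orientation-robust by construction.
#'
#' Windows with \code{NA} labels or \code{NA} in a routed feature
#' (cold-start) are excluded from training at that node.
#'
#' @param features A labelled feature table (see \code{\link{label_windows}}).
#' @param config \code{"best"}, \code{"original"} or \code{"new"}.
#' @param fs IMU sampling rate the features were extracted at (stored for
#'   provenance).
#' @return An object of class \code{hmha}.
#' @export
hmha <- function(features, config = c("best", "original", "new"), fs = NA_real_) {
  config <- match.arg(config)
  defs <- hmha_node_defs()
  lv <- activity_levels()
  lab <- as.character(features$label)
  present <- lv %in% lab
  if (!all(present)) {
    stop(sprintf("training data is missing class(es): %s",
                 paste(lv[!present], collapse = ", ")), call. = FALSE)
  }
  # uniform priors over the six activity classes: every class contributes
  # equal total weight at every node it reaches
  class_w <- 1 / table(factor(lab, levels = lv))
  nodes <- lapply(names(defs), function(nm) {
    d <- defs[[nm]]
    rows <- !is.na(lab) & lab %in% d$subset
    binary <- ifelse(lab[rows] %in% d$left, "left", "right")
    w_rows <- as.numeric(class_w[lab[rows]])
    cand_feats <- switch(config,
                         original = d$pair[["original"]],
                         new = d$pair[["new"]],
                         best = unname(d$pair))
    fits <- lapply(cand_feats, function(f) {
      vals <- features[[f]][rows]
      fit <- train_node(vals, binary, weights = w_rows)
      fit$feature <- f
      fit
    })
    if (length(fits) == 1) {
      chosen <- fits[[1]]
    } else {
      imp <- vapply(fits, `[[`, numeric(1), "impurity")
      if (abs(imp[1] - imp[2]) > 1e-9) {
        chosen <- fits[[which.min(imp)]]
      } else {
        # the training data cannot distinguish the two splits: prefer the
        # quaternion-derived member, invariant to remounting by construction
        chosen <- fits[[2]]
      }
    }
    list(feature = chosen$feature, threshold = chosen$threshold,
         impurity = chosen$impurity, left = d$left)
  })
  names(nodes) <- names(defs)
  structure(list(nodes = nodes, config = config, fs = fs,
                 n_train = sum(!is.na(lab))),
            class = "hmha")
}

#' @export
print.hmha <- function(x, ...) {
  cat(sprintf("Hierarchical activity model (%s features, %d training windows)\n",
              x$config, x$n_train))
  for (nm in names(x$nodes)) {
    nd <- x$nodes[[nm]]
    cat(sprintf("  %-10s %s <= %.4g -> %s\n", nm, nd$feature, nd$threshold,
                paste(nd$left, collapse = "/")))
  }
  invisible(x)
}

#' Classify feature windows with a fitted hierarchy
#'
#' Routes each window through the fixed tree: activity vs inactivity first,
#' then posture (standing vs sedentary) on the inactive side, then
#' postural transition vs the walking group, then stairs, on the active
#' side. Cold-start windows whose tilt feature is unavailable default to
#' \code{standing} (the neutral inactive class) and are flagged via the
#' \code{cold_start} attribute.
#'
#' @param object A fitted \code{\link{hmha}} model.
#' @param newdata A feature table with the columns the model's nodes use.
#' @param ... Unused.
#' @return A factor of predicted activity labels.
#' @export
predict.hmha <- function(object, newdata, ...) {
  nd <- object$nodes
  n <- nrow(newdata)
  fval <- function(node) newdata[[nd[[node]]$feature]]
  out <- rep(NA_character_, n)

  # cold-start windows: the tilt reference is not yet learned, so any node
  # routed on f6/f7 is blind. Default them to the neutral inactive class.
  cold <- rep(FALSE, n)
  for (nm in names(nd)) {
    v <- fval(nm)
    if (!is.null(v)) cold <- cold | is.na(v)
  }

  tf <- function(x) !is.na(x) & x   # NA comparisons never route anywhere
  inact <- tf(fval("active") <= nd$active$threshold)
  out[inact & tf(fval("posture") <= nd$posture$threshold)] <- "standing"
  out[inact & tf(fval("posture") > nd$posture$threshold)] <- "sedentary"

  act <- !inact
  walkgrp <- act & tf(fval("transition") <= nd$transition$threshold)
  out[act & tf(fval("transition") > nd$transition$threshold)] <- "postural_transition"
  down <- walkgrp & tf(fval("down") <= nd$down$threshold)
  out[down] <- "walking_downstairs"
  rest <- walkgrp & !down
  out[rest & tf(fval("up") <= nd$up$threshold)] <- "walking"
  out[rest & tf(fval("up") > nd$up$threshold)] <- "walking_upstairs"

  out[cold] <- "standing"
  res <- factor(out, levels = activity_levels())
  attr(res, "cold_start") <- cold
  res
}

#' @rdname predict.hmha
#' @param model A fitted \code{\link{hmha}} model.
#' @param features Feature table to classify.
#' @return \code{classify_windows}: the feature table with \code{.pred} and
#'   \code{.cold_start} columns appended.
#' @export
classify_windows <- function(model, features) {
  p <- predict(model, features)
  features$.pred <- factor(as.character(p), levels = activity_levels())
  features$.cold_start <- attr(p, "cold_start")
  features
}

#' Tidy a fitted hierarchical activity model
#'
#' @param x A fitted \code{\link{hmha}} model.
#' @param ... Unused.
#' @return One row per tree node: node name, chosen feature, threshold,
#'   achieved impurity and the class(es) on the "<= threshold" branch.
#' @export
tidy.hmha <- function(x, ...) {
  tibble::tibble(
    node = names(x$nodes),
    feature = unname(vapply(x$nodes, `[[`, character(1), "feature")),
    threshold = unname(vapply(x$nodes, `[[`, numeric(1), "threshold")),
    impurity = unname(vapply(x$nodes, `[[`, numeric(1), "impurity")),
    left = unname(vapply(x$nodes, function(n) paste(n$left, collapse = "+"),
                         character(1)))
  )
}

#' @rdname tidy.hmha
#' @export
glance.hmha <- function(x, ...) {
  tibble::tibble(config = x$config, fs = x$fs, n_train = x$n_train,
                 nodes = length(x$nodes))
}

#' Serialize / load a fitted model as flat key-value text
#'
#' The on-disk format is diff-friendly plain text: one \code{key = value}
#' line per field, thresholds at full precision. A round-trip reproduces
#' identical classifications.
#'
#' @param model A fitted \code{\link{hmha}} model.
#' @param path File path.
#' @export
write_hmha <- function(model, path) {
  lines <- c(
    sprintf("config = %s", model$config),
    sprintf("fs = %s", format(model$fs, digits = 17)),
    sprintf("n_train = %d", model$n_train)
  )
  for (nm in names(model$nodes)) {
    nd <- model$nodes[[nm]]
    lines <- c(lines,
               sprintf("node.%s.feature = %s", nm, nd$feature),
               sprintf("node.%s.threshold = %s", nm, format(nd$threshold, digits = 17)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_hmha
#' @export
read_hmha <- function(path) {
  raw <- readLines(path)
  kv <- strsplit(raw, "\\s*=\\s*")
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- vapply(kv, `[[`, character(1), 2)
  get <- function(k) vals[match(k, keys)]
  num <- function(k) {
    v <- get(k)
    if (is.na(v) || v == "NA") NA_real_ else as.numeric(v)
  }
  defs <- hmha_node_defs()
  nodes <- lapply(names(defs), function(nm) {
    list(feature = get(sprintf("node.%s.feature", nm)),
         threshold = num(sprintf("node.%s.threshold", nm)),
         impurity = NA_real_,
         left = defs[[nm]]$left)
  })
  names(nodes) <- names(defs)
  structure(list(nodes = nodes, config = get("config"),
                 fs = num("fs"),
                 n_train = as.integer(num("n_train"))),
            class = "hmha")
}
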