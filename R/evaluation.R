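# Performance metrics: Cohen's kappa, per-class sensitivity / specificity,
# total class sensitivity, stratified 10-fold cross-validation with
# bootstrap confidence intervals, and the Shannon-entropy statistic used to
# compare feature/class separability.

#' Confusion matrix over the six activity classes
#'
#' @param truth,pred Label vectors (coerced to the canonical class order;
#'   extra levels are an error).
#' @param levels Class levels (default the six activities).
#' @return A square integer matrix, rows = truth, columns = predicted.
#' @export
confusion_matrix <- function(truth, pred, levels = activity_levels()) {
  t_f <- factor(as.character(truth), levels = levels)
  p_f <- factor(as.character(pred), levels = levels)
  if (anyNA(t_f) & !anyNA(truth)) stop("truth contains unknown labels", call. = FALSE)
  table(truth = t_f, pred = p_f)
}

metrics_from_confusion <- function(cm) {
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (abs(1 - pe) < 1e-12) NA_real_ else (po - pe) / (1 - pe)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- n - tp - fn - fp
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  list(kappa = kappa, accuracy = 100 * po,
       sensitivity = sens, specificity = spec,
       total_sensitivity = mean(sens, na.rm = TRUE))
}

#' Score predicted activity labels against the truth
#'
#' Computes Cohen's kappa (chance-corrected agreement), per-class
#' sensitivity and specificity (%), and the total class sensitivity (the
#' unweighted mean of per-class sensitivities, so rare classes count as
#' much as common ones). Classes absent from the truth are excluded from
#' the total.
#'
#' @param truth,pred Label vectors of equal length.
#' @param levels Class levels.
#' @return A \code{har_score} object: \code{kappa},
#'   \code{total_sensitivity}, a \code{per_class} tibble and the
#'   \code{confusion} matrix.
#' @export
score <- function(truth, pred, levels = activity_levels()) {
  if (length(truth) != length(pred)) stop("length mismatch", call. = FALSE)
  cm <- confusion_matrix(truth, pred, levels)
  if (sum(rowSums(cm) > 0) < 2) {
    stop("need at least two classes present in the truth", call. = FALSE)
  }
  m <- metrics_from_confusion(cm)
  if (is.na(m$kappa)) stop("undefined kappa: degenerate single-cell table", call. = FALSE)
  structure(list(
    kappa = m$kappa,
    total_sensitivity = m$total_sensitivity,
    accuracy = m$accuracy,
    per_class = tibble::tibble(class = rownames(cm),
                               sensitivity = as.numeric(m$sensitivity),
                               specificity = as.numeric(m$specificity),
                               n = as.integer(rowSums(cm))),
    confusion = cm,
    n = sum(cm)
  ), class = "har_score")
}

#' @export
print.har_score <- function(x, ...) {
  cat(sprintf("kappa = %.3f, total class sensitivity = %.1f%% (n = %d windows)\n",
              x$kappa, x$total_sensitivity, x$n))
  if (!is.null(x$ci)) {
    cat(sprintf("  95%% CI: kappa [%.3f, %.3f], sensitivity [%.1f, %.1f]%%\n",
                x$ci$kappa[1], x$ci$kappa[2],
                x$ci$total_sensitivity[1], x$ci$total_sensitivity[2]))
  }
  print(x$per_class, n = Inf)
  invisible(x)
}

#' @rdname tidy.hmha
#' @export
tidy.har_score <- function(x, ...) x$per_class

#' @rdname tidy.hmha
#' @export
glance.har_score <- function(x, ...) {
  out <- tibble::tibble(kappa = x$kappa,
                        total_sensitivity = x$total_sensitivity,
                        accuracy = x$accuracy, n = x$n)
  if (!is.null(x$ci)) {
    out$kappa_lo <- x$ci$kappa[1]; out$kappa_hi <- x$ci$kappa[2]
    out$sens_lo <- x$ci$total_sensitivity[1]; out$sens_hi <- x$ci$total_sensitivity[2]
  }
  out
}

#' Stratified k-fold cross-validation of the hierarchical model
#'
#' Splits the labelled feature table into folds stratified by class, trains
#' the hierarchy on k-1 folds, predicts the held-out fold, pools the
#' predictions and scores them once. Confidence intervals come from a
#' stratified bootstrap over windows of the pooled predictions (percentile
#' method). Deterministic given \code{seed}.
#'
#' @param features Labelled feature table.
#' @param config Feature configuration passed to \code{\link{hmha}}.
#' @param folds Number of folds (default 10).
#' @param seed RNG seed for fold assignment and the bootstrap.
#' @param boot Number of bootstrap resamples for the 95% CIs (default 2000;
#'   0 disables).
#' @return A \code{har_score} with an added \code{ci} element.
#' @export
cross_validate <- function(features, config = "best", folds = 10, seed = 1,
                           boot = 2000) {
  feats <- features[!is.na(features$label), , drop = FALSE]
  lab <- as.character(feats$label)
  n <- nrow(feats)
  fold_id <- integer(n)
  with_preserved_seed(seed, {
    for (cl in unique(lab)) {
      idx <- which(lab == cl)
      if (length(idx) < folds) {
        stop(sprintf("class '%s' has fewer windows (%d) than folds (%d)",
                     cl, length(idx), folds), call. = FALSE)
      }
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    pred <- rep(NA_character_, n)
    for (f in seq_len(folds)) {
      train <- feats[fold_id != f, , drop = FALSE]
      model <- hmha(train, config = config)
      pred[fold_id == f] <- as.character(predict(model, feats[fold_id == f, , drop = FALSE]))
    }
    sc <- score(lab, pred)
    if (boot > 0) {
      by_class <- split(seq_len(n), lab)
      stats_b <- matrix(NA_real_, boot, 2)
      for (b in seq_len(boot)) {
        idx <- unlist(lapply(by_class, function(i) i[sample.int(length(i), replace = TRUE)]),
                      use.names = FALSE)
        m <- metrics_from_confusion(confusion_matrix(lab[idx], pred[idx]))
        stats_b[b, ] <- c(m$kappa, m$total_sensitivity)
      }
      sc$ci <- list(
        kappa = unname(stats::quantile(stats_b[, 1], c(0.025, 0.975), na.rm = TRUE)),
        total_sensitivity = unname(stats::quantile(stats_b[, 2], c(0.025, 0.975), na.rm = TRUE))
      )
    }
    sc
  })
}

#' Shannon entropy of a binned feature / class distribution
#'
#' Bins the feature values into \code{bins} equal-width bins over their
#' pooled range and computes, in bits, the entropy of the chosen
#' distribution: \code{"joint"} (the primary statistic) is the entropy of
#' the normalized (bin, class) frequency table; \code{"feature"} the
#' marginal over bins; \code{"conditional"} the class-weighted mean of the
#' per-class bin entropies. Lower joint entropy at fixed marginals means
#' better-separated class distributions.
#'
#' @param values Numeric feature values.
#' @param labels Class labels, same length.
#' @param bins Number of equal-width bins (>= 2, default 64).
#' @param type Which entropy to report.
#' @param range Optional fixed bin range (length-2), e.g. the pooled
#'   train+test range when comparing datasets.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(values, labels, bins = 64,
                            type = c("joint", "feature", "conditional"),
                            range = NULL) {
  type <- match.arg(type)
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- as.character(labels)[ok]
  if (!length(values)) stop("no finite values to bin", call. = FALSE)
  if (bins < 2) stop("bins must be >= 2", call. = FALSE)
  if (is.null(range)) range <- base::range(values)
  if (diff(range) <= 0) range <- range + c(-0.5, 0.5)
  br <- seq(range[1], range[2], length.out = bins + 1)
  bi <- findInterval(values, br, rightmost.closed = TRUE, all.inside = TRUE)
  tab <- table(bin = factor(bi, levels = seq_len(bins)), class = labels)
  p <- tab / sum(tab)
  H <- function(x) { x <- x[x > 0]; -sum(x * log2(x)) }
  switch(type,
         joint = H(as.numeric(p)),
         feature = H(rowSums(p)),
         conditional = {
           pc <- colSums(p)
           sum(vapply(seq_along(pc), function(j) {
             if (pc[j] == 0) return(0)
             pc[j] * H(p[, j] / pc[j])
           }, numeric(1)))
         })
}
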