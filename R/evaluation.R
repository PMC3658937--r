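# ROC computation with the benchmark's exclusion rule, vertical averaging
# over repeated simulations, and score extraction from fitted objects.

#' ROC points and AUC for a ranked tuple list
#'
#' Thresholds sweep the unique score values in descending order; at each
#' threshold the true and false positive rates are computed over the
#' non-excluded tuples only. Excluded tuples (e.g. tuples simulated with a
#' different kind of differential expression than the one being scored)
#' contribute to neither rate; exclusion wins over membership in
#' `positives`. Missing (`NA`) scores rank last. The AUC is the trapezoidal
#' area under the resulting step curve.
#'
#' @param scores Either a named numeric vector (names = tuple ids) or a
#'   data frame with columns `tuple_id` and `score`.
#' @param positives Character vector of truly positive tuple ids.
#' @param excluded Character vector of tuple ids removed from evaluation.
#' @return A tibble of class `pbb_roc` with columns `threshold`, `fpr`,
#'   `tpr` (including the (0,0) and (1,1) anchors) and attribute `auc`; see
#'   [roc_auc()].
#' @export
roc_points <- function(scores, positives, excluded = character(0)) {
  if (is.data.frame(scores)) {
    sc <- setNames(scores$score, scores$tuple_id)
  } else {
    sc <- scores
    if (is.null(names(sc))) names(sc) <- paste0("t", seq_along(sc))
  }
  keep <- !(names(sc) %in% excluded)
  sc <- sc[keep]
  y <- names(sc) %in% setdiff(positives, excluded)
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L) {
    abort("need at least one positive and one negative after exclusion.")
  }
  if (anyNA(sc)) {
    inform(paste0(sum(is.na(sc)), " missing score(s) ranked last."))
    sc[is.na(sc)] <- -Inf
  }
  ord <- order(sc, decreasing = TRUE)
  sc <- sc[ord]
  y <- y[ord]
  # collapse ties: cumulative counts at the last index of each unique score
  last <- rev(!duplicated(rev(sc)))
  tp <- cumsum(y)[last]
  fp <- cumsum(!y)[last]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  out <- tibble::tibble(
    threshold = c(Inf, sc[last]),
    fpr = fpr, tpr = tpr
  )
  structure(out, auc = auc, class = c("pbb_roc", class(out)))
}

#' @rdname roc_points
#' @param x A `pbb_roc` tibble.
#' @export
roc_auc <- function(x) attr(x, "auc")

#' Average ROC curves over repeated simulations
#'
#' Vertical averaging: each run's curve is interpolated as a right-
#' continuous step function of FPR, and the TPRs are averaged on a common
#' FPR grid.
#'
#' @param runs List of `pbb_roc` tibbles (or data frames with `fpr`,
#'   `tpr`).
#' @param grid FPR grid on which to average.
#' @return A tibble with columns `fpr` and `tpr` (the mean); attribute
#'   `auc` holds the trapezoidal area of the mean curve.
#' @export
mean_roc <- function(runs, grid = seq(0, 1, by = 0.01)) {
  if (length(runs) == 0L) abort("`runs` must contain at least one ROC curve.")
  tprs <- vapply(runs, function(r) {
    approx(
      x = c(r$fpr, 1), y = c(r$tpr, 1), xout = grid,
      method = "constant", f = 0, rule = 2, ties = max
    )$y
  }, numeric(length(grid)))
  tpr <- rowMeans(matrix(tprs, nrow = length(grid)))
  out <- tibble::tibble(fpr = grid, tpr = tpr)
  auc <- sum(diff(grid) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(out, auc = auc, class = c("pbb_roc", class(out)))
}

#' Plot one or more ROC curves
#'
#' @param object A `pbb_roc` tibble, or a named list of them.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pbb_roc <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object), curve = "ROC")
  plot_roc(df)
}

#' @rdname autoplot.pbb_roc
#' @param curves Named list of `pbb_roc` tibbles.
#' @export
plot_roc_curves <- function(curves) {
  df <- purrr::imap_dfr(curves, function(r, nm) {
    dplyr::mutate(tibble::as_tibble(r), curve = nm)
  })
  plot_roc(df)
}

plot_roc <- function(df) {
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$fpr, y = .data$tpr, colour = .data$curve
  )) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' Extract differential-expression scores from a posterior fit
#'
#' Scores used for ranking in benchmarks: `"within"` is the posterior of
#' the consistent-ratio model (one FREE set spanning all pairs),
#' `"between"` the posterior of the group-difference model (more than one
#' FREE set), and `"any"` the summed posterior of all models other than
#' those with only FIXED sets (the null models).
#'
#' @param fit A `pbb_fit`.
#' @param type `"within"`, `"between"` or `"any"`.
#' @return A tibble with columns `tuple_id` and `score`.
#' @export
de_scores <- function(fit, type = c("within", "between", "any")) {
  type <- match.arg(type)
  k_free <- vapply(fit$models, n_free_sets, numeric(1))
  n_sets <- vapply(fit$models, function(m) length(m$sets), numeric(1))
  pick <- switch(type,
    within = which(k_free == 1 & n_sets == 1),
    between = which(k_free >= 2),
    any = which(k_free > 0)
  )
  if (length(pick) == 0L) abort(paste0("no model matches score type `", type, "`."))
  score <- unname(rowSums(fit$posterior[, pick, drop = FALSE]))
  tibble::tibble(tuple_id = fit$tuple_id, score = score)
}
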