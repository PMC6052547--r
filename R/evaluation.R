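#' Positional cosine similarity between two profiles
#'
#' Entry `t` is the cosine of the angle between row `t` of `pred` and row `t`
#' of `target` — the per-site agreement between generated and teacher columns.
#'
#' @param pred,target Matrices of equal shape with no zero rows.
#' @return Numeric vector of length `N`, values in `[-1, 1]`.
#' @export
positional_cosine <- function(pred, target) {
  pred <- unclass(pred); target <- unclass(target)
  if (!all(dim(pred) == dim(target))) abort("pred and target shapes differ")
  np <- sqrt(rowSums(pred^2))
  nt <- sqrt(rowSums(target^2))
  if (any(np == 0) || any(nt == 0)) abort("zero-norm profile row")
  rowSums(pred * target) / (np * nt)
}

#' Mean cosine similarity by sequence position
#'
#' Aggregates positional cosine similarities across a ragged collection of
#' (prediction, target) pairs: position `t` averages over all pairs that have
#' a site `t` (absent positions are simply ignored).
#'
#' @param preds,targets Lists of matrices, pairwise equal shapes.
#' @return Tibble with columns `position`, `mean_cosine`, `n` (pairs
#'   contributing), of class `seqprof_cosine_curve`.
#' @export
positional_cosine_curve <- function(preds, targets) {
  if (length(preds) != length(targets)) abort("preds/targets length mismatch")
  cs <- purrr::map2(preds, targets, positional_cosine)
  maxn <- max(lengths(cs))
  sums <- numeric(maxn); cnts <- integer(maxn)
  for (v in cs) {
    idx <- seq_along(v)
    sums[idx] <- sums[idx] + v
    cnts[idx] <- cnts[idx] + 1L
  }
  out <- tibble(position = seq_len(maxn), mean_cosine = sums / cnts, n = cnts)
  class(out) <- c("seqprof_cosine_curve", class(out))
  out
}

#' @export
autoplot.seqprof_cosine_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$mean_cosine)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue position", y = "mean cosine similarity") +
    ggplot2::theme_minimal()
}

#' Label ranked homology hits against a SCOP-style annotation
#'
#' Applies the standard structural-classification convention: query and
#' subject in the same superfamily are a true positive; in different classes
#' or different folds, a false positive; same fold but different superfamily,
#' unknown; self-hits are unknown. Unknown hits later contribute to neither
#' ROC axis.
#'
#' @param hits Tibble/data frame with columns `query`, `subject`, `evalue`
#'   (statistical significance; smaller is better). Row order is preserved.
#' @param annotation Tibble with columns `domain`, `class`, `fold`,
#'   `superfamily` (and optionally `family`); every id in `hits` must appear.
#' @return `hits` with added columns `label` (factor TP/FP/unknown) and
#'   `query_superfamily`.
#' @export
label_hits <- function(hits, annotation) {
  need <- setdiff(unique(c(hits$query, hits$subject)), annotation$domain)
  if (length(need) > 0L)
    abort(sprintf("unannotated domain id(s): %s",
                  paste(head(need, 5L), collapse = ", ")))
  ai <- match(hits$query, annotation$domain)
  bi <- match(hits$subject, annotation$domain)
  same_sf <- annotation$superfamily[ai] == annotation$superfamily[bi]
  same_fold <- annotation$fold[ai] == annotation$fold[bi] &
    annotation$class[ai] == annotation$class[bi]
  label <- dplyr::case_when(
    hits$query == hits$subject ~ "unknown",
    same_sf ~ "TP",
    !same_fold ~ "FP",
    TRUE ~ "unknown"  # same fold, different superfamily
  )
  out <- as_tibble(hits)
  out$label <- factor(label, levels = c("TP", "FP", "unknown"))
  out$query_superfamily <- annotation$superfamily[ai]
  out
}

#' Superfamily-weighted ROC curve of a labeled hit list
#'
#' Hits are sorted by statistical significance (ascending e-value, stable tie
#' order). Each TP or FP adds weight `1 / |superfamily(query)|` to its axis —
#' the weighting that negates the bias from unevenly sized superfamilies —
#' and a curve point is appended after every counted hit; unknowns are
#' skipped. With this weighting, one false positive per query accumulates a
#' total weighted FP equal to the number of distinct superfamilies among the
#' queries.
#'
#' @param labeled Output of [label_hits()] (columns `evalue`, `label`,
#'   `query_superfamily`).
#' @param annotation Annotation tibble (used for superfamily member counts:
#'   the number of annotated domains per superfamily).
#' @return Tibble of class `seqprof_roc` with columns `fp`, `tp`
#'   (cumulative weighted counts, starting at the (0, 0) point).
#' @export
weighted_roc <- function(labeled, annotation) {
  counts <- table(annotation$superfamily)
  ord <- order(labeled$evalue)  # stable in R: ties keep input order
  lab <- labeled$label[ord]
  sf <- as.character(labeled$query_superfamily[ord])
  keep <- lab != "unknown"
  lab <- lab[keep]; sf <- sf[keep]
  w <- as.numeric(counts[sf])
  if (anyNA(w) || any(w == 0))
    abort("query superfamily with zero annotated members")
  w <- 1 / w
  fp <- cumsum(ifelse(lab == "FP", w, 0))
  tp <- cumsum(ifelse(lab == "TP", w, 0))
  out <- tibble(fp = c(0, fp), tp = c(0, tp))
  class(out) <- c("seqprof_roc", class(out))
  out
}

#' @export
autoplot.seqprof_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fp, y = .data$tp)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "weighted false positives", y = "weighted true positives") +
    ggplot2::theme_minimal()
}

#' Partial AUC of a weighted ROC curve
#'
#' Trapezoidal area under the curve for weighted FP in `[0, fp_limit]`, with
#' the FP axis normalized by `fp_limit` and the TP axis by `tp_max`, so a
#' perfect ranking scores 1. The curve is linearly interpolated at the FP
#' cutoff. The conventional cutoff is one false positive per query on
#' average, i.e. `fp_limit` = number of superfamilies in the benchmark under
#' superfamily weighting.
#'
#' @param curve A `seqprof_roc` from [weighted_roc()].
#' @param fp_limit Positive FP budget.
#' @param tp_max Normalizer for the TP axis (total weighted positives of the
#'   benchmark; must be at least the curve's maximum TP).
#' @return Scalar in `[0, 1]`.
#' @export
pauc <- function(curve, fp_limit, tp_max) {
  if (nrow(curve) < 1L) abort("empty ROC curve")
  if (fp_limit <= 0) abort("fp_limit must be positive")
  if (tp_max < max(curve$tp)) abort("tp_max below the curve's maximum TP")
  x <- curve$fp; y <- curve$tp
  if (max(x) < fp_limit) {
    # curve ends inside the budget: extend horizontally
    x <- c(x, fp_limit); y <- c(y, y[length(y)])
  } else if (!any(x == fp_limit)) {
    i <- which(x > fp_limit)[1L]
    frac <- (fp_limit - x[i - 1L]) / (x[i] - x[i - 1L])
    x <- c(x[1:(i - 1L)], fp_limit)
    y <- c(y[1:(i - 1L)], y[i - 1L] + frac * (y[i] - y[i - 1L]))
  } else {
    i <- max(which(x == fp_limit))
    x <- x[1:i]; y <- y[1:i]
  }
  area <- sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
  area / (fp_limit * tp_max)
}

#' Relative sensitivity of one method against another
#'
#' The ratio of two pAUC values: how much more sensitive method A is than
#' method B on the same benchmark.
#'
#' @param pauc_a,pauc_b pAUC values; `pauc_b` must be positive.
#' @return `pauc_a / pauc_b`.
#' @export
relative_sensitivity <- function(pauc_a, pauc_b) {
  if (pauc_b <= 0) abort("reference pAUC must be positive")
  pauc_a / pauc_b
}
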