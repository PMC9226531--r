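#' Hierarchical classification metrics
#'
#' Three evaluation perspectives for hierarchical transposon classification:
#' whole-taxonomy hierarchical precision/recall/F1 on ancestor-augmented
#' label sets ([hierarchical_prf()]), per-taxonomic-level macro metrics
#' ([level_metrics()]) and per-class F1 / Matthews correlation
#' ([class_metrics()]).  [cross_validate()] drives a stratified k-fold
#' cross-validation and averages all three perspectives across folds.
#'
#' @name te_evaluation
#' @keywords internal
NULL

## normalize predictions to a list of predicted path sets (character vectors,
## root excluded).  Accepts a character vector of deepest codes (NA =
## unclassified), a "te_paths" object, or a list of path vectors.
pred_sets <- function(preds, tax) {
  if (inherits(preds, "te_paths")) return(preds$path)
  if (is.character(preds)) {
    return(lapply(preds, function(p) {
      if (is.na(p) || !nzchar(p)) character(0) else augmented_labels(tax, p)
    }))
  }
  if (is.list(preds)) return(lapply(preds, as.character))
  stop("unsupported prediction format")
}

#' Hierarchical precision, recall and F1
#'
#' Computes set-overlap metrics on ancestor-augmented label sets.  For
#' sample i with true code t_i and predicted path P_i, the augmented truth
#' is T_i = \{t_i\} together with all its proper ancestors (virtual root
#' excluded).  Micro-pooled over samples:
#' \deqn{hP = \sum_i |P_i \cap T_i| / \sum_i |P_i|, \quad
#'       hR = \sum_i |P_i \cap T_i| / \sum_i |T_i|,}
#' and hF1 is their harmonic mean.  Empty denominators yield 0.  With
#' \code{average = "macro"} the ratios are computed per sample and averaged.
#'
#' @param truths Character vector of true class codes.
#' @param preds Predictions: a \code{"te_paths"} object, a character vector
#'   of deepest predicted codes (\code{NA} = unclassified, contributing an
#'   empty predicted set), or a list of path vectors.
#' @param tax The \code{"te_taxonomy"} the labels live in.
#' @param average \code{"micro"} (default) or \code{"macro"}.
#' @return Named numeric vector \code{c(hP, hR, hF1)}.
#' @examples
#' tax <- default_taxonomy()
#' hierarchical_prf("2/1/1", "2/1/2", tax)  # 2/3 everywhere
#' @export
hierarchical_prf <- function(truths, preds, tax,
                             average = c("micro", "macro")) {
  average <- match.arg(average)
  P <- pred_sets(preds, tax)
  if (length(truths) != length(P)) {
    stop("truths and preds have different lengths")
  }
  T <- lapply(truths, function(t) augmented_labels(tax, t))
  inter <- mapply(function(p, t) length(intersect(p, t)), P, T)
  np <- lengths(P)
  nt <- lengths(T)
  if (average == "micro") {
    hP <- if (sum(np) > 0) sum(inter) / sum(np) else 0
    hR <- if (sum(nt) > 0) sum(inter) / sum(nt) else 0
  } else {
    hP <- mean(ifelse(np > 0, inter / np, 0))
    hR <- mean(ifelse(nt > 0, inter / nt, 0))
  }
  hF1 <- if (hP + hR > 0) 2 * hP * hR / (hP + hR) else 0
  c(hP = hP, hR = hR, hF1 = hF1)
}

## truncate a code to at most `depth` components; NA when shallower
truncate_code <- function(codes, depth) {
  vapply(codes, function(code) {
    if (is.na(code)) return(NA_character_)
    comps <- strsplit(code, "/", fixed = TRUE)[[1L]]
    if (length(comps) < depth) return(NA_character_)
    paste(comps[seq_len(depth)], collapse = "/")
  }, character(1), USE.NAMES = FALSE)
}

#' Per-level classification metrics
#'
#' Evaluates the classification at a single taxonomic depth: true and
#' predicted codes are truncated to \code{depth} components, samples whose
#' truth is shallower than \code{depth} are excluded, and precision, recall
#' and F1 are macro-averaged over the classes observed at that depth.
#' Predictions shallower than \code{depth} count as wrong (they miss the
#' truth class without asserting any class at that level).
#'
#' @inheritParams hierarchical_prf
#' @param depth Taxonomic depth (1 = top level).
#' @return Named numeric vector \code{c(precision, recall, F1, n)}; all
#'   \code{NA} with \code{n = 0} when no sample's truth reaches the depth.
#' @export
level_metrics <- function(truths, preds, tax, depth) {
  stopifnot(depth >= 1L)
  P <- pred_sets(preds, tax)
  pred_code <- vapply(P, function(p) {
    if (length(p) == 0L) NA_character_ else p[length(p)]
  }, character(1))
  t_lvl <- truncate_code(truths, depth)
  p_lvl <- truncate_code(pred_code, depth)
  keep <- !is.na(t_lvl)
  if (!any(keep)) {
    return(c(precision = NA_real_, recall = NA_real_, F1 = NA_real_, n = 0))
  }
  t_lvl <- t_lvl[keep]
  p_lvl <- p_lvl[keep]
  classes <- sort(unique(c(t_lvl, p_lvl[!is.na(p_lvl)])))
  pr <- vapply(classes, function(cl) {
    tp <- sum(t_lvl == cl & !is.na(p_lvl) & p_lvl == cl)
    fp <- sum(t_lvl != cl & !is.na(p_lvl) & p_lvl == cl)
    fn <- sum(t_lvl == cl & (is.na(p_lvl) | p_lvl != cl))
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(prec, rec, f1)
  }, numeric(3))
  c(precision = mean(pr[1, ]), recall = mean(pr[2, ]), F1 = mean(pr[3, ]),
    n = sum(keep))
}

#' Per-class F1 and Matthews correlation
#'
#' One-vs-rest metrics for every taxonomy class: a sample counts as positive
#' for class \code{c} when \code{c} belongs to its ancestor-augmented label
#' set (truth side) or to its predicted path (prediction side).  MCC with a
#' zero denominator is reported as 0.
#'
#' @inheritParams hierarchical_prf
#' @param codes Classes to evaluate; defaults to every taxonomy code that is
#'   positive for at least one truth sample.
#' @return Data frame with columns \code{code}, \code{F1}, \code{MCC},
#'   \code{TP}, \code{FP}, \code{FN}, \code{TN}.
#' @export
class_metrics <- function(truths, preds, tax, codes = NULL) {
  P <- pred_sets(preds, tax)
  T <- lapply(truths, function(t) augmented_labels(tax, t))
  if (is.null(codes)) {
    codes <- tax$codes[tax$codes %in% unique(unlist(T))]
  }
  rows <- lapply(codes, function(cl) {
    tpos <- vapply(T, function(s) cl %in% s, logical(1))
    ppos <- vapply(P, function(s) cl %in% s, logical(1))
    tp <- sum(tpos & ppos); fp <- sum(!tpos & ppos)
    fn <- sum(tpos & !ppos); tn <- sum(!tpos & !ppos)
    f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
    den <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
      sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
    mcc <- if (den > 0) (as.numeric(tp) * tn - as.numeric(fp) * fn) / den
           else 0
    data.frame(code = cl, F1 = f1, MCC = mcc, TP = tp, FP = fp, FN = fn,
               TN = tn, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full evaluation report
#'
#' Bundles the three perspectives into one report object.
#'
#' @inheritParams hierarchical_prf
#' @return An object of class \code{"te_evaluation"}: list with
#'   \code{total} (hP/hR/hF1), \code{per_level} (one row per depth),
#'   \code{per_class} (see [class_metrics()]) and \code{n_samples}.
#' @export
evaluate_predictions <- function(truths, preds, tax,
                                 average = c("micro", "macro")) {
  average <- match.arg(average)
  depths <- seq_len(max(vapply(truths, function(t) tax_depth(tax, t),
                               integer(1))))
  per_level <- do.call(rbind, lapply(depths, function(d) {
    data.frame(depth = d, t(level_metrics(truths, preds, tax, d)))
  }))
  out <- list(total = hierarchical_prf(truths, preds, tax, average),
              per_level = per_level,
              per_class = class_metrics(truths, preds, tax),
              n_samples = length(truths),
              average = average)
  class(out) <- "te_evaluation"
  out
}

#' @export
print.te_evaluation <- function(x, ...) {
  cat("Hierarchical evaluation (", x$n_samples, " samples, ", x$average,
      " pooling)\n", sep = "")
  cat(sprintf("  total: hP = %.3f  hR = %.3f  hF1 = %.3f\n",
              x$total["hP"], x$total["hR"], x$total["hF1"]))
  cat("  per level:\n")
  for (i in seq_len(nrow(x$per_level))) {
    r <- x$per_level[i, ]
    cat(sprintf("    depth %d: P = %.3f  R = %.3f  F1 = %.3f  (n = %d)\n",
                r$depth, r$precision, r$recall, r$F1, as.integer(r$n)))
  }
  cat("  per class (F1 / MCC):\n")
  for (i in seq_len(nrow(x$per_class))) {
    r <- x$per_class[i, ]
    cat(sprintf("    %-8s %.3f / %.3f\n", r$code, r$F1, r$MCC))
  }
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Splits the data into \code{folds} folds stratified by leaf label (every
#' class is spread as evenly as possible across folds), fits the configured
#' classifier on each training split and evaluates on the held-out split.
#' The three evaluation perspectives are averaged arithmetically across
#' folds; per-fold reports are retained.
#'
#' @inheritParams te_classifier
#' @param folds Number of folds (default 10).
#' @return A list with \code{mean} (named numeric vector of averaged total
#'   metrics), \code{per_fold} (list of \code{"te_evaluation"} reports) and
#'   \code{fold_assignment}.
#' @export
cross_validate <- function(x, labels, taxonomy = default_taxonomy(),
                           folds = 10L,
                           structure = "binary", strategy = "selective",
                           learner = "random_forest",
                           learner_params = list(), seed = 1L,
                           min_node_examples = 2L) {
  x <- as.matrix(x)
  stopifnot(folds >= 2L, nrow(x) == length(labels))
  if (nrow(x) < folds) stop("fewer samples than folds")
  small <- names(which(table(labels) < folds))
  if (length(small)) {
    warning("class(es) with fewer samples than folds: ",
            paste(small, collapse = ", "))
  }
  set.seed(seed)
  assignment <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    assignment[idx] <- rep_len(seq_len(folds), length(idx))
  }
  reports <- lapply(seq_len(folds), function(f) {
    tr <- assignment != f
    fit <- te_classifier(x[tr, , drop = FALSE], labels[tr], taxonomy,
                         structure = structure, strategy = strategy,
                         learner = learner, learner_params = learner_params,
                         seed = seed + f, min_node_examples = min_node_examples)
    pred <- predict(fit, x[!tr, , drop = FALSE])
    evaluate_predictions(labels[!tr], pred, taxonomy)
  })
  totals <- do.call(rbind, lapply(reports, `[[`, "total"))
  list(mean = colMeans(totals), per_fold = reports,
       fold_assignment = assignment)
}
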