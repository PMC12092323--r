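# Evaluation: one-to-one matching of predicted against ground-truth dot
# coordinates within a pixel tolerance, scored as precision/recall/F1.

#' Match predicted dots against ground truth
#'
#' Pairs within `tolerance` (inclusive Euclidean distance) are candidate
#' matches; a maximum-cardinality one-to-one matching over those candidates
#' (optimal bipartite matching, so the score does not depend on point
#' order) determines true positives. Unmatched predictions are false
#' positives, unmatched ground-truth dots false negatives. A greedy
#' nearest-first mode is available for sensitivity analysis.
#'
#' Empty-versus-empty comparisons score as perfect agreement on absence
#' (precision = recall = F1 = 1); otherwise undefined ratios are 0.
#'
#' @param pred,gt data frames with numeric columns `x`, `y`.
#' @param tolerance matching tolerance in pixels (default 5).
#' @param method `"optimal"` (default) or `"greedy"`.
#' @return object of class `match_report`: counts `tp`, `fp`, `fn`, the
#'   matched index `pairs`, and `precision`, `recall`, `f1`.
#' @export
match_dots <- function(pred, gt, tolerance = 5, method = c("optimal", "greedy")) {
  method <- match.arg(method)
  stopifnot(tolerance >= 0)
  np <- if (is.null(pred)) 0L else nrow(pred)
  ng <- if (is.null(gt)) 0L else nrow(gt)
  pairs <- data.frame(pred = integer(0), gt = integer(0), dist = numeric(0))
  if (np > 0 && ng > 0) {
    dmat <- outer(pred$x, gt$x, `-`)^2 + outer(pred$y, gt$y, `-`)^2
    dmat <- sqrt(dmat)
    cand <- which(dmat <= tolerance, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      if (method == "optimal") {
        g <- igraph::make_bipartite_graph(
          types = c(rep(FALSE, np), rep(TRUE, ng)),
          edges = as.vector(t(cbind(cand[, 1], np + cand[, 2])))
        )
        mm <- igraph::max_bipartite_match(g)$matching
        mp <- mm[seq_len(np)]
        matched <- which(!is.na(mp))
        pairs <- data.frame(pred = matched, gt = as.integer(mp[matched]) - np)
      } else {
        ord <- cand[order(dmat[cand]), , drop = FALSE]
        used_p <- logical(np); used_g <- logical(ng)
        sel <- list()
        for (k in seq_len(nrow(ord))) {
          i <- ord[k, 1]; j <- ord[k, 2]
          if (!used_p[i] && !used_g[j]) {
            used_p[i] <- TRUE; used_g[j] <- TRUE
            sel[[length(sel) + 1]] <- c(i, j)
          }
        }
        sm <- do.call(rbind, sel)
        pairs <- data.frame(pred = sm[, 1], gt = sm[, 2])
      }
      pairs$dist <- dmat[cbind(pairs$pred, pairs$gt)]
      pairs <- pairs[order(pairs$pred), , drop = FALSE]
      rownames(pairs) <- NULL
    }
  }
  tp <- nrow(pairs)
  make_report(tp, np - tp, ng - tp, pairs)
}

make_report <- function(tp, fp, fn, pairs = NULL) {
  if (tp + fp == 0 && tp + fn == 0) {
    precision <- recall <- f1 <- 1
  } else {
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
  }
  structure(list(tp = tp, fp = fp, fn = fn, pairs = pairs,
                 precision = precision, recall = recall, f1 = f1),
            class = "match_report")
}

#' Aggregate match reports across patches
#'
#' Micro-aggregation: true/false positive and false negative counts are
#' summed over patches and precision/recall/F1 recomputed from the sums.
#'
#' @param reports non-empty list of `match_report` objects.
#' @return a `match_report` (without per-pair detail).
#' @export
aggregate_reports <- function(reports) {
  if (length(reports) == 0) stop("no reports to aggregate")
  tp <- sum(vapply(reports, `[[`, numeric(1), "tp"))
  fp <- sum(vapply(reports, `[[`, numeric(1), "fp"))
  fn <- sum(vapply(reports, `[[`, numeric(1), "fn"))
  make_report(tp, fp, fn)
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("match report: TP %d FP %d FN %d | precision %.3f recall %.3f F1 %.3f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}
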