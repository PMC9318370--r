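#' Single-feature ROC AUC via the rank-sum identity
#'
#' AUC equals the probability that a random AF segment outranks a random SR
#' segment (ties counted half), computed from the Mann-Whitney rank sum with
#' midranks.  AF is the positive class; the reported value is oriented as
#' `max(AUC, 1 - AUC)` with the flip recorded in `attr(, "flipped")`.
#'
#' @param table feature table from [build_feature_table()].
#' @param feature feature column name.
#' @return oriented AUC in `[0.5, 1]`; attributes `raw` (unoriented AUC) and
#'   `flipped`.
#' @export
feature_auc <- function(table, feature) {
  stopifnot(feature %in% names(table))
  y <- table$rhythm_class
  if (length(unique(y)) < 2L) stop("both classes must be present")
  x <- table[[feature]]
  r <- rank(x)
  n_pos <- sum(y == "AF")
  n_neg <- sum(y == "SR")
  auc <- (sum(r[y == "AF"]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  out <- max(auc, 1 - auc)
  attr(out, "raw") <- auc
  attr(out, "flipped") <- auc < 0.5
  out
}

#' Rank all features by oriented AUC
#'
#' @param table feature table.
#' @param pool feature names to rank (default all 13).
#' @return a `ranking_result`: method, pool, ranked `order`, `scores`.
#' @export
auc_rank <- function(table, pool = hrv_feature_names()) {
  stopifnot(all(pool %in% names(table)), length(pool) >= 1L)
  scores <- vapply(pool, function(f) as.numeric(feature_auc(table, f)),
                   numeric(1))
  ord <- order(-scores)          # ties keep pool order (stable)
  structure(list(method = "AUC", pool = pool,
                 order = pool[ord], scores = scores[ord], binning = NA),
            class = "ranking_result")
}

# equal-frequency discretization into at most `bins` cells; duplicated
# quantile breaks collapse, so heavily tied columns yield fewer cells
discretize_ef <- function(x, bins) {
  if (is.factor(x) || is.character(x) || is.logical(x)) return(as.factor(x))
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                        names = FALSE, type = 7)
  br <- unique(qs)
  if (length(br) < 2L) return(factor(rep("b1", length(x))))
  cut(x, breaks = br, include.lowest = TRUE)
}

#' Plug-in mutual information from binned histograms
#'
#' Numeric arguments are discretized by equal-frequency binning into at most
#' `bins` cells; categorical arguments (such as the class label) are used as
#' is.  MI is the plug-in estimate of the joint histogram in bits (log base
#' 2); a constant argument carries zero entropy and yields 0.
#'
#' @param x,y feature columns and/or class labels.
#' @param bins maximum number of bins per numeric argument (`>= 2`).
#' @return mutual information in bits (non-negative up to round-off).
#' @export
mutual_information <- function(x, y, bins = 16) {
  stopifnot(bins >= 2, length(x) == length(y))
  if (is.numeric(x) && any(!is.finite(x))) stop("x must be finite")
  if (is.numeric(y) && any(!is.finite(y))) stop("y must be finite")
  xf <- discretize_ef(x, bins)
  yf <- discretize_ef(y, bins)
  joint <- table(xf, yf) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  nz <- joint > 0
  outer_p <- outer(px, py)
  sum(joint[nz] * log2(joint[nz] / outer_p[nz]))
}

#' Greedy minimum-redundancy maximum-relevance feature ranking
#'
#' Relevance is the mutual information between a feature and the class
#' label; redundancy is the mean mutual information between a candidate and
#' the already selected features.  The first pick maximizes relevance; each
#' later pick maximizes the quotient relevance/redundancy (MIQ, default) or
#' the difference relevance - redundancy (MID).  The redundancy denominator
#' is floored at `epsilon` bits to keep duplicated-constant pathologies
#' finite.  Ties break toward the earlier feature in `pool`.
#'
#' @param table feature table (training rows only; feature selection must
#'   never see held-out patients).
#' @param pool feature names to rank.
#' @param bins histogram bins for [mutual_information()].
#' @param criterion `"MIQ"` or `"MID"`.
#' @param epsilon redundancy floor in bits.
#' @return a `ranking_result` with the criterion value at selection time as
#'   each feature's score; the first score equals the maximum relevance in
#'   the pool.
#' @export
mrmr_rank <- function(table, pool = hrv_feature_names(), bins = 16,
                      criterion = c("MIQ", "MID"), epsilon = 1e-12) {
  criterion <- match.arg(criterion)
  stopifnot(length(pool) >= 1L, all(pool %in% names(table)))
  y <- table$rhythm_class
  if (length(unique(y)) < 2L) stop("both classes must be present")
  cols <- lapply(table[pool], identity)
  relevance <- vapply(cols, function(x) mutual_information(x, y, bins),
                      numeric(1))
  red <- matrix(NA_real_, length(pool), length(pool),
                dimnames = list(pool, pool))
  selected <- character()
  scores <- numeric()
  remaining <- pool
  while (length(remaining)) {
    if (!length(selected)) {
      crit <- relevance[remaining]
    } else {
      crit <- vapply(remaining, function(f) {
        for (s in selected) {
          if (is.na(red[f, s])) {
            red[f, s] <<- red[s, f] <<- mutual_information(cols[[f]], cols[[s]], bins)
          }
        }
        r_bar <- mean(red[f, selected])
        if (criterion == "MIQ") relevance[f] / max(r_bar, epsilon)
        else relevance[f] - r_bar
      }, numeric(1))
    }
    best <- remaining[which.max(crit)]   # which.max keeps pool order on ties
    scores <- c(scores, crit[[best]])
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  structure(list(method = "MRMR", pool = pool, order = selected,
                 scores = stats::setNames(scores, selected), binning = bins,
                 criterion = criterion, relevance = relevance),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("<ranking_result> %s over %d features\n", x$method,
              length(x$pool)))
  print(data.frame(rank = seq_along(x$order), feature = x$order,
                   score = round(unname(x$scores), 4)))
  invisible(x)
}

#' Nested prefix feature sets of a ranking
#'
#' The k = 1..k_max best-feature sets used for classifier training: each set
#' is the previous one plus the next-ranked feature.
#'
#' @param result a `ranking_result`.
#' @param k_max number of prefixes (`<= |pool|`).
#' @return list of character vectors of lengths 1..k_max.
#' @export
ranked_prefixes <- function(result, k_max) {
  stopifnot(inherits(result, "ranking_result"),
            k_max >= 1, k_max <= length(result$pool))
  lapply(seq_len(k_max), function(k) result$order[seq_len(k)])
}
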