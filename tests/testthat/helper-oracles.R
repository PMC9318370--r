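# Independent naive oracles: direct loops over the definitions, written
# separately from the package implementation and kept deliberately dumb.

make_segment <- function(rr, adjacency = rep(TRUE, length(rr) - 1L),
                         rhythm = "SR", patient = "T1") {
  structure(list(patient_id = patient, database_tag = "TST",
                 segment_index = 0L, rhythm_class = rhythm,
                 rr_ms = as.numeric(rr), adjacency = adjacency,
                 removed_ms_total = 0, n_removed = 0L),
            class = "rr_segment")
}

naive_sd <- function(x, type = "sample") {
  m <- sum(x) / length(x)
  ss <- 0
  for (v in x) ss <- ss + (v - m)^2
  if (type == "sample") sqrt(ss / (length(x) - 1)) else sqrt(ss / length(x))
}

# feature-by-feature recomputation with explicit loops
naive_features <- function(seg, sd_type = "sample", threshold = 50) {
  rr <- seg$rr_ms
  pr <- list()
  for (j in seq_along(seg$adjacency)) {
    if (seg$adjacency[j]) pr[[length(pr) + 1L]] <- c(rr[j], rr[j + 1L])
  }
  if (length(pr) < 2L) return(NULL)
  d <- vapply(pr, function(p) p[2] - p[1], numeric(1))
  s <- vapply(pr, function(p) p[2] + p[1], numeric(1))
  rat <- vapply(pr, function(p) p[2] / p[1], numeric(1))
  n_ge <- 0L
  for (v in d) if (abs(v) >= threshold) n_ge <- n_ge + 1L
  mean_rr <- sum(rr) / length(rr)
  sdrr <- naive_sd(rr, sd_type)
  rrdif <- sum(abs(d)) / length(d)
  rng <- max(rr) - min(rr)
  sd1 <- naive_sd(d / sqrt(2), sd_type)
  sd2 <- naive_sd(s / sqrt(2), sd_type)
  list(pRR50 = 100 * n_ge / length(d),
       SD1 = sd1, SD2 = sd2,
       SD2_SD1 = if (sd1 == 0) NaN else sd2 / sd1,
       SDRR = sdrr, RRdif = rrdif, CV = sdrr / mean_rr,
       relRRdif = rrdif / mean_rr,
       meanSuccRat = sum(rat) / length(rat),
       SDSuccRat = naive_sd(rat, sd_type),
       meanRR = mean_rr, RRrange = rng, relRRrange = rng / mean_rr,
       valid_pair_count = length(pr))
}

# AUC by exhaustive pair enumeration (AF positive, ties count 1/2)
naive_auc <- function(x, y) {
  pos <- x[y == "AF"]; neg <- x[y == "SR"]
  wins <- 0
  for (a in pos) for (b in neg) {
    wins <- wins + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  wins / (length(pos) * length(neg))
}

# equal-frequency binning + plug-in MI, written independently
naive_bin <- function(x, bins) {
  if (!is.numeric(x)) return(as.character(x))
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               names = FALSE, type = 7))
  if (length(qs) < 2L) return(rep("b", length(x)))
  as.character(cut(x, breaks = qs, include.lowest = TRUE))
}

naive_mi <- function(x, y, bins = 16) {
  xb <- naive_bin(x, bins); yb <- naive_bin(y, bins)
  n <- length(xb)
  mi <- 0
  for (ux in unique(xb)) for (uy in unique(yb)) {
    pxy <- sum(xb == ux & yb == uy) / n
    if (pxy > 0) {
      px <- sum(xb == ux) / n
      py <- sum(yb == uy) / n
      mi <- mi + pxy * log2(pxy / (px * py))
    }
  }
  mi
}

naive_entropy <- function(x, bins = 16) {
  xb <- naive_bin(x, bins)
  p <- table(xb) / length(xb)
  -sum(p * log2(p))
}

# brute-force greedy MRMR: every step recomputes relevance and redundancy
# from scratch with naive_mi
naive_mrmr <- function(table, pool, bins = 16, criterion = "MIQ",
                       eps = 1e-12) {
  y <- table$rhythm_class
  selected <- character()
  remaining <- pool
  while (length(remaining)) {
    best <- NULL; best_val <- -Inf
    for (f in remaining) {
      rel <- naive_mi(table[[f]], y, bins)
      if (!length(selected)) {
        val <- rel
      } else {
        reds <- vapply(selected, function(s2)
          naive_mi(table[[f]], table[[s2]], bins), numeric(1))
        val <- if (criterion == "MIQ") rel / max(mean(reds), eps)
               else rel - mean(reds)
      }
      if (val > best_val + 1e-12) { best_val <- val; best <- f }
    }
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  selected
}

# small random feature table for ranking tests
random_feature_table <- function(n_rows, n_feats, seed) {
  withr::with_seed(seed, {
    y <- rep(c("AF", "SR"), length.out = n_rows)
    tab <- data.frame(rhythm_class = y)
    for (j in seq_len(n_feats)) {
      signal <- stats::rnorm(1, 0, 1.5)
      tab[[paste0("f", j)]] <- stats::rnorm(n_rows) +
        ifelse(y == "AF", signal, 0)
    }
    tab
  })
}

random_segment <- function(seed) {
  withr::with_seed(seed, {
    n <- sample(20:100, 1)
    rr <- stats::runif(n, 300, 1500)
    adj <- stats::runif(n - 1) > 0.1
    make_segment(rr, adj)
  })
}
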