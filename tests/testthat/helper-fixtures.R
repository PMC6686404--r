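# Shared fixtures and independent oracles for the test suite.

# --- independent split-search oracle -----------------------------------
# Self-contained re-derivation of the impurity split search: no shared code
# with the package beyond base R. Enumerates every (feature, midpoint)
# candidate and picks the largest weighted decrease with the same
# deterministic tie-break (decrease, then lower feature index, then lower
# threshold).

oracle_entropy <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

oracle_gini <- function(counts) {
  p <- counts / sum(counts)
  sum(p * (1 - p))
}

oracle_best_split <- function(x, y, N = nrow(x), criterion = "gini",
                              min_leaf = 1L) {
  imp <- if (criterion == "gini") oracle_gini else oracle_entropy
  nt <- nrow(x)
  parent <- c(sum(y == 0), sum(y == 1))
  if (nt < 2 || min(parent) == 0) return(NULL)
  best <- NULL
  for (j in seq_len(ncol(x))) {
    vals <- sort(unique(x[, j]))
    if (length(vals) < 2) next
    mids <- (vals[-1] + vals[-length(vals)]) / 2
    for (thr in mids) {
      sel <- x[, j] <= thr
      if (sum(sel) < min_leaf || sum(!sel) < min_leaf) next
      lc <- c(sum(y[sel] == 0), sum(y[sel] == 1))
      rc <- parent - lc
      dec <- nt / N * (imp(parent) - sum(lc) / nt * imp(lc) -
                         sum(rc) / nt * imp(rc))
      if (is.null(best) || dec > best$decrease + 1e-10)
        best <- list(feature = j, threshold = thr, decrease = dec)
    }
  }
  if (!is.null(best) && best$decrease <= 1e-10) best <- NULL
  best
}

# --- fixture builders ---------------------------------------------------

# one participant row from two threshold vectors
make_record <- function(left, right, id = "p1", community = "test",
                        age = 70, sex = "female") {
  stopifnot(length(left) == 4, length(right) == 4)
  df <- data.frame(id = id, community = community, age = age, sex = sex,
                   stringsAsFactors = FALSE)
  df[c("l500", "l1000", "l2000", "l4000")] <- as.list(left)
  df[c("r500", "r1000", "r2000", "r4000")] <- as.list(right)
  df
}

# small cohort from a list of left/right threshold pairs
make_toy_cohort <- function(pairs, ages = NULL) {
  rows <- lapply(seq_along(pairs), function(i) {
    make_record(pairs[[i]][[1]], pairs[[i]][[2]],
                id = sprintf("p%03d", i),
                age = if (is.null(ages)) 70 else ages[i])
  })
  cohort(do.call(rbind, rows))
}

# random quantized labeled samples for property tests
random_samples <- function(n, seed) {
  set.seed(seed)
  x <- matrix(5 * sample.int(25, n * 4, replace = TRUE) - 15, n, 4)
  colnames(x) <- c("hz500", "hz1000", "hz2000", "hz4000")
  data.frame(x, label = factor(ifelse(rowMeans(x) > 40, "positive", "negative"),
                               levels = c("negative", "positive")))
}

# small, fast generator config for pipeline tests
small_profile <- function(n = 120, community = "mini", seed = 7) {
  generator_config(n = n, community = community, seed = seed)
}
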