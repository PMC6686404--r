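# Depth-limited binary classification tree, written from first principles:
# exhaustive midpoint split search under Gini or Shannon impurity, and
# frequency importances as weighted impurity decreases.

.class_levels <- c("negative", "positive")

.counts_ok <- function(counts) {
  is.numeric(counts) && length(counts) >= 1L && !anyNA(counts) &&
    all(counts >= 0) && sum(counts) > 0
}

#' Shannon entropy of a node's class counts
#'
#' `i(t) = - sum_k p(c_k | t) log2 p(c_k | t)` with the convention
#' `0 * log2(0) = 0`. For a binary node the value lies in \[0, 1\] bits and
#' is maximal (1) at the balanced point.
#'
#' @param counts Non-negative class counts with positive total.
#' @return Entropy in bits.
#' @examples
#' impurity_shannon(c(50, 50))  # 1
#' impurity_shannon(c(90, 10))  # 0.469
#' @export
impurity_shannon <- function(counts) {
  if (!.counts_ok(counts))
    stop("impurity undefined for an empty node", call. = FALSE)
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Gini index of a node's class counts
#'
#' `i(t) = sum_k p(c_k | t) (1 - p(c_k | t))`, which for two classes equals
#' `2 p (1 - p)`: 0 on a pure node, 0.5 at the balanced point.
#'
#' @inheritParams impurity_shannon
#' @return Gini impurity.
#' @examples
#' impurity_gini(c(50, 50))  # 0.5
#' @export
impurity_gini <- function(counts) {
  if (!.counts_ok(counts))
    stop("impurity undefined for an empty node", call. = FALSE)
  p <- counts / sum(counts)
  sum(p * (1 - p))
}

.impurity_fun <- function(criterion) {
  switch(criterion, gini = impurity_gini, shannon = impurity_shannon,
         stop("unknown criterion: ", criterion, call. = FALSE))
}

#' Weighted impurity decrease of a candidate split
#'
#' The importance contribution of a split:
#' `N_t/N * (i(t) - N_tl/N_t * i(t_l) - N_tr/N_t * i(t_r))`,
#' where `N` is the total training sample count and `N_t`, `N_tl`, `N_tr`
#' the sample counts of the node and its left/right children.
#'
#' @param parent,left,right Class-count vectors; `left + right` must equal
#'   `parent`.
#' @param N Total training sample count (>= sum of `parent`).
#' @param criterion `"gini"` or `"shannon"`.
#' @return The weighted decrease (non-negative for an optimal split).
#' @examples
#' importance_decrease(c(50, 50), c(50, 0), c(0, 50), 100)  # 0.5 under Gini
#' @export
importance_decrease <- function(parent, left, right, N,
                                criterion = c("gini", "shannon")) {
  criterion <- match.arg(criterion)
  if (!isTRUE(all.equal(as.numeric(left + right), as.numeric(parent))))
    stop("child class counts must sum to the parent's", call. = FALSE)
  nt <- sum(parent)
  if (N < nt) stop("N must be at least the parent sample count", call. = FALSE)
  imp <- .impurity_fun(criterion)
  child <- function(cts) if (sum(cts) == 0) 0 else sum(cts) / nt * imp(cts)
  nt / N * (imp(parent) - child(left) - child(right))
}

# Tolerance for comparing impurity decreases; ties are then broken by
# frequency order (0.5 -> 4 kHz) and lower threshold via iteration order.
.split_tol <- 1e-10

#' Best axis-aligned split of a node
#'
#' Examines, for every frequency, every candidate threshold placed at the
#' midpoint between consecutive distinct sorted feature values, and returns
#' the candidate with the largest weighted impurity decrease. Deterministic
#' tie-break: larger decrease, then lower frequency, then lower threshold.
#'
#' @param x Numeric matrix of features (samples in rows, the four
#'   frequencies in columns, ordered 0.5, 1, 2, 4 kHz).
#' @param y Class labels (factor or values coercible to
#'   `"negative"`/`"positive"`).
#' @param N Total training sample count used in the decrease weight
#'   (defaults to `nrow(x)`, i.e. the node is the root).
#' @param criterion `"gini"` or `"shannon"`.
#' @param min_leaf Minimum samples each child must retain.
#' @return A list with `feature`, `freq_khz`, `threshold`, `decrease`,
#'   `left_counts`, `right_counts`, or `NULL` when no candidate has a
#'   positive decrease.
#' @export
best_split <- function(x, y, N = nrow(x), criterion = c("gini", "shannon"),
                       min_leaf = 1L) {
  criterion <- match.arg(criterion)
  x <- as.matrix(x)
  yi <- .as_label_int(y)
  nt <- nrow(x)
  parent <- c(sum(yi == 0L), sum(yi == 1L))
  imp <- .impurity_fun(criterion)
  if (nt < 2L || min(parent) == 0L) return(NULL)
  i_parent <- imp(parent)
  best <- NULL
  for (j in seq_len(ncol(x))) {
    ord <- order(x[, j])
    xs <- x[ord, j]
    ys <- yi[ord]
    cum_pos <- cumsum(ys)
    cum_n <- seq_len(nt)
    # split after position i valid where value changes
    cut_at <- which(diff(xs) > 0)
    if (!length(cut_at)) next
    cut_at <- cut_at[cut_at >= min_leaf & (nt - cut_at) >= min_leaf]
    if (!length(cut_at)) next
    for (i in cut_at) {
      lc <- c(i - cum_pos[i], cum_pos[i])
      rc <- parent - lc
      dec <- nt / N *
        (i_parent - i / nt * imp(lc) - (nt - i) / nt * imp(rc))
      if (is.null(best) || dec > best$decrease + .split_tol) {
        best <- list(feature = j, freq_khz = tone_frequencies()[j],
                     threshold = (xs[i] + xs[i + 1]) / 2,
                     decrease = dec,
                     left_counts = lc, right_counts = rc)
      }
    }
  }
  if (!is.null(best) && best$decrease <= .split_tol) best <- NULL
  best
}

.as_label_int <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.logical(y)) return(as.integer(y))
  if (is.numeric(y)) return(as.integer(y != 0))
  if (!all(y %in% .class_levels))
    stop("labels must be 'negative'/'positive'", call. = FALSE)
  as.integer(y == "positive")
}

.sample_matrix <- function(samples) {
  if (inherits(samples, "labeled_samples") ||
      (is.data.frame(samples) && all(.freq_cols %in% names(samples))))
    return(as.matrix(samples[.freq_cols]))
  m <- as.matrix(samples)
  if (ncol(m) != 4L) stop("feature matrix must have four columns", call. = FALSE)
  colnames(m) <- .freq_cols
  m
}

#' Fit a depth-limited classification tree
#'
#' Greedy recursive partitioning of four-frequency threshold vectors into
#' the two screening classes. A node is split unless it is pure, at maximum
#' depth, has fewer than `2 * min_leaf` samples, or no candidate split
#' decreases impurity; leaves predict their majority class, with ties
#' resolved toward the positive (refer) class to favor sensitivity.
#' Per-frequency importances are the summed weighted impurity decreases of
#' the internal nodes using that frequency, normalized to sum to 1 (raw
#' decreases are retained as well).
#'
#' @param samples A `labeled_samples` data frame (see
#'   [make_labeled_samples]), or a matrix acceptable to [best_split] when
#'   `y` is given.
#' @param y Labels, if `samples` is a bare matrix.
#' @param criterion Impurity criterion, `"gini"` (default) or `"shannon"`.
#' @param max_depth Maximum tree depth (root = depth 0); default 2, the
#'   two-tone screening setting. Deeper trees are supported but were not
#'   the design target.
#' @param min_leaf Minimum samples per leaf (default 1).
#' @return An object of class `hearing_tree`.
#' @export
fit_tree <- function(samples, y = NULL, criterion = c("gini", "shannon"),
                     max_depth = 2L, min_leaf = 1L) {
  criterion <- match.arg(criterion)
  x <- .sample_matrix(samples)
  if (is.null(y)) {
    if (!is.data.frame(samples) || is.null(samples$label))
      stop("labels are required to fit a tree", call. = FALSE)
    y <- samples$label
  }
  yi <- .as_label_int(y)
  if (nrow(x) == 0L) stop("cannot fit a tree on an empty sample set", call. = FALSE)
  if (max_depth < 1L) stop("max_depth must be >= 1", call. = FALSE)
  N <- nrow(x)
  imp <- .impurity_fun(criterion)
  next_id <- 0L

  grow <- function(idx, depth) {
    next_id <<- next_id + 1L
    counts <- c(sum(yi[idx] == 0L), sum(yi[idx] == 1L))
    node <- list(id = next_id, depth = depth, n = length(idx),
                 counts = counts, impurity = imp(counts),
                 # majority class; tie -> positive (screen-sensitive choice)
                 class = .class_levels[(counts[2] >= counts[1]) + 1L],
                 leaf = TRUE)
    if (min(counts) > 0L && depth < max_depth && length(idx) >= 2L * min_leaf) {
      sp <- best_split(x[idx, , drop = FALSE], yi[idx], N = N,
                       criterion = criterion, min_leaf = min_leaf)
      if (!is.null(sp)) {
        go_left <- x[idx, sp$feature] <= sp$threshold
        node$leaf <- FALSE
        node$feature <- sp$feature
        node$freq_khz <- sp$freq_khz
        node$threshold <- sp$threshold
        node$decrease <- sp$decrease
        node$left <- grow(idx[go_left], depth + 1L)
        node$right <- grow(idx[!go_left], depth + 1L)
      }
    }
    node
  }

  root <- grow(seq_len(N), 0L)
  raw <- numeric(4L)
  walk <- function(nd) {
    if (!nd$leaf) {
      raw[nd$feature] <<- raw[nd$feature] + nd$decrease
      walk(nd$left); walk(nd$right)
    }
  }
  walk(root)
  names(raw) <- .freq_cols
  importance <- if (sum(raw) > 0) raw / sum(raw) else raw
  structure(list(root = root, criterion = criterion,
                 max_depth = as.integer(max_depth),
                 min_leaf = as.integer(min_leaf), N = N,
                 importance = importance, raw_importance = raw),
            class = "hearing_tree")
}

#' @export
print.hearing_tree <- function(x, ...) {
  cat(sprintf("Depth-%d classification tree (%s impurity), N = %d\n",
              tree_depth(x), x$criterion, x$N))
  show <- function(nd, indent) {
    pad <- strrep("  ", indent)
    if (nd$leaf) {
      cat(sprintf("%s* leaf: %s (neg %d / pos %d)\n", pad, nd$class,
                  nd$counts[1], nd$counts[2]))
    } else {
      cat(sprintf("%s%g kHz <= %g dB HL? (neg %d / pos %d, i = %.4f)\n",
                  pad, nd$freq_khz, nd$threshold, nd$counts[1], nd$counts[2],
                  nd$impurity))
      show(nd$left, indent + 1L)
      show(nd$right, indent + 1L)
    }
  }
  show(x$root, 0L)
  cat("frequency importance:",
      paste(sprintf("%g kHz = %.3f", tone_frequencies(), x$importance),
            collapse = ", "), "\n")
  invisible(x)
}

#' Depth of a fitted tree
#' @param tree A `hearing_tree`.
#' @return Integer depth (0 for a single leaf).
#' @export
tree_depth <- function(tree) {
  d <- function(nd) if (nd$leaf) 0L else 1L + max(d(nd$left), d(nd$right))
  d(tree$root)
}

#' Predict screening classes from a fitted tree
#'
#' Routes each sample left when its feature value is less than or equal to
#' the node threshold, and returns the leaf's class.
#'
#' @param object A `hearing_tree` from [fit_tree].
#' @param newdata `labeled_samples`, data frame with `hz*` columns, or a
#'   4-column matrix.
#' @param ... Unused.
#' @return Factor of `"negative"`/`"positive"` predictions.
#' @export
predict.hearing_tree <- function(object, newdata, ...) {
  if (is.null(object$root)) stop("tree is not fitted", call. = FALSE)
  x <- .sample_matrix(newdata)
  one <- function(v) {
    nd <- object$root
    while (!nd$leaf)
      nd <- if (v[nd$feature] <= nd$threshold) nd$left else nd$right
    nd$class
  }
  factor(apply(x, 1L, one), levels = .class_levels)
}

#' Do Gini and Shannon criteria select the same tree?
#'
#' Fits one tree per impurity criterion and compares the selected
#' (frequency, threshold) pair at every internal node position.
#'
#' @inheritParams fit_tree
#' @return List with `agree` (logical), the two trees, and a data frame of
#'   per-node comparisons.
#' @export
gini_entropy_agreement <- function(samples, y = NULL, max_depth = 2L,
                                   min_leaf = 1L) {
  tg <- fit_tree(samples, y, criterion = "gini", max_depth = max_depth,
                 min_leaf = min_leaf)
  ts <- fit_tree(samples, y, criterion = "shannon", max_depth = max_depth,
                 min_leaf = min_leaf)
  rows <- list()
  cmp <- function(a, b, pos) {
    if (a$leaf && b$leaf) return(invisible())
    rows[[length(rows) + 1L]] <<- data.frame(
      position = pos,
      gini_freq = if (a$leaf) NA_real_ else a$freq_khz,
      gini_threshold = if (a$leaf) NA_real_ else a$threshold,
      shannon_freq = if (b$leaf) NA_real_ else b$freq_khz,
      shannon_threshold = if (b$leaf) NA_real_ else b$threshold)
    if (!a$leaf && !b$leaf) {
      cmp(a$left, b$left, paste0(pos, "L"))
      cmp(a$right, b$right, paste0(pos, "R"))
    }
  }
  cmp(tg$root, ts$root, "root")
  nodes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = character(), gini_freq = numeric(),
               gini_threshold = numeric(), shannon_freq = numeric(),
               shannon_threshold = numeric())
  agree <- nrow(nodes) == 0L ||
    (all(!is.na(nodes$gini_freq) == !is.na(nodes$shannon_freq)) &&
       isTRUE(all.equal(nodes$gini_freq, nodes$shannon_freq)) &&
       isTRUE(all.equal(nodes$gini_threshold, nodes$shannon_threshold)))
  list(agree = agree, gini = tg, shannon = ts, nodes = nodes)
}

#' Serialize / restore a fitted tree (JSON)
#'
#' Writes the node structure (counts, impurities, splits) and the
#' importances to a JSON file reusable by the screening module.
#'
#' @param tree A `hearing_tree`.
#' @param path JSON file path.
#' @return `write_tree` returns `path` invisibly; `read_tree` a
#'   `hearing_tree`.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "hearing_tree"))
  jsonlite::write_json(unclass(tree), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix <- function(nd) {
    nd$counts <- as.numeric(nd$counts)
    if (!is.null(nd$left)) { nd$left <- fix(nd$left); nd$right <- fix(nd$right) }
    nd
  }
  obj$root <- fix(obj$root)
  obj$importance <- stats::setNames(as.numeric(obj$importance), .freq_cols)
  obj$raw_importance <- stats::setNames(as.numeric(obj$raw_importance), .freq_cols)
  structure(obj, class = "hearing_tree")
}
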