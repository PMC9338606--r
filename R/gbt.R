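# Histogram-based gradient-boosted trees with logistic loss.
#
# Design notes (why hand-rolled): the classifier needs missing-direction
# splits (absence of a junction, RVIS, or downstream ATG is informative) and
# byte-reproducible training. Features are quantile-binned once; each node
# accumulates gradient/hessian histograms (C++ kernel) and the best split is
# chosen by the usual second-order gain with the missing bin routed to
# whichever side scores higher. Leaves take Newton steps -G/(H+lambda).

gbt_default_params <- function() {
  list(n_trees = 150L, eta = 0.1, max_depth = 3L, min_child_weight = 5,
       lambda = 1, max_bins = 255L, min_node = 10L)
}

gbt_bin_features <- function(X, max_bins) {
  p <- ncol(X)
  breaks <- vector("list", p)
  bins <- matrix(0L, nrow(X), p)
  for (j in seq_len(p)) {
    x <- X[, j]
    fin <- x[is.finite(x)]
    br <- if (length(fin)) {
      q <- unique(stats::quantile(fin, probs = seq_len(max_bins - 1L) / max_bins,
                                  type = 1, names = FALSE))
      sort(unique(q))
    } else numeric(0)
    breaks[[j]] <- br
    b <- rep(0L, nrow(X))
    ok <- is.finite(x)
    # bin t holds x in (br[t-1], br[t]]; last bin is (br[B-1], Inf)
    b[ok] <- findInterval(x[ok], br, left.open = TRUE) + 1L
    bins[, j] <- b
  }
  list(bins = bins, breaks = breaks)
}

# Best split for one node from its histograms. hist: array(3, nbins+1, p)
# with slices [g, h, count]; bin 1 of dim 2 is the missing bin.
gbt_best_split <- function(hist, breaks, lambda, min_child_weight, min_node) {
  p <- dim(hist)[3L]
  if (p == 0L) return(NULL)
  nb <- dim(hist)[2L] - 1L
  leaf_score <- function(G, H) G * G / (H + lambda)
  best <- list(gain = 0)
  # totals identical across features; feature 1 suffices
  Gt <- sum(hist[1L, , 1L]); Ht <- sum(hist[2L, , 1L]); Ct <- sum(hist[3L, , 1L])
  parent <- leaf_score(Gt, Ht)
  for (j in seq_len(p)) {
    nbr <- length(breaks[[j]])
    if (nb < 2L || nbr < 1L) next
    g0 <- hist[1L, 1L, j]; h0 <- hist[2L, 1L, j]; c0 <- hist[3L, 1L, j]
    gb <- hist[1L, -1L, j]; hb <- hist[2L, -1L, j]; cb <- hist[3L, -1L, j]
    GL <- cumsum(gb)[-nb]; HL <- cumsum(hb)[-nb]; CL <- cumsum(cb)[-nb]
    GR <- (Gt - g0) - GL; HR <- (Ht - h0) - HL; CR <- (Ct - c0) - CL
    has_break <- seq_len(nb - 1L) <= nbr  # split bin must map to a real cut
    for (miss_left in c(TRUE, FALSE)) {
      gl <- GL + if (miss_left) g0 else 0; hl <- HL + if (miss_left) h0 else 0
      cl <- CL + if (miss_left) c0 else 0
      gr <- GR + if (miss_left) 0 else g0; hr <- HR + if (miss_left) 0 else h0
      cr <- CR + if (miss_left) 0 else c0
      ok <- has_break & cl >= min_node & cr >= min_node &
        hl >= min_child_weight & hr >= min_child_weight
      if (!any(ok)) next
      gain <- leaf_score(gl, hl) + leaf_score(gr, hr) - parent
      gain[!ok] <- -Inf
      t <- which.max(gain)
      if (gain[t] > best$gain + 1e-12) {
        best <- list(gain = gain[t], feature = j, split_bin = t,
                     miss_left = miss_left)
      }
    }
  }
  if (is.null(best$feature)) NULL else best
}

gbt_grow_tree <- function(bins, breaks, rows, g, h, params) {
  nodes <- list()
  new_node <- function() length(nodes) + 1L
  grow <- function(rows, depth) {
    id <- new_node()
    nodes[[id]] <<- list(leaf = TRUE, value = 0)
    G <- sum(g[rows]); H <- sum(h[rows])
    split <- NULL
    if (depth < params$max_depth && length(rows) >= 2L * params$min_node) {
      hist <- array(gbt_node_hist(bins, rows, g, h,
                                  nbins = params$max_bins),
                    dim = c(3L, params$max_bins + 1L, ncol(bins)))
      split <- gbt_best_split(hist, breaks, params$lambda,
                              params$min_child_weight, params$min_node)
    }
    if (is.null(split)) {
      nodes[[id]] <<- list(leaf = TRUE,
                           value = -params$eta * G / (H + params$lambda),
                           rows = rows)
      return(id)
    }
    part <- gbt_partition(bins, rows, split$feature, split$split_bin,
                          split$miss_left)
    left <- grow(part$left, depth + 1L)
    right <- grow(part$right, depth + 1L)
    br <- breaks[[split$feature]]
    t <- split$split_bin
    # cut halfway between adjacent cut points so held-out values falling in
    # the empty margin between classes are routed sensibly
    thr <- if (t < length(br)) (br[t] + br[t + 1L]) / 2 else br[t]
    nodes[[id]] <<- list(leaf = FALSE, feature = split$feature,
                         threshold = thr,
                         miss_left = split$miss_left,
                         left = left, right = right)
    id
  }
  grow(rows, 0L)
  nodes
}

# Vectorised tree application on raw features. Rule: x <= threshold -> left;
# missing -> stored direction.
gbt_apply_tree <- function(nodes, X) {
  out <- numeric(nrow(X))
  recurse <- function(id, rows) {
    nd <- nodes[[id]]
    if (nd$leaf) { out[rows] <<- nd$value; return(invisible()) }
    x <- X[rows, nd$feature]
    go_left <- ifelse(is.na(x), nd$miss_left, x <= nd$threshold)
    recurse(nd$left, rows[go_left])
    recurse(nd$right, rows[!go_left])
  }
  if (nrow(X)) recurse(1L, seq_len(nrow(X)))
  out
}

#' Fit a gradient-boosted tree classifier
#'
#' Binary logistic boosting over depth-limited regression trees with
#' second-order (Newton) leaf updates and native missing-value routing:
#' at each split the missing bin is sent to whichever child maximises the
#' gain, so `NA` is a first-class feature value. Training is deterministic —
#' no subsampling, no RNG.
#'
#' @param X Numeric matrix (may contain `NA`).
#' @param y 0/1 labels.
#' @param params List overriding [gbt_default_params()]: `n_trees`, `eta`,
#'   `max_depth`, `min_child_weight`, `lambda`, `max_bins`, `min_node`.
#' @return A `gbt_model`.
#' @export
gbt_fit <- function(X, y, params = list()) {
  stopifnot(is.matrix(X), nrow(X) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) stop("gbt_fit needs both classes present")
  params <- utils::modifyList(gbt_default_params(), params)
  bn <- gbt_bin_features(X, params$max_bins)
  n <- nrow(X)
  f0 <- log(mean(y) / (1 - mean(y)))
  Fx <- rep(f0, n)
  trees <- vector("list", params$n_trees)
  rows_all <- seq_len(n)
  for (m in seq_len(params$n_trees)) {
    p <- 1 / (1 + exp(-Fx))
    g <- p - y
    h <- pmax(p * (1 - p), 1e-12)
    nodes <- gbt_grow_tree(bn$bins, bn$breaks, rows_all, g, h, params)
    # leaf rows were recorded during growth; update F without re-predicting
    for (nd in nodes) if (nd$leaf) Fx[nd$rows] <- Fx[nd$rows] + nd$value
    trees[[m]] <- lapply(nodes, function(nd) {
      if (nd$leaf) list(leaf = TRUE, value = nd$value) else nd
    })
  }
  structure(list(trees = trees, f0 = f0, params = params,
                 feature_names = colnames(X)),
            class = "gbt_model")
}

#' Predict probabilities from a fitted GBT
#'
#' @param object A `gbt_model`.
#' @param X Numeric matrix with the training columns (order enforced by name
#'   when `colnames` are present).
#' @export
gbt_predict <- function(object, X) {
  stopifnot(inherits(object, "gbt_model"), is.matrix(X))
  if (!is.null(object$feature_names) && !is.null(colnames(X))) {
    if (!setequal(colnames(X), object$feature_names))
      stop("feature columns do not match training schema")
    X <- X[, object$feature_names, drop = FALSE]
  }
  Fx <- rep(object$f0, nrow(X))
  for (tr in object$trees) Fx <- Fx + gbt_apply_tree(tr, X)
  1 / (1 + exp(-Fx))
}
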