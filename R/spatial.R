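#' Gaussian-smoothed spike signal
#'
#' Converts a spike train into a binary mask at frame resolution and
#' convolves it with a unit-area Gaussian kernel (sigma = 2 samples,
#' truncated at +/- 3 sigma, i.e. a 6-sigma total support) to reduce
#' frame-level timing variability before correlating spike trains.
#'
#' @param spike_frames integer frame indices of spikes.
#' @param n_frames length of the output signal.
#' @param sigma kernel sd in samples (default 2).
#' @return numeric vector of length `n_frames`; a single spike sums to 1.
#' @export
smoothed_spike_signal <- function(spike_frames, n_frames, sigma = 2) {
  mask <- numeric(n_frames)
  sf <- spike_frames[spike_frames >= 1 & spike_frames <= n_frames]
  mask[sf] <- mask[sf] + 1
  half <- 3 * sigma
  off <- seq(-half, half)
  k <- exp(-off^2 / (2 * sigma^2))
  k <- k / sum(k)
  out <- numeric(n_frames)
  for (j in seq_along(off)) {
    sh <- off[j]
    src <- seq_len(n_frames)
    dst <- src + sh
    ok <- dst >= 1 & dst <= n_frames
    out[dst[ok]] <- out[dst[ok]] + k[j] * mask[src[ok]]
  }
  out
}

#' Pairwise Pearson correlation matrix
#'
#' @param signals numeric matrix (rows = samples, columns = neurons) or a
#'   `ts_sig`.
#' @param source tag recorded with the result ("voltage" or
#'   "smoothed_spikes").
#' @param window optional c(start, end) row indices restricting the
#'   correlation window (e.g. the stimulation epoch).
#' @return object of class `corr_matrix`: `r` (n x n, unit diagonal),
#'   `source`, `valid` (FALSE for zero-variance neurons, whose rows/columns
#'   are NA and excluded downstream).
#' @export
correlation_matrix <- function(signals, source = "voltage", window = NULL) {
  if (inherits(signals, "ts_sig")) signals <- signals$data
  signals <- as.matrix(signals)
  if (ncol(signals) < 2) stopf("need at least 2 neurons")
  if (!is.null(window)) signals <- signals[window[1]:window[2], , drop = FALSE]
  v <- apply(signals, 2, var)
  valid <- v > 0
  r <- matrix(NA_real_, ncol(signals), ncol(signals))
  if (any(valid)) r[valid, valid] <- cor(signals[, valid, drop = FALSE])
  diag(r) <- 1
  structure(list(r = r, source = source, valid = valid), class = "corr_matrix")
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat(sprintf("<corr_matrix> %d neurons (%s), %d zero-variance excluded\n",
              nrow(x$r), x$source, sum(!x$valid)))
  invisible(x)
}

#' Hierarchical clustering with the inconsistency criterion
#'
#' Agglomerative average-linkage clustering on the correlation distance
#' d = 1 - r. Each dendrogram link receives an inconsistency coefficient
#' (its height's z-score against the heights of links within two levels
#' below, including itself; 0 where the sd is 0); the tree is cut into the
#' maximal subtrees whose links are all consistent (coefficient <=
#' `threshold`). Leaves are ordered by exact optimal leaf ordering
#' (minimizing the summed distance between adjacent leaves) for n <= 60,
#' falling back to the agglomeration order beyond.
#'
#' @param corr a [correlation_matrix()] result (or plain correlation
#'   matrix).
#' @param threshold inconsistency cutoff (default 1.1).
#' @param depth levels below a link included in its inconsistency statistic
#'   (default 2 = the link and its immediate children).
#' @return object of class `cluster_result`: `labels` (1..K), `k`,
#'   `hclust`, `inconsistency` (per-link table), `leaf_order`, `threshold`.
#' @export
cluster_hierarchical <- function(corr, threshold = 1.1, depth = 2) {
  r <- if (inherits(corr, "corr_matrix")) corr$r else as.matrix(corr)
  valid <- if (inherits(corr, "corr_matrix")) corr$valid else rep(TRUE, nrow(r))
  n_all <- nrow(r)
  if (sum(valid) < 2) stopf("need at least 2 valid neurons")
  rv <- r[valid, valid, drop = FALSE]
  d <- 1 - rv
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  inc <- inconsistency_coefficients(hc, depth = depth)
  labs_v <- cut_inconsistent(hc, inc$coefficient, threshold)
  order_v <- optimal_leaf_order(hc, d)
  labels <- rep(NA_integer_, n_all)
  labels[valid] <- labs_v
  leaf_order <- which(valid)[order_v]
  structure(list(labels = labels, k = max(labs_v), hclust = hc,
                 inconsistency = inc, leaf_order = leaf_order,
                 threshold = threshold, valid = valid),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d neurons in %d clusters (inconsistency cutoff %.2f)\n",
              sum(x$valid), x$k, x$threshold))
  print(table(cluster = x$labels[x$valid]))
  invisible(x)
}

#' @export
plot.cluster_result <- function(x, ...) {
  graphics::plot(x$hclust, labels = FALSE, main = "average-linkage dendrogram, d = 1 - r",
                 xlab = "", sub = "", ...)
  invisible(x)
}

#' Inconsistency coefficients of dendrogram links
#'
#' For each link, collect the heights of all links within `depth` levels
#' below it (the link itself = level 1, its children links = level 2, ...);
#' the coefficient is (height - mean) / sd of that set, with 0 where the sd
#' is 0 (e.g. a link over two leaves, or all-equal heights).
#'
#' @param hc an `hclust` object.
#' @param depth number of levels included (default 2).
#' @return data.frame: link, height, n_links, mean, sd, coefficient.
#' @export
inconsistency_coefficients <- function(hc, depth = 2) {
  m <- hc$merge
  h <- hc$height
  nl <- nrow(m)
  out <- data.frame(link = seq_len(nl), height = h, n_links = NA_real_,
                    mean = NA_real_, sd = NA_real_, coefficient = NA_real_)
  for (k in seq_len(nl)) {
    hs <- h[k]
    frontier <- k
    lev <- 1
    while (lev < depth) {
      kids <- unlist(lapply(frontier, function(j) m[j, m[j, ] > 0]))
      if (!length(kids)) break
      hs <- c(hs, h[kids])
      frontier <- kids
      lev <- lev + 1
    }
    mu <- mean(hs)
    s <- if (length(hs) > 1) sd(hs) else 0
    out$n_links[k] <- length(hs)
    out$mean[k] <- mu
    out$sd[k] <- s
    out$coefficient[k] <- if (s > 0) (h[k] - mu) / s else 0
  }
  out
}

# cut into maximal subtrees whose links are all consistent (coef <= thr)
cut_inconsistent <- function(hc, coef, threshold) {
  m <- hc$merge
  nl <- nrow(m)
  n <- nl + 1L
  consistent <- logical(nl)       # link and everything below it consistent
  for (k in seq_len(nl)) {
    kids <- m[k, m[k, ] > 0]
    consistent[k] <- coef[k] <= threshold && all(consistent[kids])
  }
  labels <- integer(n)
  nextlab <- 0L
  assign_subtree <- function(node, lab) {
    # node: negative = leaf index, positive = link
    if (node < 0) {
      labels[-node] <<- lab
    } else {
      assign_subtree(m[node, 1], lab)
      assign_subtree(m[node, 2], lab)
    }
  }
  walk <- function(node) {
    if (node < 0) {
      nextlab <<- nextlab + 1L
      labels[-node] <<- nextlab
    } else if (consistent[node]) {
      nextlab <<- nextlab + 1L
      assign_subtree(node, nextlab)
    } else {
      walk(m[node, 1])
      walk(m[node, 2])
    }
  }
  walk(nl)  # root is the last merge
  labels
}

#' Exact optimal leaf ordering of a dendrogram
#'
#' Dynamic program over the merge tree finding, among all 2^(n-1) orderings
#' consistent with the dendrogram, one minimizing the sum of distances
#' between adjacent leaves.
#'
#' @param hc an `hclust` object.
#' @param d distance matrix used for the clustering (full matrix form).
#' @param max_exact beyond this leaf count the agglomeration order is
#'   returned unchanged (the exact DP is cubic in n).
#' @return integer permutation of 1..n (leaf indices left to right).
#' @export
optimal_leaf_order <- function(hc, d, max_exact = 60) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n > max_exact) return(hc$order)
  m <- hc$merge
  nl <- nrow(m)
  leaves <- vector("list", nl)   # leaf sets per link
  M <- vector("list", nl)        # cost matrices (u = leftmost, w = rightmost)
  BM <- vector("list", nl)       # backpointers: chosen m (right edge of left block)
  BH <- vector("list", nl)       # chosen h (left edge of right block)
  leafset <- function(node) if (node < 0) -node else leaves[[node]]
  getM <- function(node) {
    if (node < 0) {
      mat <- matrix(0, 1, 1, dimnames = list(-node, -node))
      return(mat)
    }
    M[[node]]
  }
  for (k in seq_len(nl)) {
    L <- m[k, 1]; R <- m[k, 2]
    ll <- leafset(L); rl <- leafset(R)
    leaves[[k]] <- c(ll, rl)
    ML <- getM(L); MR <- getM(R)
    nL <- length(ll); nR <- length(rl)
    # best over h for each (mm, w): inner[mm, w] = min_h d[mm, h] + MR[h, w]
    inner <- matrix(Inf, nL, nR)
    argh <- matrix(NA_integer_, nL, nR)
    for (wi in seq_len(nR)) {
      v <- d[ll, rl, drop = FALSE] + matrix(MR[, wi], nL, nR, byrow = TRUE)
      argh[, wi] <- max.col(-v, ties.method = "first")
      inner[, wi] <- v[cbind(seq_len(nL), argh[, wi])]
    }
    cost <- matrix(Inf, nL, nR, dimnames = list(ll, rl))
    bm <- matrix(NA_integer_, nL, nR)
    bh <- matrix(NA_integer_, nL, nR)
    for (ui in seq_len(nL)) {
      v <- matrix(ML[ui, ], nL, nR) + inner     # over (mm, w)
      bm[ui, ] <- max.col(-t(v), ties.method = "first")
      cost[ui, ] <- v[cbind(bm[ui, ], seq_len(nR))]
      bh[ui, ] <- argh[cbind(bm[ui, ], seq_len(nR))]
    }
    M[[k]] <- rbind(cbind(matrix(Inf, nL, nL), cost),
                    cbind(t(cost), matrix(Inf, nR, nR)))
    dimnames(M[[k]]) <- list(c(ll, rl), c(ll, rl))
    BM[[k]] <- bm; BH[[k]] <- bh
  }
  root <- nl
  best <- which(M[[root]] == min(M[[root]]), arr.ind = TRUE)[1, ]
  rec <- function(node, u, w) {
    if (node < 0) return(-node)
    L <- m[node, 1]; R <- m[node, 2]
    ll <- leafset(L); rl <- leafset(R)
    if (u %in% rl) return(rev(rec(node, w, u)))
    ui <- match(u, ll); wi <- match(w, rl)
    mm <- ll[BM[[node]][ui, wi]]
    hh <- rl[BH[[node]][ui, wi]]
    c(rec(L, u, mm), rec(R, hh, w))
  }
  u <- leaves[[root]][best[1]]
  w <- leaves[[root]][best[2]]
  rec(root, u, w)
}

#' Distance dependence of pairwise correlations
#'
#' Ordinary least squares of pairwise correlation on pairwise Euclidean
#' centroid distance (in micrometers).
#'
#' @param corr a [correlation_matrix()] result or correlation matrix.
#' @param positions n x 2 matrix of pixel centroids.
#' @param um_per_px micrometers per pixel (default 1).
#' @return list of class `dist_regression`: `slope` (per um), `intercept`,
#'   `r_squared`, `pairs` (data.frame distance_um, r).
#' @export
distance_dependence <- function(corr, positions, um_per_px = 1) {
  r <- if (inherits(corr, "corr_matrix")) corr$r else as.matrix(corr)
  n <- nrow(r)
  if (nrow(positions) != n) stopf("positions must have one row per neuron")
  ut <- which(upper.tri(r), arr.ind = TRUE)
  dx <- (positions[ut[, 1], 1] - positions[ut[, 2], 1]) * um_per_px
  dy <- (positions[ut[, 1], 2] - positions[ut[, 2], 2]) * um_per_px
  dist_um <- sqrt(dx^2 + dy^2)
  rv <- r[ut]
  ok <- !is.na(rv)
  fit <- lm(rv[ok] ~ dist_um[ok])
  structure(list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 pairs = data.frame(distance_um = dist_um, r = rv)),
            class = "dist_regression")
}

#' @export
print.dist_regression <- function(x, ...) {
  cat(sprintf("<dist_regression> slope %.3g per um, R^2 = %.4f (%d pairs)\n",
              x$slope, x$r_squared, nrow(x$pairs)))
  invisible(x)
}
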