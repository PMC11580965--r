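#' Per-square detection counts for one feature on a section
#'
#' Covers the section with a grid of sigma x sigma squares (half-open
#' membership: a point exactly on an edge belongs to the higher-index
#' square) and counts detections per square.
#'
#' @param points Two-column matrix or data frame of in-section coordinates
#'   (micrometers) of the detections of a single feature.
#' @param sigma Square edge (default 50).
#' @param origin Grid origin, length-2; defaults to the data minimum.
#' @param dims Optional grid dimensions `c(nx, ny)`; defaults to the
#'   smallest grid covering the points.
#' @return An object of class `grid_counts`: integer matrix `counts`
#'   (nx x ny), `origin`, `sigma`.
#' @export
grid_counts <- function(points, sigma = 50, origin = NULL, dims = NULL) {
  points <- as.matrix(as.data.frame(points)[, 1:2])
  if (sigma <= 0) stop("'sigma' must be > 0")
  if (is.null(origin)) origin <- apply(points, 2L, min)
  ix <- floor((points[, 1] - origin[1]) / sigma)
  iy <- floor((points[, 2] - origin[2]) / sigma)
  if (any(ix < 0) || any(iy < 0)) stop("points fall below the grid origin")
  if (is.null(dims)) dims <- c(max(ix) + 1L, max(iy) + 1L)
  counts <- matrix(0L, dims[1], dims[2])
  tab <- table(factor(ix + 1L, levels = seq_len(dims[1])),
               factor(iy + 1L, levels = seq_len(dims[2])))
  counts[] <- as.integer(tab)
  structure(list(counts = counts, origin = as.numeric(origin), sigma = sigma),
            class = "grid_counts")
}

#' Quantile binning of per-square counts
#'
#' Discretizes a count grid by empirical-CDF quantile thresholds
#' \eqn{t_k = \inf\{t \ge 0 : F(t) \ge k/q\}}, assigning each square the bin
#' \eqn{\phi(n) = \sum_k 1\{n \ge t_k\} \in [0, q]} (non-decreasing in the
#' raw count).
#'
#' @param counts A [grid_counts()] object or a numeric matrix of counts.
#' @param q Number of quantiles (>= 2), default 10.
#' @return A list of class `binned_grid`: integer matrix `bins` (same shape
#'   as the counts), `thresholds` (the \eqn{t_k}), `q`.
#' @export
quantile_bin <- function(counts, q = 10) {
  if (q < 2) stop("'q' must be >= 2")
  m <- if (inherits(counts, "grid_counts")) counts$counts else as.matrix(counts)
  v <- sort(as.numeric(m))
  n <- length(v)
  thresholds <- v[pmin(pmax(ceiling(seq_len(q) / q * n), 1L), n)]
  bins <- matrix(rowSums(outer(as.numeric(m), thresholds, `>=`)),
                 nrow(m), ncol(m))
  structure(list(bins = bins, thresholds = thresholds, q = q),
            class = "binned_grid")
}

#' Megasquare partitioning scheme for the spatial-variability score
#'
#' Megasquares are contiguous 2K x 2K blocks of grid squares; each is split
#' into two halves either vertically or horizontally.  The score asks how
#' predictive the half containing a square is of the square's binned count.
#'
#' @param K Half-width in squares (megasquares are 2K x 2K), default 4.
#' @param stride Step between megasquare corners (default 1 = all blocks).
#' @param min_support_frac Minimum fraction of in-support squares a
#'   megasquare must contain (default 0.5).
#' @return An object of class `megasquare_scheme`.
#' @export
megasquare_scheme <- function(K = 4, stride = 1, min_support_frac = 0.5) {
  if (K < 1) stop("'K' must be >= 1")
  structure(list(K = as.integer(K), stride = as.integer(stride),
                 min_support_frac = min_support_frac),
            class = "megasquare_scheme")
}

#' Conditional mutual-information spatial-variability score
#'
#' Draws (uniformly) a megasquare, one of its squares, and a split direction;
#' records which half the square fell in (`X`, in \{left, right, bottom,
#' top\}) and the square's quantile bin (`M`).  The score is the conditional
#' mutual information \eqn{I(X; M \mid C)} (in nats), computed exactly from
#' the empirical joint counts.  Spatially constant fields score exactly 0.
#'
#' @param binned A [quantile_bin()] result (or a plain bin matrix).
#' @param scheme A [megasquare_scheme()].
#' @param support Optional logical matrix (same shape as the grid) marking
#'   in-tissue squares; megasquares with fewer than `min_support_frac`
#'   supported squares are excluded.
#' @return A list of class `mi_score`: `mi` (nats), `mi_scaled` (nats times
#'   `|Omega|`, the count-scaled variant), `n_megasquares`, `omega`.
#' @export
mi_score <- function(binned, scheme = megasquare_scheme(), support = NULL) {
  b <- if (inherits(binned, "binned_grid")) binned$bins else as.matrix(binned)
  K <- scheme$K
  side <- 2L * K
  nx <- nrow(b); ny <- ncol(b)
  if (nx < side || ny < side)
    stop(sprintf("grid (%d x %d) cannot contain a %d x %d megasquare",
                 nx, ny, side, side))
  corners_x <- seq(1L, nx - side + 1L, by = scheme$stride)
  corners_y <- seq(1L, ny - side + 1L, by = scheme$stride)
  vals <- sort(unique(as.numeric(b)))
  total_i <- 0
  n_ms <- 0L
  for (cx in corners_x) for (cy in corners_y) {
    if (!is.null(support)) {
      frac <- mean(support[cx:(cx + side - 1L), cy:(cy + side - 1L)])
      if (frac < scheme$min_support_frac) next
    }
    blk <- b[cx:(cx + side - 1L), cy:(cy + side - 1L)]
    # halves: rows of blk = grid x (column index i), cols = grid y (row j)
    h <- rbind(l = tabulate_vals(blk[1:K, ], vals),
               r = tabulate_vals(blk[(K + 1):side, ], vals),
               bo = tabulate_vals(blk[, 1:K], vals),
               t = tabulate_vals(blk[, (K + 1):side], vals))
    nm <- colSums(h) / 2                       # bin counts over the block
    pj <- h / (2 * side^2)                     # P(X = x, M = m | c)
    ratio <- sweep(h, 2L, ifelse(nm > 0, nm, 1), `/`) * 2
    lg <- log(pmax(ratio, .Machine$double.xmin))
    lg[h == 0] <- 0
    total_i <- total_i + sum(pj * lg)
    n_ms <- n_ms + 1L
  }
  if (n_ms == 0L) stop("no megasquare satisfies the support requirement")
  mi <- total_i / n_ms
  omega <- n_ms * 2L * side^2
  structure(list(mi = mi, mi_scaled = mi * omega, n_megasquares = n_ms,
                 omega = omega),
            class = "mi_score")
}

tabulate_vals <- function(x, vals) {
  vapply(vals, function(v) sum(x == v), numeric(1))
}

#' @export
print.mi_score <- function(x, ...) {
  cat(sprintf("<mi_score> I(X;M|C) = %.6g nats over %d megasquares (scaled %.6g)\n",
              x$mi, x$n_megasquares, x$mi_scaled))
  invisible(x)
}

#' Mutual-information scores for every feature of a point table
#'
#' Builds per-section count grids on a common per-section support, bins each
#' feature's counts by quantiles, and scores spatial variability with
#' [mi_score()].  Section scores aggregate across the stack by summation.
#' Decoy/control features (labels matching `decoy_pattern`) are scored like
#' any other and flagged.
#'
#' @param points Data frame with columns `x`, `y`, `feature`, and optionally
#'   `section` (one grid per section; default: a single section).
#' @param sigma Grid square edge (default 50).
#' @param q Quantile count (default 10).
#' @param scheme A [megasquare_scheme()].
#' @param decoy_pattern Regular expression flagging control features
#'   (default `"^BLANK"`).
#' @return Data frame (one row per feature): per-section nat scores, `total`
#'   (summed nats), `total_scaled` (summed count-scaled scores), `decoy`.
#' @export
mi_feature_scores <- function(points, sigma = 50, q = 10,
                              scheme = megasquare_scheme(),
                              decoy_pattern = "^BLANK") {
  points <- as.data.frame(points)
  if (!"section" %in% names(points)) points$section <- 1L
  feats <- sort(unique(as.character(points$feature)))
  secs <- sort(unique(points$section))
  per_sec <- matrix(0, length(feats), length(secs),
                    dimnames = list(feats, paste0("section_", secs)))
  per_sec_scaled <- per_sec
  for (si in seq_along(secs)) {
    sp <- points[points$section == secs[si], ]
    origin <- c(min(sp$x), min(sp$y))
    dims <- c(floor((max(sp$x) - origin[1]) / sigma) + 1L,
              floor((max(sp$y) - origin[2]) / sigma) + 1L)
    all_counts <- grid_counts(sp[, c("x", "y")], sigma, origin, dims)
    support <- all_counts$counts > 0
    for (fi in seq_along(feats)) {
      fp <- sp[sp$feature == feats[fi], c("x", "y")]
      gc <- grid_counts(fp, sigma, origin, dims)
      sc <- mi_score(quantile_bin(gc, q), scheme, support = support)
      per_sec[fi, si] <- sc$mi
      per_sec_scaled[fi, si] <- sc$mi_scaled
    }
  }
  out <- data.frame(feature = feats, per_sec,
                    total = rowSums(per_sec),
                    total_scaled = rowSums(per_sec_scaled),
                    decoy = grepl(decoy_pattern, feats),
                    row.names = NULL, check.names = FALSE)
  out[order(-out$total, out$feature), ]
}

#' Greedy top-n feature selection by decreasing score
#'
#' @param scores Data frame from [mi_feature_scores()] (or any with columns
#'   `feature` and `total`).
#' @param n Number of features to return (<= number of features).
#' @return Character vector of the top-n features, ordered by decreasing
#'   total score with lexicographic tie-breaking.
#' @export
rank_and_select <- function(scores, n) {
  if (n > nrow(scores)) stop("'n' exceeds the number of features")
  o <- order(-scores$total, as.character(scores$feature))
  as.character(scores$feature[o])[seq_len(n)]
}
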