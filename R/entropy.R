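# Random-projection estimation of the conditional entropy H(y | z, model).
#
# For a candidate attribute z with levels 1..q, a single trial draws one
# random discriminant per sub-problem (per class pair when k > 2), optimizes
# each discriminant's offset by an exact threshold search, and measures the
# weighted remaining class entropy of the induced decision regions. The
# attribute's score is the Monte-Carlo average over trials, in bits.

# Weighted class entropy of decision regions: counts is a regions x classes
# matrix; empty regions and zero proportions contribute 0 (0 log 0 == 0).
.weighted_region_entropy <- function(counts) {
  counts <- as.matrix(counts)
  total <- sum(counts)
  if (total < 1) stop("no samples in any region", call. = FALSE)
  h <- 0
  for (r in seq_len(nrow(counts))) {
    nr <- sum(counts[r, ])
    if (nr == 0) next
    p <- counts[r, ] / nr
    p <- p[p > 0]
    h <- h + (nr / total) * sum(-p * log2(p))
  }
  h
}

#' Weighted two-cell class entropy of a binary split
#'
#' Given the class composition of the two decision regions of a discriminant
#' (`f(x) >= 0` vs `f(x) < 0`), returns the remaining class uncertainty
#' \eqn{\sum_{cell} (|cell|/n) H(p_{cell})} in bits, with class proportions
#' estimated empirically inside each cell and `0 log 0 = 0`.
#'
#' @param cells A 2-row matrix of nonnegative counts, one row per decision
#'   region and one column per class.
#' @return Entropy in bits.
#' @examples
#' binary_split_entropy(rbind(c(5, 0), c(0, 5)))  # pure cells -> 0
#' binary_split_entropy(rbind(c(5, 5), c(0, 0)))  # one uniform cell -> 1
#' @export
binary_split_entropy <- function(cells) {
  cells <- as.matrix(cells)
  if (nrow(cells) != 2L) stop("a binary split has exactly two cells", call. = FALSE)
  if (any(cells < 0)) stop("cell counts must be nonnegative", call. = FALSE)
  .weighted_region_entropy(cells)
}

# Exact best-threshold scan. Returns c(entropy, threshold) minimizing the
# weighted two-cell entropy of the partition {score >= t} vs {score < t}
# over all achievable partitions: thresholds at midpoints between distinct
# consecutive sorted scores plus the two all-in-one-cell extremes. Ties are
# broken by the smallest threshold.
.best_split_scan <- function(scores, pos) {
  n <- length(scores)
  o <- order(scores)
  s <- scores[o]
  cp <- cumsum(pos[o])
  tp <- cp[n]
  # candidate cut after sorted index i (lower cell = first i samples)
  i <- 0:n
  valid <- c(TRUE, s[-n] < s[-1L], TRUE)
  i <- i[valid]
  nl <- i
  pl <- c(0, cp)[i + 1L]
  nu <- n - nl
  pu <- tp - pl
  cell_h <- function(np, m) {
    # m * 0 cells never reach here with m > 0 guards below
    pp <- np / m
    qq <- 1 - pp
    out <- numeric(length(m))
    a <- pp > 0 & pp < 1
    out[a] <- -(pp[a] * log2(pp[a]) + qq[a] * log2(qq[a]))
    out
  }
  e <- numeric(length(i))
  lo <- nl > 0
  up <- nu > 0
  e[lo] <- e[lo] + (nl[lo] / n) * cell_h(pl[lo], nl[lo])
  e[up] <- e[up] + (nu[up] / n) * cell_h(pu[up], nu[up])
  j <- which.min(e)  # first minimum == smallest cut index == smallest threshold
  cut <- i[j]
  t <- if (cut == 0L) s[1L] else if (cut == n) s[n] + 1 else (s[cut] + s[cut + 1L]) / 2
  c(e[j], t)
}

# Column-wise minimum split entropy for a score matrix (samples x trials).
.best_entropy_cols <- function(scores, pos) {
  apply(scores, 2L, function(col) .best_split_scan(col, pos)[1L])
}

#' Optimal offset of a fixed discriminant direction
#'
#' For fixed per-sample scores \eqn{s_i = w'x_i} (or the dual kernel
#' analogue), finds the intercept `c` minimizing the weighted two-cell
#' entropy of the split `{s + c >= 0}` vs `{s + c < 0}`. The search set --
#' midpoints between consecutive distinct sorted scores plus the two
#' degenerate all-in-one-cell extremes -- attains every achievable
#' partition, so the minimum is exact. Ties are broken by the smallest
#' threshold.
#'
#' @param scores Finite numeric scores, one per sample.
#' @param labels Binary labels (any two-valued vector).
#' @return A list with `offset` (the minimizing `c`) and `entropy` (bits).
#' @examples
#' best_offset(c(-2, -1, 1, 2), c(-1, -1, 1, 1))$entropy  # separable -> 0
#' @export
best_offset <- function(scores, labels) {
  if (length(scores) < 1L) stop("empty input", call. = FALSE)
  if (length(scores) != length(labels)) {
    stop("scores and labels disagree on length", call. = FALSE)
  }
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  ulab <- unique(labels)
  if (length(ulab) > 2L) stop("labels must be binary", call. = FALSE)
  pos <- labels == ulab[1L]
  res <- .best_split_scan(scores, pos)
  list(offset = -res[2L], entropy = res[1L])
}

#' Filter candidate partition attributes by cardinality
#'
#' Keeps attributes with between 2 and `max_levels` observed levels.
#' Constant attributes induce no partition and attributes with many levels
#' produce sub-problems too small to train on; both are dropped, each with a
#' logged reason.
#'
#' @param x A [supervised_dataset()] or a data frame of categorical codes.
#' @param max_levels Largest admissible number of observed unique values
#'   (default 10; an attribute with exactly `max_levels` levels is kept).
#' @return Character vector of retained attribute names (possibly empty).
#' @export
filter_candidates <- function(x, max_levels = 10L) {
  if (max_levels < 2) stop("max_levels must be at least 2", call. = FALSE)
  tab <- if (inherits(x, "supervised_dataset")) x$categorical else as.data.frame(x)
  keep <- character(0)
  for (nm in names(tab)) {
    q <- length(unique(tab[[nm]]))
    if (q < 2L) {
      message(sprintf("dropping '%s': constant attribute (1 unique value)", nm))
    } else if (q > max_levels) {
      message(sprintf("dropping '%s': %d unique values exceed the cap of %d",
                      nm, q, max_levels))
    } else {
      keep <- c(keep, nm)
    }
  }
  keep
}

# One-vs-one majority vote; scores is samples x pairs with offsets applied,
# pairs is a 2 x P matrix of class indices. A function votes for its first
# class when the score is >= 0; vote ties go to the smallest class index.
.vote_regions <- function(scores, pairs, k) {
  scores <- as.matrix(scores)
  votes <- matrix(0L, nrow(scores), k)
  for (p in seq_len(ncol(scores))) {
    a <- pairs[1L, p]
    b <- pairs[2L, p]
    up <- scores[, p] >= 0
    votes[, a] <- votes[, a] + up
    votes[, b] <- votes[, b] + !up
  }
  max.col(votes, ties.method = "first")
}

#' Region entropy of a one-vs-one multi-class discriminant set
#'
#' Assigns each sample to one of `k` decision regions by majority vote of
#' the `k(k-1)/2` pairwise discriminants (offsets already applied; a
#' discriminant votes for the first class of its pair when its score is
#' nonnegative, and vote ties go to the smallest class index), then returns
#' the region-weighted class entropy in bits. With `k = 2` this reduces
#' exactly to [binary_split_entropy()] on the sign split.
#'
#' @param pairwise_scores Matrix (samples x class pairs) of discriminant
#'   scores with their offsets applied; a vector is taken as one column.
#' @param labels Integer class labels in `1..k`.
#' @param pairs 2-row integer matrix giving the class pair of each column;
#'   defaults to the single pair `(1, 2)` for one column.
#' @param k Number of classes (default `max(labels)`).
#' @return Entropy in bits.
#' @export
multiclass_region_entropy <- function(pairwise_scores, labels, pairs = NULL,
                                      k = NULL) {
  if (length(labels) < 1L) stop("empty sub-problem", call. = FALSE)
  scores <- as.matrix(pairwise_scores)
  k <- k %||% max(labels)
  if (k < 2L) stop("need at least two classes", call. = FALSE)
  if (is.null(pairs)) {
    if (ncol(scores) != 1L) stop("pairs must be given for k > 2", call. = FALSE)
    pairs <- rbind(1L, 2L)
  }
  if (ncol(scores) != ncol(pairs)) {
    stop("one score column per class pair is required", call. = FALSE)
  }
  region <- .vote_regions(scores, pairs, k)
  counts <- table(factor(region, levels = seq_len(k)),
                  factor(labels, levels = seq_len(k)))
  .weighted_region_entropy(unclass(counts))
}

.class_pairs <- function(k) {
  if (k == 2L) return(matrix(c(1L, 2L), nrow = 2L))
  idx <- utils::combn(k, 2L)
  storage.mode(idx) <- "integer"
  idx
}

# Draw one random projection for a sub-problem: primal unit normals for the
# linear kernel, dual weights alpha with alpha' K alpha = 1 otherwise.
# Returns list(W = d x P) or list(alpha = n x P).
.draw_projection <- function(kernel, n_features, n_sub, n_pairs, gram = NULL) {
  if (kernel$kind == "linear") {
    w <- matrix(stats::rnorm(n_features * n_pairs), n_features)
    nrm <- sqrt(colSums(w^2))
    nrm[nrm == 0] <- 1
    list(W = sweep(w, 2L, nrm, "/"))
  } else {
    a <- matrix(stats::rnorm(n_sub * n_pairs), n_sub)
    ka <- gram %*% a
    nrm <- sqrt(pmax(colSums(a * ka), .Machine$double.eps))
    list(alpha = sweep(a, 2L, nrm, "/"), scores = sweep(ka, 2L, nrm, "/"))
  }
}

#' Entropy of one sub-problem under one random projection
#'
#' Scores the sub-problem's samples with the draw's direction(s), optimizes
#' each discriminant's offset with [best_offset()] against its own class
#' pair, and returns the remaining class entropy: [binary_split_entropy()]
#' for two classes, [multiclass_region_entropy()] otherwise. A sub-problem
#' containing a single class has zero entropy by definition.
#'
#' @param features Feature matrix of the sub-problem's samples.
#' @param labels Integer class labels in `1..k` for those samples.
#' @param draw Projection draw: `list(W = ...)` with one primal direction
#'   column per class pair, or `list(alpha = ...)` with one dual weight
#'   column per class pair (weights over the sub-problem's samples).
#' @param kernel A [kernel_spec()].
#' @param k Number of classes of the full problem (default `max(labels)`).
#' @return Entropy in bits.
#' @export
subproblem_entropy <- function(features, labels, draw,
                               kernel = kernel_spec("linear"), k = NULL) {
  if (length(labels) < 1L) stop("empty sub-problem", call. = FALSE)
  kernel <- .as_kernel_spec(kernel)
  k <- k %||% max(labels)
  if (length(unique(labels)) < 2L) return(0)
  features <- as.matrix(features)
  pairs <- .class_pairs(k)
  if (!is.null(draw$W)) {
    scores <- features %*% draw$W
  } else if (!is.null(draw$scores)) {
    scores <- as.matrix(draw$scores)
  } else {
    scores <- kernel_matrix(kernel, features) %*% draw$alpha
  }
  present <- pairs[1L, ] %in% labels & pairs[2L, ] %in% labels
  if (ncol(scores) != ncol(pairs)) {
    stop("draw must carry one direction per class pair", call. = FALSE)
  }
  if (k == 2L) {
    bo <- best_offset(scores[, 1L], labels)
    return(bo$entropy)
  }
  shifted <- scores
  for (p in seq_len(ncol(pairs))) {
    in_pair <- labels %in% pairs[, p]
    if (present[p]) {
      bo <- best_offset(scores[in_pair, p], labels[in_pair])
      shifted[, p] <- scores[, p] + bo$offset
    } else {
      # neither or only one class of the pair occurs here; center the scores
      shifted[, p] <- scores[, p] - stats::median(scores[, p])
    }
  }
  multiclass_region_entropy(shifted, labels, pairs = pairs, k = k)
}

#' Expected conditional entropy of the class given an attribute
#'
#' Monte-Carlo estimate of the expected conditional entropy
#' \eqn{H(y \mid z, m)} of the class label `y` given the partition induced
#' by categorical attribute `z` and a random discriminant set `m` from the
#' chosen model family. Each of `n_projections` trials draws one random
#' direction per sub-problem and class pair (primal unit normals for the
#' linear kernel; dual weights with unit RKHS norm otherwise), optimizes
#' every offset exactly with [best_offset()], and averages the sub-problem
#' entropies weighted by the empirical level proportions
#' \eqn{\hat p(z = j)}. Small values mean the attribute's partition makes
#' the problem easy for the model family.
#'
#' @param dataset A [supervised_dataset()].
#' @param attribute Name of a categorical attribute of `dataset`.
#' @param kernel A [kernel_spec()] (default linear).
#' @param n_projections Number of Monte-Carlo trials `N` (default 1000).
#' @param seed Optional integer seed; all draws flow from it.
#' @param allow_single_level Permit a constant attribute, in which case the
#'   estimate degenerates to the mean best-offset entropy of the whole
#'   problem. Off by default: a constant attribute is an error.
#' @return An object of class `entropy_estimate`: a list with `attribute`,
#'   `entropy` (the mean, bits), `trials` (per-trial entropies), `q`,
#'   `n_projections`, `seed` and `kernel`.
#' @export
attribute_conditional_entropy <- function(dataset, attribute,
                                          kernel = kernel_spec("linear"),
                                          n_projections = 1000L, seed = NULL,
                                          allow_single_level = FALSE) {
  stopifnot(inherits(dataset, "supervised_dataset"))
  kernel <- .as_kernel_spec(kernel)
  if (!attribute %in% names(dataset$categorical)) {
    stop(sprintf("attribute '%s' not found", attribute), call. = FALSE)
  }
  if (n_projections < 1L) stop("n_projections must be at least 1", call. = FALSE)
  z <- dataset$categorical[[attribute]]
  lev <- sort(unique(z))
  if (length(lev) < 2L && !allow_single_level) {
    stop(sprintf("attribute '%s' is constant on the data", attribute),
         call. = FALSE)
  }
  n <- length(z)
  k <- n_classes(dataset)
  npairs <- ncol(.class_pairs(k))
  N <- as.integer(n_projections)
  if (!is.null(seed)) set.seed(seed)

  weights <- numeric(length(lev))
  H <- matrix(0, N, length(lev))
  for (jj in seq_along(lev)) {
    idx <- which(z == lev[jj])
    weights[jj] <- length(idx) / n
    if (length(idx) < 2L) {
      warning(sprintf("level '%s' of '%s' has fewer than 2 samples",
                      dataset$cat_levels[[attribute]][lev[jj]], attribute))
    }
    yj <- dataset$labels[idx]
    if (length(unique(yj)) < 2L) next  # pure level: zero entropy, no draws
    Xj <- dataset$features[idx, , drop = FALSE]
    if (k == 2L) {
      pos <- yj == 1L
      if (kernel$kind == "linear") {
        W <- matrix(stats::rnorm(ncol(Xj) * N), ncol(Xj))
        nrm <- sqrt(colSums(W^2))
        nrm[nrm == 0] <- 1
        S <- Xj %*% sweep(W, 2L, nrm, "/")
      } else {
        K <- kernel_matrix(kernel, Xj)
        A <- matrix(stats::rnorm(length(idx) * N), length(idx))
        KA <- K %*% A
        nrm <- sqrt(pmax(colSums(A * KA), .Machine$double.eps))
        S <- sweep(KA, 2L, nrm, "/")
      }
      H[, jj] <- .best_entropy_cols(S, pos)
    } else {
      gram <- if (kernel$kind == "linear") NULL else kernel_matrix(kernel, Xj)
      for (i in seq_len(N)) {
        draw <- .draw_projection(kernel, ncol(Xj), length(idx), npairs, gram)
        H[i, jj] <- subproblem_entropy(Xj, yj, draw, kernel, k = k)
      }
    }
  }
  trials <- drop(H %*% weights)
  structure(
    list(attribute = attribute, entropy = mean(trials), trials = trials,
         q = length(lev), n_projections = N, seed = seed, kernel = kernel),
    class = "entropy_estimate"
  )
}

#' @export
print.entropy_estimate <- function(x, ...) {
  cat(sprintf("<entropy_estimate> %s: %.4f bits (q=%d, N=%d, kernel=%s)\n",
              x$attribute, x$entropy, x$q, x$n_projections, format(x$kernel)))
  invisible(x)
}

#' Rank candidate attributes by estimated conditional entropy
#'
#' Runs [attribute_conditional_entropy()] on every candidate with draws that
#' are independent across attributes but fully determined by `seed`, and
#' returns the attributes sorted by ascending estimated entropy (ties broken
#' by attribute name for determinism).
#'
#' @param dataset A [supervised_dataset()].
#' @param candidates Character vector of attribute names; defaults to
#'   [filter_candidates()] with `max_levels`.
#' @param kernel A [kernel_spec()].
#' @param n_projections Trials per attribute.
#' @param seed Integer seed for the shared stream.
#' @param max_levels Cardinality cap applied when `candidates` is NULL.
#' @return A `ranking_report`: a data frame with columns `rank`,
#'   `attribute`, `q`, `entropy_bits`, carrying the estimates and run
#'   metadata as attributes.
#' @export
rank_attributes <- function(dataset, candidates = NULL,
                            kernel = kernel_spec("linear"),
                            n_projections = 1000L, seed = NULL,
                            max_levels = 10L) {
  stopifnot(inherits(dataset, "supervised_dataset"))
  kernel <- .as_kernel_spec(kernel)
  if (is.null(candidates)) candidates <- filter_candidates(dataset, max_levels)
  if (length(candidates) < 1L) stop("no candidate attributes to rank", call. = FALSE)
  estimates <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    s <- if (is.null(seed)) NULL else seed + i - 1L
    estimates[[i]] <- attribute_conditional_entropy(
      dataset, candidates[i], kernel = kernel,
      n_projections = n_projections, seed = s)
  }
  ranking_report(estimates, seed = seed)
}
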