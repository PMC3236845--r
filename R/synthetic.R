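# Piecewise-separable synthetic benchmarks.
#
# The domain is a rectangle centred at the origin; X3 is the plane quadrant
# of (X1, X2) (1: x>=0,y>=0; 2: x<0,y>=0; 3: x<0,y<0; 4: x>=0,y<0) and X4
# is an independent uniform binary attribute. Labels are a noiseless
# deterministic function of (X1, X2) through one boundary per quadrant, so
# each quadrant is exactly separable by the pattern's model family while the
# union problem is not:
#   pattern 1 -- one horizontal line per quadrant, higher on the left than
#     on the right and mirrored below the axis (piecewise linear, globally
#     non-linear: positives sit near both the top and bottom edges);
#   pattern 2 -- one quarter-ellipse arc centred at the origin per quadrant,
#     positive inside in quadrants 1 and 3 and outside in 2 and 4, with
#     radii differing per quadrant (per-quadrant central conics, hence
#     exactly representable by the homogeneous degree-2 polynomial kernel;
#     globally not);
#   pattern 3 -- arcs in quadrants 1 and 3, axis-parallel lines in 2 and 4
#     (within a half-plane the line x = t equals the central conic
#     x^2 = t^2, so those quadrants stay poly2-separable).
#
# The domain is deliberately anisotropic (X1 much wider than X2): random
# unit directions then mostly project onto X1 while the class signal lives
# in X2, which sets the scale of the conditional-entropy estimates. The
# aspect ratio, overall scale and per-quadrant positive fractions (0.72 on
# the right half, 0.38 on the left) were calibrated once against the
# intended difficulty profile (class balance, baseline accuracy, entropy
# scale) of the three benchmark patterns and are frozen here.

.default_bounds <- function(pattern) {
  switch(as.character(pattern),
    "1" = c(48, 8), "2" = c(6, 1), "3" = c(8.4, 1.4),
    stop("pattern must be 1, 2 or 3", call. = FALSE)
  )
}

.default_quadrants <- function(pattern) {
  b <- .default_bounds(pattern)
  # positive fraction inside a quarter-ellipse of normalized radius r is
  # pi r^2 / 4, so c = 4p/pi puts fraction p on the positive side
  ell_in <- function(p) list(type = "conic", w = c(-1 / b[1]^2, 0, -1 / b[2]^2),
                             c = 4 * p / pi)
  ell_out <- function(p) list(type = "conic", w = c(1 / b[1]^2, 0, 1 / b[2]^2),
                              c = -4 * (1 - p) / pi)
  switch(as.character(pattern),
    # horizontal lines, positive fraction 0.72 on x >= 0 and 0.38 on x < 0,
    # positive side toward the top edge above the axis and toward the bottom
    # edge below it: no global linear separator
    "1" = list(
      list(type = "linear", w = c(0, 1), c = -0.28 * b[2]),
      list(type = "linear", w = c(0, 1), c = -0.62 * b[2]),
      list(type = "linear", w = c(0, -1), c = -0.62 * b[2]),
      list(type = "linear", w = c(0, -1), c = -0.28 * b[2])
    ),
    # quarter-ellipse arcs centred at the origin, positive inside in
    # quadrants 1 and 3 and outside in 2 and 4, radii differing per quadrant
    "2" = list(ell_in(0.72), ell_out(0.38), ell_in(0.38), ell_out(0.72)),
    # mixed: arcs in quadrants 1 and 3, axis-parallel lines in 2 and 4
    # (within their half-planes the lines are central conics too)
    "3" = list(
      ell_in(0.72),
      list(type = "linear", w = c(-1, 0), c = -0.38 * b[1]),
      ell_out(0.38),
      list(type = "linear", w = c(0, -1), c = -0.28 * b[2])
    )
  )
}

#' Geometry of a synthetic benchmark pattern
#'
#' A pattern is four per-quadrant boundary descriptors on the square
#' `[-1, 1]^2`. Each descriptor is `list(type, w, c)` where the decision
#' value is `w %*% phi(x, y) + c` with `phi = (x, y)` for `type = "linear"`
#' and `phi = (x^2, x*y, y^2)` (a central conic) for `type = "conic"`; the
#' positive class is the region where the value is nonnegative.
#'
#' @param pattern Pattern id in 1..3 selecting the calibrated default
#'   geometry.
#' @param quadrants Optional list of four boundary descriptors overriding
#'   the defaults.
#' @param bounds Half-widths of the centred rectangular domain, recycled to
#'   length 2 (`c(x, y)`); defaults to the pattern's calibrated domain.
#' @param flip_rate Label noise rate; labels are flipped independently with
#'   this probability (default 0, noiseless).
#' @return An object of class `pattern_spec`.
#' @export
pattern_spec <- function(pattern = 1L, quadrants = NULL, bounds = NULL,
                         flip_rate = 0) {
  pattern <- as.integer(pattern)
  if (!pattern %in% 1:3) stop("pattern must be 1, 2 or 3", call. = FALSE)
  bounds <- rep_len(as.numeric(bounds %||% .default_bounds(pattern)), 2L)
  if (any(bounds <= 0)) stop("degenerate bounds", call. = FALSE)
  if (flip_rate < 0 || flip_rate >= 0.5) {
    stop("flip_rate must be in [0, 0.5)", call. = FALSE)
  }
  quadrants <- quadrants %||% .default_quadrants(pattern)
  if (length(quadrants) != 4L) stop("need one boundary per quadrant", call. = FALSE)
  structure(list(pattern = pattern, bounds = bounds, quadrants = quadrants,
                 flip_rate = flip_rate),
            class = "pattern_spec")
}

#' @export
print.pattern_spec <- function(x, ...) {
  cat(sprintf(
    "<pattern_spec> pattern %d on [-%g, %g] x [-%g, %g], flip_rate=%g\n",
    x$pattern, x$bounds[1L], x$bounds[1L], x$bounds[2L], x$bounds[2L],
    x$flip_rate))
  invisible(x)
}

#' Serialize or load a pattern geometry as JSON
#'
#' @param spec A [pattern_spec()].
#' @param path JSON file path.
#' @return `write_pattern_spec()` returns `path` invisibly;
#'   `read_pattern_spec()` returns the [pattern_spec()].
#' @export
write_pattern_spec <- function(spec, path) {
  stopifnot(inherits(spec, "pattern_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_pattern_spec
#' @export
read_pattern_spec <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  pattern_spec(js$pattern,
               quadrants = lapply(js$quadrants, function(q) {
                 list(type = q$type, w = as.numeric(q$w), c = as.numeric(q$c))
               }),
               bounds = js$bounds, flip_rate = js$flip_rate %||% 0)
}

.quadrant_of <- function(x, y) {
  ifelse(x >= 0,
         ifelse(y >= 0, 1L, 4L),
         ifelse(y >= 0, 2L, 3L))
}

.boundary_value <- function(b, x, y) {
  phi <- if (b$type == "linear") cbind(x, y) else cbind(x^2, x * y, y^2)
  drop(phi %*% b$w) + b$c
}

.pattern_labels <- function(spec, x, y) {
  q <- .quadrant_of(x, y)
  lab <- integer(length(x))
  for (j in 1:4) {
    idx <- which(q == j)
    if (length(idx) == 0L) next
    f <- .boundary_value(spec$quadrants[[j]], x[idx], y[idx])
    lab[idx] <- ifelse(f >= 0, 1L, 2L)
  }
  if (spec$flip_rate > 0) {
    flip <- stats::runif(length(lab)) < spec$flip_rate
    lab[flip] <- 3L - lab[flip]
  }
  lab
}

#' Generate one synthetic pattern dataset
#'
#' Draws `X1, X2` uniform on the pattern's square, sets `X3` to the quadrant
#' of `(X1, X2)` and `X4` to an independent uniform value in `{1, 2}`, and
#' labels every point by its quadrant's boundary (noiselessly unless the
#' spec sets a flip rate).
#'
#' @param pattern Pattern id in 1..3 or a [pattern_spec()].
#' @param n_train,n_test Split sizes; both must be at least 40.
#' @param seed Optional integer seed.
#' @return A list with elements `train` and `test`, both
#'   [supervised_dataset()]s.
#' @export
generate_pattern <- function(pattern, n_train = 400L, n_test = 1600L,
                             seed = NULL) {
  spec <- if (inherits(pattern, "pattern_spec")) pattern else pattern_spec(pattern)
  if (n_train < 40L || n_test < 40L) {
    stop("n_train and n_test must be at least 40", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- n_train + n_test
  x <- stats::runif(n, -spec$bounds[1L], spec$bounds[1L])
  y <- stats::runif(n, -spec$bounds[2L], spec$bounds[2L])
  lab <- .pattern_labels(spec, x, y)
  x4 <- sample(1:2, n, replace = TRUE)
  build <- function(idx) {
    supervised_dataset(
      features = cbind(X1 = x[idx], X2 = y[idx]),
      labels = c("pos", "neg")[lab[idx]],
      categorical = data.frame(X3 = .quadrant_of(x[idx], y[idx]), X4 = x4[idx]),
      label_levels = c("pos", "neg"),
      cat_levels = list(X3 = c("1", "2", "3", "4"), X4 = c("1", "2"))
    )
  }
  list(train = build(seq_len(n_train)), test = build(n_train + seq_len(n_test)))
}

#' Generate replicate sets of a synthetic pattern
#'
#' All replicate sets share a single base draw of the continuous features,
#' the quadrant attribute and the labels; only the independent random
#' attribute `X4` is redrawn per set.
#'
#' @inheritParams generate_pattern
#' @param n_sets Number of replicate sets (default 10).
#' @return A list of `n_sets` elements, each a list with `train` and `test`
#'   [supervised_dataset()]s.
#' @export
generate_replicates <- function(pattern, n_train = 400L, n_test = 1600L,
                                n_sets = 10L, seed = NULL) {
  spec <- if (inherits(pattern, "pattern_spec")) pattern else pattern_spec(pattern)
  if (n_sets < 1L) stop("n_sets must be at least 1", call. = FALSE)
  base <- generate_pattern(spec, n_train, n_test, seed = seed)
  lapply(seq_len(n_sets), function(r) {
    redraw <- function(d) {
      d$categorical$X4 <- sample(1:2, n_samples(d), replace = TRUE)
      d
    }
    list(train = redraw(base$train), test = redraw(base$test))
  })
}

#' Small parametric toy datasets for unit testing
#'
#' Three fixture families: `separable` is globally linearly separable with
#' `k` classes strung along the first axis; `checkerboard` is the XOR
#' problem on the four plane quadrants (no global linear separator, trivial
#' once partitioned by the quadrant attribute `quad`); `label_leak` has
#' random features and labels but carries a categorical attribute `leak`
#' equal to the label, whose conditional entropy is exactly zero.
#'
#' @param kind One of `"separable"`, `"checkerboard"`, `"label_leak"`.
#' @param n Number of samples (at least `2 * k`).
#' @param k Number of classes (checkerboard is binary only).
#' @param seed Optional integer seed.
#' @return A [supervised_dataset()].
#' @export
make_unit_toy <- function(kind = c("separable", "checkerboard", "label_leak"),
                          n = 40L, k = 2L, seed = NULL) {
  kind <- match.arg(kind)
  if (n < 2L * k) stop("n must be at least 2 * k", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (kind == "checkerboard" && k != 2L) {
    stop("the checkerboard toy is binary", call. = FALSE)
  }
  switch(kind,
    separable = {
      lab <- sample(rep_len(seq_len(k), n))
      x1 <- 3 * lab + stats::runif(n, -1, 1)
      x2 <- stats::rnorm(n)
      supervised_dataset(
        features = cbind(X1 = x1, X2 = x2), labels = lab,
        categorical = data.frame(g = sample(1:2, n, replace = TRUE)),
        label_levels = as.character(seq_len(k)),
        cat_levels = list(g = c("1", "2"))
      )
    },
    checkerboard = {
      x1 <- stats::runif(n, -1, 1)
      x2 <- stats::runif(n, -1, 1)
      lab <- ifelse(x1 * x2 >= 0, 1L, 2L)
      supervised_dataset(
        features = cbind(X1 = x1, X2 = x2), labels = lab,
        categorical = data.frame(quad = .quadrant_of(x1, x2),
                                 g = sample(1:2, n, replace = TRUE)),
        label_levels = c("1", "2"),
        cat_levels = list(quad = c("1", "2", "3", "4"), g = c("1", "2"))
      )
    },
    label_leak = {
      lab <- sample(rep_len(seq_len(k), n))
      supervised_dataset(
        features = cbind(X1 = stats::rnorm(n), X2 = stats::rnorm(n)),
        labels = lab,
        categorical = data.frame(leak = lab,
                                 g = sample(1:2, n, replace = TRUE)),
        label_levels = as.character(seq_len(k)),
        cat_levels = list(leak = as.character(seq_len(k)), g = c("1", "2"))
      )
    }
  )
}
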