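#' Grey-level co-occurrence matrix
#'
#' Quantizes an 8-bit image to `levels` grey levels by
#' `floor(gray * levels / 256)` and, for each requested angle, counts
#' ordered pixel pairs `(p, p + offset)` lying inside the image at the
#' given distance. With `symmetric = TRUE` the transpose is added before
#' normalisation, so each pair is counted in both orders. The result is
#' normalised to a probability matrix `p(i, j)` summing to 1.
#'
#' Angle conventions (offset as (row, col) displacement): 0 degrees =
#' (0, d); 45 = (-d, d); 90 = (-d, 0); 135 = (-d, -d).
#'
#' @param img a [gray_image()] or numeric matrix in \[0, 255\].
#' @param levels number of grey levels G (>= 2); level values are 0..G-1.
#' @param distance pair offset in pixels (>= 1).
#' @param angles angles in degrees, subset of \{0, 45, 90, 135\}.
#' @param symmetric add the transposed counts before normalising.
#' @return A list of `glcm` objects, one per angle. Each holds the
#'   probability matrix `p`, the parameters, and the marginal means and
#'   standard deviations `mu_x`, `mu_y`, `sigma_x`, `sigma_y` (computed over
#'   level values 0..G-1).
#' @export
compute_glcm <- function(img, levels = 8L, distance = 1L,
                         angles = c(0, 45, 90, 135), symmetric = TRUE) {
  img <- as_gray(img)
  levels <- as.integer(levels)
  distance <- as.integer(distance)
  if (levels < 2L) stop("levels must be >= 2", call. = FALSE)
  if (distance < 1L) stop("distance must be >= 1", call. = FALSE)
  if (!all(angles %in% c(0, 45, 90, 135))) {
    stop("angles must be a subset of {0, 45, 90, 135}", call. = FALSE)
  }
  q <- matrix(as.integer(floor(as.numeric(unclass(img)) * levels / 256)),
              nrow(img), ncol(img))
  nr <- nrow(q); nc <- ncol(q)
  lapply(angles, function(a) {
    off <- switch(as.character(a),
                  "0"   = c(0L, distance),
                  "45"  = c(-distance, distance),
                  "90"  = c(-distance, 0L),
                  "135" = c(-distance, -distance))
    rows <- seq_len(nr)[seq_len(nr) + off[1] >= 1L & seq_len(nr) + off[1] <= nr]
    cols <- seq_len(nc)[seq_len(nc) + off[2] >= 1L & seq_len(nc) + off[2] <= nc]
    if (length(rows) == 0L || length(cols) == 0L) {
      stop("image too small for the requested offset", call. = FALSE)
    }
    from <- q[rows, cols, drop = FALSE]
    to <- q[rows + off[1], cols + off[2], drop = FALSE]
    counts <- matrix(tabulate(from * levels + to + 1L, nbins = levels^2),
                     levels, levels, byrow = TRUE)
    if (symmetric) counts <- counts + t(counts)
    new_glcm(counts / sum(counts), levels, distance, a, symmetric)
  })
}

new_glcm <- function(p, levels, distance, angle, symmetric) {
  lev <- 0:(levels - 1L)
  px <- rowSums(p)
  py <- colSums(p)
  mu_x <- sum(lev * px)
  mu_y <- sum(lev * py)
  structure(list(p = p, levels = levels, distance = distance, angle = angle,
                 symmetric = symmetric,
                 mu_x = mu_x, mu_y = mu_y,
                 sigma_x = sqrt(sum(lev^2 * px) - mu_x^2),
                 sigma_y = sqrt(sum(lev^2 * py) - mu_y^2)),
            class = "glcm")
}

#' Construct a GLCM directly from a probability matrix
#'
#' Mainly useful for closed-form checks; the matrix is validated and the
#' marginal moments are recomputed.
#'
#' @param p square non-negative matrix summing to 1.
#' @param distance,angle,symmetric metadata carried along.
#' @return A `glcm` object.
#' @export
glcm_from_matrix <- function(p, distance = 1L, angle = 0, symmetric = TRUE) {
  if (!is.matrix(p) || nrow(p) != ncol(p)) {
    stop("p must be a square matrix", call. = FALSE)
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
    stop("p must be non-negative and sum to 1", call. = FALSE)
  }
  new_glcm(p, nrow(p), distance, angle, symmetric)
}

assert_glcm <- function(g) {
  if (!inherits(g, "glcm")) stop("expected a glcm object", call. = FALSE)
  g
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("<glcm %d levels, d=%d, angle=%g deg, %s>\n", x$levels,
              x$distance, x$angle, if (x$symmetric) "symmetric" else "asym"))
  invisible(x)
}

#' GLCM texture descriptors
#'
#' The five Haralick-type descriptors used as classifier inputs. Level
#' coordinates are the quantized grey values 0..G-1.
#'
#' * `glcm_asm`: angular second moment, sum of p(i,j)^2 — texture uniformity
#'   in (0, 1], 1 iff a single cell carries all mass.
#' * `glcm_entropy`: -sum p log2 p in bits (0 log 0 = 0); 0 for a
#'   deterministic GLCM, log2(G^2) for the uniform one.
#' * `glcm_contrast`: sum (i - j)^2 p(i,j); 0 iff all mass is diagonal.
#' * `glcm_correlation`: (sum ij p(i,j) - mu_x mu_y) / (sigma_x sigma_y),
#'   in \[-1, 1\]; `NA` when either marginal variance is zero (a constant
#'   texture carries no correlation signal — callers decide policy).
#' * `glcm_idm`: inverse difference moment, sum p(i,j) / (1 + (i - j)^2),
#'   in (0, 1], 1 iff all mass is diagonal.
#'
#' @param g a `glcm` object.
#' @param base logarithm base for the entropy (default 2, i.e. bits).
#' @return A numeric scalar (`glcm_correlation` may be `NA_real_`).
#' @name glcm_descriptors
NULL

#' @rdname glcm_descriptors
#' @export
glcm_asm <- function(g) {
  g <- assert_glcm(g)
  sum(g$p^2)
}

#' @rdname glcm_descriptors
#' @export
glcm_entropy <- function(g, base = 2) {
  g <- assert_glcm(g)
  p <- g$p[g$p > 0]
  -sum(p * log(p, base = base))
}

#' @rdname glcm_descriptors
#' @export
glcm_contrast <- function(g) {
  g <- assert_glcm(g)
  lev <- 0:(g$levels - 1L)
  d2 <- outer(lev, lev, function(i, j) (i - j)^2)
  sum(d2 * g$p)
}

#' @rdname glcm_descriptors
#' @export
glcm_correlation <- function(g) {
  g <- assert_glcm(g)
  if (g$sigma_x == 0 || g$sigma_y == 0) return(NA_real_)
  lev <- 0:(g$levels - 1L)
  eij <- sum(outer(lev, lev) * g$p)
  (eij - g$mu_x * g$mu_y) / (g$sigma_x * g$sigma_y)
}

#' @rdname glcm_descriptors
#' @export
glcm_idm <- function(g) {
  g <- assert_glcm(g)
  lev <- 0:(g$levels - 1L)
  w <- outer(lev, lev, function(i, j) 1 / (1 + (i - j)^2))
  sum(w * g$p)
}

#' Extract the five-descriptor feature vector of an image
#'
#' Computes one GLCM per angle and averages each descriptor over the
#' angles. An undefined correlation (zero marginal variance) at any angle
#' propagates `NA` for the correlation feature.
#'
#' @inheritParams compute_glcm
#' @param entropy_base logarithm base for the entropy descriptor.
#' @return Named numeric vector with elements `asm`, `entropy`, `contrast`,
#'   `correlation`, `idm`.
#' @export
extract_features <- function(img, levels = 8L, distance = 1L,
                             angles = c(0, 45, 90, 135), symmetric = TRUE,
                             entropy_base = 2) {
  gs <- compute_glcm(img, levels = levels, distance = distance,
                     angles = angles, symmetric = symmetric)
  per <- vapply(gs, function(g) {
    c(asm = glcm_asm(g),
      entropy = glcm_entropy(g, base = entropy_base),
      contrast = glcm_contrast(g),
      correlation = glcm_correlation(g),
      idm = glcm_idm(g))
  }, numeric(5))
  corr <- per["correlation", ]
  out <- rowMeans(per)
  out["correlation"] <- if (anyNA(corr)) NA_real_ else mean(corr)
  out
}
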