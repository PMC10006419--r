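#' Body-morphology PCA
#'
#' Principal component analysis of the four body traits (body mass, tarsus
#' length, wing length, tail length). Traits are log10-transformed and the
#' PCA runs on the correlation matrix (standardized columns). The first axis
#' captures overall size, the second shape. Sign convention: the loading of
#' body mass on axis 1 is positive, and the largest-magnitude loading of axis
#' 2 is positive.
#'
#' @param mass,tarsus,wing,tail Strictly positive trait vectors (g, mm).
#' @return List: \code{scores} (n x 2 matrix, columns PCA1m/PCA2m),
#'   \code{variance_explained} (length-4 fractions), \code{loadings}.
#' @export
pca_body <- function(mass, tarsus, wing, tail) {
  X <- cbind(body_mass = mass, tarsus_length = tarsus,
             wing_length = wing, tail_length = tail)
  if (nrow(X) < 3) stop("at least 3 species required")
  bad <- which(!is.finite(X) | X <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-positive or missing trait values for rows: ",
         paste(unique(bad[, 1]), collapse = ", "))
  run_pca(log10(X), n_axes = 2, anchor = "body_mass",
          axis_names = c("PCA1m", "PCA2m"))
}

# correlation-matrix PCA with deterministic axis signs
run_pca <- function(L, n_axes, anchor = NULL, axis_names = NULL) {
  sds <- apply(L, 2, sd)
  if (any(sds == 0))
    stop("constant column(s): ", paste(colnames(L)[sds == 0], collapse = ", "))
  pc <- prcomp(L, center = TRUE, scale. = TRUE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  for (a in seq_len(ncol(pc$rotation))) {
    flip <- if (!is.null(anchor) && a == 1L) {
      pc$rotation[anchor, 1] < 0
    } else {
      pc$rotation[which.max(abs(pc$rotation[, a])), a] < 0
    }
    if (flip) {
      pc$rotation[, a] <- -pc$rotation[, a]
      pc$x[, a] <- -pc$x[, a]
    }
  }
  scores <- pc$x[, seq_len(n_axes), drop = FALSE]
  if (!is.null(axis_names)) colnames(scores) <- axis_names
  list(scores = scores, variance_explained = ve, loadings = pc$rotation)
}

#' Size-correct beak traits against body mass
#'
#' For each beak trait (log scale), ordinary least-squares on log body mass;
#' the residuals carry the size-independent beak shape variation and are
#' exactly orthogonal to log mass.
#'
#' @param beak_log n x 4 matrix of log-transformed beak traits.
#' @param mass_log Vector of log-transformed body mass.
#' @return n x 4 residual matrix.
#' @export
size_correct_beak <- function(beak_log, mass_log) {
  beak_log <- as.matrix(beak_log)
  stopifnot(nrow(beak_log) == length(mass_log))
  if (sd(mass_log) == 0) stop("body mass has zero variance")
  X <- cbind(1, mass_log)
  beak_log - X %*% qr.solve(X, beak_log)
}

#' Beak-shape PCA
#'
#' Correlation-matrix PCA of the four size-corrected beak residuals; the
#' first axis (PCA1b) summarizes beak shape.
#'
#' @param beak_residuals Residual matrix from \code{\link{size_correct_beak}}.
#' @return List: \code{scores} (n x 1, PCA1b), \code{variance_explained},
#'   \code{loadings}.
#' @export
pca_beak <- function(beak_residuals) {
  colnames(beak_residuals) <- colnames(beak_residuals) %||%
    paste0("beak", seq_len(ncol(beak_residuals)))
  run_pca(as.matrix(beak_residuals), n_axes = 1, axis_names = "PCA1b")
}

#' Assemble the six-variable trait table
#'
#' Builds the analysis trait table from a raw species table: PCA1m and PCA2m
#' from the body PCA, PCA1b from the PCA of mass-corrected beak residuals,
#' raw hand-wing index, and the two categorical traits.
#'
#' @param pool Species table with the eight morphometric columns used by
#'   \code{\link{generate_species_pool}} plus \code{hand_wing_index},
#'   \code{trophic_niche}, \code{primary_lifestyle} and \code{species_id}.
#' @return A data.frame (rownames = species_id) with columns \code{PCA1m},
#'   \code{PCA2m}, \code{PCA1b}, \code{HWI}, \code{trophic_niche},
#'   \code{primary_lifestyle}; PCA variance fractions are attached as
#'   attributes \code{body_pca} and \code{beak_pca}.
#' @export
build_trait_table <- function(pool) {
  body <- pca_body(pool$body_mass, pool$tarsus_length,
                   pool$wing_length, pool$tail_length)
  beak_log <- log10(as.matrix(pool[, c("beak_culmen", "beak_nares",
                                       "beak_width", "beak_depth")]))
  if (any(!is.finite(beak_log))) stop("non-positive beak trait values")
  res <- size_correct_beak(beak_log, log10(pool$body_mass))
  beak <- pca_beak(res)
  out <- data.frame(PCA1m = body$scores[, 1], PCA2m = body$scores[, 2],
                    PCA1b = beak$scores[, 1], HWI = pool$hand_wing_index,
                    trophic_niche = factor(pool$trophic_niche),
                    primary_lifestyle = factor(pool$primary_lifestyle),
                    row.names = pool$species_id)
  attr(out, "body_pca") <- body$variance_explained
  attr(out, "beak_pca") <- beak$variance_explained
  out
}

gower_per_variable <- function(x) {
  if (is.numeric(x)) {
    rg <- diff(range(x))
    if (rg == 0) stop("zero range on a quantitative variable")
    abs(outer(x, x, "-")) / rg
  } else {
    x <- as.character(x)
    outer(x, x, "!=") * 1
  }
}

#' Gower distance on mixed trait variables
#'
#' Pairwise dissimilarity over quantitative and categorical variables:
#' range-normalized absolute difference for quantitative variables, simple
#' mismatch for categorical ones, combined as a weighted mean
#' \eqn{d(i,j) = \sum_v w_v d_v(i,j)} with weights summing to 1 (equal by
#' default).
#'
#' @param traits Trait data.frame (numeric and factor/character columns).
#' @param weights Optional non-negative weights, one per column; normalized
#'   to sum to 1.
#' @return n x n symmetric matrix in [0, 1] with zero diagonal; attributes
#'   \code{weights} and \code{variables}.
#' @examples
#' tt <- data.frame(a = c(0, 5, 10), b = c(0, 1, 2), g = c("x", "x", "y"))
#' gower_distance(tt)[1, 3]
#' @export
gower_distance <- function(traits, weights = NULL) {
  stopifnot(is.data.frame(traits), nrow(traits) >= 2)
  v <- names(traits)
  if (is.null(weights)) weights <- rep(1, length(v))
  stopifnot(length(weights) == length(v), all(weights >= 0), sum(weights) > 0)
  weights <- weights / sum(weights)
  D <- 0
  for (j in seq_along(v)) D <- D + weights[j] * gower_per_variable(traits[[j]])
  dimnames(D) <- list(rownames(traits), rownames(traits))
  attr(D, "weights") <- setNames(weights, v)
  attr(D, "variables") <- v
  D
}

#' Per-trait contributions to the global Gower distance
#'
#' Additive decomposition of the mean Gower distance: the contribution of
#' variable v is \eqn{w_v \bar d_v / \bar D}, so shares are non-negative and
#' sum exactly to 1. The Pearson correlation between each per-variable
#' distance matrix (upper triangle) and the global matrix is reported as a
#' secondary diagnostic of the same question (which traits structure the
#' distances).
#'
#' @inheritParams gower_distance
#' @param dist Optional precomputed \code{\link{gower_distance}} output for
#'   the same table and weights.
#' @return Data.frame: \code{variable}, \code{contribution},
#'   \code{matrix_correlation}.
#' @export
trait_contributions <- function(traits, weights = NULL, dist = NULL) {
  if (nrow(traits) < 2) stop("at least 2 species required")
  if (is.null(dist)) dist <- gower_distance(traits, weights)
  w <- attr(dist, "weights")
  ut <- upper.tri(dist)
  mean_total <- mean(dist[ut])
  contrib <- corr <- numeric(length(w))
  for (j in seq_along(w)) {
    dv <- gower_per_variable(traits[[j]])
    contrib[j] <- w[j] * mean(dv[ut]) / mean_total
    corr[j] <- if (sd(dv[ut]) > 0) cor(dv[ut], dist[ut]) else NA_real_
  }
  data.frame(variable = names(w), contribution = contrib,
             matrix_correlation = corr, row.names = NULL)
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical scaling: double-centering of \eqn{-\tfrac12 d^2}, eigen-
#' decomposition, and retention of the \code{k_axes} eigenvectors with the
#' largest positive eigenvalues, scaled by the square root of their
#' eigenvalue (via \code{stats::cmdscale}). Variance explained is relative to
#' the sum of positive eigenvalues; negative eigenvalues are reported
#' unchanged, with no Cailliez/Lingoes correction. Axis signs are fixed so
#' the largest-magnitude coordinate of each axis is positive.
#'
#' @param dist Symmetric distance matrix (e.g. \code{\link{gower_distance}}).
#' @param k_axes Number of axes to retain (default 5).
#' @return A \code{functional_space}: list with \code{coordinates} (n x
#'   k_axes), \code{eigenvalues} (all, signed, decreasing),
#'   \code{variance_explained} (retained axes), \code{negative_eigenvalues}.
#' @export
pcoa <- function(dist, k_axes = 5) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  if (k_axes >= n) stop("k_axes must be smaller than the number of points")
  cs <- suppressWarnings(cmdscale(dist, k = n - 1, eig = TRUE))
  ev <- cs$eig
  n_pos <- sum(ev > sqrt(.Machine$double.eps) * max(abs(ev)))
  if (n_pos < k_axes)
    stop("only ", n_pos, " positive eigenvalues; cannot retain ", k_axes, " axes")
  coords <- cs$points[, seq_len(k_axes), drop = FALSE]
  for (a in seq_len(k_axes)) {
    if (coords[which.max(abs(coords[, a])), a] < 0) coords[, a] <- -coords[, a]
  }
  colnames(coords) <- paste0("PCoA", seq_len(k_axes))
  rownames(coords) <- rownames(dist)
  structure(list(coordinates = coords,
                 eigenvalues = ev,
                 variance_explained = ev[seq_len(k_axes)] / sum(ev[ev > 0]),
                 negative_eigenvalues = ev[ev < 0]),
            class = "functional_space")
}

#' @export
print.functional_space <- function(x, ...) {
  cat(sprintf("<functional_space> %d species x %d axes; variance explained: %s\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", ")))
  if (length(x$negative_eigenvalues))
    cat(sprintf("  %d negative eigenvalues (min %.3g), uncorrected\n",
                length(x$negative_eigenvalues), min(x$negative_eigenvalues)))
  invisible(x)
}
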