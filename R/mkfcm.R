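#' Kernel specifications
#'
#' Describe the kernels combined by the multiple-kernel fuzzy c-means.
#' Gaussian bandwidths may be given absolutely (`sigma`) or relative to the
#' median pairwise distance of the data (`factor`), resolved when the Gram
#' matrices are built. Linear and polynomial Gram matrices are
#' diagonal-normalized to unit diagonal so all kernels are commensurable
#' with the Gaussian ones.
#'
#' @param sigma Gaussian bandwidth (> 0), or `NULL` to use `factor` times
#'   the median pairwise distance.
#' @param factor multiplier for the median-distance heuristic.
#' @param degree,offset polynomial kernel parameters
#'   `(x.y + offset)^degree`, `degree >= 1`, `offset >= 0`.
#' @return a `mkftm_kernel` list.
#' @export
gaussian_kernel <- function(sigma = NULL, factor = 1) {
  if (!is.null(sigma)) stopifnot(sigma > 0)
  stopifnot(factor > 0)
  structure(list(kind = "gaussian", sigma = sigma, factor = factor),
            class = "mkftm_kernel")
}

#' @rdname gaussian_kernel
#' @export
polynomial_kernel <- function(degree = 2, offset = 1) {
  stopifnot(degree >= 1, offset >= 0)
  structure(list(kind = "polynomial", degree = degree, offset = offset),
            class = "mkftm_kernel")
}

#' @rdname gaussian_kernel
#' @export
linear_kernel <- function() {
  structure(list(kind = "linear"), class = "mkftm_kernel")
}

# default bank: three self-scaling gaussians around the median distance
default_kernels <- function() {
  list(gaussian_kernel(factor = 0.5), gaussian_kernel(factor = 1),
       gaussian_kernel(factor = 2))
}

#' Gram matrices for a kernel bank
#'
#' Evaluates each kernel on all point pairs. Gaussian kernels have unit
#' diagonal by construction; linear and polynomial Gram matrices are
#' normalized as G(i,j)/sqrt(G(i,i) G(j,j)).
#'
#' @param points numeric matrix, observations in rows.
#' @param kernels list of kernel specs (see [gaussian_kernel()]).
#' @return list of symmetric B x B matrices with unit diagonal.
#' @export
gram_matrices <- function(points, kernels = default_kernels()) {
  points <- as.matrix(points)
  B <- nrow(points)
  stopifnot(B >= 2L)
  D2 <- as.matrix(stats::dist(points))^2
  med <- stats::median(as.matrix(stats::dist(points))[upper.tri(D2)])
  if (!is.finite(med) || med <= 0) med <- 1  # coincident data fallback
  lapply(kernels, function(k) {
    G <- switch(k$kind,
      gaussian = {
        sigma <- k$sigma %||% (k$factor * med)
        exp(-D2 / (2 * sigma^2))
      },
      linear = {
        G0 <- tcrossprod(points)
        d <- sqrt(pmax(diag(G0), .Machine$double.eps))
        G0 / outer(d, d)
      },
      polynomial = {
        G0 <- (tcrossprod(points) + k$offset)^k$degree
        d <- sqrt(pmax(diag(G0), .Machine$double.eps))
        G0 / outer(d, d)
      },
      stop_mkftm("unknown kernel kind: ", k$kind, class = "mkftm_config_error"))
    if (any(!is.finite(G))) {
      stop_mkftm("non-finite Gram entries", class = "mkftm_numeric_error")
    }
    G <- (G + t(G)) / 2
    dimnames(G) <- NULL
    G
  })
}

#' MKFCM configuration
#'
#' @param n_clusters number of fuzzy clusters F (>= 1).
#' @param fuzzifier membership exponent s > 1 (default 2); s -> 1
#'   approaches hard clustering.
#' @param tolerance convergence threshold on the Frobenius norm of the
#'   membership change between iterations.
#' @param max_iterations iteration cap.
#' @param seed integer seed driving initialization (and restart seeds).
#' @param n_starts number of restarts; the run with the smallest final
#'   fuzzy objective `sum_i sum_f v_if^s T2_if` is kept.
#' @param kernels kernel bank; default three Gaussians at 0.5/1/2 times the
#'   median pairwise distance.
#' @param debug_checks assert the simplex constraints (membership rows and
#'   kernel weights) at every iteration.
#' @return a `mkftm_mkfcm_config` list.
#' @export
mkfcm_config <- function(n_clusters, fuzzifier = 2, tolerance = 1e-5,
                         max_iterations = 100L, seed = 1L, n_starts = 5L,
                         kernels = NULL, debug_checks = FALSE) {
  stopifnot(n_clusters >= 1, fuzzifier > 1, tolerance > 0, max_iterations >= 1,
            n_starts >= 1)
  structure(list(n_clusters = as.integer(n_clusters), fuzzifier = fuzzifier,
                 tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed), n_starts = as.integer(n_starts),
                 kernels = kernels %||% default_kernels(),
                 debug_checks = isTRUE(debug_checks)),
            class = "mkftm_mkfcm_config")
}

# squared feature-space distance of every point to each cluster's fuzzy
# centroid, for one kernel: alpha[i, f] =
#   G(i,i) - 2 sum_j vhat[j,f] G(i,j) + sum_jj' vhat[j,f] vhat[j',f] G(j,j')
# vhat columns must be the per-cluster normalized membership powers.
#' Feature-space distances to fuzzy centroids
#'
#' @param gram symmetric B x B Gram matrix.
#' @param vhat B x F matrix of normalized membership powers (columns sum
#'   to 1).
#' @return B x F matrix of squared distances (tiny negatives clipped to 0).
#' @export
alpha_coefficients <- function(gram, vhat) {
  if (any(abs(colSums(vhat) - 1) > 1e-6)) {
    stop_mkftm("vhat columns must sum to 1", class = "mkftm_state_error")
  }
  cross <- gram %*% vhat                              # B x F
  cent <- colSums(vhat * cross)                       # F: vhat_f' G vhat_f
  alpha <- matrix(diag(gram), nrow(gram), ncol(vhat)) - 2 * cross +
    matrix(cent, nrow(gram), ncol(vhat), byrow = TRUE)
  if (any(alpha < -1e-9)) {
    stop_mkftm("negative squared distance beyond tolerance",
               class = "mkftm_numeric_error")
  }
  pmax(alpha, 0)
}

#' Kernel weight update
#'
#' Computes beta_g = sum_{i,f} v_if^s alpha_ifg and the inverse-beta
#' normalized kernel weights z_g = (1/beta_g) / sum_h (1/beta_h). A kernel
#' with beta = 0 fits perfectly; its inverse is guarded with 1e-12 so the
#' arithmetic stays finite. If every beta is zero the weights fall back to
#' uniform with a notice.
#'
#' @param alpha list (length S) of B x F distance matrices.
#' @param membership B x F membership matrix V.
#' @param fuzzifier exponent s.
#' @return list with `beta` and simplex `z`, both length S.
#' @export
kernel_weight_update <- function(alpha, membership, fuzzifier) {
  Vs <- membership^fuzzifier
  beta <- vapply(alpha, function(a) sum(Vs * a), numeric(1))
  if (all(beta <= 1e-12)) {
    message("mkfcm: all kernels fit perfectly; uniform kernel weights")
    z <- rep(1 / length(beta), length(beta))
  } else {
    inv <- 1 / pmax(beta, 1e-12)
    z <- inv / sum(inv)
  }
  list(beta = beta, z = z)
}

#' Fuzzy membership update
#'
#' v_if = 1 / sum_f' (T2_if / T2_if')^(1/(s-1)). Rows with one or more
#' zero distances put uniform membership on the zero-distance clusters.
#'
#' @param T2 B x F matrix of combined squared distances (>= 0).
#' @param fuzzifier exponent s.
#' @return row-stochastic B x F membership matrix.
#' @export
membership_update <- function(T2, fuzzifier) {
  B <- nrow(T2); F_ <- ncol(T2)
  V <- matrix(0, B, F_)
  expo <- 1 / (fuzzifier - 1)
  for (i in seq_len(B)) {
    t2 <- T2[i, ]
    zero <- t2 <= 0
    if (any(zero)) {
      V[i, zero] <- 1 / sum(zero)
    } else {
      inv <- (1 / t2)^expo
      V[i, ] <- inv / sum(inv)
    }
  }
  V
}

#' Multiple-kernel fuzzy c-means
#'
#' Clusters points with fuzzy memberships under a convex combination of
#' kernel-induced feature-space geometries. Each iteration normalizes the
#' membership powers per cluster, computes the squared feature-space
#' distance of every point to every fuzzy centroid under every kernel,
#' re-weights the kernels inversely to their total fuzzy within-cluster
#' scatter, combines distances with the squared kernel weights, and updates
#' memberships; it stops when the Frobenius norm of the membership change
#' drops below the tolerance.
#'
#' @param points numeric matrix (B x d), e.g. PCA scores of documents.
#' @param config an [mkfcm_config()].
#' @param init optional B x F row-stochastic membership matrix used as the
#'   starting point (a single run; restarts are skipped).
#' @return `mkftm_mkfcm`: `membership` (B x F, rows sum to 1),
#'   `kernel_weights` (simplex, length S), `n_iter`, `converged`,
#'   `membership_change_trace`.
#' @export
mkfcm_fit <- function(points, config, init = NULL) {
  stopifnot(inherits(config, "mkftm_mkfcm_config"))
  points <- as.matrix(points)
  if (any(!is.finite(points))) {
    stop_mkftm("non-finite data", class = "mkftm_numeric_error")
  }
  B <- nrow(points)
  F_ <- config$n_clusters
  if (B < F_) {
    stop_mkftm("fewer points (", B, ") than clusters (", F_, ")",
               class = "mkftm_config_error")
  }
  grams <- gram_matrices(points, config$kernels)

  if (!is.null(init)) {
    init <- as.matrix(init)
    stopifnot(nrow(init) == B, ncol(init) == F_,
              all(abs(rowSums(init) - 1) < 1e-9))
    best <- mkfcm_single_run(points, grams, config, init_seed = NULL,
                             V0 = init)
  } else {
    # restart seeds derived reproducibly from the master seed
    init_seeds <- with_seed(config$seed,
                            sample.int(.Machine$integer.max, config$n_starts))
    best <- NULL
    for (r in seq_len(config$n_starts)) {
      run <- mkfcm_single_run(points, grams, config, init_seeds[r])
      if (is.null(best) || run$objective < best$objective) best <- run
      if (F_ == 1L) break   # single cluster: every start is identical
    }
  }
  rownames(best$membership) <- rownames(points)
  structure(list(membership = best$membership,
                 kernel_weights = best$kernel_weights,
                 n_iter = best$n_iter, converged = best$converged,
                 membership_change_trace = best$membership_change_trace,
                 objective = best$objective, config = config),
            class = "mkftm_mkfcm")
}

# one MKFCM run from one initialization; returns the final fuzzy objective
# sum_{i,f} v_if^s T2_if used to pick the best restart
mkfcm_single_run <- function(points, grams, config, init_seed, V0 = NULL) {
  B <- nrow(points)
  F_ <- config$n_clusters
  s <- config$fuzzifier
  S <- length(grams)

  # Initialization: F seed points chosen by k-means++-style D^2 weighting,
  # then fuzzy memberships from squared distances to the seeds. A fully
  # random row-stochastic start leaves every fuzzy centroid at the global
  # mean (the uniform membership fixed point), so seeds anchored at data
  # points are needed to break the symmetry. Reproducible from the seed.
  V <- if (!is.null(V0)) V0 else with_seed(init_seed, {
    seeds <- integer(F_)
    seeds[1] <- sample.int(B, 1L)
    if (F_ > 1L) {
      d2min <- rowSums(sweep(points, 2L, points[seeds[1], ])^2)
      for (f in 2:F_) {
        seeds[f] <- sample.int(B, 1L, prob = pmax(d2min, 1e-12))
        d2min <- pmin(d2min,
                      rowSums(sweep(points, 2L, points[seeds[f], ])^2))
      }
    }
    D2 <- vapply(seeds, function(sd) {
      rowSums(sweep(points, 2L, points[sd, ])^2)
    }, numeric(B))
    membership_update(matrix(D2, B, F_), s)
  })
  if (F_ == 1L) V[] <- 1

  trace <- numeric(0)
  converged <- FALSE
  z <- rep(1 / S, S)
  T2 <- matrix(0, B, F_)
  iter <- 0L
  for (iter in seq_len(config$max_iterations)) {
    Vs <- V^s
    vhat <- sweep(Vs, 2L, pmax(colSums(Vs), .Machine$double.xmin), "/")
    alpha <- lapply(grams, alpha_coefficients, vhat = vhat)
    kw <- kernel_weight_update(alpha, V, s)
    z <- kw$z
    T2 <- Reduce(`+`, Map(function(a, zg) a * zg^2, alpha, z))
    V_new <- membership_update(T2, s)
    if (isTRUE(config$debug_checks)) {
      stopifnot(all(abs(rowSums(V_new) - 1) < 1e-9),
                all(V_new >= 0), all(z >= 0), abs(sum(z) - 1) < 1e-9)
    }
    delta <- sqrt(sum((V_new - V)^2))
    trace <- c(trace, delta)
    V <- V_new
    if (delta < config$tolerance) {
      converged <- TRUE
      break
    }
  }
  list(membership = V, kernel_weights = z, n_iter = iter,
       converged = converged, membership_change_trace = trace,
       objective = sum(V^s * T2))
}

#' @export
print.mkftm_mkfcm <- function(x, ...) {
  cat(sprintf("<mkftm_mkfcm> %d points x %d clusters, %d kernels; %s in %d iterations\n",
              nrow(x$membership), ncol(x$membership),
              length(x$kernel_weights),
              if (x$converged) "converged" else "stopped", x$n_iter))
  invisible(x)
}

#' Hard cluster assignments from fuzzy memberships
#'
#' Argmax per row; ties go to the lowest cluster index.
#'
#' @param membership B x F membership matrix (or an `mkftm_mkfcm`).
#' @return integer vector of cluster indices in 1..F.
#' @export
hard_assignments <- function(membership) {
  if (inherits(membership, "mkftm_mkfcm")) membership <- membership$membership
  apply(membership, 1L, which.max)
}
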