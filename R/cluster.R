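## Shape-based clustering of individual telomere profiles: discrete
## Frechet distance between deviation curves, k centers seeded
## k-means++-style, assignment to the nearest center, centers updated as
## the pointwise median of their members (an update is only accepted when
## it does not increase the total within-cluster distance, so the
## objective is non-increasing by construction).

as_curve_matrix <- function(profiles) {
  if (is.matrix(profiles)) return(profiles)
  if (inherits(profiles, "trajectory")) profiles <- list(profiles)
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  grid <- profiles[[1L]]$age_month
  vals <- t(vapply(profiles, function(p) {
    stopifnot(identical(p$age_month, grid))
    p$value
  }, numeric(length(grid))))
  ids <- vapply(profiles, function(p) p$animal_id[1L], character(1))
  if (!anyNA(ids) && !anyDuplicated(ids)) rownames(vals) <- ids
  attr(vals, "grid") <- grid
  vals
}

#' Discrete Frechet distance between two curves
#'
#' Curve distance over monotone couplings of the two point sequences in
#' the (age, value) plane: the smallest achievable maximum pointwise gap
#' when both curves are traversed forward.  Symmetric, zero iff the
#' sampled curves are identical, and a metric on sampled curves.
#'
#' @param curve_a,curve_b \code{\link{trajectory}} objects, or numeric
#'   value vectors (then \code{grid} supplies the shared x coordinates).
#' @param grid Ages for plain numeric inputs.
#' @return Non-negative distance.
#' @export
frechet_distance <- function(curve_a, curve_b, grid = NULL) {
  get_xy <- function(cv) {
    if (inherits(cv, "trajectory") || (is.data.frame(cv) &&
                                       all(c("age_month", "value") %in%
                                             names(cv))))
      return(list(x = cv$age_month, y = cv$value))
    if (is.null(grid)) grid <- seq_along(cv)
    list(x = grid, y = as.numeric(cv))
  }
  a <- get_xy(curve_a); b <- get_xy(curve_b)
  if (!length(a$y) || !length(b$y)) stop("empty curve")
  dfrechet_cpp(a$x, a$y, b$x, b$y)
}

#' Cluster individual profiles into k shape groups
#'
#' Profiles (deviations from the fixed curve, all on one age grid) are
#' grouped under the discrete Frechet distance.  Initial centers are
#' seeded k-means++-style (first center uniform, subsequent ones with
#' probability proportional to squared distance from the chosen set);
#' iterations alternate nearest-center assignment with pointwise-median
#' center updates, accepting an update only if it does not increase the
#' total within-cluster distance.  Deterministic under \code{seed}.
#'
#' @param profiles List of \code{\link{trajectory}} objects (e.g. from
#'   \code{\link{animal_profiles}}) or an n x grid matrix with attribute
#'   \code{"grid"} (plain matrices default to a unit grid).
#' @param k Number of clusters (default 5: no change, mild and marked
#'   early-life decline, mild and marked early-life rise).
#' @param seed Integer seed.
#' @param max_iter Iteration cap.
#' @param nstart Number of k-means++ restarts; the solution with the lowest
#'   total within-cluster distance is kept (restart r uses seed
#'   \code{seed + r - 1}).
#' @return Object of class \code{cluster_result}: \code{cluster} (named
#'   integer labels, clusters ordered by decreasing size), \code{centers}
#'   (k x grid matrix), \code{proportions}, \code{total_within},
#'   \code{within_trace}, \code{iterations}, \code{grid}, \code{seed}.
#' @export
cluster_profiles <- function(profiles, k = 5L, seed = 1L, max_iter = 50L,
                             nstart = 5L) {
  M <- as_curve_matrix(profiles)
  grid <- attr(M, "grid")
  if (is.null(grid)) grid <- seq_len(ncol(M)) - 1
  n <- nrow(M)
  if (k < 1L) stop("k must be >= 1")
  if (k > n) stop("k exceeds the number of profiles")
  if (is.null(rownames(M))) rownames(M) <- paste0("A", seq_len(n))
  best <- NULL
  for (r in seq_len(nstart)) {
    res <- cluster_once(M, grid, k, seed + r - 1L, max_iter)
    if (is.null(best) || res$total_within < best$total_within) best <- res
  }
  best$seed <- seed
  best
}

cluster_once <- function(M, grid, k, seed, max_iter) {
  n <- nrow(M)
  set.seed(seed)

  ## k-means++ seeding under the Frechet distance
  centers <- M[sample.int(n, 1L), , drop = FALSE]
  while (nrow(centers) < k) {
    d2 <- apply(frechet_cross_cpp(M, centers, grid), 1L, min)^2
    nxt <- if (sum(d2) > 0) sample.int(n, 1L, prob = d2)
           else sample.int(n, 1L)
    centers <- rbind(centers, M[nxt, , drop = FALSE])
  }

  labels <- integer(n)
  within_trace <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    D <- frechet_cross_cpp(M, centers, grid)
    new_labels <- max.col(-D, ties.method = "first")
    ## re-seed any emptied cluster with the farthest profile
    if (!all(seq_len(k) %in% new_labels)) {
      for (cl in seq_len(k)) {
        if (!any(new_labels == cl)) {
          far <- which.max(D[cbind(seq_len(n), new_labels)])
          centers[cl, ] <- M[far, ]
          new_labels[far] <- cl
        }
      }
      D <- frechet_cross_cpp(M, centers, grid)
      new_labels <- max.col(-D, ties.method = "first")
    }
    within <- sum(D[cbind(seq_len(n), new_labels)])
    stable <- identical(new_labels, labels)
    labels <- new_labels
    within_trace <- c(within_trace, within)
    if (stable || iter >= max_iter) break
    ## median update, accepted per cluster only if it does not worsen
    for (cl in seq_len(k)) {
      mem <- M[labels == cl, , drop = FALSE]
      cand <- apply(mem, 2L, stats::median)
      old_d <- sum(frechet_cross_cpp(mem, centers[cl, , drop = FALSE],
                                     grid))
      new_d <- sum(frechet_cross_cpp(mem, matrix(cand, 1L), grid))
      if (new_d <= old_d) centers[cl, ] <- cand
    }
  }

  ## relabel by decreasing cluster size (stable, permutation-invariant)
  sizes <- tabulate(labels, k)
  perm <- order(sizes, decreasing = TRUE)
  relab <- match(seq_len(k), perm)
  labels <- relab[labels]
  centers <- centers[perm, , drop = FALSE]
  rownames(centers) <- paste0("C", seq_len(k))
  structure(list(
    cluster = stats::setNames(labels, rownames(M)),
    centers = centers,
    proportions = tabulate(labels, k) / n,
    total_within = within_trace[length(within_trace)],
    within_trace = within_trace,
    iterations = iter, grid = grid, seed = seed),
    class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Profile clustering: %d curves in %d cluster(s), total within-cluster Frechet distance %.4f\n",
              length(x$cluster), nrow(x$centers), x$total_within))
  cat("  proportions:",
      paste(sprintf("%.1f%%", 100 * x$proportions), collapse = " "), "\n")
  invisible(x)
}

#' Write cluster labels and cluster mean curves as CSVs
#'
#' @param result A \code{\link{cluster_profiles}} result.
#' @param labels_path,curves_path Output CSV paths (either may be
#'   \code{NULL} to skip).
#' @export
write_clusters <- function(result, labels_path = NULL, curves_path = NULL) {
  stopifnot(inherits(result, "cluster_result"))
  if (!is.null(labels_path)) {
    utils::write.csv(data.frame(animal_id = names(result$cluster),
                                cluster = paste0("C", result$cluster)),
                     labels_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(curves_path)) {
    k <- nrow(result$centers)
    df <- data.frame(
      cluster = rep(rownames(result$centers), each = length(result$grid)),
      age_month = rep(result$grid, k),
      value = as.vector(t(result$centers)))
    utils::write.csv(df, curves_path, row.names = FALSE, quote = FALSE)
  }
  invisible(result)
}
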