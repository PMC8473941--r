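# From-scratch community/lipid multivariate statistics: Bray-Curtis
# dissimilarity, two-dimensional non-metric multidimensional scaling with
# Kruskal stress-1, and the one-tailed permutation Mantel test.

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|x - y|) / sum(x + y)`, in `[0, 1]`: 0 for identical vectors, 1 for
#' vectors sharing no taxa. Not scale-invariant (doubling one sample's
#' counts changes the value), which is why community inputs are converted to
#' relative abundances first (see [bray_curtis_matrix()]).
#'
#' @param x,y Non-negative numeric vectors of equal length, not both zero.
#' @return Dissimilarity in `[0, 1]`.
#' @export
#' @examples
#' bray_curtis(c(1, 1), c(1, 3))
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) abort("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) abort("abundances must be non-negative")
  total <- sum(x) + sum(y)
  if (total == 0) {
    abort("Bray-Curtis undefined for two all-zero vectors")
  }
  sum(abs(x - y)) / total
}

#' Pairwise Bray-Curtis distance matrix
#'
#' Rows are samples. With `relative = TRUE` (the default) each row is first
#' normalised to sum to one, so the distance reflects composition rather
#' than sequencing depth or total concentration.
#'
#' @param x Numeric matrix or data frame of non-negative abundances with
#'   samples as rows; row names (or a `sample_id` column) label the output.
#' @param relative Convert rows to relative abundances first.
#' @return A symmetric labelled matrix with zero diagonal.
#' @export
bray_curtis_matrix <- function(x, relative = TRUE) {
  if (is.data.frame(x)) {
    if ("sample_id" %in% names(x)) {
      labels <- x$sample_id
      x <- as.matrix(x[setdiff(names(x), "sample_id")])
      rownames(x) <- labels
    } else {
      x <- as.matrix(x)
    }
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("sample_", seq_len(nrow(x)))
  if (relative) {
    rs <- rowSums(x)
    if (any(rs == 0)) abort("cannot normalise an all-zero sample row")
    x <- x / rs
  }
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- bray_curtis(x[i, ], x[j, ])
    }
  }
  d
}

validate_distance_matrix <- function(d, arg = "D") {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    abort(paste0(arg, " must be a square matrix or dist object"))
  }
  if (any(d < 0)) abort(paste0(arg, " must be non-negative"))
  if (any(abs(d - t(d)) > 1e-8)) abort(paste0(arg, " must be symmetric"))
  if (any(abs(diag(d)) > 1e-12)) abort(paste0(arg, " must have zero diagonal"))
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("sample_", seq_len(nrow(d)))
  }
  d
}

# Pool-adjacent-violators: weighted least-squares monotone non-decreasing fit.
pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (n == 0) return(numeric(0))
  # blocks as running (value, weight, size) stacks
  val <- numeric(n); wt <- numeric(n); sz <- integer(n)
  nb <- 0L
  for (i in seq_len(n)) {
    nb <- nb + 1L
    val[nb] <- y[i]; wt[nb] <- w[i]; sz[nb] <- 1L
    while (nb > 1L && val[nb - 1L] > val[nb]) {
      merged_w <- wt[nb - 1L] + wt[nb]
      val[nb - 1L] <- (wt[nb - 1L] * val[nb - 1L] + wt[nb] * val[nb]) / merged_w
      wt[nb - 1L] <- merged_w
      sz[nb - 1L] <- sz[nb - 1L] + sz[nb]
      nb <- nb - 1L
    }
  }
  rep.int(val[seq_len(nb)], sz[seq_len(nb)])
}

# Kruskal stress-1 of configuration distances d against dissimilarities
# delta, with the primary (weak-tie) treatment: within blocks of tied delta
# the configuration distances are pre-sorted so ties carry no penalty.
stress1 <- function(delta, d) {
  ord <- order(delta, d)
  dhat_sorted <- pava(d[ord])
  dhat <- numeric(length(d))
  dhat[ord] <- dhat_sorted
  sqrt(sum((d - dhat)^2) / sum(d^2))
}

lower_tri_vec <- function(m) m[lower.tri(m)]

config_distances <- function(x) as.matrix(dist(x))

guttman_update <- function(x, dhat_m) {
  n <- nrow(x)
  dm <- config_distances(x)
  ratio <- matrix(0, n, n)
  pos <- dm > 0
  ratio[pos] <- dhat_m[pos] / dm[pos]
  b <- -ratio
  diag(b) <- rowSums(ratio)
  (b %*% x) / n
}

nmds_one_start <- function(delta_m, x, max_iter, tol) {
  delta_v <- lower_tri_vec(delta_m)
  d_v <- lower_tri_vec(config_distances(x))
  s <- stress1(delta_v, d_v)
  trajectory <- s
  for (iter in seq_len(max_iter)) {
    # optimal monotone dhat for the current configuration
    ord <- order(delta_v, d_v)
    dhat_v <- numeric(length(d_v))
    dhat_v[ord] <- pava(d_v[ord])
    dhat_m <- matrix(0, nrow(x), nrow(x))
    dhat_m[lower.tri(dhat_m)] <- dhat_v
    dhat_m <- dhat_m + t(dhat_m)
    x_new <- guttman_update(x, dhat_m)
    d_new <- lower_tri_vec(config_distances(x_new))
    s_new <- stress1(delta_v, d_new)
    if (s_new > s) break # monotone descent: reject any uphill step
    improvement <- s - s_new
    x <- x_new
    d_v <- d_new
    s <- s_new
    trajectory <- c(trajectory, s)
    if (improvement < tol) {
      return(list(x = x, stress = s, converged = TRUE, trajectory = trajectory))
    }
  }
  list(x = x, stress = s, converged = FALSE, trajectory = trajectory)
}

#' Non-metric multidimensional scaling with Kruskal stress-1
#'
#' Embeds a dissimilarity matrix in `ndim` dimensions by minimising Kruskal
#' stress-1, `sqrt(sum((d - dhat)^2) / sum(d^2))`, where `d` are
#' configuration distances and `dhat` is the isotonic (pool-adjacent-
#' violators) regression of `d` on the input dissimilarities, with the
#' primary treatment of ties. Optimisation alternates the monotone
#' regression with a Guttman-transform configuration update and accepts only
#' stress-decreasing steps, so the stress trajectory is non-increasing by
#' construction. The first start is the classical-scaling (Torgerson)
#' configuration; remaining starts are random. The best of `n_restarts`
#' starts is returned; results are deterministic for a fixed `seed`.
#'
#' @param d Square symmetric dissimilarity matrix (or `dist`), `n >= 3`.
#' @param ndim Embedding dimension (default 2).
#' @param n_restarts Number of starts (default 20).
#' @param max_iter Iteration cap per start.
#' @param tol Stop when the stress improvement falls below this.
#' @param seed Integer seed for the random starts.
#' @return An object of class `nmds_fit`: `coordinates` (centred, labelled
#'   `n x ndim` matrix), `stress`, `converged`, `n_restarts_used`, and the
#'   best start's `stress_trajectory`. `tidy()` gives a coordinate tibble,
#'   `glance()` the fit summary, `autoplot()` an ordination plot.
#' @export
nmds <- function(d, ndim = 2, n_restarts = 20, max_iter = 500,
                 tol = 1e-7, seed = 1) {
  dm <- validate_distance_matrix(d)
  n <- nrow(dm)
  if (n < 3) abort("nmds needs at least 3 objects")
  off <- lower_tri_vec(dm)
  degenerate <- max(off) - min(off) < 1e-12
  if (degenerate) {
    warn("all dissimilarities are equal; ordination is degenerate")
  }

  starts <- withr::with_seed(seed, {
    lapply(seq_len(n_restarts), function(i) {
      if (i == 1 && !degenerate) {
        x0 <- tryCatch(
          cmdscale(dm, k = ndim),
          error = function(e) NULL,
          warning = function(w) suppressWarnings(cmdscale(dm, k = ndim))
        )
        if (!is.null(x0) && ncol(x0) == ndim) {
          return(x0)
        }
      }
      matrix(rnorm(n * ndim), n, ndim)
    })
  })

  fits <- lapply(starts, function(x0) {
    nmds_one_start(dm, x0, max_iter = max_iter, tol = tol)
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "stress"))]]
  coords <- scale(best$x, center = TRUE, scale = FALSE)
  attr(coords, "scaled:center") <- NULL
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("NMDS", seq_len(ndim))
  structure(
    list(
      coordinates = coords,
      stress = best$stress,
      converged = best$converged && !degenerate,
      n_restarts_used = n_restarts,
      stress_trajectory = best$trajectory,
      dissimilarity = dm
    ),
    class = "nmds_fit"
  )
}

#' @export
print.nmds_fit <- function(x, ...) {
  cat(sprintf(
    "NMDS ordination: %d points in %d dimensions\n",
    nrow(x$coordinates), ncol(x$coordinates)
  ))
  cat(sprintf(
    "  stress-1 = %.4g (%s)\n", x$stress,
    if (x$converged) "converged" else "not converged"
  ))
  invisible(x)
}

#' @rdname nmds
#' @param x,object An `nmds_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.nmds_fit <- function(x, ...) {
  tibble::as_tibble(x$coordinates, rownames = "sample_id")
}

#' @rdname nmds
#' @exportS3Method generics::glance
glance.nmds_fit <- function(x, ...) {
  tibble::tibble(
    stress = x$stress,
    converged = x$converged,
    n_restarts_used = x$n_restarts_used,
    n = nrow(x$coordinates),
    ndim = ncol(x$coordinates)
  )
}

#' @rdname nmds
#' @param colour_by Optional named vector (by sample label) used to colour
#'   points, e.g. a depth-cluster assignment.
#' @exportS3Method ggplot2::autoplot
autoplot.nmds_fit <- function(object, colour_by = NULL, ...) {
  dat <- tidy(object)
  if (!is.null(colour_by)) {
    dat$group <- unname(colour_by[dat$sample_id])
  }
  p <- ggplot2::ggplot(
    dat, ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2)
  )
  p <- if (is.null(colour_by)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
  }
  p +
    ggplot2::labs(
      title = sprintf("NMDS ordination (stress = %.3f)", object$stress),
      colour = NULL
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Permutation Mantel test between two distance matrices
#'
#' Pearson correlation of the lower-triangle entries, with significance from
#' jointly permuting the rows and columns of the second matrix. The p-value
#' is one-tailed for positive association with the add-one correction:
#' `p = (1 + #(r_perm >= r_obs)) / (1 + n_perm)`, so the smallest attainable
#' p with 999 permutations is 0.001.
#'
#' @param d1,d2 Square symmetric distance matrices (or `dist`) with matching
#'   labels, `n >= 4`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return An object of class `mantel_test` with `statistic` (r), `p_value`,
#'   `n_perm` and `n`. `tidy()`/`glance()` return a one-row tibble.
#' @export
mantel <- function(d1, d2, n_perm = 999, seed = 1) {
  m1 <- validate_distance_matrix(d1, "d1")
  m2 <- validate_distance_matrix(d2, "d2")
  n <- nrow(m1)
  if (n < 4) abort("mantel needs at least 4 objects")
  if (nrow(m2) != n) abort("matrices must have the same dimension")
  if (!identical(rownames(m1), rownames(m2))) {
    abort("matrices must share labels in the same order")
  }
  lt <- which(lower.tri(m1))
  v1 <- m1[lt]
  v2 <- m2[lt]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    abort("mantel undefined: a distance matrix has zero variance")
  }
  v1c <- v1 - mean(v1)
  ss1 <- sum(v1c^2)
  r_obs <- sum(v1c * (v2 - mean(v2))) / sqrt(ss1 * sum((v2 - mean(v2))^2))

  # permute labels of d2; index the flattened matrix directly
  idx <- arrayInd(lt, c(n, n))
  ii <- idx[, 1]
  jj <- idx[, 2]
  perm_r <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      p <- sample.int(n)
      v2p <- m2[cbind(p[ii], p[jj])]
      v2pc <- v2p - mean(v2p)
      sum(v1c * v2pc) / sqrt(ss1 * sum(v2pc^2))
    }, numeric(1))
  })
  p_value <- (1 + sum(perm_r >= r_obs)) / (1 + n_perm)
  structure(
    list(
      statistic = r_obs, p_value = p_value, n_perm = n_perm, n = n,
      perm_r = perm_r
    ),
    class = "mantel_test"
  )
}

#' @export
print.mantel_test <- function(x, ...) {
  cat(sprintf(
    "Mantel test: r = %.4f, p = %.4g (%d permutations, n = %d)\n",
    x$statistic, x$p_value, x$n_perm, x$n
  ))
  invisible(x)
}

#' @rdname mantel
#' @param x A `mantel_test`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mantel_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, p_value = x$p_value,
    n_perm = x$n_perm, n = x$n
  )
}

#' @rdname mantel
#' @exportS3Method generics::glance
glance.mantel_test <- function(x, ...) {
  tidy(x)
}
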