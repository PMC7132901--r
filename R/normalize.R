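#' Normalized expression matrix container
#'
#' Light wrapper tying a cells x genes real-valued matrix to the
#' normalization method that produced it and its parameters.
#'
#' @param values Matrix (dense or sparse), cells x genes.
#' @param method `"lognorm"`, `"nb_residual"` or `"scaled"`.
#' @param params List of method parameters.
#' @param clip Symmetric clip bound applied to the values (or `NA`).
#' @return An object of class `norm_matrix`.
#' @export
norm_matrix <- function(values, method, params = list(), clip = NA_real_) {
  structure(list(values = values, method = method, params = params, clip = clip),
            class = "norm_matrix")
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat("norm_matrix (", x$method, "): ", nrow(x$values), " cells x ",
      ncol(x$values), " genes\n", sep = "")
  invisible(x)
}

#' Log-normalize UMI counts
#'
#' `value = ln(1 + count * scale_factor / cell_total)`: counts are scaled to
#' a common library size and shifted-log transformed, so equal proportions
#' give equal values regardless of depth.
#'
#' @param um A [umi_matrix()].
#' @param scale_factor Common library size (default 1e4).
#' @return A `norm_matrix` with method `"lognorm"` (sparse values).
#' @export
lognormalize <- function(um, scale_factor = 1e4) {
  total <- Matrix::rowSums(um$counts)
  if (any(total == 0))
    stop("cells with zero total UMI cannot be log-normalized: ",
         paste(um$barcodes[total == 0], collapse = ", "))
  v <- Matrix::Diagonal(x = scale_factor / total) %*% um$counts
  v <- methods::as(methods::as(v, "generalMatrix"), "CsparseMatrix")
  v@x <- log1p(v@x)
  dimnames(v) <- dimnames(um$counts)
  norm_matrix(v, "lognorm", params = list(scale_factor = scale_factor))
}

# Local-linear Gaussian kernel regression of y on x, evaluated at x.
# Fitted on a grid of 200 points and linearly interpolated; local-linear
# fits avoid the boundary and design bias of a local-constant smoother on
# the near-linear parameter-vs-mean curves being regularized.
kernel_smooth <- function(x, y, bandwidth) smooth_from(x, y, x, bandwidth)

# Fit the local-linear smoother on (x, y), evaluate at xout (constant
# extrapolation beyond the training range).
smooth_from <- function(x, y, xout, bandwidth) {
  ok <- is.finite(y) & is.finite(x)
  xs <- x[ok]; ys <- y[ok]
  grid <- seq(min(xs), max(xs), length.out = min(200, length(unique(xs))))
  fit <- vapply(grid, function(x0) {
    w <- stats::dnorm((xs - x0) / bandwidth)
    z <- xs - x0
    sw <- sum(w); swz <- sum(w * z); swz2 <- sum(w * z^2)
    swy <- sum(w * ys); swzy <- sum(w * z * ys)
    det <- sw * swz2 - swz^2
    if (det <= .Machine$double.eps * sw * swz2 || !is.finite(det) || det == 0)
      return(swy / sw)
    (swz2 * swy - swz * swzy) / det     # intercept of the local line at x0
  }, numeric(1))
  if (length(grid) == 1) return(rep(fit, length(xout)))
  stats::approx(grid, fit, xout = xout, rule = 2)$y
}

# Method-of-moments dispersion from counts and fitted means.
theta_mom <- function(y, mu) {
  num <- sum(mu^2)
  den <- sum((y - mu)^2 - mu)
  if (den <= 0) return(Inf)
  num / den
}

#' Regularized negative-binomial Pearson residuals
#'
#' Variance-stabilizing normalization for UMI counts: per gene, a
#' negative-binomial regression of counts on log10 of the cell total
#' (intercept + slope, log link) is fitted, the dispersion `theta` is
#' estimated (method-of-moments start, maximum-likelihood refinement), and
#' the per-gene parameters are then regularized by Gaussian kernel
#' regression over log10 of the gene mean so that parameter estimates vary
#' smoothly with expression level. The output is the Pearson residual
#' `(x - mu) / sqrt(mu + mu^2/theta)` under the regularized model, clipped
#' to `+/- sqrt(n_cells)`.
#'
#' @param um A [umi_matrix()].
#' @param min_cells Genes detected in fewer cells are carried with zero
#'   residuals (reported via message).
#' @param max_cells_fit Per-gene fits use at most this many cells
#'   (seeded subsample); residuals are computed for all cells.
#' @param bandwidth_factor Kernel bandwidth as a multiple of the Silverman
#'   rule-of-thumb bandwidth on log10 gene means (default 3).
#' @param seed Seed for the fitting subsample.
#' @return A `norm_matrix` with method `"nb_residual"`; `params` holds the
#'   per-gene raw and regularized intercept, slope and theta.
#' @export
nb_regularized_residuals <- function(um, min_cells = 5, max_cells_fit = 2000,
                                     bandwidth_factor = 3, seed = 1L) {
  cnt <- um$counts
  n_cells <- nrow(cnt); n_genes <- ncol(cnt)
  total <- Matrix::rowSums(cnt)
  if (any(total == 0)) stop("cells with zero total UMI must be filtered first")
  lt <- log10(total)
  X <- cbind(intercept = 1, log10_total = lt)

  det <- Matrix::colSums(cnt > 0)
  fit_genes <- which(det >= min_cells)
  if (length(fit_genes) < n_genes)
    message(n_genes - length(fit_genes),
            " gene(s) detected in fewer than ", min_cells,
            " cells carried with zero residuals")
  if (length(fit_genes) == 0) stop("no genes pass the detection threshold")

  sub <- if (n_cells > max_cells_fit) {
    set.seed(seed); sort(sample.int(n_cells, max_cells_fit))
  } else seq_len(n_cells)
  Xs <- X[sub, , drop = FALSE]

  beta0 <- beta1 <- theta <- rep(NA_real_, n_genes)
  dense <- as.matrix(cnt[sub, fit_genes, drop = FALSE])
  for (j in seq_along(fit_genes)) {
    y <- dense[, j]
    fit <- tryCatch(
      stats::glm.fit(Xs, y, family = stats::poisson()),
      error = function(e) NULL)
    if (!is.null(fit) && anyNA(fit$coefficients)) {
      # degenerate design (constant depth): intercept-only model
      fit$coefficients <- c(log(mean(y)), 0)
      fit$fitted.values <- rep(mean(y), length(y))
      fit$converged <- TRUE
    }
    if (is.null(fit) || !fit$converged) {
      # fall back to intercept-only Poisson (theta = Inf)
      beta0[fit_genes[j]] <- log(mean(y)); beta1[fit_genes[j]] <- 0
      theta[fit_genes[j]] <- Inf
      warning("gene ", um$genes$gene_id[fit_genes[j]],
              ": regression did not converge; Poisson fallback")
      next
    }
    mu <- fit$fitted.values
    th <- theta_mom(y, mu)
    if (is.finite(th)) {
      th <- tryCatch(
        suppressWarnings(as.numeric(MASS::theta.ml(y, mu, limit = 25))),
        error = function(e) th)
    }
    beta0[fit_genes[j]] <- fit$coefficients[1]
    beta1[fit_genes[j]] <- fit$coefficients[2]
    theta[fit_genes[j]] <- th
  }

  # Regularize over log10 gene mean; theta smoothed on log10 scale with a
  # finite cap so Poisson-like genes do not dominate the kernel average.
  # Genes whose raw parameter estimates are gross outliers relative to a
  # first-pass smooth (e.g. a single aberrant count dominating the fit) are
  # excluded from the regression; they still receive regularized values
  # from the final curve.
  gene_mean <- Matrix::colMeans(cnt)
  lm10 <- log10(pmax(gene_mean, 1e-8))
  bw <- bandwidth_factor * stats::bw.nrd0(lm10[fit_genes])
  log_theta <- log10(pmin(theta, 1e6))
  b0_reg <- b1_reg <- th_reg <- rep(NA_real_, n_genes)
  if (length(fit_genes) >= 3) {
    x <- lm10[fit_genes]
    param_outlier <- function(y) {
      d <- y - kernel_smooth(x, y, bw)
      s <- 1.4826 * stats::mad(d, constant = 1)
      # gross outliers only: beyond 5 robust SDs and beyond 1 unit
      s > 0 & abs(d) > 5 * s & abs(d) > 1
    }
    out_fl <- param_outlier(beta0[fit_genes]) |
      param_outlier(beta1[fit_genes]) | param_outlier(log_theta[fit_genes])
    use <- if (sum(!out_fl) >= 3) !out_fl else rep(TRUE, length(fit_genes))
    b0_reg[fit_genes] <- smooth_from(x[use], beta0[fit_genes][use], x, bw)
    b1_reg[fit_genes] <- smooth_from(x[use], beta1[fit_genes][use], x, bw)
    th_reg[fit_genes] <- 10^smooth_from(x[use], log_theta[fit_genes][use], x, bw)
  } else {
    b0_reg <- beta0; b1_reg <- beta1; th_reg <- theta
  }

  clip <- sqrt(n_cells)
  res <- matrix(0, n_cells, n_genes, dimnames = dimnames(cnt))
  mu_fit <- exp(outer(rep(1, n_cells), b0_reg[fit_genes]) +
                  outer(lt, b1_reg[fit_genes]))
  sd_fit <- sqrt(mu_fit + sweep(mu_fit^2, 2, th_reg[fit_genes], `/`))
  res[, fit_genes] <- (as.matrix(cnt[, fit_genes, drop = FALSE]) - mu_fit) / sd_fit
  res[res > clip] <- clip
  res[res < -clip] <- -clip

  norm_matrix(res, "nb_residual",
              params = list(beta0 = beta0, beta1 = beta1, theta = theta,
                            beta0_reg = b0_reg, beta1_reg = b1_reg,
                            theta_reg = th_reg, bandwidth = bw,
                            fit_genes = um$genes$gene_id[fit_genes]),
              clip = clip)
}
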