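#' Log-likelihood of the bivariate Brownian-Motion model
#'
#' Under multivariate Brownian Motion on a rooted time tree, the stacked
#' observation vector \code{y = (x[1, ], x[2, ])} is multivariate normal with
#' mean \code{theta[a]} repeated per trait and covariance
#' \deqn{\Sigma_{(i,a),(j,b)} = C_{ij} R_{ab} + 1\{i=j, a=b\}\, se_{a,i}^2,}
#' where \code{C} is the species covariance matrix of the tree and \code{R}
#' the 2 x 2 evolutionary rate matrix (trait variances per unit time on the
#' diagonal, trait covariance off-diagonal).
#'
#' This is the reference (dense, pure-R) implementation; model fitting uses a
#' compiled equivalent that is cross-checked against it.
#'
#' @param C Species covariance matrix (n x n), e.g. from [tree_vcv()].
#' @param x 2 x n matrix of trait values (rows = traits, columns = species in
#'   the order of \code{C}).
#' @param se 2 x n matrix of measurement standard errors (default 0).
#' @param theta Length-2 root state.
#' @param R 2 x 2 positive-definite rate matrix.
#' @return The log density (numeric scalar).
#' @export
mvbm_loglik <- function(C, x, se = NULL, theta, R) {
  n <- ncol(C)
  stopifnot(nrow(x) == 2, ncol(x) == n, length(theta) == 2,
            identical(dim(R), c(2L, 2L)))
  if (is.null(se)) se <- matrix(0, 2, n)
  se <- check_se(se, n)
  Sigma <- kronecker(R, C) + diag(c(se[1, ]^2, se[2, ]^2), 2 * n)
  y <- c(x[1, ], x[2, ]) - rep(theta, each = n)
  L <- tryCatch(t(chol(Sigma)), error = function(e) {
    stop("covariance matrix is singular (condition number ~ ",
         format(kappa(Sigma), digits = 3), ")")
  })
  z <- forwardsolve(L, y)
  -0.5 * (2 * n * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
}

check_se <- function(se, n) {
  if (length(se) == 1) se <- matrix(se, 2, n)
  se <- as.matrix(se)
  stopifnot(nrow(se) == 2, ncol(se) == n)
  if (any(is.na(se))) {
    warning("missing SE treated as 0; consider apply_proxy_se()")
    se[is.na(se)] <- 0
  }
  if (any(se < 0)) stop("standard errors must be nonnegative")
  se
}

# Multi-start ML fit in the (log r11, log r22, atanh rho) parameterization.
# theta is profiled out by GLS inside the objective.
ZMAX <- atanh(1 - 1e-6)

fit_mvbm <- function(C, x, se, constrain_zero_cov = FALSE,
                     z_starts = c(-0.5, 0, 0.5), extra_starts = FALSE) {
  n <- ncol(C)
  y <- c(x[1, ], x[2, ])
  se2 <- c(se[1, ]^2, se[2, ]^2)
  depth <- mean(diag(C))
  a0 <- log(max(stats::var(x[1, ]), 1e-12) / depth)
  b0 <- log(max(stats::var(x[2, ]), 1e-12) / depth)
  if (constrain_zero_cov) z_starts <- 0
  if (extra_starts) z_starts <- unique(c(z_starts, -2, 2))
  best <- NULL
  for (z0 in z_starts) {
    par0 <- if (constrain_zero_cov) c(a0, b0) else c(a0, b0, z0)
    lower <- c(-40, -40, -ZMAX)[seq_along(par0)]
    upper <- c(40, 40, ZMAX)[seq_along(par0)]
    opt <- tryCatch(
      stats::optim(par0, .mvbm_nll, C = C, y = y, se2 = se2,
                   constrained = constrain_zero_cov, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 10, maxit = 500)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    return(list(converged = FALSE, loglik = NA_real_, theta = c(NA, NA),
                R = matrix(NA, 2, 2), rho_c = NA_real_, boundary = FALSE,
                n_species = n))
  }
  if (best$convergence != 0) {
    # polish an abnormal L-BFGS-B termination with a derivative-free search
    polish <- tryCatch(
      stats::optim(best$par, .mvbm_nll, C = C, y = y, se2 = se2,
                   constrained = constrain_zero_cov, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(polish) && polish$value <= best$value + 1e-8) {
      polish$par <- pmin(pmax(polish$par, c(-40, -40, -ZMAX)[seq_along(polish$par)]),
                         c(40, 40, ZMAX)[seq_along(polish$par)])
      best <- polish
    }
  }
  ev <- .mvbm_eval(best$par, C, y, se2, constrain_zero_cov)
  z <- if (constrain_zero_cov) 0 else best$par[3]
  rho <- tanh(z)
  boundary <- abs(rho) >= 1 - 1e-6 - 1e-12
  if (boundary) rho <- sign(rho) * (1 - 1e-6)
  list(converged = best$convergence == 0, loglik = ev$loglik,
       theta = as.numeric(ev$theta), R = ev$R, rho_c = rho,
       boundary = boundary, n_species = n)
}

#' Fit the bivariate Brownian-Motion coevolution model for one gene pair
#'
#' Fits, by maximum likelihood, a bivariate Brownian-Motion model of two
#' traits (gene expression values) evolving on a phylogeny, optionally with
#' per-observation measurement error. The full model allows a nonzero
#' evolutionary covariance \code{r12}; the nested null model forces
#' independent evolution (\code{r12 = 0}). The phylogenetically-corrected
#' correlation is \deqn{\rho_C = r_{12} / \sqrt{r_{11} r_{22}},} and the
#' likelihood-ratio statistic \code{2 * (logLik_full - logLik_null)} is
#' referred to a chi-squared distribution with 1 degree of freedom.
#'
#' Optimization uses a quasi-Newton search over \code{(log r11, log r22,
#' atanh rho)} with three deterministic starts for the correlation, profiling
#' the root state out by GLS. Collinear traits drive the estimate to the
#' boundary; \code{|rho_C|} is then clamped to \code{1 - 1e-6} and flagged.
#'
#' @param x,y Numeric vectors of trait values per species (named, or in the
#'   order of the tree's tips / of \code{C}).
#' @param tree A rooted \code{"phylo"} object; alternatively supply \code{C}.
#' @param C Species covariance matrix; computed from \code{tree} if missing.
#' @param se_x,se_y Measurement standard errors per species (scalar or
#'   vector; default 0). Missing values are treated as 0 with a warning.
#' @param fit_null Logical; also fit the constrained (r12 = 0) model and
#'   compute the likelihood-ratio test (default \code{TRUE}).
#' @return An object of class \code{"bm_corr"} with components \code{full} and
#'   \code{null} (each with \code{theta}, \code{R}, \code{loglik},
#'   \code{rho_c}, \code{converged}, \code{boundary}), plus \code{lrt},
#'   \code{p_value}, \code{rho_u} (uncorrected Pearson correlation),
#'   \code{n_species} and \code{data}.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' fit <- bm_corr(c(A = 1, B = 0.5, C = -1), c(A = 0.8, B = 0.2, C = -1.2), tr)
#' fit$rho_c
#' @export
bm_corr <- function(x, y, tree = NULL, C = NULL, se_x = 0, se_y = 0,
                    fit_null = TRUE) {
  if (is.null(C)) {
    if (is.null(tree)) stop("supply either 'tree' or 'C'")
    C <- tree_vcv(tree)
  }
  n <- ncol(C)
  if (!is.null(names(x)) && !is.null(rownames(C))) {
    if (!all(rownames(C) %in% names(x))) stop("species names of x do not cover the tree")
    x <- x[rownames(C)]
    y <- y[rownames(C)]
  }
  if (length(x) != n || length(y) != n) stop("trait length must match the tree")
  if (n < 3) stop("need at least 3 species")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("traits must be non-constant")
  se <- check_se(rbind(rep_len(se_x, n), rep_len(se_y, n)), n)
  xm <- rbind(x, y)
  full <- fit_mvbm(C, xm, se, constrain_zero_cov = FALSE)
  if (fit_null) {
    null <- fit_mvbm(C, xm, se, constrain_zero_cov = TRUE)
    lrt <- lrt_stat(full, null, C, xm, se)
  } else {
    null <- NULL
    lrt <- list(stat = NA_real_, p = NA_real_)
  }
  ru <- rho_u(x, y)
  structure(list(full = full, null = null, lrt = lrt$stat,
                 p_value = lrt$p, rho_c = full$rho_c, rho_u = ru$r,
                 n_species = n, data = list(x = x, y = y, se = se, C = C)),
            class = "bm_corr")
}

# LRT with a refit escape hatch: if the constrained optimum beats the full
# one beyond tolerance, rerun the full fit with extra starts.
lrt_stat <- function(full, null, C, xm, se, tol = 1e-6) {
  if (!full$converged || !null$converged) {
    return(list(stat = NA_real_, p = NA_real_, full = full))
  }
  stat <- 2 * (full$loglik - null$loglik)
  if (stat < -tol) {
    full2 <- fit_mvbm(C, xm, se, constrain_zero_cov = FALSE,
                      extra_starts = TRUE)
    if (full2$loglik >= full$loglik) full <- full2
    stat <- 2 * (full$loglik - null$loglik)
    if (stat < -tol) {
      stop("constrained log-likelihood exceeds the full model beyond tolerance")
    }
  }
  stat <- max(stat, 0)
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       full = full)
}

#' Phylogenetically-uncorrected Pearson correlation
#'
#' The ordinary Pearson correlation of tip values across species, with the
#' standard two-sided t-test on \code{n - 2} degrees of freedom. This ignores
#' shared ancestry and serves as the baseline the phylogenetic method is
#' compared against.
#'
#' @param x,y Numeric vectors, length \code{n >= 3}, non-constant.
#' @return A list with \code{r} and \code{p}.
#' @export
rho_u <- function(x, y) {
  if (length(x) < 3) stop("need at least 3 species")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("traits must be non-constant")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' @export
print.bm_corr <- function(x, ...) {
  cat("Bivariate Brownian-Motion fit (", x$n_species, " species)\n", sep = "")
  cat(sprintf("  rho_C = %.4f   rho_U = %.4f\n", x$rho_c, x$rho_u))
  cat(sprintf("  LRT = %.4f, p = %.4g\n", x$lrt, x$p_value))
  if (isTRUE(x$full$boundary)) cat("  note: correlation at boundary\n")
  invisible(x)
}

#' @export
summary.bm_corr <- function(object, ...) {
  R <- object$full$R
  cat("Bivariate Brownian-Motion model of trait coevolution\n")
  cat("Species:", object$n_species, "\n\n")
  cat("Evolutionary rate matrix (full model):\n")
  print(round(R, 6))
  cat(sprintf("\nRoot state theta: (%.4f, %.4f)\n",
              object$full$theta[1], object$full$theta[2]))
  cat(sprintf("rho_C = %.4f (phylogenetically corrected)\n", object$rho_c))
  cat(sprintf("rho_U = %.4f (uncorrected Pearson)\n", object$rho_u))
  if (!is.null(object$null)) {
    cat(sprintf("logLik full = %.4f, null (r12 = 0) = %.4f\n",
                object$full$loglik, object$null$loglik))
    cat(sprintf("LRT = %.4f on 1 df, p = %.4g\n", object$lrt, object$p_value))
  }
  invisible(object)
}

#' @export
coef.bm_corr <- function(object, ...) {
  R <- object$full$R
  c(theta1 = object$full$theta[1], theta2 = object$full$theta[2],
    r11 = R[1, 1], r22 = R[2, 2], r12 = R[1, 2], rho_c = object$rho_c)
}

#' @export
logLik.bm_corr <- function(object, ...) {
  structure(object$full$loglik, df = 5, nobs = 2 * object$n_species,
            class = "logLik")
}

#' @export
simulate.bm_corr <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  C <- object$data$C
  out <- replicate(nsim, simulate_pair(C = C, R = object$full$R,
                                       theta = object$full$theta,
                                       se = object$data$se),
                   simplify = FALSE)
  if (nsim == 1) out[[1]] else out
}

#' @export
residuals.bm_corr <- function(object, ...) {
  # phylogenetically whitened residuals of the full model
  C <- object$data$C
  se <- object$data$se
  n <- ncol(C)
  R <- object$full$R
  Sigma <- kronecker(R, C) + diag(c(se[1, ]^2, se[2, ]^2), 2 * n)
  y <- c(object$data$x, object$data$y) - rep(object$full$theta, each = n)
  z <- forwardsolve(t(chol(Sigma)), y)
  matrix(z, nrow = 2, byrow = TRUE,
         dimnames = list(c("trait1", "trait2"), colnames(C)))
}

#' Fit the coevolution model for a table of gene pairs
#'
#' Runs [bm_corr()] for each row of \code{pairs} against an expression panel,
#' returning one row per pair with the fitted rate matrix, the
#' phylogenetically-corrected correlation \code{rho_c}, the uncorrected
#' correlation \code{rho_u}, likelihood-ratio statistics and (BH-adjusted)
#' p-values. Non-convergent pairs are flagged and their test columns set to
#' \code{NA} with a warning.
#'
#' @param panel An \code{"expression_panel"} with complete data for the genes
#'   used (see [filter_complete()]).
#' @param pairs Data frame with columns \code{gene1}, \code{gene2}; other
#'   columns (e.g. \code{group}) are carried through.
#' @param tree A rooted \code{"phylo"} object whose tips match
#'   \code{panel$species}; alternatively supply \code{C}.
#' @param C Optional precomputed species covariance matrix.
#' @param use_se Logical; use the panel's standard errors as measurement
#'   error (default \code{TRUE}).
#' @param adjust Logical; append BH-adjusted q-values over all tested pairs
#'   (default \code{TRUE}).
#' @return A data frame of class \code{"phycor_fits"}.
#' @export
fit_pairs <- function(panel, pairs, tree = NULL, C = NULL, use_se = TRUE,
                      adjust = TRUE) {
  stopifnot(inherits(panel, "expression_panel"))
  if (is.null(C)) C <- tree_vcv(tree)
  sp <- rownames(C)
  if (!all(sp %in% panel$species)) stop("panel does not cover all tree tips")
  m <- nrow(pairs)
  cols <- c("rho_c", "rho_u", "p_u", "theta1", "theta2", "r11", "r22", "r12",
            "loglik_full", "loglik_null", "lrt", "p")
  out <- as.data.frame(matrix(NA_real_, m, length(cols)))
  names(out) <- cols
  out <- cbind(pairs, out, boundary = FALSE, converged = FALSE)
  se0 <- matrix(0, 1, length(sp))
  for (k in seq_len(m)) {
    g1 <- pairs$gene1[k]; g2 <- pairs$gene2[k]
    x <- panel$mean[sp, g1]; y <- panel$mean[sp, g2]
    if (anyNA(x) || anyNA(y)) {
      warning("missing data for pair ", g1, "-", g2, "; skipped")
      next
    }
    sx <- if (use_se) panel$se[sp, g1] else se0[1, ]
    sy <- if (use_se) panel$se[sp, g2] else se0[1, ]
    sx[is.na(sx)] <- 0; sy[is.na(sy)] <- 0
    fit <- bm_corr(x, y, C = C, se_x = sx, se_y = sy)
    out$rho_c[k] <- fit$rho_c
    out$rho_u[k] <- fit$rho_u
    ru <- rho_u(x, y)
    out$p_u[k] <- ru$p
    out$theta1[k] <- fit$full$theta[1]; out$theta2[k] <- fit$full$theta[2]
    R <- fit$full$R
    out$r11[k] <- R[1, 1]; out$r22[k] <- R[2, 2]; out$r12[k] <- R[1, 2]
    out$loglik_full[k] <- fit$full$loglik
    out$loglik_null[k] <- fit$null$loglik
    out$lrt[k] <- fit$lrt
    out$p[k] <- fit$p_value
    out$boundary[k] <- isTRUE(fit$full$boundary)
    out$converged[k] <- fit$full$converged && fit$null$converged
  }
  if (any(!out$converged)) {
    warning(sum(!out$converged), " pairs failed to converge; excluded from tests")
  }
  if (adjust) {
    out$q <- NA_real_
    ok <- out$converged & !is.na(out$p)
    out$q[ok] <- bh_adjust(out$p[ok])
    out$q_u <- NA_real_
    oku <- !is.na(out$p_u)
    out$q_u[oku] <- bh_adjust(out$p_u[oku])
  }
  class(out) <- c("phycor_fits", "data.frame")
  out
}

#' @export
print.phycor_fits <- function(x, ...) {
  cat("Coevolution fits for", nrow(x), "gene pairs\n")
  cat(sprintf("  mean rho_C = %.3f, mean rho_U = %.3f\n",
              mean(x$rho_c, na.rm = TRUE), mean(x$rho_u, na.rm = TRUE)))
  if ("q" %in% names(x)) {
    cat("  pairs with q < 0.05:", sum(x$q < 0.05, na.rm = TRUE), "\n")
  }
  invisible(x)
}
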