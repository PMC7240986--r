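#' Simulation configuration
#'
#' Bundles the parameters of the synthetic world used for benchmarking:
#' an 18-tip time tree with a root age of 723 million years, binding pairs
#' whose true evolutionary correlation is drawn from a truncated normal with
#' mean 0.45 and sd 0.25 on (-1, 1), control pairs with correlation 0,
#' per-trait Brownian rates drawn lognormal(0, 0.5), and replicate-level
#' observation noise.
#'
#' @param n_tips Number of species (default 18).
#' @param root_age Root age in millions of years (default 723).
#' @param n_binding,n_control Pair counts (defaults 500, 500).
#' @param rho_mean,rho_sd Mean and sd of the truncated-normal distribution of
#'   binding-pair correlations (defaults 0.45, 0.25).
#' @param sigma_meanlog,sigma_sdlog Lognormal parameters of the per-trait
#'   rates r11, r22 (defaults 0, 0.5).
#' @param n_replicates Replicates per species (default 3).
#' @param obs_noise_sd Standard deviation of replicate-level observation
#'   noise (default 1).
#' @param seed Integer seed (default 1).
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_tips = 18, root_age = 723, n_binding = 500,
                       n_control = 500, rho_mean = 0.45, rho_sd = 0.25,
                       sigma_meanlog = 0, sigma_sdlog = 0.5,
                       n_replicates = 3, obs_noise_sd = 1, seed = 1) {
  stopifnot(n_tips >= 3, root_age > 0, n_binding >= 0, n_control >= 0,
            abs(rho_mean) < 1, rho_sd > 0, n_replicates >= 1,
            obs_noise_sd >= 0)
  structure(list(n_tips = n_tips, root_age = root_age, n_binding = n_binding,
                 n_control = n_control, rho_mean = rho_mean, rho_sd = rho_sd,
                 sigma_meanlog = sigma_meanlog, sigma_sdlog = sigma_sdlog,
                 n_replicates = n_replicates, obs_noise_sd = obs_noise_sd,
                 seed = seed),
            class = "sim_config")
}

#' Simulate a time-calibrated phylogeny
#'
#' A pure-birth (Yule) topology with the requested number of tips, rescaled
#' so the root-to-tip height equals \code{root_age}. Deterministic under a
#' fixed seed.
#'
#' @param n_tips Number of tips (>= 3).
#' @param root_age Root height after rescaling (default 723).
#' @param seed Optional integer seed.
#' @return An ultrametric \code{"phylo"} object with tips \code{s1..sn}.
#' @export
simulate_tree <- function(n_tips, root_age = 723, seed = NULL) {
  if (n_tips < 3) stop("need at least 3 tips")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  tree$tip.label <- paste0("s", seq_len(n_tips))
  tree$edge.length <- tree$edge.length * root_age / tree_height(tree)
  tree
}

#' Construct an evolutionary rate matrix from variances and correlation
#'
#' @param r11,r22 Positive per-trait variances per unit time.
#' @param rho Evolutionary correlation in (-1, 1).
#' @return A 2 x 2 positive-definite matrix.
#' @export
rate_matrix <- function(r11, r22, rho) {
  stopifnot(r11 > 0, r22 > 0, abs(rho) < 1)
  matrix(c(r11, rho * sqrt(r11 * r22), rho * sqrt(r11 * r22), r22), 2, 2)
}

#' Simulate one trait pair under bivariate Brownian Motion
#'
#' Draws tip values from the multivariate normal with mean \code{theta} per
#' trait and covariance \code{R (x) C} plus independent observation noise
#' with the given standard errors — the same covariance structure evaluated
#' by [mvbm_loglik()].
#'
#' @param tree A \code{"phylo"} object; alternatively supply \code{C}.
#' @param C Optional species covariance matrix.
#' @param R 2 x 2 positive-definite rate matrix.
#' @param theta Length-2 root state (default \code{c(0, 0)}).
#' @param se 2 x n matrix (or scalar) of observation noise sds (default 0).
#' @param seed Optional integer seed.
#' @return A 2 x n matrix of trait values (columns named by species).
#' @export
simulate_pair <- function(tree = NULL, C = NULL, R, theta = c(0, 0), se = 0,
                          seed = NULL) {
  if (is.null(C)) C <- tree_vcv(tree)
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(C)
  se <- check_se(se, n)
  L_C <- t(chol(C))
  L_R <- t(chol(R))
  Z <- matrix(stats::rnorm(2 * n), n, 2)
  X <- t(L_C %*% Z %*% t(L_R))  # 2 x n, covariance R (x) C
  X <- X + theta + matrix(stats::rnorm(2 * n, sd = c(se)), 2, n)
  colnames(X) <- colnames(C)
  rownames(X) <- c("trait1", "trait2")
  X
}

# Truncated-normal draw by rejection (support (-1, 1)); fine for the
# moderate sds used here.
rtruncnorm_pm1 <- function(n, mean, sd) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * n, mean, sd)
    out <- c(out, x[x > -1 & x < 1])
  }
  out[seq_len(n)]
}

#' Generate labeled binding/control pair sets with replicate-level data
#'
#' For each binding pair a true evolutionary correlation is drawn from the
#' configured truncated normal and a trait pair simulated under bivariate
#' Brownian Motion; control pairs are simulated with correlation 0. Every
#' species yields \code{n_replicates} noisy replicates per gene, which are
#' summarized into per-gene means and standard errors with
#' [summarize_replicates()], exercising the normalization path end-to-end.
#' Genes are unique per pair (\code{bNNN_1/2}, \code{cNNN_1/2}).
#'
#' @param config A \code{"sim_config"}.
#' @param tree Optional fixed tree; simulated from the config when missing.
#' @return A list with \code{tree}, \code{panel} (an
#'   \code{"expression_panel"}), \code{pairs} (data frame with \code{gene1},
#'   \code{gene2}, \code{group}, \code{truth}, \code{true_rho}) and
#'   \code{replicates} (list of species x replicate matrices per gene).
#' @export
generate_pair_sets <- function(config, tree = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  if (is.null(tree)) {
    tree <- simulate_tree(config$n_tips, config$root_age)
  }
  C <- tree_vcv(tree)
  sp <- rownames(C)
  n <- length(sp)
  m <- config$n_binding + config$n_control
  group <- rep(c("binding", "control"),
               c(config$n_binding, config$n_control))
  idx_in_group <- c(seq_len(config$n_binding), seq_len(config$n_control))
  prefix <- ifelse(group == "binding", "b", "c")
  pairs <- data.frame(
    gene1 = sprintf("%s%04d_1", prefix, idx_in_group),
    gene2 = sprintf("%s%04d_2", prefix, idx_in_group),
    group = group,
    truth = group == "binding",
    true_rho = 0,
    stringsAsFactors = FALSE)
  if (config$n_binding > 0) {
    pairs$true_rho[pairs$truth] <- rtruncnorm_pm1(config$n_binding,
                                                  config$rho_mean,
                                                  config$rho_sd)
  }
  genes <- c(rbind(pairs$gene1, pairs$gene2))
  mean_m <- matrix(NA_real_, n, 2 * m, dimnames = list(sp, genes))
  se_m <- mean_m
  L_C <- t(chol(C))
  nr <- config$n_replicates
  for (k in seq_len(m)) {
    rates <- stats::rlnorm(2, config$sigma_meanlog, config$sigma_sdlog)
    R <- rate_matrix(rates[1], rates[2], pairs$true_rho[k])
    Z <- matrix(stats::rnorm(2 * n), n, 2)
    X <- t(L_C %*% Z %*% chol(R))  # 2 x n true tip values, cov R (x) C
    for (t in 1:2) {
      reps <- matrix(X[t, ], n, nr) +
        matrix(stats::rnorm(n * nr, sd = config$obs_noise_sd), n, nr)
      smry <- summarize_replicates(reps)
      g <- if (t == 1) pairs$gene1[k] else pairs$gene2[k]
      mean_m[, g] <- smry$mean
      se_m[, g] <- if (nr > 1) smry$se else 0
    }
  }
  panel <- new_expression_panel(sp, genes, mean_m, se_m,
                                stats::setNames(rep(nr, n), sp))
  list(tree = tree, panel = panel, pairs = pairs)
}

#' Generate a stochastic-block-model interaction network fixture
#'
#' Planted modules with STRING-like confidence weights: within-module edges
#' appear with probability \code{p_within} and weights uniform on (600, 999);
#' between-module edges with probability \code{p_between} and weights uniform
#' on (150, 400).
#'
#' @param n_modules Number of planted modules (>= 2).
#' @param module_size Nodes per module (>= 2).
#' @param p_within,p_between Edge probabilities (defaults 0.8, 0.05).
#' @param seed Optional integer seed.
#' @return A \code{"weighted_network"} with a \code{truth} attribute mapping
#'   nodes to planted modules.
#' @export
generate_network_fixture <- function(n_modules, module_size, p_within = 0.8,
                                     p_between = 0.05, seed = NULL) {
  stopifnot(n_modules >= 2, module_size >= 2)
  if (!is.null(seed)) set.seed(seed)
  nodes <- paste0("g", seq_len(n_modules * module_size))
  truth <- stats::setNames(rep(seq_len(n_modules), each = module_size), nodes)
  e1 <- character(0); e2 <- character(0); w <- numeric(0)
  nn <- length(nodes)
  for (i in seq_len(nn - 1)) {
    for (j in seq((i + 1), nn)) {
      same <- truth[i] == truth[j]
      p <- if (same) p_within else p_between
      if (stats::runif(1) < p) {
        e1 <- c(e1, nodes[i]); e2 <- c(e2, nodes[j])
        w <- c(w, if (same) stats::runif(1, 600, 999)
               else stats::runif(1, 150, 400))
      }
    }
  }
  net <- as_weighted_network(data.frame(gene1 = e1, gene2 = e2, weight = w,
                                        stringsAsFactors = FALSE))
  attr(net, "truth") <- truth
  net
}
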