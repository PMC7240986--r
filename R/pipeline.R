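#' Validate an analysis configuration
#'
#' Checks that referenced input files exist and that the species names of the
#' tree and the expression panel agree; tips absent from the panel are
#' reported (the tree is pruned to the shared set downstream).
#'
#' @param config Named list: paths \code{tree}, \code{mean}, \code{se}
#'   (optional), \code{pairs}, \code{network} (optional), plus options.
#' @return A list report with \code{tree}, \code{panel}, \code{pairs},
#'   \code{shared_species}, \code{tree_only}, \code{panel_only}.
#' @export
validate_inputs <- function(config) {
  need <- c("tree", "mean", "pairs")
  for (p in need) {
    if (is.null(config[[p]])) stop("config is missing required path: ", p)
    if (!file.exists(config[[p]])) stop("file not found: ", config[[p]])
  }
  if (!is.null(config$se) && !file.exists(config$se)) {
    stop("file not found: ", config$se)
  }
  tree <- read_newick(config$tree)
  panel <- read_panel(config$mean, config$se)
  pairs <- utils::read.delim(config$pairs, stringsAsFactors = FALSE)
  if (!all(c("gene1", "gene2") %in% names(pairs))) {
    stop("pairs table must have columns gene1, gene2")
  }
  shared <- intersect(tree$tip.label, panel$species)
  if (length(shared) < 3) {
    stop("tree and panel share fewer than 3 species")
  }
  tree_only <- setdiff(tree$tip.label, panel$species)
  if (length(tree_only) > 0) {
    message("tree tips absent from panel (will be pruned): ",
            paste(tree_only, collapse = ", "))
  }
  list(tree = tree, panel = panel, pairs = pairs, shared_species = shared,
       tree_only = tree_only,
       panel_only = setdiff(panel$species, tree$tip.label))
}

#' Run the full coevolution analysis
#'
#' Composes the pipeline stages in order: input validation, completeness
#' filtering, Brownian-Motion assumption screening, per-pair model fitting,
#' group-level tests, and (when a network is supplied) Markov clustering with
#' the covariance-ratio modularity test. Results are written as TSV/JSON
#' files to \code{out_dir} together with a manifest recording the seed.
#'
#' @param config Named list with paths (\code{tree}, \code{mean}, \code{se},
#'   \code{pairs}, \code{network}) and options: \code{bm_filter} (default
#'   TRUE), \code{use_se} (default TRUE), \code{seed} (default 1),
#'   \code{min_module_size} (default 15), \code{n_perm} (default 999).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with \code{fits}, \code{group_summary},
#'   \code{modules} and \code{cr}.
#' @export
run_full_analysis <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  opt <- function(name, default) {
    if (is.null(config[[name]])) default else config[[name]]
  }
  seed <- opt("seed", 1)
  inputs <- validate_inputs(config)
  tree <- inputs$tree
  if (length(inputs$tree_only) > 0) {
    tree <- prune_tree(tree, inputs$shared_species)
  }
  fc <- filter_complete(inputs$panel, inputs$pairs)
  panel <- fc$panel
  pairs <- fc$pairs
  if (isTRUE(opt("bm_filter", TRUE))) {
    bm <- filter_bm(panel, tree, pairs)
    pairs <- bm$pairs
    utils::write.table(bm$report, file.path(out_dir, "bm_screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (nrow(pairs) == 0) stop("no pairs left after filtering")
  fits <- fit_pairs(panel, pairs, tree, use_se = opt("use_se", TRUE))
  utils::write.table(as.data.frame(fits), file.path(out_dir, "fits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  group_summary <- NULL
  if ("group" %in% names(fits) && all(c("binding", "control") %in% fits$group)) {
    rb <- fits$rho_c[fits$group == "binding" & fits$converged]
    rc <- fits$rho_c[fits$group == "control" & fits$converged]
    group_summary <- group_tests(rb, rc)
    writeLines(to_json(group_summary),
               file.path(out_dir, "group_summary.json"))
  }
  modules <- NULL
  cr <- NULL
  if (!is.null(config$network)) {
    net <- read_network_tsv(config$network)
    modules <- mcl(net)
    utils::write.table(data.frame(gene = names(modules), module = modules),
                       file.path(out_dir, "modules.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    genes_avail <- intersect(names(modules), panel$genes)
    if (length(genes_avail) >= 4) {
      C <- tree_vcv(tree)
      Xt <- phylo_transform(panel$mean[rownames(C), genes_avail], C)
      colnames(Xt) <- genes_avail
      cr <- tryCatch(
        covariance_ratio(Xt, modules[genes_avail],
                         n_perm = opt("n_perm", 999),
                         min_size = opt("min_module_size", 15),
                         seed = seed),
        error = function(e) {
          message("covariance-ratio test skipped: ", conditionMessage(e))
          NULL
        })
      if (!is.null(cr)) {
        writeLines(to_json(list(cr = cr$cr, p_value = cr$p_value,
                                n_permutations = cr$n_permutations)),
                   file.path(out_dir, "cr.json"))
      }
    }
  }
  manifest <- c(package = as.character(utils::packageVersion("phycor")),
                seed = seed, date = format(Sys.time()))
  writeLines(paste(names(manifest), manifest, sep = "\t"),
             file.path(out_dir, "manifest.tsv"))
  invisible(list(fits = fits, group_summary = group_summary,
                 modules = modules, cr = cr))
}

# Minimal JSON serializer for the small summary lists written by the
# pipeline (avoids a hard dependency for one output file).
to_json <- function(x) {
  ser <- function(v) {
    if (is.list(v)) {
      paste0("{", paste(sprintf("\"%s\": %s", names(v),
                                vapply(v, ser, "")), collapse = ", "), "}")
    } else if (is.character(v)) {
      sprintf("\"%s\"", v)
    } else if (length(v) > 1) {
      paste0("[", paste(format(v, digits = 10), collapse = ", "), "]")
    } else {
      format(v, digits = 10)
    }
  }
  ser(x)
}
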