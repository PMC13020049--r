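#' Configuration of a synthetic planted-module world
#'
#' Describes a ground-truth world with the statistical structure the
#' analysis assumes: a planted-partition (stochastic block) interaction
#' network whose dense blocks play the role of functional protein modules,
#' human disease traits and mouse phenotypes seeded from those modules with
#' noise, organ annotations aligned with module membership, and (optionally)
#' a cell-type expression matrix with signal for the disease-module genes.
#'
#' @param n_genes Total genes; module genes come first, the remainder is
#'   background wired at `p_out`.
#' @param n_modules,module_size Number and size of planted modules
#'   (`n_modules * module_size <= n_genes`).
#' @param p_in,p_out Intra-/inter-module edge probabilities
#'   (`p_out < p_in`).
#' @param n_human_traits,n_mouse_traits Number of traits of each class,
#'   assigned to modules round-robin.
#' @param human_seeds_range Range of human seed-set sizes (uniform draw);
#'   minimum 2 per trait.
#' @param human_seed_counts Optional explicit per-trait seed counts
#'   (overrides the range; useful to build seed-size strata exactly).
#' @param mouse_seeds_range Range of mouse seed-set sizes; the minimum must
#'   be at least 10, mirroring the filter that excludes mouse models
#'   specific to one monogenic disease.
#' @param seed_noise_frac Fraction of each trait's seeds drawn uniformly
#'   from outside its generating module(s); in `[0, 1]`.
#' @param mouse_seed_noise_frac Separate noise fraction for mouse traits
#'   (default: same as `seed_noise_frac`; set to 1 for an independence
#'   null in which mouse phenotypes carry no module signal).
#' @param human_modules_per_trait Modules per human trait (2 emulates
#'   multi-systemic diseases); default 1.
#' @param disjoint_human_seeds Force human traits sharing a module to take
#'   disjoint in-module seeds (zero forced seed overlap); default `FALSE`.
#' @param organ_per_module Character vector of organ labels recycled over
#'   modules; traits sharing a module share its organ label.
#' @param background_hub_degree Optional extra expected degree given to a
#'   background hub (degree heterogeneity); default 0 (off).
#' @param rng_seed Master integer seed; every sub-generator (graph, traits,
#'   expression) derives its own stream from it.
#' @return A validated `synthetic_world_config` list.
#' @export
synthetic_world_config <- function(n_genes = 400L, n_modules = 8L,
                                   module_size = 20L, p_in = 0.3, p_out = 0.02,
                                   n_human_traits = 8L, n_mouse_traits = 24L,
                                   human_seeds_range = c(4L, 12L),
                                   human_seed_counts = NULL,
                                   mouse_seeds_range = c(10L, 16L),
                                   seed_noise_frac = 0.1,
                                   mouse_seed_noise_frac = NULL,
                                   human_modules_per_trait = 1L,
                                   disjoint_human_seeds = FALSE,
                                   organ_per_module = c("retinal", "hearing",
                                                        "CNS", "polydactyly",
                                                        "renal", "skeletal"),
                                   background_hub_degree = 0,
                                   rng_seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_modules = as.integer(n_modules),
              module_size = as.integer(module_size), p_in = p_in, p_out = p_out,
              n_human_traits = as.integer(n_human_traits),
              n_mouse_traits = as.integer(n_mouse_traits),
              human_seeds_range = as.integer(human_seeds_range),
              human_seed_counts = if (!is.null(human_seed_counts))
                as.integer(human_seed_counts) else NULL,
              mouse_seeds_range = as.integer(mouse_seeds_range),
              seed_noise_frac = seed_noise_frac,
              mouse_seed_noise_frac = mouse_seed_noise_frac %||% seed_noise_frac,
              human_modules_per_trait = as.integer(human_modules_per_trait),
              disjoint_human_seeds = disjoint_human_seeds,
              organ_per_module = organ_per_module,
              background_hub_degree = background_hub_degree,
              rng_seed = as.integer(rng_seed))
  with(cfg, {
    if (n_modules * module_size > n_genes) {
      stopf("infeasible config: %d modules of %d genes exceed %d genes",
            n_modules, module_size, n_genes)
    }
    if (p_out >= p_in) stopf("p_out must be < p_in")
    if (p_in > 1 || p_in < 0 || p_out < 0) stopf("edge probabilities must lie in [0, 1]")
    if (seed_noise_frac < 0 || seed_noise_frac > 1) stopf("seed_noise_frac in [0, 1]")
    if (human_seeds_range[1] < 2) stopf("human traits need >= 2 seeds")
    if (mouse_seeds_range[1] < 10) stopf("mouse traits need >= 10 seeds")
    if (!is.null(human_seed_counts) && length(human_seed_counts) != n_human_traits) {
      stopf("human_seed_counts must have length n_human_traits")
    }
  })
  class(cfg) <- "synthetic_world_config"
  cfg
}

#' Generate a synthetic planted-module world
#'
#' Wires a planted-partition graph (`n_modules` blocks of `module_size`
#' genes connected with probability `p_in` internally and `p_out`
#' externally; leftover genes form background wired at `p_out`), assigns
#' edge confidences, and draws human and mouse trait seed sets from the
#' modules with the configured noise. Everything is deterministic given
#' `config$rng_seed`.
#'
#' @param config A [synthetic_world_config()].
#' @return A `synthetic_world`: list with `network` (igraph),
#'   `module_truth` (named integer vector, 0 = background),
#'   `human_traits`, `mouse_traits` (lists of [trait_seed_set()], each
#'   recording its generating `modules`), `organ_annotations` (named list),
#'   `expression` (`NULL` until [generate_expression()]), `config`.
#' @export
generate_world <- function(config = synthetic_world_config()) {
  stopifnot(inherits(config, "synthetic_world_config"))
  n <- config$n_genes
  genes <- sprintf("g%04d", seq_len(n))

  # --- graph stream ---------------------------------------------------
  set.seed(derive_seed(config$rng_seed, 1L))
  n_bg <- n - config$n_modules * config$module_size
  sizes <- c(rep(config$module_size, config$n_modules), if (n_bg > 0) n_bg)
  nb <- length(sizes)
  pm <- matrix(config$p_out, nb, nb)
  diag(pm)[seq_len(config$n_modules)] <- config$p_in
  if (n_bg > 0) pm[nb, nb] <- config$p_out
  g <- igraph::sample_sbm(n, pref.matrix = pm, block.sizes = sizes)
  igraph::V(g)$name <- genes
  if (config$background_hub_degree > 0 && n_bg > 0) {
    hub <- genes[n]  # last background gene becomes a promiscuous hub
    extra <- sample(genes[-n], min(round(config$background_hub_degree), n - 1))
    new_e <- extra[!vapply(extra, function(v) igraph::are_adjacent(g, hub, v),
                           logical(1))]
    if (length(new_e)) g <- igraph::add_edges(g, rbind(hub, new_e))
  }
  igraph::E(g)$weight <- stats::runif(igraph::ecount(g), 0.5, 1)
  module_truth <- c(rep(seq_len(config$n_modules), each = config$module_size),
                    rep(0L, n_bg))
  names(module_truth) <- genes

  # --- trait stream ---------------------------------------------------
  set.seed(derive_seed(config$rng_seed, 2L))
  organs <- rep_len(config$organ_per_module, config$n_modules)
  mod_genes <- split(genes[module_truth > 0], module_truth[module_truth > 0])

  draw_trait <- function(tid, cls, mods, k, noise, reserved) {
    pool <- unlist(mod_genes[as.character(mods)], use.names = FALSE)
    pool <- setdiff(pool, reserved)
    n_in <- min(round((1 - noise) * k), length(pool))
    inside <- if (n_in > 0) sample(pool, n_in) else character()
    out_pool <- setdiff(genes, unlist(mod_genes[as.character(mods)], use.names = FALSE))
    outside <- if (k - n_in > 0) sample(out_pool, k - n_in) else character()
    trait_seed_set(tid, cls, c(inside, outside),
                   organs = unique(organs[mods]), modules = mods)
  }

  human <- list()
  used_in_module <- stats::setNames(vector("list", config$n_modules),
                                    seq_len(config$n_modules))
  for (t in seq_len(config$n_human_traits)) {
    mods <- ((t - 1L + seq_len(config$human_modules_per_trait) - 1L) %%
               config$n_modules) + 1L
    k <- if (!is.null(config$human_seed_counts)) config$human_seed_counts[t]
         else sample(config$human_seeds_range[1]:config$human_seeds_range[2], 1)
    reserved <- if (config$disjoint_human_seeds)
      unlist(used_in_module[as.character(mods)]) else character()
    ts <- draw_trait(sprintf("HT%02d", t), "human", mods, k,
                     config$seed_noise_frac, reserved)
    if (config$disjoint_human_seeds) {
      for (m in mods) used_in_module[[as.character(m)]] <-
        c(used_in_module[[as.character(m)]], ts$seeds)
    }
    human[[ts$trait_id]] <- ts
  }
  mouse <- list()
  for (t in seq_len(config$n_mouse_traits)) {
    mods <- ((t - 1L) %% config$n_modules) + 1L
    k <- sample(config$mouse_seeds_range[1]:config$mouse_seeds_range[2], 1)
    ts <- draw_trait(sprintf("MP%02d", t), "mouse", mods, k,
                     config$mouse_seed_noise_frac, character())
    mouse[[ts$trait_id]] <- ts
  }

  ann <- lapply(c(human, mouse), `[[`, "organs")
  structure(list(network = g, module_truth = module_truth,
                 human_traits = human, mouse_traits = mouse,
                 organ_annotations = ann, expression = NULL, config = config),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_world> %d genes, %d edges, %d planted modules; ",
                     "%d human traits, %d mouse traits%s (rng_seed %d)\n"),
              igraph::vcount(x$network), igraph::ecount(x$network),
              x$config$n_modules, length(x$human_traits), length(x$mouse_traits),
              if (is.null(x$expression)) "" else
                sprintf("; expression %d x %d", nrow(x$expression),
                        ncol(x$expression)),
              x$config$rng_seed))
  invisible(x)
}

#' Generate a synthetic cell-type expression matrix
#'
#' Genes x cell-types matrix of nonnegative values: baseline
#' Normal(5, 1) truncated at zero, with the genes of the human-trait
#' generating modules shifted upward by `effect_size` (in SD units of the
#' baseline) in the designated signal cell types.
#'
#' @param world A [generate_world()] result.
#' @param n_celltypes Number of cell types; default 20.
#' @param signal_celltypes Number of cell types carrying the disease-module
#'   signal (`<= n_celltypes`); default 3.
#' @param effect_size Mean shift in baseline-SD units; default 2.
#' @param rng_seed Integer seed (default: derived from the world's master
#'   seed).
#' @return The world with `$expression` filled in; the matrix carries
#'   attributes `signal_celltypes` and `signal_genes` (ground truth).
#' @export
generate_expression <- function(world, n_celltypes = 20L, signal_celltypes = 3L,
                                effect_size = 2, rng_seed = NULL) {
  stopifnot(inherits(world, "synthetic_world"))
  if (signal_celltypes > n_celltypes) {
    stopf("signal_celltypes must not exceed n_celltypes")
  }
  set.seed(rng_seed %||% derive_seed(world$config$rng_seed, 3L))
  genes <- names(world$module_truth)
  cts <- sprintf("ct%02d", seq_len(n_celltypes))
  M <- matrix(stats::rnorm(length(genes) * n_celltypes, mean = 5, sd = 1),
              nrow = length(genes), dimnames = list(genes, cts))
  disease_mods <- unique(unlist(lapply(world$human_traits, `[[`, "modules")))
  signal_genes <- genes[world$module_truth %in% disease_mods]
  sig_ct <- cts[seq_len(signal_celltypes)]
  M[signal_genes, sig_ct] <- M[signal_genes, sig_ct] + effect_size
  M <- pmax(M, 0)
  attr(M, "signal_celltypes") <- sig_ct
  attr(M, "signal_genes") <- signal_genes
  world$expression <- M
  world
}

#' Write a synthetic world to plain-text files
#'
#' Writes `network.tsv` (edge list), `traits.tsv` (gene, trait_id,
#' trait_class, evidence_score), `organs.tsv`, `expression.tsv` (if
#' present) and `truth.json` (module truth + provenance) into a directory.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_network(world$network, file.path(dir, "network.tsv"))
  traits <- c(world$human_traits, world$mouse_traits)
  tdf <- do.call(rbind, lapply(traits, function(t) {
    data.frame(gene = t$seeds, trait_id = t$trait_id, trait_class = t$trait_class,
               evidence_score = 1, stringsAsFactors = FALSE)
  }))
  utils::write.table(tdf, file.path(dir, "traits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  odf <- do.call(rbind, lapply(names(world$organ_annotations), function(tid) {
    orgs <- world$organ_annotations[[tid]]
    if (length(orgs) == 0) return(NULL)
    data.frame(trait_id = tid, organ = orgs, stringsAsFactors = FALSE)
  }))
  utils::write.table(odf, file.path(dir, "organs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(world$expression)) {
    utils::write.table(
      data.frame(gene = rownames(world$expression), world$expression,
                 check.names = FALSE),
      file.path(dir, "expression.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  truth <- list(
    module_truth = as.list(world$module_truth),
    trait_modules = lapply(traits, `[[`, "modules"),
    config = world$config[setdiff(names(world$config), "human_seed_counts")])
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
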