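#' Configuration for the synthetic benchmark generator
#'
#' Describes a desk-scale dataset with the statistical shape of curated
#' herb/disease annotation resources: a heavy-tailed connected interactome,
#' small locally clustered disease modules, herbs with broad multi-compound
#' multi-target footprints, multi-database evidence labels, and a sparse gold
#' standard of positive herb-disease pairs carrying a planted
#' proximity-plus-multiplicity signal.
#'
#' Positive pairs are planted through two dials:
#' * `module_locality` — probability that a positive herb's compound draws its
#'   target set from the radius-`module_radius` ball around the disease
#'   module (proximity signal, visible to ACP and WACP alike);
#' * `multiplicity_boost` — number of extra compounds per positive herb whose
#'   targets concentrate on the module's radius-1 *shell* (neighbours of
#'   module genes, excluding the module itself). Stacking compounds on
#'   shell genes raises their weights while leaving their distances at 1, so
#'   this component of the signal is legible only to the weighted measure.
#'
#' @param seed Integer RNG seed; identical config + seed gives identical
#'   output.
#' @param n_nodes Interactome size before LCC extraction.
#' @param graph_model `"pa"` (preferential attachment, heavy-tailed degree;
#'   default) or `"er"` (Erdos-Renyi fallback).
#' @param pa_edges_per_node Edges each new node attaches with (`"pa"` model).
#' @param er_edge_prob Edge probability (`"er"` model).
#' @param n_diseases,n_herbs Entity counts.
#' @param disease_genes_range,disease_genes_mean Module size range and target
#'   mean (genes per disease).
#' @param compounds_per_herb_range,compounds_per_herb_mean Compounds per herb.
#' @param targets_per_compound_range,targets_per_compound_mean Target genes
#'   per compound.
#' @param n_source_databases Number of source-database labels in play.
#' @param extra_evidence_prob Per-database probability of each record carrying
#'   one more label beyond its first; controls the fraction surviving the
#'   >=2-database evidence filter.
#' @param fraction_positive_herbs Fraction of herbs given a planted disease
#'   association (the gold standard).
#' @param positives_per_herb_range Known diseases per positive herb.
#' @param module_locality,multiplicity_boost Signal dials (see above); both 0
#'   gives a null dataset with no planted signal.
#' @param module_radius Radius of the ball around disease-module genes from
#'   which local compounds draw targets.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_nodes = 500L,
                         graph_model = c("pa", "er"),
                         pa_edges_per_node = 2L,
                         er_edge_prob = 0.02,
                         n_diseases = 12L,
                         disease_genes_range = c(2L, 74L),
                         disease_genes_mean = 6,
                         n_herbs = 60L,
                         compounds_per_herb_range = c(1L, 80L),
                         compounds_per_herb_mean = 34.5,
                         targets_per_compound_range = c(1L, 15L),
                         targets_per_compound_mean = 5,
                         n_source_databases = 5L,
                         extra_evidence_prob = 0.35,
                         fraction_positive_herbs = 0.1,
                         positives_per_herb_range = c(1L, 2L),
                         module_locality = 0.8,
                         multiplicity_boost = 3L,
                         module_radius = 1L) {
  cfg <- list(seed = as.integer(seed), n_nodes = as.integer(n_nodes),
              graph_model = match.arg(graph_model),
              pa_edges_per_node = as.integer(pa_edges_per_node),
              er_edge_prob = er_edge_prob,
              n_diseases = as.integer(n_diseases),
              disease_genes_range = as.integer(disease_genes_range),
              disease_genes_mean = disease_genes_mean,
              n_herbs = as.integer(n_herbs),
              compounds_per_herb_range = as.integer(compounds_per_herb_range),
              compounds_per_herb_mean = compounds_per_herb_mean,
              targets_per_compound_range = as.integer(targets_per_compound_range),
              targets_per_compound_mean = targets_per_compound_mean,
              n_source_databases = as.integer(n_source_databases),
              extra_evidence_prob = extra_evidence_prob,
              fraction_positive_herbs = fraction_positive_herbs,
              positives_per_herb_range = as.integer(positives_per_herb_range),
              module_locality = module_locality,
              multiplicity_boost = as.integer(multiplicity_boost),
              module_radius = as.integer(module_radius))
  counts <- c("n_nodes", "pa_edges_per_node", "n_diseases", "n_herbs",
              "n_source_databases")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) {
      stop(sprintf("%s must be a positive integer", f), call. = FALSE)
    }
  }
  probs <- c("er_edge_prob", "extra_evidence_prob", "fraction_positive_herbs",
             "module_locality")
  for (f in probs) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop(sprintf("%s must lie in [0, 1]", f), call. = FALSE)
    }
  }
  for (f in c("disease_genes_range", "compounds_per_herb_range",
              "targets_per_compound_range", "positives_per_herb_range")) {
    r <- cfg[[f]]
    if (length(r) != 2 || any(r < 1L) || r[1] > r[2]) {
      stop(sprintf("%s must be an increasing pair of positive integers", f),
           call. = FALSE)
    }
  }
  if (cfg$multiplicity_boost < 0L) {
    stop("multiplicity_boost must be >= 0", call. = FALSE)
  }
  if (cfg$disease_genes_range[2] > cfg$n_nodes) {
    stop("disease module larger than the graph is infeasible", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

# Count samples from a geometric shifted to `lo`, clipped to [lo, hi];
# the geometric's tail echoes the long-tailed annotation counts seen in
# curated herb/compound resources.
rcount <- function(n, lo, hi, mean) {
  mu <- max(mean - lo, 1e-6)
  pmin(lo + stats::rgeom(n, 1 / (1 + mu)), hi)
}

draw_sources <- function(n, n_db, extra_p) {
  k <- 1L + stats::rbinom(n, n_db - 1L, extra_p)
  lapply(k, function(ki) sort(sample(paste0("DB", seq_len(n_db)), ki)))
}

#' Generate a synthetic herb-disease benchmark
#'
#' Produces, from one seeded configuration, every input the pipeline
#' consumes: an interactome edge list, the four association tables
#' (disease-gene, herb-compound, compound-gene, herb-disease), and the gold
#' standard of planted positive pairs. See [synth_config()] for how the
#' signal is planted.
#'
#' @param config A [synth_config()].
#' @return A `synth_data` list: `config`, `edges` (data frame `gene_a`,
#'   `gene_b`), `disease_gene`, `herb_compound`, `compound_gene`,
#'   `herb_disease` (association tables), `gold` (data frame `herb`,
#'   `disease`, identical pairs to `herb_disease`).
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  ## interactome
  g <- if (cfg$graph_model == "pa") {
    igraph::sample_pa(cfg$n_nodes, m = cfg$pa_edges_per_node,
                      directed = FALSE)
  } else {
    igraph::sample_gnp(cfg$n_nodes, cfg$er_edge_prob)
  }
  igraph::V(g)$name <- sprintf("G%05d", seq_len(cfg$n_nodes))
  g <- largest_connected_component(igraph::simplify(g))
  nodes <- igraph::V(g)$name
  if (cfg$disease_genes_range[1] > length(nodes)) {
    stop("disease module larger than the interactome LCC is infeasible",
         call. = FALSE)
  }

  ## disease modules: connected neighbourhoods (ball around a seed node)
  disease_ids <- sprintf("D%03d", seq_len(cfg$n_diseases))
  module_sizes <- rcount(cfg$n_diseases, cfg$disease_genes_range[1],
                         min(cfg$disease_genes_range[2], length(nodes)),
                         cfg$disease_genes_mean)
  modules <- lapply(module_sizes, function(s) {
    anchor <- sample(nodes, 1)
    ball <- anchor
    r <- 1L
    while (length(ball) < s && r <= 4L) {
      ball <- igraph::ego(g, order = r, nodes = anchor)[[1]]$name
      r <- r + 1L
    }
    s <- min(s, length(ball))
    unique(c(anchor, sample(setdiff(ball, anchor), s - 1L)))
  })
  names(modules) <- disease_ids

  module_ball <- lapply(modules, function(m) {
    unique(unlist(lapply(igraph::ego(g, order = cfg$module_radius, nodes = m),
                         function(v) v$name)))
  })
  module_shell <- lapply(disease_ids, function(d) {
    sh <- setdiff(module_ball[[d]], modules[[d]])
    if (length(sh) == 0) module_ball[[d]] else sh
  })
  names(module_shell) <- disease_ids

  ## herbs: the first round(fraction * n) carry planted disease associations
  herb_ids <- sprintf("H%03d", seq_len(cfg$n_herbs))
  n_pos <- round(cfg$fraction_positive_herbs * cfg$n_herbs)
  gold_rows <- list()
  hc_subject <- hc_object <- cg_subject <- character(0)
  cg_targets <- list()

  for (i in seq_len(cfg$n_herbs)) {
    h <- herb_ids[i]
    planted <- i <= n_pos
    assigned <- character(0)
    if (planted) {
      kr <- cfg$positives_per_herb_range
      k <- if (kr[1] == kr[2]) kr[1] else sample(kr[1]:kr[2], 1)
      assigned <- sample(disease_ids, min(k, cfg$n_diseases))
      gold_rows[[h]] <- data.frame(herb = h, disease = assigned,
                                   stringsAsFactors = FALSE)
    }
    pool_local <- if (planted) {
      unique(unlist(module_ball[assigned], use.names = FALSE))
    }
    pool_shell <- if (planted) {
      unique(unlist(module_shell[assigned], use.names = FALSE))
    }

    n_comp <- rcount(1, cfg$compounds_per_herb_range[1],
                     cfg$compounds_per_herb_range[2],
                     cfg$compounds_per_herb_mean)
    n_boost <- if (planted) cfg$multiplicity_boost else 0L
    comp_ids <- sprintf("%s_C%04d", h, seq_len(n_comp + n_boost))
    sizes <- rcount(n_comp + n_boost, cfg$targets_per_compound_range[1],
                    cfg$targets_per_compound_range[2],
                    cfg$targets_per_compound_mean)
    local <- c(planted & stats::runif(n_comp) < cfg$module_locality,
               rep(FALSE, n_boost))
    boost <- c(rep(FALSE, n_comp), rep(TRUE, n_boost))
    targets <- lapply(seq_along(comp_ids), function(j) {
      pool <- if (boost[j]) pool_shell else if (local[j]) pool_local else nodes
      if (length(pool) == 1) pool else sample(pool, min(sizes[j], length(pool)))
    })
    hc_subject <- c(hc_subject, rep(h, length(comp_ids)))
    hc_object <- c(hc_object, comp_ids)
    cg_subject <- c(cg_subject, rep(comp_ids, lengths(targets)))
    cg_targets <- c(cg_targets, targets)
  }

  gold <- do.call(rbind, c(gold_rows, list(
    data.frame(herb = character(0), disease = character(0),
               stringsAsFactors = FALSE))))
  rownames(gold) <- NULL

  dg_subject <- rep(disease_ids, lengths(modules))
  dg_object <- unlist(modules, use.names = FALSE)
  cg_object <- unlist(cg_targets, use.names = FALSE)

  mk <- function(subject, object, kind) {
    association_table(subject, object,
                      draw_sources(length(subject), cfg$n_source_databases,
                                   cfg$extra_evidence_prob),
                      kind)
  }
  el <- igraph::as_edgelist(g)
  structure(list(
    config = cfg,
    edges = data.frame(gene_a = el[, 1], gene_b = el[, 2],
                       stringsAsFactors = FALSE),
    disease_gene = mk(dg_subject, dg_object, "disease_gene"),
    herb_compound = mk(hc_subject, hc_object, "herb_compound"),
    compound_gene = mk(cg_subject, cg_object, "compound_gene"),
    herb_disease = if (nrow(gold) > 0) {
      mk(gold$herb, gold$disease, "herb_disease")
    },
    gold = gold), class = "synth_data")
}

#' @export
print.synth_data <- function(x, ...) {
  cat(sprintf("<synth_data> seed %d: %d edges, %d disease-gene, %d herb-compound, %d compound-gene records, %d gold pair(s)\n",
              x$config$seed, nrow(x$edges), nrow(x$disease_gene),
              nrow(x$herb_compound), nrow(x$compound_gene), nrow(x$gold)))
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Emits the TSV dialects consumed by [load_association_table()] and
#' [read_edge_list()], the configuration as JSON, and a manifest recording
#' the seed and per-file MD5 checksums.
#'
#' @param x A `synth_data` object from [synth_generate()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_synthetic_data <- function(x, dir) {
  stopifnot(inherits(x, "synth_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(edges = "edges.tsv", disease_gene = "disease_gene.tsv",
             herb_compound = "herb_compound.tsv",
             compound_gene = "compound_gene.tsv",
             herb_disease = "herb_disease.tsv")
  paths <- file.path(dir, files)
  names(paths) <- names(files)

  utils::write.table(x$edges, paths[["edges"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  for (tab in c("disease_gene", "herb_compound", "compound_gene",
                "herb_disease")) {
    t <- x[[tab]]
    if (is.null(t)) next
    flat <- data.frame(subject = t$subject, object = t$object,
                       sources = vapply(t$sources, paste, character(1),
                                        collapse = "|"),
                       stringsAsFactors = FALSE)
    utils::write.table(flat, paths[[tab]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(x$config), cfg_path, auto_unbox = TRUE,
                       digits = NA)
  written <- c(paths[file.exists(paths)], config = cfg_path)
  manifest <- list(seed = x$config$seed,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   files = lapply(written, function(p) {
                     list(path = basename(p),
                          md5 = unname(tools::md5sum(p)))
                   }))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(written, manifest = file.path(dir, "manifest.json")))
}

#' Descriptive statistics of a dataset
#'
#' Summarizes the four shape panels that characterize these data: genes per
#' disease, compounds per herb, target genes per herb, and interactome node
#' degree.
#'
#' @param disease_profiles Named list from [build_disease_profiles()].
#' @param herb_profiles Named list from [build_herb_profiles()].
#' @param g The interactome igraph (optional; degree row omitted if missing).
#' @return Data frame with columns `metric`, `n`, `mean`, `min`, `max`.
#' @export
summarize_inputs <- function(disease_profiles, herb_profiles, g = NULL) {
  row <- function(metric, x) {
    if (length(x) == 0) {
      warning(sprintf("no data for %s", metric), call. = FALSE)
      return(data.frame(metric = metric, n = 0L, mean = NA_real_,
                        min = NA_real_, max = NA_real_,
                        stringsAsFactors = FALSE))
    }
    data.frame(metric = metric, n = length(x), mean = mean(x),
               min = min(x), max = max(x), stringsAsFactors = FALSE)
  }
  out <- rbind(
    row("genes_per_disease",
        vapply(disease_profiles, function(d) length(d$genes), numeric(1))),
    row("compounds_per_herb",
        vapply(herb_profiles, function(h) length(h$compounds), numeric(1))),
    row("genes_per_herb",
        vapply(herb_profiles, function(h) length(h$gene_weights), numeric(1))))
  if (!is.null(g)) {
    out <- rbind(out, row("node_degree", igraph::degree(g)))
  }
  rownames(out) <- NULL
  out
}
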