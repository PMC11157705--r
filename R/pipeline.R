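#' Run the end-to-end prediction pipeline
#'
#' Executes the full workflow: load (or simulate) inputs, evidence-filter the
#' association tables, build profiles, construct the interactome LCC, score
#' all herb-disease pairs with the requested measures, evaluate against the
#' gold standard, derive the FPR-anchored threshold, select reliable herbs,
#' and propose novel associations. All outputs are written to
#' `config$out_dir` together with a manifest of checksums; identical
#' configuration and inputs reproduce identical outputs.
#'
#' @param config A list (or path to a JSON file) with fields:
#'   \describe{
#'     \item{inputs}{List of paths: `edges`, `disease_gene`, `herb_compound`,
#'       `compound_gene`, `gold`. Omit when `simulate` is given.}
#'     \item{simulate}{Optional list of [synth_config()] arguments; the
#'       dataset is generated, written under `out_dir/simulated/` and used as
#'       input.}
#'     \item{min_sources}{Evidence filter threshold (default 2).}
#'     \item{measures}{Character vector among `"WACP"`, `"ACP"`, `"ASP"`
#'       (default all three). The first is the primary measure used for
#'       per-entity evaluation and discovery.}
#'     \item{target_fpr}{FPR anchor for the score threshold (default 0.05).}
#'     \item{auroc_min}{Reliable-herb AUROC floor (default 0.9).}
#'     \item{min_known}{Reliable-herb minimum known diseases (default 3).}
#'     \item{out_dir}{Output directory (required).}
#'   }
#' @return Invisibly, a list with the filtered tables, profiles, graph,
#'   score matrices, evaluation reports, per-entity AUROCs, correlation
#'   diagnostics, threshold, reliable herbs and discovery candidates.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config), !is.null(config$out_dir))
  min_sources <- config$min_sources %||% 2L
  measures <- config$measures %||% c("WACP", "ACP", "ASP")
  target_fpr <- config$target_fpr %||% 0.05
  auroc_min <- config$auroc_min %||% 0.9
  min_known <- config$min_known %||% 3L
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$simulate)) {
    sim <- synth_generate(do.call(synth_config, as.list(config$simulate)))
    write_synthetic_data(sim, file.path(out_dir, "simulated"))
    edges <- sim$edges
    dg <- sim$disease_gene
    hc <- sim$herb_compound
    cg <- sim$compound_gene
    gold <- sim$gold
  } else {
    inp <- config$inputs
    need <- c("edges", "disease_gene", "herb_compound", "compound_gene",
              "gold")
    miss <- setdiff(need, names(inp))
    if (length(miss) > 0) {
      stop(sprintf("missing input path(s): %s", paste(miss, collapse = ", ")),
           call. = FALSE)
    }
    for (p in unlist(inp[need])) {
      if (!file.exists(p)) stop(sprintf("input not found: %s", p),
                                call. = FALSE)
    }
    edges <- read_edge_list(inp$edges)
    dg <- load_association_table(inp$disease_gene, "disease_gene")
    hc <- load_association_table(inp$herb_compound, "herb_compound")
    cg <- load_association_table(inp$compound_gene, "compound_gene")
    gold_tab <- load_association_table(inp$gold, "herb_disease")
    gold <- data.frame(herb = gold_tab$subject, disease = gold_tab$object,
                       stringsAsFactors = FALSE)
  }

  # the gold standard is used as-is; only the evidence tables are filtered
  dg <- filter_by_evidence(dg, min_sources)
  hc <- filter_by_evidence(hc, min_sources)
  cg <- filter_by_evidence(cg, min_sources)
  for (nm in c("disease_gene", "herb_compound", "compound_gene")) {
    t <- switch(nm, disease_gene = dg, herb_compound = hc, compound_gene = cg)
    flat <- data.frame(subject = t$subject, object = t$object,
                       sources = vapply(t$sources, paste, character(1),
                                        collapse = "|"))
    utils::write.table(flat, file.path(out_dir,
                                       paste0("filtered_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  diseases <- build_disease_profiles(dg)
  herbs <- build_herb_profiles(hc, cg)
  if (length(diseases) == 0 || length(herbs) == 0) {
    stop("no usable disease or herb profiles after filtering", call. = FALSE)
  }
  g <- largest_connected_component(build_graph(edges))
  oracle <- distance_oracle(g)

  reports <- list()
  scores_primary <- NULL
  for (m in measures) {
    sc <- score_all_pairs(herbs, diseases, oracle, measure = m)
    write_score_matrix(sc, file.path(out_dir,
                                     sprintf("scores_%s.tsv", tolower(m))))
    rep <- evaluate_predictions(sc, gold)
    write_eval_report(rep, file.path(out_dir,
                                     sprintf("eval_%s.json", tolower(m))))
    reports[[m]] <- rep
    if (is.null(scores_primary)) scores_primary <- sc
  }

  primary <- measures[1]
  per_herb <- per_entity_auroc(scores_primary, gold, "herb")
  per_disease <- per_entity_auroc(scores_primary, gold, "disease")
  utils::write.table(data.frame(herb = names(per_herb), auroc = per_herb),
                     file.path(out_dir, "per_herb_auroc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(disease = names(per_disease),
                                auroc = per_disease),
                     file.path(out_dir, "per_disease_auroc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pcc <- list(
    herb = tryCatch(auroc_vs_count_correlation(per_herb, gold, "herb"),
                    error = function(e) list(r = NA_real_, p = NA_real_)),
    disease = tryCatch(auroc_vs_count_correlation(per_disease, gold,
                                                  "disease"),
                       error = function(e) list(r = NA_real_, p = NA_real_)))

  thr <- threshold_at_fpr(reports[[primary]]$roc, target_fpr)
  reliable <- select_reliable_herbs(per_herb, scores_primary, gold,
                                    auroc_min = auroc_min,
                                    min_known = min_known,
                                    wacp_threshold = thr$threshold)
  discovery <- if (nrow(reliable) > 0) {
    discover_novel(scores_primary, gold, per_disease, reliable$herb,
                   disease_auroc_min = mean(per_disease))
  } else {
    data.frame(herb = character(0), disease = character(0),
               score = numeric(0), disease_auroc = numeric(0),
               mean_known_score = numeric(0))
  }
  utils::write.table(reliable, file.path(out_dir, "reliable_herbs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(discovery, file.path(out_dir, "discovery.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  outputs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- outputs[outputs != file.path(out_dir, "manifest.json")]
  manifest <- list(
    package_version = as.character(utils::packageVersion("herbprox")),
    config = config,
    files = lapply(outputs, function(p) {
      list(path = sub(paste0("^", out_dir, "/?"), "", p),
           md5 = unname(tools::md5sum(p)))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(disease_profiles = diseases, herb_profiles = herbs,
                 graph = g, scores = scores_primary, reports = reports,
                 per_herb_auroc = per_herb, per_disease_auroc = per_disease,
                 pcc = pcc, threshold = thr, reliable_herbs = reliable,
                 discovery = discovery, gold = gold))
}
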