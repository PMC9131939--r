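#' Run the full analysis pipeline from a config
#'
#' Wires the modules together in the study's order — synthetic inputs,
#' network statistics, hub ranking, term enrichment, GSEA, seed-site
#' scanning, circuit simulation with Boolean validation, and dynamic
#' network inference — and writes every artifact under `out_dir` together
#' with a manifest of paths and checksums. Stages can be toggled; the root
#' `seed` is fanned out per stage (seed + stage index) so stages are
#' individually reproducible.
#'
#' @param config a named list, or the path to a YAML file holding one.
#'   Recognized keys: `out_dir` (required), `seed` (default 1), `stages`
#'   (character vector among `"syndata"`, `"network"`, `"hubs"`,
#'   `"gsea"`, `"seedscan"`, `"circuit"`, `"netinfer"`; default all), and
#'   optional per-stage parameter lists (`network = list(n_mirna = ...)`,
#'   `netinfer = list(n_iter = ...)`, ...).
#' @return data frame manifest (`stage`, `artifact`, `path`, `md5`),
#'   invisibly; also written to `manifest.csv` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  abort_if(!is.list(config) || is.null(config$out_dir),
           "config must be a list (or YAML file) with an `out_dir`")
  all_stages <- c("syndata", "network", "hubs", "gsea", "seedscan",
                  "circuit", "netinfer")
  stages <- config$stages %||% all_stages
  unknown <- setdiff(stages, all_stages)
  abort_if(length(unknown) > 0,
           paste0("unknown stage(s): ", paste(unknown, collapse = ", ")))
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  add <- function(stage, artifact, path) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, artifact = artifact, path = path,
      md5 = unname(tools::md5sum(path)), stringsAsFactors = FALSE)
  }
  path_of <- function(name) file.path(out_dir, name)
  stage_seed <- function(stage) derive_seed(seed, match(stage, all_stages))
  opts <- function(stage) config[[stage]] %||% list()

  mirna <- mature_mirna(config$mirna_name %||% "miR-520c-3p",
                        config$mirna_seq %||% "AAAGUGCUUCCUUUUAGAGGGU")

  net <- NULL; fixtures <- NULL
  if ("syndata" %in% stages) {
    o <- opts("syndata")
    net <- make_bipartite_network(o$n_mirna %||% 91L, o$n_target %||% 713L,
                                  o$n_edges %||% 1278L,
                                  o$degree_skew %||% 1.5,
                                  seed = stage_seed("syndata"))
    write_network(net, path_of("network.tsv"), "tsv")
    add("syndata", "edge list", path_of("network.tsv"))
    utrs <- make_utr_set(o$n_seqs %||% 20L,
                         implant_table = data.frame(
                           seq = 1:10, pos = seq(30, 120, by = 10),
                           type = rep(c("8mer", "7mer-m8", "7mer-A1"),
                                      length.out = 10)),
                         mirna = mirna, seed = stage_seed("syndata"))
    write_utr_fasta(utrs$seqs, path_of("utrs.fasta"))
    write.table(utrs$truth, path_of("utr_truth.csv"), sep = ",",
                row.names = FALSE, quote = FALSE)
    add("syndata", "UTR FASTA", path_of("utrs.fasta"))
    add("syndata", "UTR truth table", path_of("utr_truth.csv"))
    fixtures <- list(utrs = utrs)
    ex <- make_expression(o$n_genes %||% 500L, o$n_samples %||% 10L,
                          enriched_set = o$set_size %||% 40L,
                          shift = o$shift %||% 2, sigma = o$sigma %||% 1,
                          seed = stage_seed("syndata"),
                          gct_path = path_of("expression.gct"),
                          cls_path = path_of("phenotype.cls"),
                          gmt_path = path_of("sets.gmt"))
    add("syndata", "GCT", path_of("expression.gct"))
    add("syndata", "CLS", path_of("phenotype.cls"))
    add("syndata", "GMT", path_of("sets.gmt"))
    fixtures$expression <- ex
  }

  needs_net <- intersect(c("network", "hubs"), stages)
  if (length(needs_net) > 0 && is.null(net)) {
    abort_if(is.null(config$network_file),
             "network/hubs stages need the syndata stage or a `network_file`",
             class = "mirhub_dependency_error")
    net <- read_network(config$network_file,
                        config$network_dialect %||% "tsv")
  }

  if ("network" %in% stages) {
    stats <- global_statistics(net)
    flds <- setdiff(names(stats), "conventions")
    write.table(data.frame(statistic = flds,
                           value = vapply(flds, function(f)
                             as.numeric(stats[[f]]), numeric(1))),
                path_of("network_stats.csv"), sep = ",", row.names = FALSE,
                quote = FALSE)
    add("network", "global statistics", path_of("network_stats.csv"))
    ord <- anneal_order(net, seed = stage_seed("network"))
    write.table(ord, path_of("node_order.csv"), sep = ",",
                row.names = FALSE, quote = FALSE)
    add("network", "annealed node order", path_of("node_order.csv"))
  }

  if ("hubs" %in% stages) {
    o <- opts("hubs")
    fnet <- filter_by_out_degree(net, o$min_deg %||% 1L, o$max_deg %||% 56L)
    lists <- lapply(hub_methods(), function(m) {
      top_k(score_nodes(fnet, m, seed = stage_seed("hubs")), o$k %||% 10L)
    })
    names(lists) <- hub_methods()
    hubs <- aggregate_hubs(lists, o$n_hubs %||% 5L)
    write.table(hubs, path_of("hubs.csv"), sep = ",", row.names = FALSE,
                quote = FALSE)
    add("hubs", "hub summary", path_of("hubs.csv"))
  }

  if ("gsea" %in% stages) {
    o <- opts("gsea")
    if (is.null(fixtures$expression)) {
      abort_if(is.null(o$gct) || is.null(o$cls) || is.null(o$gmt),
               "gsea stage needs syndata or gct/cls/gmt paths",
               class = "mirhub_dependency_error")
      expr <- read_gct(o$gct); labels <- read_cls(o$cls)
      gene_set <- read_gmt(o$gmt)[[1]]
    } else {
      expr <- fixtures$expression$expr
      labels <- fixtures$expression$labels
      gene_set <- fixtures$expression$gene_set
    }
    ranked <- rank_genes(expr, labels)
    res <- permutation_significance(ranked, gene_set,
                                    n_perm = o$n_perm %||% 1000L,
                                    seed = stage_seed("gsea"))
    es <- enrichment_score(ranked, gene_set)
    jsonlite::write_json(
      list(ES = res$ES, NES = res$NES, p_value = res$p_value,
           n_permutations = res$n_permutations,
           leading_edge = es$leading_edge, running_sum = es$running_sum),
      path_of("gsea.json"), auto_unbox = TRUE, digits = NA)
    add("gsea", "enrichment result", path_of("gsea.json"))
  }

  if ("seedscan" %in% stages) {
    o <- opts("seedscan")
    seqs <- if (!is.null(o$fasta)) read_utr_fasta(o$fasta)
            else if (!is.null(fixtures$utrs)) fixtures$utrs$seqs
            else NULL
    abort_if(is.null(seqs), "seedscan stage needs syndata or a `fasta` path",
             class = "mirhub_dependency_error")
    sites <- scan_utr(mirna, seqs, with_features = TRUE)
    write.table(sites, path_of("seed_sites.csv"), sep = ",",
                row.names = FALSE, quote = FALSE)
    add("seedscan", "seed sites", path_of("seed_sites.csv"))
  }

  model <- build_default_circuit(opts("circuit")$overrides %||% list())
  if ("circuit" %in% stages) {
    off <- run_case(model, "off_case1")
    on <- run_case(model, "on_case2")
    write.table(as.data.frame(off$trajectory), path_of("trajectory_off.csv"),
                sep = ",", row.names = FALSE, quote = FALSE)
    write.table(as.data.frame(on$trajectory), path_of("trajectory_on.csv"),
                sep = ",", row.names = FALSE, quote = FALSE)
    add("circuit", "OFF trajectory", path_of("trajectory_off.csv"))
    add("circuit", "ON trajectory", path_of("trajectory_on.csv"))
    val <- validate_circuit_boolean(model)
    jsonlite::write_json(
      list(off_label = off$state, on_label = on$state,
           n_attractors = val$n_attractors,
           off_state = as.list(val$off_state),
           on_state = as.list(val$on_state),
           rules = lapply(val$network$rules, function(r)
             list(inputs = r$inputs, table = r$table,
                  mismatches = r$mismatches))),
      path_of("boolean_validation.json"), auto_unbox = TRUE, digits = NA)
    add("circuit", "Boolean validation", path_of("boolean_validation.json"))
  }

  if ("netinfer" %in% stages) {
    o <- opts("netinfer")
    series <- circuit_switch_series(model, n_points = o$n_points %||% 100L)
    post <- gibbs_infer(series, n_iter = o$n_iter %||% 20000L,
                        n_chains = o$n_chains %||% 2L,
                        seed = stage_seed("netinfer"))
    write.table(round(post$P, 6), path_of("link_probabilities.csv"),
                sep = ",", quote = FALSE, col.names = NA)
    jsonlite::write_json(
      list(diagnostic = post$convergence$diagnostic,
           converged = post$convergence$converged,
           lacr_to_mir = post$P["LacR", "miR520c"]),
      path_of("netinfer_diagnostics.json"), auto_unbox = TRUE, digits = NA)
    add("netinfer", "link probability matrix",
        path_of("link_probabilities.csv"))
    add("netinfer", "diagnostics", path_of("netinfer_diagnostics.json"))
  }

  manifest <- do.call(rbind, manifest)
  if (is.null(manifest)) {
    manifest <- data.frame(stage = character(0), artifact = character(0),
                           path = character(0), md5 = character(0))
  }
  write.table(manifest, path_of("manifest.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
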