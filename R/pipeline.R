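#' Pipeline configuration
#'
#' Bundles the parameters of the end-to-end synthetic run: simulation sizes,
#' the analysis thresholds (alpha, soft power, correlation threshold, fold
#' change), permutation counts, and the master seed from which every stage
#' derives its own sub-stream.
#'
#' @param seed master seed (mandatory).
#' @param n_genes,n_organs,n_coupled_pairs,module_sizes simulation scale.
#' @param n_pairs,n_repeats pair-sampling design.
#' @param alpha,beta,r_threshold,fold analysis thresholds.
#' @param n_perm_disease,n_perm_proximity permutation counts.
#' @param n_interactome interactome size.
#' @param loo run leave-one-out robustness (slowest stage).
#' @param day_start,day_end day window.
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(seed, n_genes = 500, n_organs = 20,
                            n_coupled_pairs = 40,
                            module_sizes = c(60, 60, 60),
                            n_pairs = 1000, n_repeats = 3,
                            alpha = 0.05, beta = 16, r_threshold = 0.8,
                            fold = 2, n_perm_disease = 200,
                            n_perm_proximity = 200, n_interactome = 400,
                            loo = FALSE, day_start = 0, day_end = 12) {
  if (missing(seed)) stop("seed is mandatory")
  structure(as.list(environment()), class = "PipelineConfig")
}

config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  format(sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
           1e9, scientific = FALSE)
}

#' Run the full synthetic analysis pipeline
#'
#' simulate -> filter -> global cycling (+ optional leave-one-out) ->
#' rhythmic interactions -> co-expression networks (modules, day/night
#' topology) -> ZT06/ZT18 comparison -> network medicine (disease modules on
#' the simulated interactome, proximity). All result tables are written as
#' TSV under `out_dir` with the configuration hash in a header comment;
#' reruns with the same config are byte-identical. A manifest (parameters,
#' seeds, runtime) is written last and is the only file carrying timing.
#'
#' @param config a `PipelineConfig`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "PipelineConfig"))
  t0 <- Sys.time()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  note <- paste0("chronet run config=", hash, " seed=", config$seed)
  emit <- function(df, name) write_tsv_table(df, file.path(out_dir, name),
                                             comment = note)

  # --- stage 1: simulate -----------------------------------------------------
  sim <- simulate_atlas(sim_config(
    seed = config$seed, n_genes = config$n_genes, n_organs = config$n_organs,
    n_coupled_pairs = config$n_coupled_pairs,
    modules = if (length(config$module_sizes))
      list(sizes = config$module_sizes,
           rhythmic = rep(c(TRUE, FALSE), length.out =
                            length(config$module_sizes))) else NULL,
    night_factor = list(loading_sd = 1, night_gain = 2)))
  inter <- simulate_interactome(
    config$n_interactome, planted_module_sizes = c(12, 12),
    n_proximal_pairs = 1, seed = config$seed)
  write_atlas(sim$atlas, file.path(out_dir, "atlas.tsv"))
  write_edge_list(inter$edges, file.path(out_dir, "interactome.tsv"))
  emit(sim$truth$genes, "truth_genes.tsv")
  if (!is.null(sim$truth$pairs)) emit(sim$truth$pairs, "truth_pairs.tsv")

  # --- stage 2: filter -------------------------------------------------------
  atlas <- filter_expressed(sim$atlas)
  emit(attr(atlas, "audit"), "filter_audit.tsv")
  refs <- build_references(atlas$zt_times)

  # --- stage 3: global cycling -----------------------------------------------
  cyc <- detect_global_cycling(atlas, config$alpha, refs, per_organ = TRUE)
  emit(cyc$table, "global_cycling.tsv")
  ph <- phase_summary(cyc, atlas$period_hours)
  emit(ph$table, "phase_summary.tsv")
  loo <- NULL
  if (config$loo) {
    loo <- leave_one_out(atlas, config$alpha, refs)
    emit(loo$counts, "loo.tsv")
  }
  calls <- stats::setNames(cyc$table$is_global_cycler, cyc$table$gene)

  # --- stage 4: rhythmic interactions ---------------------------------------
  batches <- sample_pairs(atlas$gene_ids, config$n_pairs, config$n_repeats,
                          seed = config$seed)
  ib <- interaction_batches(atlas, batches, config$alpha, refs)
  first <- ib$results[[1]]
  strat <- stratify_by_cycling(first, calls)
  emit(first, "interactions.tsv")
  emit(strat$strata, "strata.tsv")
  emit(data.frame(batch = seq_along(ib$per_batch),
                  proportion = ib$per_batch), "interaction_batches.tsv")

  # --- stage 5: networks -----------------------------------------------------
  flat <- flatten_atlas(atlas)
  net_all <- build_network(flat, config$beta)
  assign_all <- detect_modules(net_all, flat)
  if (!is.null(assign_all$eigengenes)) {
    mr <- module_rhythmicity(assign_all, attr(flat, "samples"), config$alpha)
    emit(mr, "module_rhythm.tsv")
  }
  emit(data.frame(gene = names(assign_all$membership),
                  module = assign_all$membership), "modules.tsv")
  topo <- day_night_topology(atlas, config$beta, config$day_start,
                             config$day_end)
  emit(topo$per_zt, "concepts_per_zt.tsv")
  if (!is.null(topo$tests)) emit(topo$tests, "day_night_tests.tsv")

  # --- stage 6: ZT06 vs ZT18 comparison -------------------------------------
  netA <- network_at_zt(atlas, 6, config$beta)
  netB <- network_at_zt(atlas, 18, config$beta)
  diffc <- differential_connectivity(netA, netB, config$fold)
  emit(diffc, "differential.tsv")
  eu <- node_euclidean_distance(netA, netB)
  emit(data.frame(gene = names(eu), euclid = eu), "euclid.tsv")
  pwd <- pair_weight_difference(netA, netB, calls)
  emit(pwd$summary, "pair_delta_summary.tsv")
  assignA <- detect_modules(netA, atlas$values[, , match(6, atlas$zt_times)])
  assignB <- detect_modules(netB, atlas$values[, , match(18, atlas$zt_times)])
  if (!is.null(assignA$eigengenes) && !is.null(assignB$eigengenes)) {
    mj <- module_jaccard(assignA, assignB)
    emit(mj$consensus, "consensus_modules.tsv")
  }

  # --- stage 7: network medicine --------------------------------------------
  ig <- graph_from_edges(inter$edges)
  Dm <- lcc_distance_matrix(ig)
  dis <- do.call(rbind, lapply(seq_along(inter$truth$modules), function(i)
    cbind(disease = paste0("planted", i),
          disease_module_significance(ig, inter$truth$modules[[i]],
                                      config$n_perm_disease,
                                      seed = config$seed + i, D = Dm))))
  dis$q <- adjust_bh(dis$p_empirical)
  emit(dis, "disease_modules.tsv")
  pp <- inter$truth$proximal_pairs[[1]]
  prox <- proximity_significance(ig, pp$A, pp$B, config$n_perm_proximity,
                                 seed = config$seed, D = Dm)
  emit(prox, "proximity.tsv")

  # --- manifest --------------------------------------------------------------
  writeLines(c(
    paste0("chronet version: ",
           as.character(utils::packageVersion("chronet"))),
    paste0("config hash: ", hash),
    paste0("master seed: ", config$seed),
    paste0("parameters: ", paste(names(config), unlist(lapply(config, function(x)
      paste(unlist(x), collapse = "/"))), sep = "=", collapse = "; ")),
    paste0("runtime_sec: ",
           round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1))),
    file.path(out_dir, "manifest.txt"))
  invisible(list(sim = sim, atlas = atlas, cycling = cyc, phase = ph,
                 loo = loo, interactions = ib, strata = strat,
                 modules = assign_all, topology = topo,
                 differential = diffc, disease = dis, proximity = prox))
}
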