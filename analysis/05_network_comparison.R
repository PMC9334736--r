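#!/usr/bin/env Rscript
# Stage 5 — compare the noon (ZT06) and midnight (ZT18) networks.
#
# Differential connectivity (>2-fold), per-gene Euclidean distance between
# adjacency rows, pairwise |delta cor| stratified by cycling status, module
# Jaccard similarity with mutual-best consensus, and the hub subnetwork of
# the largest ZT06 module.

library(chronet)

atlas <- filter_expressed(read_atlas("results/atlas.tsv"))
truth <- read_tsv_table("results/truth_genes.tsv")
cyc <- read_tsv_table("results/global_cycling.tsv")
calls <- stats::setNames(cyc$is_global_cycler == TRUE, cyc$gene)

keep <- atlas$gene_ids[1:600]
sub <- subset_atlas(atlas, genes = keep)
netA <- network_at_zt(sub, 6, beta = 16)
netB <- network_at_zt(sub, 18, beta = 16)

dc <- differential_connectivity(netA, netB, fold = 2)
write_tsv_table(dc, "results/differential.tsv")
tg <- truth[match(dc$gene, truth$gene), ]
fisher_dc <- enrichment_fisher(
  stats::setNames(dc$differential, dc$gene),
  tg$gene[tg$class == "global_cycler"])
cat(sprintf("%d differentially connected genes; cycler enrichment OR %.2f (p = %.3g)\n",
            sum(dc$differential), fisher_dc$odds_ratio, fisher_dc$p))

eu <- node_euclidean_distance(netA, netB)
write_tsv_table(data.frame(gene = names(eu), euclid = eu),
                "results/euclid.tsv")
is_cyc <- tg$class[match(names(eu), tg$gene)] == "global_cycler"
w <- wilcox.test(eu[is_cyc], eu[!is_cyc])
cat(sprintf("Euclidean distance median: cyclers %.3g vs others %.3g (p = %.3g)\n",
            median(eu[is_cyc]), median(eu[!is_cyc]), w$p.value))

pwd <- pair_weight_difference(netA, netB, calls)
write_tsv_table(pwd$summary, "results/pair_delta_summary.tsv")
cat("median |delta cor| by stratum:",
    sprintf("%s %.3g;", pwd$summary$stratum, pwd$summary$median_delta), "\n")

exprA <- sub$values[, , match(6, sub$zt_times)]
exprB <- sub$values[, , match(18, sub$zt_times)]
asgA <- detect_modules(netA, exprA)
asgB <- detect_modules(netB, exprB)
if (length(asgA$sizes) && length(asgB$sizes)) {
  mj <- module_jaccard(asgA, asgB)
  write_tsv_table(mj$consensus, "results/consensus_modules.tsv")
  cat(sprintf("%d/%d ZT06 modules have a consensus partner at ZT18\n",
              nrow(mj$consensus), length(asgA$sizes)))
  big <- names(asgA$membership)[asgA$membership == 1]
  hub <- hub_subnetwork(netA, big, top_n = 50)
  write_tsv_table(hub$hubs, "results/hub_subnetwork.tsv")
}
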