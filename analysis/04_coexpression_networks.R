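#!/usr/bin/env Rscript
# Stage 4 — weighted co-expression networks, modules, day/night topology.
#
# Builds the all-sample unsigned network (|cor|^16) on a 600-gene subset that
# includes the planted modules, detects modules on the TOM dendrogram, tests
# module eigengene/mean rhythmicity, then builds one network per ZT and
# compares the six fundamental network concepts between day and night.

library(chronet)

atlas <- filter_expressed(read_atlas("results/atlas.tsv"))
truth <- read_tsv_table("results/truth_genes.tsv")

# subset: all module members plus the first background genes up to 600
mod_genes <- truth$gene[truth$module > 0]
keep <- unique(c(mod_genes, atlas$gene_ids))[1:600]
keep <- intersect(keep, atlas$gene_ids)
sub <- subset_atlas(atlas, genes = keep)

flat <- flatten_atlas(sub)
net <- build_network(flat, beta = 16)
asg <- detect_modules(net, flat)
write_tsv_table(data.frame(gene = names(asg$membership),
                           module = asg$membership), "results/modules.tsv")
cat(sprintf("%d modules detected (sizes: %s); %d genes unassigned\n",
            length(asg$sizes), paste(asg$sizes, collapse = ", "),
            sum(asg$membership == 0)))

mr <- module_rhythmicity(asg, attr(flat, "samples"), alpha = 0.05)
write_tsv_table(mr, "results/module_rhythm.tsv")
cat(sprintf("%d of %d modules rhythmic; eigengene phases: %s\n",
            sum(mr$rhythmic), nrow(mr),
            paste(mr$phase_eigen[mr$rhythmic], collapse = ", ")))

# enrichment of the planted rhythmic-module genes in detected modules
enr <- module_set_enrichment(asg, truth$gene[truth$module == 1])
write_tsv_table(enr, "results/module_enrichment.tsv")

topo <- day_night_topology(sub, beta = 16)
write_tsv_table(topo$per_zt, "results/concepts_per_zt.tsv")
write_tsv_table(topo$tests, "results/day_night_tests.tsv")
tk <- topo$tests[topo$tests$index == "median_connectivity", ]
cat(sprintf("median connectivity: day %.3g vs night %.3g (Wilcoxon p = %.3g)\n",
            tk$median_day, tk$median_night, tk$p))
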