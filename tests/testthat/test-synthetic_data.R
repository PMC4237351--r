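test_that("configs validate and reject impossible parameters", {
  expect_s3_class(synth_config(), "synth_config")
  expect_error(synth_config(module_size = 5000), "module_size")
  expect_error(synth_config(er_p = 0.3, module_edge_boost = 5), "above 1")
  expect_error(synth_config(signal_beta = 0), "signal_beta")
})

test_that("generated networks are simple, seeded, with a connected module", {
  cfg <- synth_config(n_proteins = 300L, module_size = 25L, seed = 5)
  nm1 <- make_network(cfg)
  nm2 <- make_network(cfg)
  expect_true(igraph::identical_graphs(nm1$network, nm2$network))
  expect_identical(nm1$module, nm2$module)
  nm3 <- make_network(synth_config(n_proteins = 300L, module_size = 25L,
                                   seed = 6))
  expect_false(identical(igraph::ecount(nm3$network),
                         igraph::ecount(nm1$network)) &&
                 identical(nm3$module, nm1$module))
  g <- nm1$network
  expect_equal(igraph::vcount(g), 300L)
  expect_false(any(igraph::which_loop(g)))
  expect_false(any(igraph::which_multiple(g)))
  # module connected within its own induced subgraph
  expect_equal(length(lcc_proteins(g, nm1$module)), 25L)
})

test_that("a large boost drives the module toward a clique", {
  cfg <- synth_config(n_proteins = 100L, module_size = 8L, er_p = 0.01,
                      module_edge_boost = 100, seed = 2)
  nm <- make_network(cfg)
  sub <- igraph::induced_subgraph(nm$network, nm$module)
  expect_equal(igraph::ecount(sub), choose(8, 2))  # p_within capped at 1
})

test_that("unboosted modules are statistically indistinguishable from background", {
  set.seed(99)
  degs_mod <- c(); degs_bg <- c()
  for (i in 1:20) {
    cfg <- synth_config(n_proteins = 400L, module_size = 40L,
                        module_edge_boost = 1, seed = 1000 + i)
    nm <- make_network(cfg)
    deg <- igraph::degree(nm$network)
    degs_mod <- c(degs_mod, deg[nm$module])
    degs_bg <- c(degs_bg, deg[setdiff(names(deg), nm$module)])
  }
  # module degrees only gain the few forced connectivity bridges; a KS test
  # at alpha = 0.001 should not separate the two degree samples
  ks <- suppressWarnings(ks.test(degs_mod, degs_bg))
  expect_gt(ks$p.value, 0.001)
})

test_that("association p-values follow the declared null and signal laws", {
  # null: all SNP p-values uniform (KS at alpha = 0.001, large n)
  cfg0 <- synth_config(signal_beta = 1, seed = 21)
  d0 <- simulate_dataset(cfg0)
  ks0 <- ks.test(d0$snps$pvalue, "punif")
  expect_gt(ks0$p.value, 0.001)
  # signal: SNPs of signal genes follow Beta(b, 1), CDF p^b
  cfg1 <- synth_config(signal_beta = 0.2, signal_fraction = 1, seed = 22)
  d1 <- simulate_dataset(cfg1)
  asg <- assign_snps_to_genes(d1$snps, d1$genes, window_bp = 0)
  sig_p <- asg$pvalue[asg$gene_id %in% d1$signal_genes]
  ks1 <- ks.test(sig_p, function(q) q^0.2)
  expect_gt(ks1$p.value, 0.001)
})

test_that("signal genes beat background at best-SNP level per the Beta oracle", {
  cfg <- synth_config(signal_beta = 0.2, signal_fraction = 1, seed = 30)
  d <- simulate_dataset(cfg)
  asg <- assign_snps_to_genes(d$snps, d$genes, window_bp = 0)
  best <- best_snp_pvalue(asg)
  sig <- best[best$gene_id %in% d$signal_genes]
  bg <- best[!best$gene_id %in% d$signal_genes]
  # closed-form oracle: P(best of k p-values < 0.1) with CDF F
  p_best_lt <- function(k, F01) 1 - (1 - F01)^k
  exp_sig <- mean(p_best_lt(sig$n_snps, 0.1^0.2))
  exp_bg <- mean(p_best_lt(bg$n_snps, 0.1))
  expect_gt(exp_sig, exp_bg)  # oracle itself predicts enrichment
  expect_equal(mean(sig$best_snp_p < 0.1), exp_sig, tolerance = 0.05)
  expect_equal(mean(bg$best_snp_p < 0.1), exp_bg, tolerance = 0.05)
})

test_that("gene layout is assignment-exact and the map is one-to-one", {
  d <- simulate_dataset(synth_config(n_proteins = 150L, n_genes = 200L,
                                     module_size = 12L, candidate_size = 10L,
                                     seed = 9))
  expect_equal(nrow(d$map), 150L)
  expect_equal(anyDuplicated(d$map$gene_id), 0L)
  expect_equal(anyDuplicated(d$map$protein_id), 0L)
  # every SNP lies inside its own gene body (window 0 reassigns all SNPs)
  asg <- assign_snps_to_genes(d$snps, d$genes, window_bp = 0)
  expect_equal(attr(asg, "n_unassigned_snps"), 0L)
  # gene bodies do not overlap, so window-0 assignment is unique
  expect_equal(nrow(asg), nrow(d$snps))
  # module genes are exactly the genes mapping to module proteins
  expect_setequal(d$module_genes,
                  d$map$gene_id[d$map$protein_id %in% d$module])
})

test_that("candidate lists honour size and overlap exactly", {
  cfg <- synth_config(n_proteins = 200L, n_genes = 300L, module_size = 30L,
                      candidate_size = 20L, candidate_overlap = 0.5, seed = 4)
  d <- simulate_dataset(cfg)
  expect_equal(length(d$candidates), 20L)
  expect_equal(sum(d$candidates %in% d$module_genes), 10L)
  # overlap 1 with size = module size reproduces the module genes
  cfg1 <- synth_config(n_proteins = 200L, n_genes = 300L, module_size = 30L,
                       candidate_size = 30L, candidate_overlap = 1, seed = 4)
  d1 <- simulate_dataset(cfg1)
  expect_setequal(d1$candidates, d1$module_genes)
  # overlap 0 is disjoint from the module
  cfg0 <- synth_config(n_proteins = 200L, n_genes = 300L, module_size = 30L,
                       candidate_size = 15L, candidate_overlap = 0, seed = 4)
  d0 <- simulate_dataset(cfg0)
  expect_equal(sum(d0$candidates %in% d0$module_genes), 0L)
  # impossible overlap errors
  expect_error(
    simulate_dataset(synth_config(n_proteins = 100L, n_genes = 150L,
                                  module_size = 5L, candidate_size = 40L,
                                  candidate_overlap = 1, seed = 4)),
    "overlap")
})

test_that("the full generator is deterministic under its seed", {
  a <- simulate_dataset(synth_config(n_proteins = 150L, n_genes = 200L,
                                     module_size = 10L, candidate_size = 8L,
                                     seed = 77))
  b <- simulate_dataset(synth_config(n_proteins = 150L, n_genes = 200L,
                                     module_size = 10L, candidate_size = 8L,
                                     seed = 77))
  expect_equal(a$snps, b$snps)
  expect_equal(a$candidates, b$candidates)
  expect_identical(a$module, b$module)
  expect_true(igraph::identical_graphs(a$network, b$network))
})
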