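make_snps <- function(pos, p = NULL, chrom = "1") {
  data.frame(snp_id = sprintf("rs%03d", seq_along(pos)), chrom = chrom,
             pos = as.integer(pos),
             pvalue = if (is.null(p)) runif(length(pos)) else p)
}

test_that("SNP assignment respects the symmetric window boundary exactly", {
  genes <- data.frame(gene_id = "g1", chrom = "1",
                      start = 100000L, end = 200000L)
  snps <- make_snps(c(195000, 210000, 210001, 90000, 89999),
                    p = rep(0.5, 5))
  asg <- assign_snps_to_genes(snps, genes, window_bp = 10000)
  expect_setequal(asg$snp_id, c("rs001", "rs002", "rs004"))
  expect_equal(attr(asg, "n_unassigned_snps"), 2L)
  # window 0 assigns only in-gene SNPs
  asg0 <- assign_snps_to_genes(snps, genes, window_bp = 0)
  expect_equal(asg0$snp_id, "rs001")
  # different chromosome never assigns
  snps2 <- make_snps(150000, p = 0.5, chrom = "2")
  expect_equal(nrow(assign_snps_to_genes(snps2, genes)), 0L)
})

test_that("a SNP inside two overlapping genes is assigned to both", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "1",
                      start = c(100L, 400L), end = c(600L, 900L))
  snps <- make_snps(500, p = 0.5)
  asg <- assign_snps_to_genes(snps, genes, window_bp = 0)
  expect_setequal(asg$gene_id, c("g1", "g2"))
})

test_that("assignments grow monotonically with the window", {
  set.seed(42)
  genes <- data.frame(gene_id = sprintf("g%d", 1:20), chrom = "1",
                      start = as.integer(seq(1e5, 2e6, length.out = 20)),
                      end = as.integer(seq(1e5, 2e6, length.out = 20)) + 5000L)
  snps <- make_snps(sample.int(2.2e6, 400))
  prev <- 0L
  for (w in c(0, 1000, 10000, 50000)) {
    n <- nrow(assign_snps_to_genes(snps, genes, window_bp = w))
    expect_gte(n, prev)
    prev <- n
  }
})

test_that("best SNP p-value is the bin minimum with deterministic tie id", {
  asg <- data.frame(
    gene_id = c("g1", "g1", "g1", "g2", "g3", "g3"),
    snp_id = c("rs5", "rs2", "rs9", "rs1", "rsB", "rsA"),
    pos = 1:6,
    pvalue = c(0.5, 0.01, 0.2, 0.7, 0.05, 0.05))
  best <- best_snp_pvalue(asg)
  expect_equal(best$best_snp_p, c(0.01, 0.7, 0.05))
  expect_equal(best$n_snps, c(3L, 1L, 2L))
  expect_equal(best$best_snp_id[3], "rsA")  # lexicographic tie-break
})

test_that("corrected p-values are the rank-uniform transform", {
  set.seed(1)
  n <- 50
  raw <- data.frame(gene_id = sprintf("g%02d", 1:n),
                    best_snp_p = runif(n),
                    gene_size_kb = rep(10, n), n_snps = rep(5L, n),
                    snps_per_kb = rep(0.5, n))
  out <- suppressWarnings(correct_gene_scores(raw))
  # identical covariates: none can enter; ordering equals best_p ordering
  expect_equal(attr(out, "selected_covariates"), character(0))
  expect_equal(order(out$corrected_p), order(out$best_snp_p))
  # exact permutation of i/(N+1), so never 0 or 1
  expect_setequal(out$corrected_p, seq_len(n) / (n + 1))
  expect_equal(out$neg_log10_p, -log10(out$corrected_p))
})

test_that("stepwise correction removes a planted confounder", {
  set.seed(7)
  n <- 2000
  spk <- runif(n, 0.1, 3)
  y <- 2 * spk + rnorm(n)
  raw <- data.frame(gene_id = sprintf("g%04d", 1:n),
                    best_snp_p = pmin(1, pmax(1e-300, 10^(-y))),
                    gene_size_kb = runif(n, 1, 100),
                    n_snps = sample(1:50, n, TRUE),
                    snps_per_kb = spk)
  out <- correct_gene_scores(raw)
  expect_true("snps_per_kb" %in% attr(out, "selected_covariates"))
  rho <- cor(out$corrected_p, spk, method = "spearman")
  expect_lt(abs(rho), 0.1)
  # raw best-p ranks, by contrast, are strongly confounded
  expect_lt(cor(raw$best_snp_p, spk, method = "spearman"), -0.5)
})

test_that("correction refuses too-few genes and non-finite covariates", {
  raw <- data.frame(gene_id = c("g1", "g2"), best_snp_p = c(0.1, 0.2),
                    gene_size_kb = c(1, 2), n_snps = c(1L, 2L),
                    snps_per_kb = c(1, 1))
  expect_error(correct_gene_scores(raw), ">= 10 genes")
  raw10 <- data.frame(gene_id = sprintf("g%d", 1:10),
                      best_snp_p = seq(0.05, 0.5, 0.05),
                      gene_size_kb = c(Inf, rep(1, 9)),
                      n_snps = 1:10, snps_per_kb = 1:10)
  expect_error(correct_gene_scores(raw10), "finite")
})

test_that("collinear covariates are dropped with a warning", {
  set.seed(3)
  n <- 40
  ns <- sample(1:30, n, TRUE)
  raw <- data.frame(gene_id = sprintf("g%02d", 1:n),
                    best_snp_p = runif(n),
                    gene_size_kb = runif(n, 5, 20),
                    n_snps = ns, snps_per_kb = ns / 10)
  raw$snps_per_kb <- raw$n_snps / 10  # exact duplicate of n_snps up to scale
  expect_warning(correct_gene_scores(raw), "collinear")
})

test_that("null gene scores are calibrated: ~10% of genes below p = 0.1", {
  set.seed(11)
  fracs <- replicate(20, {
    d <- simulate_dataset(synth_config(n_proteins = 200L, n_genes = 300L,
                                       module_size = 10L, signal_beta = 1,
                                       candidate_size = 8L,
                                       seed = sample.int(1e6, 1)))
    sc <- suppressWarnings(gene_scores(d$snps, d$genes))
    mean(sc$corrected_p < 0.1)
  })
  # rank transform makes the fraction nearly deterministic at 10%
  expect_equal(mean(fracs), 0.1, tolerance = 0.01)
})

test_that("end-to-end gene_scores excludes genes without SNPs", {
  genes <- data.frame(gene_id = sprintf("g%02d", 1:12), chrom = "1",
                      start = as.integer(seq(1e5, 12e5, 1e5)),
                      end = as.integer(seq(1e5, 12e5, 1e5)) + 10000L)
  set.seed(5)
  # SNPs only in the first 11 genes
  snps <- make_snps(unlist(lapply(seq(1e5, 11e5, 1e5),
                                  function(s) s + c(10, 20, 30))))
  sc <- suppressWarnings(gene_scores(snps, genes, window_bp = 0))
  expect_equal(nrow(sc), 11L)
  expect_false("g12" %in% sc$gene_id)
  expect_true(all(sc$n_snps == 3L))
})
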