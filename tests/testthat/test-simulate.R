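test_that("evolve_codon_pair honours zero and saturating targets", {
  p <- evolve_codon_pair(50, 0, 0, kappa = 2, seed = 3)
  expect_identical(p$a, p$b)
  expect_error(evolve_codon_pair(1, 5, 0.1, seed = 1), "saturation")
  expect_error(evolve_codon_pair(0, 0.1, 0.1), "length_codons")
  expect_error(evolve_codon_pair(10, -0.1, 0), ">= 0")
})

test_that("evolved pairs never contain stop codons", {
  tab <- Biostrings::GENETIC_CODE
  for (s in 1:5) {
    p <- evolve_codon_pair(80, 0.8, 0.2, kappa = 2, seed = s)
    for (seqn in c(p$a, p$b)) {
      cod <- substring(seqn, seq(1, nchar(seqn), 3), seq(3, nchar(seqn), 3))
      expect_false(any(tab[cod] == "*"))
    }
  }
})

test_that("realized synonymous divergence matches the target (NG86 readout)", {
  set.seed(7)
  est <- replicate(40, {
    p <- evolve_codon_pair(500, 0.2, 0.05, kappa = 1)
    ng86(align_codons_equal(p$a, p$b))$ks
  })
  expect_lt(abs(mean(est) - 0.2), 0.03)
})

test_that("the same seed reproduces a byte-identical dataset", {
  prm <- simulation_params(n_chromosomes = 1, genes_per_chromosome = 15,
                           n_tf_families = 1, tf_family_size = 3,
                           codon_length = c(30, 40), seed = 55)
  expect_identical(simulate_genome(prm), simulate_genome(prm))
})

test_that("full retention under a single WGD duplicates every gene", {
  prm <- simulation_params(
    n_chromosomes = 1, genes_per_chromosome = 20,
    wgd_events = list(list(name = "sigma", ks_depth = 0.3,
                           retention_prob_background = 1,
                           retention_prob_tf = 1)),
    tandem_rate = 0, n_tf_families = 1, tf_family_size = 2,
    codon_length = c(30, 40), seed = 9)
  ds <- simulate_genome(prm)
  mc <- ds$genes[ds$genes$species == "MC", ]
  expect_true(all(table(mc$family) == 2))
  expect_equal(sum(mc$copy != "0"), 20)
})

test_that("a WGD at near-zero depth leaves duplicate pairs undiverged", {
  prm <- simulation_params(
    n_chromosomes = 1, genes_per_chromosome = 12,
    wgd_events = list(list(name = "sigma", ks_depth = 0.004,
                           retention_prob_background = 1,
                           retention_prob_tf = 1)),
    tandem_rate = 0, ortholog_ks = 0.002, n_tf_families = 1,
    tf_family_size = 2, codon_length = c(50, 60), seed = 12)
  ds <- simulate_genome(prm)
  mc <- ds$genes[ds$genes$species == "MC", ]
  ks <- vapply(unique(mc$family), function(fam) {
    g <- mc$gene_id[mc$family == fam]
    ng86(align_codons_equal(ds$cds[[g[1]]], ds$cds[[g[2]]]))$ks
  }, numeric(1))
  # a single substitution on a ~55-codon gene already gives Ks ~ 0.025,
  # so individual pairs are bounded loosely and the mean tightly
  expect_lt(mean(ks), 0.02)
  expect_true(all(ks <= 0.06))
})

test_that("realized retention matches the binomial expectation", {
  # pooled over replicate genomes: retention draws are Bernoulli(p) per
  # duplicate, so the pooled fraction sits within 3 binomial SE of p
  p_ret <- 0.2
  kept <- 0; tried <- 0
  for (s in 1:10) {
    prm <- simulation_params(
      n_chromosomes = 1, genes_per_chromosome = 100,
      wgd_events = list(list(name = "sigma", ks_depth = 0.3,
                             retention_prob_background = p_ret,
                             retention_prob_tf = p_ret)),
      tandem_rate = 0, n_tf_families = 1, tf_family_size = 2,
      codon_length = c(30, 31), seed = 1000 + s)
    ds <- simulate_genome(prm)
    mc <- ds$genes[ds$genes$species == "MC", ]
    kept <- kept + sum(mc$copy != "0")
    tried <- tried + 100
  }
  se <- sqrt(p_ret * (1 - p_ret) / tried)
  expect_lt(abs(kept / tried - p_ret), 3 * se)
})

test_that("higher TF retention raises TF-family retention monotonically", {
  frac_tf <- function(p_tf, seed) {
    prm <- simulation_params(
      n_chromosomes = 1, genes_per_chromosome = 60,
      wgd_events = list(list(name = "sigma", ks_depth = 0.3,
                             retention_prob_background = 0.2,
                             retention_prob_tf = p_tf)),
      tandem_rate = 0, n_tf_families = 2, tf_family_size = 10,
      codon_length = c(30, 31), seed = seed)
    simulate_genome(prm)$truth$events$realized_retention_tf
  }
  lo <- mean(vapply(1:6, function(s) frac_tf(0.2, 300 + s), numeric(1)))
  hi <- mean(vapply(1:6, function(s) frac_tf(0.7, 300 + s), numeric(1)))
  expect_gt(hi, lo)
})

test_that("ground-truth labels are consistent with the simulated genome", {
  ds <- small_sim()
  ids <- ds$genes$gene_id
  expect_true(all(ds$true_pair_labels$gene_a %in% ids))
  expect_true(all(ds$true_pair_labels$gene_b %in% ids))
  # canonical order makes the map symmetric
  expect_true(all(ds$true_pair_labels$gene_a < ds$true_pair_labels$gene_b))
  # tandem pairs: same chromosome, rank distance <= 5
  tand <- ds$true_pair_labels[ds$true_pair_labels$label == "tandem", ]
  if (nrow(tand) > 0) {
    ia <- match(tand$gene_a, ids); ib <- match(tand$gene_b, ids)
    expect_true(all(ds$genes$chromosome[ia] == ds$genes$chromosome[ib]))
    expect_true(all(abs(ds$genes$rank[ia] - ds$genes$rank[ib]) <= 5))
  }
  # sigma-labeled pairs diverged at the younger depth: their Ks estimates
  # cluster near the younger event, not the older one
  sig <- ds$true_pair_labels[ds$true_pair_labels$label == "sigma", ][1:10, ]
  ks <- vapply(seq_len(nrow(sig)), function(i)
    ng86(align_codons_equal(ds$cds[[sig$gene_a[i]]],
                            ds$cds[[sig$gene_b[i]]]))$ks, numeric(1))
  expect_lt(abs(mean(ks) - 0.27), 0.15)
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(simulation_params(genes_per_chromosome = 5), "blocks")
  expect_error(simulation_params(n_species = 2), "n_species")
  expect_error(simulation_params(wgd_events = list(
    list(name = "a", ks_depth = 0.9, retention_prob_background = 0.2,
         retention_prob_tf = 0.3),
    list(name = "b", ks_depth = 0.3, retention_prob_background = 0.2,
         retention_prob_tf = 0.3))), "increasing")
  expect_error(simulation_params(tandem_rate = 1.2), "probabilities")
})

test_that("write_dataset emits files that round-trip through the readers", {
  ds <- small_sim()
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  cds <- read_fasta(file.path(dir, "cds.fasta"))
  expect_identical(unname(cds[names(ds$cds)]), unname(ds$cds))
  genes <- read_gene_positions(file.path(dir, "gene_positions.tsv"))
  m <- match(ds$genes$gene_id, genes$gene_id)
  expect_equal(genes$rank[m], ds$genes$rank)
  trees <- read_gene_trees(file.path(dir, "gene_trees.tsv"))
  expect_identical(names(trees), names(ds$trees))
  pairs <- read_pairs(file.path(dir, "pairs.tsv"))
  expect_equal(nrow(pairs), nrow(ds$pairs))
})
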