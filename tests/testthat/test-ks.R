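test_that("protein alignments back-thread onto codons with gap exclusion", {
  aln <- backthread_codon_alignment("M-K", "MAK", "ATGAAA", "ATGGCTAAA",
                                    "gA", "gB")
  expect_identical(aln$codons_a, c("ATG", "---", "AAA"))
  expect_identical(aln$codons_b, c("ATG", "GCT", "AAA"))
  expect_identical(aln$counted, c(TRUE, FALSE, TRUE))

  ident <- backthread_codon_alignment("MKL", "MKL", "ATGAAACTG", "ATGAAACTG")
  expect_true(all(ident$counted))

  expect_error(
    backthread_codon_alignment("MK", "MK", "ATGAAAGGG", "ATGAAA", "gX"),
    "gX")
  expect_error(
    backthread_codon_alignment("MW", "MW", "ATGAAA", "ATGTGG"),
    "translates")
})

test_that("columns with N or a stop codon are excluded from counting", {
  aln <- align_codons_equal("ATGANATAA", "ATGAAATAA")
  # codon 2 has N, codon 3 is a stop in both
  expect_identical(aln$counted, c(TRUE, FALSE, FALSE))
})

test_that("NG86 on an identical pair gives zero divergence and exact sites", {
  cds <- paste(rep("ATGGCTAAACTG", 25), collapse = "")  # 100 codons
  est <- ng86(align_codons_equal(cds, cds))
  expect_equal(est$Sd, 0)
  expect_equal(est$Nd, 0)
  expect_equal(est$ks, 0)
  expect_equal(est$ka, 0)
  expect_equal(est$S + est$N, 300)
})

test_that("NG86 equals the enumeration oracle exactly on short alignments", {
  set.seed(11)
  for (rep in 1:25) {
    L <- sample(1:20, 1)
    ca <- random_sense_codons(L)
    cb <- random_sense_codons(L)
    est <- ng86(new_codon_alignment_for_test(ca, cb))
    orc <- oracle_ng86(ca, cb)
    expect_equal(est$S, orc$S, tolerance = 1e-12)
    expect_equal(est$Sd, orc$Sd, tolerance = 1e-12)
    expect_equal(est$Nd, orc$Nd, tolerance = 1e-12)
    if (is.na(orc$ds)) expect_false(est$valid)
    else expect_equal(est$ks, orc$ds, tolerance = 1e-12)
  }
})

test_that("S + N equals three times the counted codons", {
  set.seed(2)
  for (rep in 1:10) {
    L <- sample(5:40, 1)
    est <- ng86(new_codon_alignment_for_test(random_sense_codons(L),
                                             random_sense_codons(L)))
    expect_equal(est$S + est$N, 3 * L)
  }
})

test_that("estimates are symmetric in the two sequences", {
  p <- evolve_codon_pair(120, 0.4, 0.1, kappa = 2, seed = 21)
  for (fun in list(ng86, yn00)) {
    e1 <- fun(align_codons_equal(p$a, p$b))
    e2 <- fun(align_codons_equal(p$b, p$a))
    expect_equal(e1$ks, e2$ks)
    expect_equal(e1$ka, e2$ka)
    expect_equal(e1$S, e2$S)
  }
})

test_that("NG86 recovers simulated synonymous divergence", {
  set.seed(31)
  est <- replicate(40, {
    p <- evolve_codon_pair(500, 0.3, 0.05, kappa = 1)
    ng86(align_codons_equal(p$a, p$b))$ks
  })
  expect_lt(abs(mean(est) - 0.3), 0.04)
})

test_that("YN00 zeroes on identical pairs and recovers kappa", {
  cds <- paste(random_sense_codons(60), collapse = "")
  est <- yn00(align_codons_equal(cds, cds))
  expect_equal(est$ks, 0)
  expect_equal(est$ka, 0)
  expect_true(est$valid)

  set.seed(41)
  kap <- replicate(40, {
    p <- evolve_codon_pair(500, 0.4, 0.08, kappa = 2)
    yn00(align_codons_equal(p$a, p$b))$kappa
  })
  expect_gt(mean(kap), 1.5)
  expect_lt(mean(kap), 2.5)
})

test_that("YN00 and NG86 coincide at kappa 1 with uniform codon usage", {
  set.seed(51)
  diffs <- replicate(15, {
    p <- evolve_codon_pair(400, 0.3, 0.06, kappa = 1)
    aln <- align_codons_equal(p$a, p$b)
    yn00(aln)$ks - ng86(aln)$ks
  })
  # the models coincide in this limit up to finite-sample noise in the
  # empirical codon frequencies and the kappa estimate
  expect_lt(abs(mean(diffs)), 0.02)
  expect_lt(max(abs(diffs)), 0.05)
})

test_that("saturated alignments are flagged invalid, not clamped", {
  # every codon differs synonymously: pS = 3 > 3/4
  a <- paste(rep("TTT", 30), collapse = "")
  b <- paste(rep("TTC", 30), collapse = "")
  est <- ng86(align_codons_equal(a, b))
  expect_false(est$valid)
  expect_true(is.na(est$ks))
  est2 <- yn00(align_codons_equal(a, b))
  expect_false(est2$valid)
})

test_that("yn00 requires at least 10 counted codons", {
  cds <- paste(random_sense_codons(9), collapse = "")
  expect_error(yn00(align_codons_equal(cds, cds)), "10")
})

test_that("Ks grows with simulated divergence until saturation", {
  set.seed(61)
  mean_ks <- vapply(c(0.1, 0.4, 0.8), function(d) {
    mean(replicate(8, {
      p <- evolve_codon_pair(300, d, 0.1 * d, kappa = 2)
      yn00(align_codons_equal(p$a, p$b))$ks
    }))
  }, numeric(1))
  expect_true(all(diff(mean_ks) > 0))
})

test_that("filter_ks applies strict bounds and drops invalid estimates", {
  df <- data.frame(gene_a = "a", gene_b = "b", ks = c(0.04, 0.05, 0.06, 1.50,
                                                      1.49, 0.3),
                   valid = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  kept <- filter_ks(df)
  expect_equal(sort(kept$ks), c(0.06, 1.49))
  expect_equal(nrow(filter_ks(df[0, ])), 0)
  expect_error(filter_ks(df, lo = 1, hi = 0.5), "lo")

  # oracle: plain comprehension
  set.seed(71)
  df2 <- data.frame(gene_a = "a", gene_b = "b", ks = runif(100, 0, 2),
                    valid = runif(100) > 0.1)
  kept2 <- filter_ks(df2, 0.2, 1.1)
  expect_identical(kept2$ks,
                   df2$ks[df2$valid & df2$ks > 0.2 & df2$ks < 1.1])
})

test_that("single-copy ortholog Ks uses only strict 1:1 orthogroups", {
  p1 <- evolve_codon_pair(60, 0.25, 0.05, seed = 81)
  p2 <- evolve_codon_pair(60, 0.25, 0.05, seed = 82)
  cds <- c(g1 = p1$a, g2 = p1$b, g3 = p2$a, g4 = p2$b, g5 = p2$b)
  og <- data.frame(
    orthogroup = c("og1", "og1", "og2", "og2", "og2"),
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    species = c("A", "B", "A", "A", "B"))
  est <- single_copy_ortholog_ks(og, c("A", "B"), cds, method = "NG86")
  # og2 has two A genes and contributes nothing
  expect_equal(nrow(est), 1)
  expect_setequal(c(est$gene_a, est$gene_b), c("g1", "g2"))
})

test_that("ortholog Ks distribution peaks at the simulated divergence", {
  set.seed(91)
  rows <- lapply(1:50, function(i) {
    p <- evolve_codon_pair(150, 0.25, 0.05, kappa = 2)
    data.frame(orthogroup = sprintf("og%02d", i),
               gene_id = c(sprintf("a%02d", i), sprintf("b%02d", i)),
               species = c("A", "B"), seq = c(p$a, p$b))
  })
  og <- do.call(rbind, rows)
  cds <- stats::setNames(og$seq, og$gene_id)
  est <- single_copy_ortholog_ks(og[, 1:3], c("A", "B"), cds)
  h <- hist(est$ks, breaks = seq(0, 1, 0.05), plot = FALSE)
  mode_mid <- h$mids[which.max(h$counts)]
  expect_lt(abs(mode_mid - 0.25), 0.075)
})
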