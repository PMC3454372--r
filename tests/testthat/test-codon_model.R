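# Codon usage, frame-shift Markov chains and frame probabilities.

test_that("codon usage counts every triplet including the terminal stop", {
  fa <- tempfile(fileext = ".fasta")
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(">t", "ATGAAATAA"), fa)
  write.table(data.frame(gene_id = "g", start = 1, end = 9, strand = "+"),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- read_genome(fa, format = "fasta", gene_table = tsv)
  u <- codon_usage(extract_aorfs(rec, filter_genes(rec)), rec$sequence)
  expect_equal(unname(u["ATG"]), 1 / 3)
  expect_equal(unname(u["AAA"]), 1 / 3)
  expect_equal(unname(u["TAA"]), 1 / 3)
  expect_equal(sum(u), 1)

  # two genes of 2 and 4 codons: denominator 6
  writeLines(c(">t", "ATGTAAATGCCCGGGTAA"), fa)
  write.table(data.frame(gene_id = c("a", "b"), start = c(1, 7), end = c(6, 18),
                         strand = "+"),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  rec2 <- read_genome(fa, format = "fasta", gene_table = tsv)
  aorfs <- extract_aorfs(rec2, filter_genes(rec2))
  u2 <- codon_usage(aorfs, rec2$sequence)
  expect_equal(unname(u2["ATG"]), 2 / 6)
  expect_equal(unname(u2["TAA"]), 2 / 6)
  expect_equal(unname(u2["CCC"]), 1 / 6)
  # gene-subset restriction reuses the same estimator
  u_sub <- codon_usage(aorfs, rec2$sequence, gene_ids = "a")
  expect_equal(unname(u_sub["ATG"]), 1 / 2)
})

test_that("minus-strand genes are counted on the coding strand", {
  fa <- tempfile(fileext = ".fasta")
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(">t", "TTACATCAT"), fa)  # revcomp ATGATGTAA
  write.table(data.frame(gene_id = "g", start = 1, end = 9, strand = "-"),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- read_genome(fa, format = "fasta", gene_table = tsv)
  u <- codon_usage(extract_aorfs(rec, filter_genes(rec)), rec$sequence)
  expect_equal(unname(u["ATG"]), 2 / 3)
  expect_equal(unname(u["TAA"]), 1 / 3)
})

test_that("the -1 frame distribution is the usage under reverse complement", {
  p <- rep(0, 64)
  names(p) <- orfstat:::CODONS
  p["CTA"] <- 0.2
  p["AAA"] <- 0.8
  q <- frame_minus1_usage(orfstat:::as_codon_usage(p))
  expect_equal(unname(q["TAG"]), 0.2)
  expect_equal(unname(q["TTT"]), 0.8)
  # uniform usage is invariant; double application is the identity
  expect_equal(unname(unclass(frame_minus1_usage(uniform_usage()))),
               rep(1 / 64, 64), ignore_attr = TRUE)
  u <- random_usage(3)
  expect_equal(unclass(frame_minus1_usage(frame_minus1_usage(u))), unclass(u),
               ignore_attr = TRUE)
})

test_that("transition matrices collapse correctly for uniform and degenerate usages", {
  for (fr in c("+2", "+3", "-2", "-3")) {
    Q <- transition_matrix(uniform_usage(), fr)
    expect_equal(max(abs(Q - 1 / 64)), 0)
  }
  # single-codon usage absorbs at that codon
  p <- rep(0, 64); names(p) <- orfstat:::CODONS; p["AAA"] <- 1
  for (fr in c("+2", "+3")) {
    Q <- transition_matrix(orfstat:::as_codon_usage(p), fr)
    expect_equal(unname(Q["AAA", "AAA"]), 1)
    expect_equal(max(abs(rowSums(Q) - 1)), 0, tolerance = 1e-12)
  }
})

test_that("transition probabilities match frame +2 dicodon statistics of an IID simulation", {
  p <- rep(0, 64)
  names(p) <- orfstat:::CODONS
  p[c("ATG", "TAA", "GGC")] <- c(0.5, 0.3, 0.2)
  u <- orfstat:::as_codon_usage(p)
  Q <- transition_matrix(u, "+2")
  s <- rcodon_simulate(u, 3e6, seed = 17)           # 1e6 codons
  codes <- orfstat:::seq_to_codes(as.character(s))
  f2 <- orfstat:::frame_codon_index(codes, 1L)
  n <- length(f2) - 1L
  pair <- (f2[-length(f2)] - 1L) * 64L + f2[-1L]
  cnt <- tabulate(pair, nbins = 64L * 64L)
  row_cnt <- tabulate(f2[-length(f2)], nbins = 64L)
  for (i in which(row_cnt >= 1000)) {
    qhat <- cnt[(i - 1L) * 64L + 1:64] / row_cnt[i]
    se <- sqrt(Q[i, ] * (1 - Q[i, ]) / row_cnt[i])
    cells <- Q[i, ] > 0
    expect_true(all(abs(qhat[cells] - Q[i, cells]) <= 3 * se[cells] + 1e-12))
  }
})

test_that("stationary distributions are exact fixed points", {
  # uniform and doubly stochastic matrices have the uniform stationary law
  expect_equal(stationary_distribution(matrix(1 / 64, 64, 64)), rep(1 / 64, 64))
  P <- diag(4)[c(2, 3, 4, 1), ] * 0.9 + 0.025   # lazy cyclic, doubly stochastic
  expect_equal(stationary_distribution(P), rep(0.25, 4))
  for (seed in 1:5) {
    u <- random_usage(seed)
    for (fr in c("+2", "+3", "-2", "-3")) {
      Q <- transition_matrix(u, fr)
      d <- stationary_distribution(Q)
      expect_lt(sum(abs(as.vector(d %*% Q) - d)), 1e-10)
      expect_equal(sum(d), 1, tolerance = 1e-12)
      expect_true(all(d >= 0))
    }
  }
})

test_that("reducible chains are rejected with their closed classes", {
  Q <- diag(2)  # two absorbing states
  expect_error(stationary_distribution(Q), "closed classes")
})

test_that("stationary laws match empirical frame-shifted codon frequencies", {
  u <- random_usage(8)
  s <- as.character(rcodon_simulate(u, 1.5e6, seed = 9))
  for (fr in c("+2", "+3", "-2", "-3")) {
    d <- stationary_distribution(transition_matrix(u, fr))
    emp <- empirical_frame_dist(s, fr)
    n <- 5e5 - 1
    se <- sqrt(d * (1 - d) / n)
    expect_true(all(abs(emp - d) <= 4 * se + 1e-9))
  }
})

test_that("frame probabilities reproduce closed forms", {
  fp <- frame_probabilities(uniform_usage())
  expect_equal(fp$rho, rep(3 / 64, 6))
  expect_equal(fp$tau, rep(4 / 64, 6))
  fpm <- frame_probabilities(uniform_usage(), mollicute_code())
  expect_equal(fpm$rho, rep(2 / 64, 6))

  p <- rep(0, 64); names(p) <- orfstat:::CODONS
  p[c("ATG", "AAA", "TAA")] <- 1 / 3
  expect_warning(fp3 <- frame_probabilities(orfstat:::as_codon_usage(p)),
                 "frame")
  expect_equal(fp3["+1", "rho"], 1 / 3)
  expect_equal(fp3["+1", "tau"], 1 / 3)
  expect_equal(fp3["-1", "rho"], 0)   # no TTA/CTA/TCA in the usage
})

test_that("position-independent GC-only usages collapse all six frames", {
  for (gc in c(0.3, 0.5, 0.65)) {
    pn <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    p <- vapply(orfstat:::CODONS, function(cd) {
      prod(pn[strsplit(cd, "")[[1]]])
    }, numeric(1))
    u <- orfstat:::as_codon_usage(p)
    fp <- frame_probabilities(u)
    dists <- attr(fp, "distributions")
    for (fr in c("+2", "+3", "-1", "-2", "-3")) {
      expect_equal(unname(dists[[fr]]), unname(dists[["+1"]]), tolerance = 1e-12)
    }
  }
})

test_that("usage tables round-trip through TSV", {
  u <- random_usage(2)
  f <- tempfile(fileext = ".tsv")
  write_usage_tsv(u, f)
  u2 <- read_usage_tsv(f)
  expect_equal(unclass(u2), unclass(u), tolerance = 1e-12, ignore_attr = TRUE)
})
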