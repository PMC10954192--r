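test_that("K80 distance matches its closed form", {
  s <- rand_seq(100, 91)
  # identical sequences
  d0 <- k80_distance(s, s)
  expect_equal(d0$d, 0)
  expect_equal(c(d0$P, d0$Q), c(0, 0))
  expect_equal(d0$n_sites, 100)

  # 10 transitions, 0 transversions over 100 sites -> -1/2 ln(0.8)
  a <- strsplit(s, "")[[1]]
  b <- a
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  b[1:10] <- ts_map[a[1:10]]
  d1 <- k80_distance(s, paste(b, collapse = ""))
  expect_equal(d1$P, 0.10)
  expect_equal(d1$Q, 0)
  expect_equal(d1$d, 0.111571776, tolerance = 1e-8)

  # P = Q = 0.05 -> -1/2 ln(0.85 * sqrt(0.9))
  tv_map <- c(A = "C", G = "T", C = "A", T = "G")
  b2 <- a
  b2[1:5] <- ts_map[a[1:5]]
  b2[6:10] <- tv_map[a[6:10]]
  d2 <- k80_distance(s, paste(b2, collapse = ""))
  expect_equal(c(d2$P, d2$Q), c(0.05, 0.05))
  expect_equal(d2$d, 0.107599594, tolerance = 1e-8)

  # symmetry
  d2r <- k80_distance(paste(b2, collapse = ""), s)
  expect_equal(d2r$d, d2$d)
})

test_that("gap, N, and ambiguity columns are excluded from K80 counting", {
  a <- "ACGTACGTAC"
  b <- "GCGT-CGNRC"   # col1 transition; col5 gap; col8 N; col9 ambiguity
  d <- k80_distance(a, b)
  expect_equal(d$n_sites, 7)
  expect_equal(d$P, 1 / 7)
  expect_equal(d$Q, 0)
})

test_that("K80 agrees with the ape reference implementation on random pairs", {
  set.seed(92)
  for (i in 1:20) {
    a <- rand_seq(800, 920 + i)
    b <- mutate_reference(a, runif(1, 0.01, 0.12), 950 + i)
    mine <- k80_distance(a, b)
    bin <- ape::as.DNAbin(list(x = strsplit(tolower(a), "")[[1]],
                               y = strsplit(tolower(b), "")[[1]]))
    ref <- as.numeric(ape::dist.dna(bin, model = "K80"))
    expect_equal(mine$d, ref, tolerance = 1e-10)
  }
})

test_that("K80 reduces to -1/2 ln(1-2P) when there are no transversions", {
  set.seed(93)
  for (P in c(0.02, 0.1, 0.2, 0.4)) {
    n <- 1000
    a <- strsplit(rand_seq(n, 900 + P * 100), "")[[1]]
    b <- a
    k <- n * P
    ts_map <- c(A = "G", G = "A", C = "T", T = "C")
    b[seq_len(k)] <- ts_map[a[seq_len(k)]]
    d <- k80_distance(paste(a, collapse = ""), paste(b, collapse = ""))
    expect_equal(d$d, -0.5 * log(1 - 2 * P), tolerance = 1e-10)
  }
})

test_that("saturated distances are flagged undefined and rejected by UPGMA", {
  a <- strrep("A", 100)
  b <- strrep("G", 100)   # P = 1: 1 - 2P - Q < 0
  d <- k80_distance(a, b)
  expect_false(d$defined)
  expect_true(is.na(d$d))
  D <- matrix(c(0, NA, NA, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_error(upgma(D), "undefined")
})

test_that("UPGMA reproduces hand-worked joins and is ultrametric", {
  D2 <- matrix(c(0, 0.2, 0.2, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- upgma(D2)
  expect_setequal(t2$tip.label, c("A", "B"))
  expect_equal(sort(t2$edge.length), c(0.1, 0.1))

  # 3 taxa: d(A,B)=0.1, d(A,C)=d(B,C)=0.4 -> ((A:0.05,B:0.05):0.15,C:0.2)
  D3 <- matrix(c(0, 0.1, 0.4,
                 0.1, 0, 0.4,
                 0.4, 0.4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgma(D3)
  pd <- patristic_distances(t3)
  expect_equal(pd["A", "B"], 0.1)
  expect_equal(pd["A", "C"], 0.4)
  expect_equal(pd["B", "C"], 0.4)
  # root-to-leaf heights all equal 0.2
  expect_equal(unname(ape::node.depth.edgelength(t3)[1:3]), rep(0.2, 3))

  # ultrametricity holds for random matrices
  set.seed(94)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    M <- matrix(runif(n * n, 0.05, 1), n, n)
    M <- (M + t(M)) / 2; diag(M) <- 0
    dimnames(M) <- list(paste0("t", 1:n), paste0("t", 1:n))
    tr <- upgma(M)
    depths <- ape::node.depth.edgelength(tr)[seq_len(n)]
    expect_lt(max(depths) - min(depths), 1e-9)
  }
})

test_that("UPGMA matches the definitional brute-force agglomeration oracle", {
  set.seed(95)
  for (i in 1:60) {
    n <- sample(2:5, 1)
    M <- matrix(runif(n * n, 0.05, 1), n, n)
    M <- (M + t(M)) / 2; diag(M) <- 0
    dimnames(M) <- list(paste0("t", 1:n), paste0("t", 1:n))
    tr <- upgma(M)
    oracle <- upgma_oracle_heights(M)
    got <- tree_clade_heights(tr)
    got_internal <- got[vapply(got, function(x) length(x$tips) > 1, logical(1))]
    expect_equal(length(got_internal), length(oracle))
    for (o in oracle) {
      tips_o <- sort(paste0("t", o$tips))
      match_idx <- which(vapply(got_internal, function(g)
        identical(g$tips, tips_o), logical(1)))
      expect_length(match_idx, 1)
      expect_equal(got_internal[[match_idx]]$height, o$height,
                   tolerance = 1e-9)
    }
  }
})

test_that("UPGMA on an already-ultrametric matrix reconstructs the generating tree", {
  set.seed(96)
  for (i in 1:10) {
    n <- sample(4:7, 1)
    M <- matrix(runif(n * n, 0.1, 1), n, n)
    M <- (M + t(M)) / 2; diag(M) <- 0
    dimnames(M) <- list(paste0("t", 1:n), paste0("t", 1:n))
    t1 <- upgma(M)
    P1 <- patristic_distances(t1)[paste0("t", 1:n), paste0("t", 1:n)]
    t2 <- upgma(P1)
    P2 <- patristic_distances(t2)[paste0("t", 1:n), paste0("t", 1:n)]
    expect_equal(P2, P1, tolerance = 1e-9)
  }
})

test_that("UPGMA topology agrees with the phangorn implementation", {
  skip_if_not_installed("phangorn")
  set.seed(97)
  for (i in 1:10) {
    n <- sample(4:7, 1)
    M <- matrix(runif(n * n, 0.05, 1), n, n)
    M <- (M + t(M)) / 2; diag(M) <- 0
    dimnames(M) <- list(paste0("t", 1:n), paste0("t", 1:n))
    mine <- upgma(M)
    theirs <- phangorn::upgma(as.dist(M))
    # identical patristic matrices pin down a rooted ultrametric tree
    expect_equal(patristic_distances(mine)[paste0("t", 1:n), paste0("t", 1:n)],
                 patristic_distances(theirs)[paste0("t", 1:n), paste0("t", 1:n)],
                 tolerance = 1e-9)
  }
})

test_that("MSA of identical or near-identical sequences behaves sanely", {
  a <- rand_seq(500, 98)
  m1 <- build_msa(c(x = a, y = a))
  expect_false(any(grepl("-", m1)))
  expect_identical(unname(m1["x"]), a)

  # one insertion -> a single gap column in the other rows
  b <- paste0(substr(a, 1, 250), "T", substr(a, 251, 500))
  m2 <- build_msa(c(x = a, y = b))
  expect_equal(nchar(m2[["x"]]), 501)
  expect_equal(sum(strsplit(m2[["x"]], "")[[1]] == "-"), 1)
  expect_false(grepl("-", m2[["y"]]))

  expect_error(build_msa(c(x = a)), "at least 2")
  expect_error(build_msa(c(x = a, y = "")), "length 0")
})

test_that("MSA pairwise identities match direct pairwise alignment on mini-genomes", {
  set.seed(99)
  anc <- rand_seq(2000, 990)
  seqs <- c(s1 = anc,
            s2 = mutate_reference(anc, 0.03, 991),
            s3 = mutate_reference(anc, 0.05, 992),
            s4 = mutate_reference(anc, 0.02, 993),
            s5 = mutate_reference(anc, 0.04, 994))
  msa <- build_msa(seqs)
  mat <- Biostrings::nucleotideSubstitutionMatrix(1, -2, baseOnly = TRUE)
  combs <- combn(names(seqs), 2)
  for (k in seq_len(ncol(combs))) {
    i <- combs[1, k]; j <- combs[2, k]
    x <- strsplit(msa[[i]], "")[[1]]; y <- strsplit(msa[[j]], "")[[1]]
    use <- x != "-" & y != "-"
    msa_ident <- 100 * sum(x[use] == y[use]) / sum(use)
    pa <- Biostrings::pairwiseAlignment(seqs[[i]], seqs[[j]], type = "global",
                                        substitutionMatrix = mat,
                                        gapOpening = 3, gapExtension = 1)
    ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    use2 <- ap != "-" & as_ != "-"
    pw_ident <- 100 * sum(ap[use2] == as_[use2]) / sum(use2)
    expect_lt(abs(msa_ident - pw_ident), 0.5)
  }
})

test_that("Newick output round-trips topology, lengths, and supports", {
  msa <- build_msa(setNames(mini_panel(7)$genomes$sequence,
                            mini_panel(7)$genomes$id))
  bs <- bootstrap_support(msa, n_replicates = 25, seed = 4)
  f1 <- tempfile(fileext = ".nwk"); f2 <- tempfile(fileext = ".nwk")
  write_newick(bs$tree, f1)
  t2 <- read_newick(f1)
  write_newick(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(t2$node.label, bs$tree$node.label)
  expect_equal(patristic_distances(t2)[bs$tree$tip.label, bs$tree$tip.label],
               patristic_distances(bs$tree))
})

test_that("bootstrap support is deterministic, optional, and high for distinct clades", {
  p <- mini_panel(seed = 5)
  hap <- mutate_reference(p$genomes$sequence[2], 0.002, 55)  # near-sheep leaf
  msa <- build_msa(c(setNames(p$genomes$sequence, p$genomes$id),
                     sample_x = hap))
  b0 <- bootstrap_support(msa, n_replicates = 0, seed = 1)
  expect_null(b0$support)

  b1 <- bootstrap_support(msa, n_replicates = 50, seed = 10)
  b2 <- bootstrap_support(msa, n_replicates = 50, seed = 10)
  expect_identical(b1$support, b2$support)
  expect_identical(ape::write.tree(b1$tree), ape::write.tree(b2$tree))

  # the sheep + sample clade is separated by many substitutions
  cl <- parchmentid:::tree_clades(b1$tree)
  idx <- which(vapply(cl, function(x)
    identical(sort(x), c("sample_x", "syn_sheep_mt")), logical(1)))
  expect_length(idx, 1)
  expect_gte(b1$support[idx], 95)
})

test_that("placement check identifies the nearest reference leaf's species", {
  p <- mini_panel(seed = 5)
  hap <- mutate_reference(p$genomes$sequence[2], 0.002, 56)
  msa <- build_msa(c(setNames(p$genomes$sequence, p$genomes$id),
                     consensus_1 = hap))
  tree <- upgma(k80_matrix(msa))
  expect_true(placement_check(tree, "consensus_1", "Ovis aries", p))
  expect_false(placement_check(tree, "consensus_1", "Bos taurus", p))
  expect_error(placement_check(tree, "nope", "Ovis aries", p), "not in tree")
})

test_that("patristic distances equal the brute-force path-length oracle", {
  set.seed(101)
  for (i in 1:100) {
    tr <- ape::rtree(10)
    pd <- patristic_distances(tr)
    tips <- sample(tr$tip.label, 2)
    expect_equal(pd[tips[1], tips[2]],
                 patristic_oracle(tr, tips[1], tips[2]),
                 tolerance = 1e-10)
  }
})
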