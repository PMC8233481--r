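random_leaf_seqs <- function(tips, n_sites) {
  setNames(vapply(tips, function(t)
    paste(sample(RNA, n_sites, replace = TRUE), collapse = ""), ""), tips)
}

test_that("Fitch parsimony matches hand-checked and exhaustive solutions", {
  fp <- fitch_parsimony("((a,b),(c,d));", c(a = "A", b = "A", c = "G", d = "G"))
  expect_equal(fp$score, 1)
  root <- names(fp$mpr)[1]
  expect_identical(fp$mpr[[root]], "AG")
  expect_true(fp$ambiguous[[root]])
  # unanimous leaves: no changes anywhere
  fp0 <- fitch_parsimony("((a,b),(c,d));",
                         c(a = "ACG", b = "ACG", c = "ACG", d = "ACG"))
  expect_equal(fp0$score, 0)
  expect_true(all(fp0$sequences == "ACG"))
  expect_error(fitch_parsimony("((a,b),(c,d));", c(a = "A", b = "A", c = "G")),
               "leaf")
})

test_that("Fitch score and MPR sets equal the exhaustive-labeling oracle", {
  set.seed(41)
  topologies <- c("((a,b),(c,d));", "(((a,b),c),d);", "((a,b,c),(d,e));",
                  "(a,b,c,d);", "(((a,b),(c,d)),e,f);")
  for (rep in 1:10) for (nwk in topologies) {
    phy <- ape::read.tree(text = nwk)
    seqs <- random_leaf_seqs(phy$tip.label, 5)
    fp <- fitch_parsimony(phy, seqs)
    orc <- oracle_parsimony(phy, seqs)
    expect_equal(fp$score, orc$score)
    for (j in seq_len(phy$Nnode))
      expect_identical(unname(fp$mpr[[j]]), unname(orc$mpr[j, ]))
  }
})

test_that("Fitch score is invariant under leaf order and rerooting", {
  set.seed(42)
  phy <- ape::rtree(7)
  seqs <- random_leaf_seqs(phy$tip.label, 12)
  s0 <- fitch_parsimony(phy, seqs)$score
  # permute leaves
  phy2 <- ape::rotateConstr(phy, rev(phy$tip.label))
  expect_equal(fitch_parsimony(phy2, seqs)$score, s0)
  # reroot on several edges
  for (tip in phy$tip.label[1:4]) {
    phy3 <- ape::root(ape::unroot(phy), outgroup = tip, resolve.root = TRUE)
    expect_equal(fitch_parsimony(phy3, seqs)$score, s0)
  }
})

test_that("ML marginal posteriors match the brute-force Bayes oracle (JC69)", {
  set.seed(43)
  for (rep in 1:30) {
    phy <- ape::rtree(5)
    phy$edge.length <- stats::runif(nrow(phy$edge), 0.01, 0.6)
    seqs <- random_leaf_seqs(phy$tip.label, 5)
    ml <- ml_marginal_reconstruction(phy, seqs, model = "JC69")
    for (s in 1:5) {
      st <- setNames(vapply(seqs, function(x) substr(x, s, s), ""),
                     names(seqs))
      orc <- oracle_ml_posterior_site(phy, st, jc69_p)
      for (j in seq_len(phy$Nnode))
        expect_equal(unname(ml$posterior[[j]][, s]), orc[, j],
                     tolerance = 1e-8)
    }
  }
})

test_that("ML marginal posteriors match the oracle under TN93", {
  set.seed(44)
  phy <- ape::rtree(5)
  phy$edge.length <- stats::runif(nrow(phy$edge), 0.05, 0.4)
  seqs <- random_leaf_seqs(phy$tip.label, 6)
  pi <- c(0.35, 0.15, 0.3, 0.2)
  ml <- ml_marginal_reconstruction(phy, seqs, model = "TN93",
                                   base_freqs = pi, kappa1 = 3, kappa2 = 1.5)
  # independent TN93 propagator via series matrix exponential
  R <- matrix(1, 4, 4); R[1, 3] <- R[3, 1] <- 3; R[2, 4] <- R[4, 2] <- 1.5
  Q <- R * rep(pi, each = 4); diag(Q) <- 0; diag(Q) <- -rowSums(Q)
  Q <- Q / sum(-diag(Q) * pi)
  tn_p <- function(t) as.matrix(Matrix::expm(Q * t))
  for (s in 1:6) {
    st <- setNames(vapply(seqs, function(x) substr(x, s, s), ""), names(seqs))
    orc <- oracle_ml_posterior_site(phy, st, tn_p, pi = pi)
    for (j in seq_len(phy$Nnode))
      expect_equal(unname(ml$posterior[[j]][, s]), orc[, j], tolerance = 1e-7)
  }
})

test_that("ML reconstruction degenerate and invariance properties hold", {
  # two identical leaves: argmax at the shared state
  ml <- ml_marginal_reconstruction("(a:0.1,b:0.2);", c(a = "A", b = "A"),
                                   model = "JC69")
  expect_identical(ml$sequences[[1]], "A")
  # posteriors sum to one everywhere
  set.seed(45)
  phy <- ape::rtree(6)
  seqs <- random_leaf_seqs(phy$tip.label, 8)
  ml <- ml_marginal_reconstruction(phy, seqs)
  for (p in ml$posterior)
    expect_equal(unname(colSums(p)), rep(1, ncol(p)), tolerance = 1e-9)
  # star tree, unanimous leaves, vanishing branch lengths: posterior -> 1
  star <- ape::read.tree(text = "(a:1e-7,b:1e-7,c:1e-7,d:1e-7);")
  mls <- ml_marginal_reconstruction(star, c(a = "C", b = "C", c = "C", d = "C"),
                                    model = "JC69")
  expect_gt(mls$posterior[[1]]["C", 1], 0.9999)
  # root log-likelihood is invariant under rerooting (reversible model)
  phy$edge.length <- stats::runif(nrow(phy$edge), 0.05, 0.3)
  l0 <- ml_marginal_reconstruction(phy, seqs, model = "JC69")$loglik
  for (tip in phy$tip.label[1:3]) {
    phy2 <- ape::root(ape::unroot(phy), outgroup = tip, resolve.root = TRUE)
    l1 <- ml_marginal_reconstruction(phy2, seqs, model = "JC69")$loglik
    expect_equal(l1, l0, tolerance = 1e-8)
  }
  expect_error(ml_marginal_reconstruction("(a:-0.1,b:0.1);",
                                          c(a = "A", b = "C")), "negative")
})

test_that("parsimony and ML agree and recover truth on low-divergence trees", {
  sc <- default_scheme()
  agree <- logical(20)
  recover <- numeric(20)
  # basal trifurcation: a binary root's orientation is unidentifiable by
  # both methods (no outgroup), so the fixture uses unrooted-style trees
  for (r in 1:20) {
    set.seed(100 + r)
    phy <- ape::unroot(ape::rtree(8))
    phy$edge.length <- phy$edge.length / sum(phy$edge.length) * 0.05
    sim <- simulate_tree_sequences(phy, sc$backbone, seed = 200 + r)
    fp <- fitch_parsimony(sim$tree, sim$leaf_sequences)
    ml <- ml_marginal_reconstruction(sim$tree, sim$leaf_sequences)
    cmp <- compare_reconstructions(fp, ml)
    agree[r] <- cmp$agreement == 1
    truth <- sim$node_sequences[names(ml$sequences)]
    recover[r] <- mean(unlist(strsplit(ml$sequences, "")) ==
                         unlist(strsplit(truth, "")))
  }
  expect_gte(mean(agree), 0.95)
  expect_gte(mean(recover), 0.99)
})

test_that("reconstruction comparison reports disagreements and guards trees", {
  fp <- fitch_parsimony("((a,b),(c,d));", c(a = "A", b = "A", c = "G", d = "G"))
  cmp <- compare_reconstructions(fp, fp)
  expect_equal(cmp$agreement, 1.0)
  expect_equal(nrow(cmp$disagreements), 0L)
  fp2 <- fitch_parsimony("((a,b),(c,e));", c(a = "A", b = "A", c = "G", e = "G"))
  expect_error(compare_reconstructions(fp, fp2), "same tree")
})

test_that("node activities follow the measured / rule_G1 / rule_L4 precedence", {
  sc <- default_scheme()
  anc <- ancestral_genotype(sc)
  tbl <- data.frame(genotype = anc, mean_fraction = 0.92)
  bb <- sc$backbone
  # sequences: ancestral (measured), off-scheme G1A, off-scheme L4-only,
  # and a sequence with an off-scheme change elsewhere (external)
  s_g1 <- bb; substr(s_g1, 1, 1) <- "A"; substr(s_g1, 2, 2) <- "C"
  l4pos <- sc$positions$index[sc$positions$element == "L4"][1]
  s_l4 <- bb
  substr(s_l4, l4pos, l4pos) <-
    setdiff(c("A", "C", "G", "U"),
            c(substr(bb, l4pos, l4pos),
              sc$positions$alleles[[which(sc$positions$index == l4pos)]]))[1]
  s_ext <- bb; substr(s_ext, 3, 3) <- "U"
  seqs <- c(a = bb, b = s_g1, c = s_l4, d = s_ext)
  na <- assign_node_activity("((a,b),(c,d));", seqs, tbl, sc)
  a <- function(node) na[na$node == node, ]
  expect_identical(a("a")$source, "measured")
  expect_equal(a("a")$activity, 0.92)
  expect_identical(a("b")$source, "rule_G1")
  expect_equal(a("b")$activity, 0.05)
  expect_identical(a("b")$class, "low")
  expect_identical(a("c")$source, "rule_L4")
  expect_equal(a("c")$activity, 0.92)
  expect_identical(a("d")$source, "external")
  expect_true(is.na(a("d")$activity))
  # internal nodes without sequences are external, never guessed
  expect_true(all(na$source[!na$node %in% names(seqs)] == "external"))
  # measured precedence beats the G1 rule for in-library G1 mutants
  g1a <- anc; substr(g1a, 1, 1) <- "A"
  tbl2 <- rbind(tbl, data.frame(genotype = g1a, mean_fraction = 0.031))
  na2 <- assign_node_activity("(a,b);",
                              c(a = bb, b = genotype_to_sequence(sc, g1a)),
                              tbl2, sc)
  expect_identical(na2$source[na2$node == "b"], "measured")
  expect_equal(na2$activity[na2$node == "b"], 0.031)
})

test_that("ancestral states and assignments export to TSV", {
  sim <- simulate_tree_sequences("((a:0.05,b:0.05):0.02,(c:0.05,d:0.05):0.02);",
                                 default_scheme()$backbone, seed = 31)
  fp <- fitch_parsimony(sim$tree, sim$leaf_sequences)
  ml <- ml_marginal_reconstruction(sim$tree, sim$leaf_sequences)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ancestral_tsv(fp, f, ml = ml)
  df <- utils::read.delim(f)
  expect_equal(nrow(df), 3 * 67)
  expect_true(all(c("parsimony_set", "ml_state", "ml_posterior_max") %in%
                    names(df)))
  expect_true(all(df$ml_posterior_max > 0.25 - 1e-9 &
                    df$ml_posterior_max <= 1 + 1e-9))
})
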