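#' Fitch (Hartigan) parsimony ancestral reconstruction
#'
#' Infers per-site most-parsimonious ancestral state sets on a rooted tree
#' by the Hartigan generalization of the Fitch algorithm, which handles
#' multifurcating nodes natively. The downpass computes, per node and site,
#' the set of states attaining the minimum number of changes below that
#' node; the uppass refines these into the full most-parsimonious
#' reconstruction (MPR) sets. The reported single sequence per node takes
#' the alphabetically first member of each MPR set, with a per-site
#' ambiguity flag wherever the set has more than one member.
#'
#' @param tree A \code{"phylo"} object, Newick string or file (branch
#'   lengths ignored). Internal nodes without labels are auto-named.
#' @param leaf_sequences Named character vector of equal-length sequences;
#'   names must cover every tip label.
#' @return An \code{"ancestral_states"} object (method "fitch"): list with
#'   \code{tree}, \code{mpr} (per internal node, a character vector of
#'   per-site state sets such as \code{"AG"}), \code{sequences} (chosen
#'   sequence per internal node), \code{ambiguous} (per-node logical
#'   matrix rows), and \code{score} (total parsimony length).
#' @export
fitch_parsimony <- function(tree, leaf_sequences) {
  phy <- prep_tree(tree, leaf_sequences)
  leaf_sequences <- normalize_rna(leaf_sequences[phy$tip.label])
  S <- nchar(leaf_sequences[1])
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  root <- ntip + 1L

  # state sets as bitmasks over A,C,G,U
  bit <- c(A = 1L, C = 2L, G = 4L, U = 8L)
  leaf_masks <- lapply(leaf_sequences, function(s) unname(bit[seq_chars(s)]))
  VU <- VL <- vector("list", nnode)
  for (i in seq_len(ntip)) VU[[i]] <- leaf_masks[[i]]

  children <- children_list(phy)
  score <- integer(S)
  po <- postorder_nodes(phy)
  for (v in po) {
    kids <- children[[v]]
    # per-state child votes, vectorized over sites
    k <- matrix(0L, 4L, S)
    for (c in kids) {
      m <- VU[[c]]
      for (b in 1:4) k[b, ] <- k[b, ] + bitwAnd(m, bitwShiftL(1L, b - 1L)) %/%
          bitwShiftL(1L, b - 1L)
    }
    K <- apply(k, 2L, max)
    vu <- vl <- integer(S)
    for (b in 1:4) {
      pw <- bitwShiftL(1L, b - 1L)
      vu <- vu + pw * (k[b, ] == K)
      vl <- vl + pw * (k[b, ] == K - 1L)
    }
    VU[[v]] <- vu
    VL[[v]] <- vl
    score <- score + (length(kids) - K)
  }

  # Hartigan uppass: MPR sets
  MPR <- vector("list", nnode)
  MPR[[root]] <- VU[[root]]
  for (v in rev(po)) {
    for (c in children[[v]]) {
      if (c <= ntip) next
      M <- MPR[[v]]
      inVU <- bitwAnd(M, VU[[c]])
      MPR[[c]] <- ifelse(inVU == M, M,
                         bitwOr(VU[[c]], bitwAnd(M, VL[[c]])))
    }
  }

  internal <- root:nnode
  mask_to_set <- function(m) {
    vapply(m, function(x) paste(names(bit)[bitwAnd(x, bit) > 0L],
                                collapse = ""), "")
  }
  mpr_sets <- lapply(MPR[internal], mask_to_set)
  names(mpr_sets) <- phy$node.label
  sequences <- vapply(mpr_sets, function(s) paste(substr(s, 1L, 1L),
                                                  collapse = ""), "")
  ambiguous <- lapply(mpr_sets, function(s) nchar(s) > 1L)
  structure(list(method = "fitch", tree = phy, mpr = mpr_sets,
                 sequences = sequences, ambiguous = ambiguous,
                 score = sum(score), site_scores = score),
            class = "ancestral_states")
}

#' Marginal maximum-likelihood ancestral reconstruction
#'
#' Computes per-site marginal posterior distributions over \{A,C,G,U\} at
#' every internal node under JC69 or the Tamura-Nei (TN93) substitution
#' model with uniform rates across sites, by the pruning (Felsenstein)
#' recursion combined with an outside pass — equivalent to re-rooting at
#' each node. The chosen state per site is the posterior argmax
#' (alphabetical tie-break).
#'
#' @inheritParams fitch_parsimony
#' @param model \code{"TN93"} (default) or \code{"JC69"}.
#' @param base_freqs Stationary base frequencies (A, C, G, U). Default:
#'   empirical frequencies of the leaf sequences (TN93) or uniform (JC69).
#' @param kappa1,kappa2 Purine (A<->G) and pyrimidine (C<->U) transition /
#'   transversion rate ratios for TN93 (default 2, the value used when no
#'   estimate is supplied).
#' @return An \code{"ancestral_states"} object (method "ml"): list with
#'   \code{tree}, \code{posterior} (per internal node a 4 x sites matrix),
#'   \code{sequences}, \code{max_posterior} (per internal node, vector of
#'   per-site posterior maxima), \code{loglik}, \code{model} and
#'   \code{params}.
#' @export
ml_marginal_reconstruction <- function(tree, leaf_sequences,
                                       model = c("TN93", "JC69"),
                                       base_freqs = NULL,
                                       kappa1 = 2, kappa2 = 2) {
  model <- match.arg(model)
  phy <- prep_tree(tree, leaf_sequences)
  if (is.null(phy$edge.length)) stop("branch lengths required for ML")
  if (any(phy$edge.length < 0)) stop("negative branch length")
  leaf_sequences <- normalize_rna(leaf_sequences[phy$tip.label])
  S <- nchar(leaf_sequences[1])
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  root <- ntip + 1L

  if (is.null(base_freqs)) {
    base_freqs <- if (model == "JC69") rep(0.25, 4) else {
      tab <- table(factor(unlist(strsplit(leaf_sequences, "")),
                          levels = RNA_BASES))
      f <- (as.numeric(tab) + 1) / (sum(tab) + 4)  # pseudocount guard
      f / sum(f)
    }
  }
  stopifnot(length(base_freqs) == 4, all(base_freqs > 0))
  base_freqs <- base_freqs / sum(base_freqs)
  Qd <- substitution_model(model, base_freqs, kappa1, kappa2)

  children <- children_list(phy)
  parent_of <- integer(nnode)
  edge_len_of <- numeric(nnode)
  parent_of[phy$edge[, 2]] <- phy$edge[, 1]
  edge_len_of[phy$edge[, 2]] <- phy$edge.length
  Pmat <- vector("list", nnode)  # transition matrix along the edge above node
  for (v in seq_len(nnode)) if (v != root)
    Pmat[[v]] <- trans_prob(Qd, edge_len_of[v])

  # inside (pruning) pass
  Lk <- vector("list", nnode)
  Msg <- vector("list", nnode)  # message from node to its parent
  logscale <- 0
  for (i in seq_len(ntip)) {
    m <- matrix(0, 4L, S, dimnames = list(RNA_BASES, NULL))
    m[cbind(match(seq_chars(leaf_sequences[i]), RNA_BASES), seq_len(S))] <- 1
    Lk[[i]] <- m
    Msg[[i]] <- Pmat[[i]] %*% m
  }
  po <- postorder_nodes(phy)
  for (v in po) {
    m <- matrix(1, 4L, S)
    for (c in children[[v]]) m <- m * Msg[[c]]
    sc <- apply(m, 2L, max)
    sc[sc == 0] <- 1
    m <- sweep(m, 2L, sc, "/")
    logscale <- logscale + sum(log(sc))
    Lk[[v]] <- m
    if (v != root) Msg[[v]] <- Pmat[[v]] %*% m
  }
  site_lik <- colSums(base_freqs * Lk[[root]])
  loglik <- sum(log(site_lik)) + logscale

  # outside pass (equivalent to re-rooting at every node)
  Out <- vector("list", nnode)
  Out[[root]] <- matrix(base_freqs, 4L, S)
  for (v in rev(po)) {
    kids <- children[[v]]
    for (c in kids) {
      if (c <= ntip) next
      s <- Out[[v]]
      for (b in kids) if (b != c) s <- s * Msg[[b]]
      o <- crossprod(Pmat[[c]], s)  # t(P) %*% s
      sc <- apply(o, 2L, max); sc[sc == 0] <- 1
      Out[[c]] <- sweep(o, 2L, sc, "/")
    }
  }

  internal <- root:nnode
  posterior <- vector("list", length(internal))
  for (j in seq_along(internal)) {
    v <- internal[j]
    post <- Out[[v]] * Lk[[v]]
    posterior[[j]] <- sweep(post, 2L, colSums(post), "/")
    rownames(posterior[[j]]) <- RNA_BASES
  }
  names(posterior) <- phy$node.label
  sequences <- vapply(posterior, function(p)
    paste(RNA_BASES[apply(p, 2L, which.max)], collapse = ""), "")
  max_posterior <- lapply(posterior, function(p) apply(p, 2L, max))
  structure(list(method = "ml", tree = phy, posterior = posterior,
                 sequences = sequences, max_posterior = max_posterior,
                 loglik = loglik, model = model,
                 params = list(base_freqs = base_freqs,
                               kappa1 = kappa1, kappa2 = kappa2)),
            class = "ancestral_states")
}

#' @export
print.ancestral_states <- function(x, ...) {
  cat("Ancestral reconstruction (", x$method, "): ",
      length(x$sequences), " internal nodes, ",
      nchar(x$sequences[1]), " sites\n", sep = "")
  if (x$method == "fitch") {
    cat("Parsimony score:", x$score, "\n")
    namb <- sum(vapply(x$ambiguous, sum, 0L))
    cat("Ambiguous node-sites:", namb, "\n")
  } else {
    cat("Model:", x$model, " log-likelihood:", format(x$loglik), "\n")
    cat(sprintf("Min per-site posterior of chosen states: %.4f\n",
                min(unlist(x$max_posterior))))
  }
  invisible(x)
}

#' Compare parsimony and ML reconstructions
#'
#' Site-by-site comparison of the chosen sequences at every internal node
#' shared by two reconstructions of the same tree.
#'
#' @param x,y Two \code{"ancestral_states"} objects on the same tree
#'   (typically one "fitch", one "ml").
#' @return List with \code{agreement} (fraction of agreeing node-sites),
#'   \code{per_node} (data.frame node, n_sites, n_agree) and
#'   \code{disagreements} (data.frame node, site, state_x, state_y).
#' @export
compare_reconstructions <- function(x, y) {
  stopifnot(inherits(x, "ancestral_states"), inherits(y, "ancestral_states"))
  if (!identical(sort(names(x$sequences)), sort(names(y$sequences))) ||
      !identical(sort(x$tree$tip.label), sort(y$tree$tip.label)))
    stop("reconstructions are not on the same tree")
  nodes <- names(x$sequences)
  per_node <- data.frame(node = nodes, n_sites = NA_integer_,
                         n_agree = NA_integer_, stringsAsFactors = FALSE)
  dis <- list()
  for (i in seq_along(nodes)) {
    a <- seq_chars(x$sequences[[nodes[i]]])
    b <- seq_chars(y$sequences[[nodes[i]]])
    per_node$n_sites[i] <- length(a)
    per_node$n_agree[i] <- sum(a == b)
    d <- which(a != b)
    if (length(d))
      dis[[length(dis) + 1L]] <- data.frame(node = nodes[i], site = d,
                                            state_x = a[d], state_y = b[d])
  }
  disagreements <- if (length(dis)) do.call(rbind, dis) else
    data.frame(node = character(0), site = integer(0),
               state_x = character(0), state_y = character(0))
  list(agreement = sum(per_node$n_agree) / sum(per_node$n_sites),
       per_node = per_node, disagreements = disagreements)
}

#' Assign an activity to every tree node
#'
#' Applies the three-source precedence rule used to put an activity on each
#' node of the species tree: (1) \emph{measured} — the node's sequence maps
#' into the combinatorial library and its genotype has a measured mean
#' fraction cleaved; (2) \emph{rule_G1} — the sequence carries a
#' non-reference base at the G1 position, predicting very low activity
#' (numeric stand-in 0.05); (3) \emph{rule_L4} — the sequence differs from
#' the ancestral backbone only at L4-element positions, predicting high,
#' ancestral-like activity (numeric stand-in: the ancestral genotype's
#' measured value); (4) \emph{external} — none of the above (e.g.
#' gel-assayed, length-variant sequences): flagged with \code{NA} activity
#' for a user-supplied value, never guessed.
#'
#' @param tree A \code{"phylo"}, Newick string or file.
#' @param node_sequences Named character vector of sequences for tree nodes
#'   (leaves and/or internal); nodes without a sequence are reported as
#'   external with reason "no_sequence".
#' @param activity_table An \code{"activity_table"} (or data.frame with
#'   \code{genotype} and \code{mean_fraction}).
#' @param scheme A \code{"variant_scheme"}.
#' @param rules List with \code{low_value} (numeric stand-in for rule_G1
#'   nodes, default 0.05) and optionally \code{high_value} (stand-in for
#'   rule_L4 nodes; default: the ancestral genotype's measured value).
#' @return A \code{"node_activity"} data.frame: \code{node},
#'   \code{activity}, \code{class} ("low", "high" or \code{NA}),
#'   \code{source} ("measured", "rule_G1", "rule_L4", "external").
#' @export
assign_node_activity <- function(tree, node_sequences, activity_table,
                                 scheme, rules = list(low_value = 0.05)) {
  phy <- as_phylo_tree(tree)
  if (is.null(phy$node.label) || !length(phy$node.label))
    phy$node.label <- paste0("Node", seq_len(phy$Nnode))
  all_nodes <- c(phy$tip.label, phy$node.label)
  act <- stats::setNames(activity_table$mean_fraction, activity_table$genotype)
  low_value <- if (is.null(rules$low_value)) 0.05 else rules$low_value
  anc <- ancestral_genotype(scheme)
  high_value <- if (!is.null(rules$high_value)) rules$high_value else
    unname(act[anc])
  bb <- seq_chars(scheme$backbone)
  l4 <- l4_indices(scheme)

  n <- length(all_nodes)
  out <- data.frame(node = all_nodes, activity = NA_real_,
                    class = NA_character_, source = "external",
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    s <- node_sequences[all_nodes[i]]
    if (is.na(s)) next
    s <- normalize_rna(s)
    if (nchar(s) != length(bb)) next  # length variant: external
    g <- tryCatch(sequence_to_genotype(scheme, s), error = function(e) NULL)
    if (!is.null(g) && !is.na(act[g])) {
      out$activity[i] <- unname(act[g])
      out$source[i] <- "measured"
      next
    }
    ch <- seq_chars(s)
    if (ch[1] != bb[1]) {             # any non-reference base at G1
      out$activity[i] <- low_value
      out$class[i] <- "low"
      out$source[i] <- "rule_G1"
      next
    }
    d <- which(ch != bb)
    if (length(d) && all(d %in% l4)) {
      out$activity[i] <- high_value
      out$class[i] <- "high"
      out$source[i] <- "rule_L4"
    }
  }
  class(out) <- c("node_activity", "data.frame")
  out
}

#' Write ancestral states or node assignments as TSV
#'
#' For a reconstruction, one row per (node, site) with the parsimony MPR
#' set and/or ML state and posterior; for a \code{"node_activity"}, the
#' assignment table as-is.
#'
#' @param x An \code{"ancestral_states"} or \code{"node_activity"}.
#' @param path File path.
#' @param ml Optional second \code{"ancestral_states"} (method "ml") to
#'   merge alongside a parsimony \code{x}.
#' @return \code{path}, invisibly.
#' @export
write_ancestral_tsv <- function(x, path, ml = NULL) {
  if (inherits(x, "node_activity")) {
    utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  stopifnot(inherits(x, "ancestral_states"))
  nodes <- names(x$sequences)
  S <- nchar(x$sequences[1])
  df <- data.frame(node = rep(nodes, each = S),
                   site = rep(seq_len(S), length(nodes)))
  if (x$method == "fitch") {
    df$parsimony_set <- unlist(x$mpr, use.names = FALSE)
    df$parsimony_state <- substr(df$parsimony_set, 1L, 1L)
  } else {
    ml <- x
  }
  if (!is.null(ml)) {
    stopifnot(ml$method == "ml")
    df$ml_state <- unlist(lapply(ml$sequences[nodes], seq_chars),
                          use.names = FALSE)
    df$ml_posterior_max <- unlist(ml$max_posterior[nodes], use.names = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- internal: models and traversal ---------------------------------------

# rate matrix eigendecomposition for a reversible model; order A,C,G,U
substitution_model <- function(model, pi, kappa1 = 2, kappa2 = 2) {
  R <- matrix(1, 4, 4)  # exchangeability; transversions = 1
  if (model == "TN93") {
    R[1, 3] <- R[3, 1] <- kappa1  # A<->G
    R[2, 4] <- R[4, 2] <- kappa2  # C<->U
  }
  Q <- R * rep(pi, each = 4)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(-diag(Q) * pi)  # 1 expected substitution per unit time
  d <- sqrt(pi)
  B <- diag(d) %*% Q %*% diag(1 / d)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  list(values = eig$values,
       right = diag(1 / d) %*% eig$vectors,
       left = t(eig$vectors) %*% diag(d),
       pi = pi)
}

trans_prob <- function(Qd, t) {
  P <- Qd$right %*% (exp(Qd$values * t) * Qd$left)
  P[P < 0] <- 0
  P / rowSums(P)
}

prep_tree <- function(tree, leaf_sequences) {
  phy <- as_phylo_tree(tree)
  if (is.null(phy$node.label) || !length(phy$node.label) ||
      any(is.na(phy$node.label)) || any(phy$node.label == ""))
    phy$node.label <- paste0("Node", seq_len(phy$Nnode))
  missing <- setdiff(phy$tip.label, names(leaf_sequences))
  if (length(missing))
    stop("no sequence for leaf: ", paste(missing, collapse = ", "))
  lens <- nchar(leaf_sequences[phy$tip.label])
  if (length(unique(lens)) != 1L)
    stop("leaf sequences must all have the same length")
  phy
}

children_list <- function(phy) {
  nnode <- length(phy$tip.label) + phy$Nnode
  ch <- vector("list", nnode)
  for (e in seq_len(nrow(phy$edge)))
    ch[[phy$edge[e, 1L]]] <- c(ch[[phy$edge[e, 1L]]], phy$edge[e, 2L])
  ch
}

# internal nodes, children before parents
postorder_nodes <- function(phy) {
  unique(ape::reorder.phylo(phy, "postorder")$edge[, 1L])
}
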