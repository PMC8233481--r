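#' Simulate sequence evolution along a tree
#'
#' Evolves a root sequence down a rooted tree with branch lengths in
#' expected substitutions per site, recording the true sequence at every
#' node. Substitution events on a branch of length b are Poisson with mean
#' \code{rate * b * n_sites}; each event picks an eligible site uniformly
#' and replaces its base with a uniform draw from the alternatives
#' (Jukes-Cantor-like). With \code{restrict_to_scheme}, only the scheme's
#' variable positions are eligible and replacement alleles are drawn from
#' each position's allowed set, so every leaf stays inside the combinatorial
#' library.
#'
#' @param tree An \pkg{ape} \code{"phylo"} object, a Newick string, or a
#'   path to a Newick file. Branch lengths required, non-negative.
#'   Internal nodes without labels are auto-named \code{Node1, Node2, ...}.
#' @param root_sequence Root nucleotide string (e.g. the scheme backbone).
#' @param rate Rate multiplier on branch lengths (default 1: branch lengths
#'   are used as expected substitutions/site directly).
#' @param seed Integer seed.
#' @param restrict_to_scheme If \code{TRUE}, substitutions are confined to
#'   scheme positions/alleles; requires \code{scheme}.
#' @param scheme A \code{"variant_scheme"} (only used when
#'   \code{restrict_to_scheme = TRUE}).
#' @return A \code{"sim_tree"}: list with \code{tree} (phylo, node labels
#'   filled in), \code{leaf_sequences} (named character),
#'   \code{node_sequences} (named character, internal nodes incl. root) and
#'   \code{n_events} (total substitution events drawn).
#' @export
simulate_tree_sequences <- function(tree, root_sequence, rate = 1,
                                    seed = 1L, restrict_to_scheme = FALSE,
                                    scheme = NULL) {
  phy <- as_phylo_tree(tree)
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (any(phy$edge.length < 0)) stop("negative branch length")
  if (is.null(phy$node.label) || !length(phy$node.label) ||
      any(is.na(phy$node.label)) || any(phy$node.label == ""))
    phy$node.label <- paste0("Node", seq_len(phy$Nnode))
  root_sequence <- normalize_rna(root_sequence)
  rootc <- seq_chars(root_sequence)

  if (restrict_to_scheme) {
    stopifnot(inherits(scheme, "variant_scheme"))
    eligible <- scheme$positions$index
    allowed <- scheme$positions$alleles
  } else {
    eligible <- seq_along(rootc)
    allowed <- NULL
  }

  set.seed(as.integer(seed))
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  seqs <- vector("list", nnode)
  root_id <- ntip + 1L
  seqs[[root_id]] <- rootc
  n_events <- 0L
  # preorder: parents before children
  edges <- ape::reorder.phylo(phy, "cladewise")$edge
  edge_len <- ape::reorder.phylo(phy, "cladewise")$edge.length
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1L]; child <- edges[e, 2L]
    s <- seqs[[par]]
    k <- stats::rpois(1L, rate * edge_len[e] * length(eligible))
    n_events <- n_events + k
    if (k > 0) {
      sites <- sample(seq_along(eligible), k, replace = TRUE)
      for (m in sites) {
        idx <- eligible[m]
        alt <- if (is.null(allowed)) setdiff(RNA_BASES, s[idx])
               else setdiff(allowed[[m]], s[idx])
        s[idx] <- sample(alt, 1L)
      }
    }
    seqs[[child]] <- s
  }
  collapse <- function(i) paste(seqs[[i]], collapse = "")
  leaf_sequences <- stats::setNames(vapply(seq_len(ntip), collapse, ""),
                                    phy$tip.label)
  node_sequences <- stats::setNames(
    vapply(root_id:nnode, collapse, ""), phy$node.label)
  structure(list(tree = phy, leaf_sequences = leaf_sequences,
                 node_sequences = node_sequences, n_events = n_events),
            class = "sim_tree")
}

#' @export
print.sim_tree <- function(x, ...) {
  cat("Simulated tree:", length(x$leaf_sequences), "leaves,",
      length(x$node_sequences), "internal nodes,",
      nchar(x$leaf_sequences[1]), "sites,",
      x$n_events, "substitution events\n")
  invisible(x)
}

#' Write a simulated tree's outputs
#'
#' Writes the tree as Newick, leaf sequences as FASTA (ids equal to leaf
#' labels) and the true node sequences as TSV.
#'
#' @param sim A \code{"sim_tree"}.
#' @param newick,fasta,truth_tsv Output paths (NULL to skip any).
#' @return Invisibly, the paths written.
#' @export
write_sim_tree <- function(sim, newick = NULL, fasta = NULL, truth_tsv = NULL) {
  stopifnot(inherits(sim, "sim_tree"))
  if (!is.null(newick)) ape::write.tree(sim$tree, newick)
  if (!is.null(fasta)) {
    x <- Biostrings::BStringSet(sim$leaf_sequences)
    Biostrings::writeXStringSet(x, fasta, format = "fasta")
  }
  if (!is.null(truth_tsv)) {
    df <- data.frame(node = names(sim$node_sequences),
                     sequence = unname(sim$node_sequences))
    utils::write.table(df, truth_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(newick = newick, fasta = fasta, truth_tsv = truth_tsv))
}

## ---- internal -------------------------------------------------------------

# accept phylo | newick string | file path
as_phylo_tree <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  stopifnot(is.character(tree), length(tree) == 1L)
  phy <- if (grepl("\\(", tree)) {
    tryCatch(suppressWarnings(ape::read.tree(text = tree)),
             error = function(e) stop("malformed Newick: ", conditionMessage(e)))
  } else {
    ape::read.tree(tree)
  }
  if (is.null(phy)) stop("malformed Newick: could not parse tree")
  phy
}
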