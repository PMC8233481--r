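# Fixtures and independent brute-force oracles used across the suite.

RNA <- c("A", "C", "G", "U")

# small random scheme: positions at odd backbone indices, allele sizes given
toy_scheme <- function(allele_sizes, seed = 1) {
  set.seed(seed)
  n <- length(allele_sizes)
  idx <- seq(1L, by = 2L, length.out = n)
  backbone <- paste(sample(RNA, max(idx) + 3L, replace = TRUE), collapse = "")
  ref <- strsplit(backbone, "")[[1]][idx]
  alleles <- vapply(seq_len(n), function(i) {
    extra <- sample(setdiff(RNA, ref[i]), allele_sizes[i] - 1L)
    paste(c(ref[i], extra), collapse = ",")
  }, "")
  variant_scheme(backbone, data.frame(index = idx, alleles = alleles))
}

# default-style rules with the scheme-specific position names dropped, for
# toy schemes that lack the packaged C9/G30/U36 labels
toy_landscape <- function(scheme, ...) {
  generate_truth_landscape(
    scheme,
    default_landscape_rules(mild_names = character(0),
                            wobble_name = character(0), ...))
}

random_genotype <- function(scheme) {
  paste(vapply(scheme$positions$alleles, sample, "", size = 1L), collapse = "")
}

# ---- parsimony oracle: exhaustive minimization over internal labelings ----

# per single site; returns min score and the set of states each internal
# node takes across all minimum-score labelings
oracle_parsimony_site <- function(phy, leaf_states) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  leaf <- match(leaf_states[phy$tip.label], RNA)
  combos <- as.matrix(expand.grid(rep(list(1:4), nnode)))
  cost <- numeric(nrow(combos))
  state_of <- function(node, combos) {
    if (node <= ntip) rep(leaf[node], nrow(combos)) else combos[, node - ntip]
  }
  for (e in seq_len(nrow(phy$edge))) {
    ps <- state_of(phy$edge[e, 1], combos)
    cs <- state_of(phy$edge[e, 2], combos)
    cost <- cost + (ps != cs)
  }
  best <- min(cost)
  opt <- combos[cost == best, , drop = FALSE]
  sets <- lapply(seq_len(nnode), function(j)
    paste(RNA[sort(unique(opt[, j]))], collapse = ""))
  list(score = best, mpr = unlist(sets))  # order: node ntip+1, ntip+2, ...
}

oracle_parsimony <- function(phy, leaf_sequences) {
  S <- nchar(leaf_sequences[1])
  chars <- lapply(leaf_sequences, function(s) strsplit(s, "")[[1]])
  score <- 0
  mpr <- matrix("", phy$Nnode, S)
  for (s in seq_len(S)) {
    st <- vapply(chars, `[`, "", s)
    r <- oracle_parsimony_site(phy, st)
    score <- score + r$score
    mpr[, s] <- r$mpr
  }
  list(score = score, mpr = mpr)
}

# ---- ML oracle: Bayes posterior by exhaustive labeling enumeration --------

# closed-form JC69 transition probability, independent of the package's
# eigendecomposition route
jc69_p <- function(t) {
  same <- 0.25 + 0.75 * exp(-4 * t / 3)
  diff <- 0.25 - 0.25 * exp(-4 * t / 3)
  m <- matrix(diff, 4, 4)
  diag(m) <- same
  m
}

# Pfun(t) -> 4x4 transition matrix; pi = root frequencies
oracle_ml_posterior_site <- function(phy, leaf_states, Pfun, pi = rep(0.25, 4)) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  leaf <- match(leaf_states[phy$tip.label], RNA)
  combos <- as.matrix(expand.grid(rep(list(1:4), nnode)))
  P <- lapply(phy$edge.length, Pfun)
  w <- pi[combos[, 1]]  # root is node ntip+1, first internal column
  state_of <- function(node) {
    if (node <= ntip) rep(leaf[node], nrow(combos)) else combos[, node - ntip]
  }
  for (e in seq_len(nrow(phy$edge))) {
    ps <- state_of(phy$edge[e, 1])
    cs <- state_of(phy$edge[e, 2])
    w <- w * P[[e]][cbind(ps, cs)]
  }
  post <- matrix(0, 4, nnode)
  for (j in seq_len(nnode)) for (s in 1:4)
    post[s, j] <- sum(w[combos[, j] == s])
  sweep(post, 2, colSums(post), "/")
}

# ---- naive read-scan oracle (exact string matching) -----------------------

oracle_read_counts <- function(reads, scheme) {
  key <- list()
  unassigned <- 0L
  for (i in seq_len(nrow(reads))) {
    s <- reads$sequence[i]
    hits <- gregexpr(scheme$primer_site, s, fixed = TRUE)[[1]]
    if (hits[1] == -1) { unassigned <- unassigned + 1L; next }
    p <- hits[length(hits)]
    rstart <- p - nchar(scheme$backbone)
    if (rstart < 1) { unassigned <- unassigned + 1L; next }
    ribo <- substr(s, rstart, p - 1L)
    lead <- substr(s, rstart - 9L, rstart - 1L)
    if (rstart > 9L && lead == scheme$leader) {
      state <- "uncleaved"; prefix <- rstart - 10L
    } else {
      state <- "cleaved"; prefix <- rstart - 1L
    }
    if (prefix > 18L) { unassigned <- unassigned + 1L; next }
    g <- paste(strsplit(ribo, "")[[1]][scheme$positions$index], collapse = "")
    ok <- all(mapply(function(a, set) a %in% set, strsplit(g, "")[[1]],
                     scheme$positions$alleles))
    if (!ok) { unassigned <- unassigned + 1L; next }
    k <- paste(g, reads$replicate[i], state, sep = "|")
    key[[k]] <- (if (is.null(key[[k]])) 0L else key[[k]]) + 1L
  }
  list(tab = key, unassigned = unassigned)
}

# ---- pathway oracle: explicit permutation enumeration ---------------------

perms <- function(v) {
  if (length(v) <= 1L) return(matrix(v, nrow = length(v) > 0))
  out <- NULL
  for (i in seq_along(v))
    out <- rbind(out, cbind(v[i], perms(v[-i])))
  out
}

oracle_pathways <- function(scheme, start, L, threshold, act) {
  np <- nrow(scheme$positions)
  startc <- strsplit(start, "")[[1]]
  total <- 0L; viable <- 0L
  subsets <- utils::combn(np, L)
  for (k in seq_len(ncol(subsets))) {
    for (r in seq_len(nrow(pm <- perms(subsets[, k])))) {
      ordpos <- pm[r, ]
      alts <- lapply(ordpos, function(i)
        setdiff(scheme$positions$alleles[[i]], startc[i]))
      choice <- expand.grid(alts, stringsAsFactors = FALSE)
      for (q in seq_len(nrow(choice))) {
        total <- total + 1L
        g <- startc
        ok <- TRUE
        for (step in seq_len(L)) {
          g[ordpos[step]] <- choice[q, step]
          a <- act[paste(g, collapse = "")]
          if (is.na(a) || a <= threshold) { ok <- FALSE; break }
        }
        if (ok) viable <- viable + 1L
      }
    }
  }
  list(total = total, viable = viable)
}

# ---- epistasis square oracle (ternary effect directions) ------------------

oracle_square_class <- function(w00, w10, w01, w11, delta = 0) {
  e <- w11 - w10 - w01 + w00
  if (abs(e) <= delta) return("none")
  dir <- function(a, b) if (b - a > delta) 1L else if (a - b > delta) -1L else 0L
  m1 <- c(dir(w00, w10), dir(w01, w11))
  m2 <- c(dir(w00, w01), dir(w10, w11))
  flip <- function(d) all(d != 0L) && d[1] != d[2]
  if (flip(m1) && flip(m2)) "reciprocal_sign"
  else if (flip(m1) || flip(m2)) "sign"
  else "magnitude"
}
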