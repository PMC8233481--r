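#' Default truth-landscape rules
#'
#' Rule constants for [generate_truth_landscape()]. The defaults encode the
#' qualitative structure of the measured CPEB3 ribozyme landscape: the
#' ancestral genotype cleaves at \code{p0 = 0.92}; any mutation at the G1
#' position (which provides the 5'-hydroxyl leaving group and the first base
#' pair) collapses activity to \code{p_g1 = 0.03}; mutations in the
#' peripheral L4 loop are nearly neutral (penalty 0.98); the C9U and G30A
#' changes are mildly deleterious (0.97); the U36C change breaks the G1:U36
#' wobble pair (0.15); all remaining positions carry a strong 0.35 penalty.
#' Under these rules the landscape is strongly bimodal: most random
#' combinations of mutations are essentially inactive while the ancestral
#' neighborhood (L4/C9/G30 variation) stays highly active.
#'
#' @param p0 Ancestral cleavage probability.
#' @param p_g1 Activity of the single G1 mutant (any G1 mutation multiplies
#'   activity by \code{p_g1/p0}, so the pure G1 single mutant lands exactly
#'   at \code{p_g1}).
#' @param penalty_l4 Multiplicative penalty per mutation at an L4-element
#'   position.
#' @param penalty_mild Penalty for positions named in \code{mild_names}.
#' @param penalty_strong Penalty for all other non-L4, non-G1 positions.
#' @param mild_names Position names treated as mild (default C9, G30).
#' @param wobble_name,penalty_wobble Position (default U36) whose mutation
#'   disrupts the G1 wobble pair, and its penalty.
#' @param noise_sd Gaussian noise sd applied on the logit scale (0 disables
#'   noise; the default landscape is deterministic).
#' @param epistasis Optional data.frame with columns \code{name1},
#'   \code{name2}, \code{multiplier}: an extra multiplicative term applied
#'   when both named positions are mutated.
#' @return A named list of rule constants.
#' @export
default_landscape_rules <- function(p0 = 0.92, p_g1 = 0.03,
                                    penalty_l4 = 0.98,
                                    penalty_mild = 0.97,
                                    penalty_strong = 0.35,
                                    mild_names = c("C9", "G30"),
                                    wobble_name = "U36",
                                    penalty_wobble = 0.15,
                                    noise_sd = 0,
                                    epistasis = NULL) {
  list(p0 = p0, p_g1 = p_g1, penalty_l4 = penalty_l4,
       penalty_mild = penalty_mild, penalty_strong = penalty_strong,
       mild_names = mild_names, wobble_name = wobble_name,
       penalty_wobble = penalty_wobble, noise_sd = noise_sd,
       epistasis = epistasis)
}

#' Generate a true cleavage-probability landscape
#'
#' Assigns a true cleavage probability p in [0,1] to every genotype of the
#' scheme under a multiplicative-penalty model: starting from the ancestral
#' activity \code{p0}, each mutated position multiplies activity by its
#' per-position penalty (see [default_landscape_rules()]); optional pairwise
#' epistasis multipliers apply when both members of a pair are mutated;
#' optional Gaussian noise is added on the logit scale; results are clamped
#' to [0,1]. Deterministic given \code{seed}.
#'
#' @param scheme A \code{"variant_scheme"}.
#' @param rules Rule list as from [default_landscape_rules()]. Position
#'   names referenced in \code{mild_names}, \code{wobble_name} or
#'   \code{epistasis} must exist in the scheme (an error otherwise), except
#'   that the packaged defaults are silently ignored for custom schemes that
#'   lack them only if \code{rules} is not user-supplied... see Details.
#' @param seed Integer seed for the noise stream.
#' @details Rule names are matched against \code{scheme$positions$name}; an
#'   unknown name in a user-supplied rule set is an error. The per-position
#'   penalty is: 0 replaced by \code{p_g1/p0} at the G1 position (backbone
#'   index 1), \code{penalty_l4} at L4-element positions,
#'   \code{penalty_mild} / \code{penalty_wobble} for the named positions,
#'   and \code{penalty_strong} elsewhere.
#' @return A \code{"truth_landscape"}: data.frame with columns
#'   \code{genotype} and \code{p}, with the rules and seed as attributes.
#' @export
#' @examples
#' sc <- default_scheme()
#' tl <- generate_truth_landscape(sc)
#' tl$p[tl$genotype == ancestral_genotype(sc)]  # 0.92
generate_truth_landscape <- function(scheme, rules = default_landscape_rules(),
                                     seed = 1L) {
  stopifnot(inherits(scheme, "variant_scheme"))
  pos <- scheme$positions
  known <- pos$name
  referenced <- c(rules$mild_names, rules$wobble_name,
                  if (!is.null(rules$epistasis))
                    c(rules$epistasis$name1, rules$epistasis$name2))
  unknown <- setdiff(referenced, known)
  if (length(unknown))
    stop("rules reference unknown position name(s): ",
         paste(unknown, collapse = ", "))

  penalty <- rep(rules$penalty_strong, nrow(pos))
  penalty[pos$element == "L4"] <- rules$penalty_l4
  penalty[pos$name %in% rules$mild_names] <- rules$penalty_mild
  penalty[pos$name %in% rules$wobble_name] <- rules$penalty_wobble
  g1 <- g1_position(scheme)
  if (!is.na(g1)) penalty[g1] <- rules$p_g1 / rules$p0

  genos <- enumerate_genotypes(scheme)
  mut <- genotype_matrix(genos) != rep(pos$reference, each = length(genos))
  logp <- log(rules$p0) + drop(mut %*% log(penalty))
  if (!is.null(rules$epistasis)) {
    ep <- rules$epistasis
    for (k in seq_len(nrow(ep))) {
      i <- match(ep$name1[k], known); j <- match(ep$name2[k], known)
      logp <- logp + ifelse(mut[, i] & mut[, j], log(ep$multiplier[k]), 0)
    }
  }
  p <- exp(logp)
  if (rules$noise_sd > 0) {
    set.seed(as.integer(seed))
    eps <- stats::rnorm(length(p), 0, rules$noise_sd)
    p <- stats::plogis(stats::qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12)) + eps)
  }
  p <- pmin(pmax(p, 0), 1)
  out <- data.frame(genotype = genos, p = p, stringsAsFactors = FALSE)
  attr(out, "rules") <- rules
  attr(out, "seed") <- seed
  class(out) <- c("truth_landscape", "data.frame")
  out
}

#' @export
print.truth_landscape <- function(x, ...) {
  cat("Truth landscape over", nrow(x), "genotypes\n")
  cat(sprintf("  p range [%.3f, %.3f]; %.1f%% below 0.2; %.1f%% above 0.8\n",
              min(x$p), max(x$p), 100 * mean(x$p < 0.2), 100 * mean(x$p > 0.8)))
  invisible(x)
}

#' Read / write a truth landscape as TSV
#' @param path File path.
#' @return \code{read_landscape_tsv}: data.frame(genotype, p);
#'   \code{write_landscape_tsv}: \code{path}, invisibly.
#' @export
write_landscape_tsv <- function(landscape, path) {
  utils::write.table(as.data.frame(landscape)[, c("genotype", "p")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landscape_tsv
#' @param landscape A \code{"truth_landscape"} or data.frame(genotype, p).
#' @export
read_landscape_tsv <- function(path) {
  utils::read.delim(path, colClasses = c(genotype = "character"))
}
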