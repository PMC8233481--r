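#' Build the genotype network of active genotypes
#'
#' Nodes are the genotypes whose activity is strictly greater than
#' \code{threshold}; undirected edges connect every pair of nodes at
#' Hamming distance one. Returned as an \pkg{igraph} graph with the
#' genotype as vertex name and its activity as a vertex attribute.
#'
#' @param activity An \code{"activity_table"}, a \code{"truth_landscape"},
#'   or a named numeric vector of activities keyed by genotype.
#' @param scheme A \code{"variant_scheme"} (defines the single-substitution
#'   moves).
#' @param threshold Strict inclusion threshold (default 0.5, the value used
#'   to emphasize mutations that maintain self-cleaving potential).
#' @return An \code{igraph} object with vertex attributes \code{name}
#'   (genotype) and \code{activity}.
#' @export
build_network <- function(activity, scheme, threshold = 0.5) {
  act <- activity_vector(activity)
  act <- act[!is.na(act)]
  keep <- act[act > threshold]
  if (!length(keep)) {
    warning("no genotype above threshold: empty network")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  genos <- names(keep)
  from <- character(0); to <- character(0)
  for (i in seq_len(n_positions(scheme))) {
    for (a in scheme$positions$alleles[[i]]) {
      mv <- mutate_at(scheme, genos, i, a)
      hit <- !is.na(match(mv$to, genos))
      # keep each undirected edge once
      ord <- hit & mv$from < mv$to
      from <- c(from, mv$from[ord])
      to <- c(to, mv$to[ord])
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(genos, activity = unname(keep))
  if (length(from))
    g <- igraph::add_edges(g, rbind(match(from, genos), match(to, genos)))
  g
}

#' Export / import a genotype network
#'
#' \code{format = "edgelist"} writes a TSV with columns \code{g1},
#' \code{g2}, \code{activity1}, \code{activity2} plus an
#' \code{#isolated:} header listing degree-zero nodes (so the round trip
#' is lossless); \code{format = "graphml"} writes GraphML with the
#' activity as a node attribute.
#'
#' @param network An igraph genotype network from [build_network()].
#' @param path Output file.
#' @param format \code{"edgelist"} or \code{"graphml"}.
#' @return \code{path} (export, invisibly) or an igraph object (import).
#' @export
export_network <- function(network, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_edgelist(network, names = TRUE)
  act <- stats::setNames(igraph::V(network)$activity,
                         igraph::V(network)$name)
  iso <- names(act)[igraph::degree(network) == 0]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#isolated: ", paste(iso, collapse = ",")), con)
  writeLines(paste0("#isolated_activity: ",
                    paste(act[iso], collapse = ",")), con)
  df <- data.frame(g1 = el[, 1], g2 = el[, 2],
                   activity1 = unname(act[el[, 1]]),
                   activity2 = unname(act[el[, 2]]))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml")
    return(igraph::read_graph(path, format = "graphml"))
  lines <- readLines(path)
  iso_line <- trimws(sub("^#isolated:", "", lines[1]))
  isoact_line <- trimws(sub("^#isolated_activity:", "", lines[2]))
  iso <- if (nzchar(iso_line)) strsplit(iso_line, ",")[[1]] else character(0)
  isoact <- if (nzchar(isoact_line))
    as.numeric(strsplit(isoact_line, ",")[[1]]) else numeric(0)
  body <- lines[!startsWith(lines, "#")]
  df <- if (length(body) > 1L) {
    utils::read.delim(text = body,
                      colClasses = c(g1 = "character", g2 = "character"))
  } else {
    data.frame(g1 = character(0), g2 = character(0),
               activity1 = numeric(0), activity2 = numeric(0))
  }
  act <- c(stats::setNames(df$activity1, df$g1),
           stats::setNames(df$activity2, df$g2),
           stats::setNames(isoact, iso))
  act <- act[!duplicated(names(act))]
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(names(act), activity = unname(act))
  if (nrow(df))
    g <- igraph::add_edges(g, rbind(match(df$g1, names(act)),
                                    match(df$g2, names(act))))
  g
}

## ---- internal -------------------------------------------------------------

# normalize the various activity carriers to a named numeric vector
activity_vector <- function(activity) {
  if (is.numeric(activity) && !is.null(names(activity))) return(activity)
  if (inherits(activity, "truth_landscape") ||
      (is.data.frame(activity) && all(c("genotype", "p") %in% names(activity))))
    return(stats::setNames(activity$p, activity$genotype))
  if (is.data.frame(activity) &&
      all(c("genotype", "mean_fraction") %in% names(activity)))
    return(stats::setNames(activity$mean_fraction, activity$genotype))
  stop("cannot interpret 'activity': give an activity_table, ",
       "truth_landscape, or named numeric vector")
}
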