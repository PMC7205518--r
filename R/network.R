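#' Build the bipartite spacer-virome network
#'
#' One node per distinct spacer and per distinct matched viral contig; one
#' edge per (spacer, target) match. Edge weight is the alignment score
#' normalized to (0, 1] by the maximum score over the edges of that spacer,
#' standing in for "alignment strength". Node attribute `kind` is
#' `"spacer"` or `"<set>_virome"`; spacer nodes may carry the host phylum.
#'
#' @param matches Data.frame from [match_spacers()] (rbind over sets is
#'   fine; a spacer matching several sets keeps one node).
#' @param spacers Optional spacer table to attach `phylum` to spacer nodes.
#' @return An [igraph::graph] with attributes `kind`, `phylum` (nodes),
#'   `weight`, `identity_pct`, `target_set` (edges), and a `component`
#'   node attribute labelling connected components.
#' @export
build_network <- function(matches, spacers = NULL) {
  if (nrow(matches) == 0) {
    g <- igraph::make_empty_graph(directed = FALSE)
    return(g)
  }
  max_per_spacer <- tapply(matches$score, matches$spacer_id, max)
  weight <- matches$score / as.numeric(max_per_spacer[matches$spacer_id])

  spacer_ids <- sort(unique(matches$spacer_id))
  tkey <- !duplicated(matches$target_contig_id)
  target_ids <- matches$target_contig_id[tkey]
  target_kind <- paste0(matches$target_set[tkey], "_virome")
  o <- order(target_ids)
  target_ids <- target_ids[o]; target_kind <- target_kind[o]

  nodes <- data.frame(
    name = c(spacer_ids, target_ids),
    kind = c(rep("spacer", length(spacer_ids)), target_kind),
    stringsAsFactors = FALSE
  )
  nodes$phylum <- NA_character_
  if (!is.null(spacers)) {
    idx <- match(nodes$name, spacers$spacer_id)
    nodes$phylum <- spacers$phylum[idx]
  }
  edges <- data.frame(from = matches$spacer_id, to = matches$target_contig_id,
                      weight = weight, identity_pct = matches$identity_pct,
                      target_set = matches$target_set, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  comp <- igraph::components(g)
  igraph::V(g)$component <- comp$membership
  g
}

#' Export a phage-host network
#'
#' @param network An igraph object from [build_network()].
#' @param path Output file path.
#' @param format `"graphml"`, `"sif"` or `"tsv"` (node and edge tables;
#'   `path` gets suffixes `.nodes.tsv` / `.edges.tsv`).
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("graphml", "sif", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else if (format == "sif") {
    if (igraph::ecount(network) == 0) {
      writeLines(character(0), path)
    } else {
      el <- igraph::as_edgelist(network)
      writeLines(sprintf("%s\tmatches\t%s", el[, 1], el[, 2]), path)
    }
  } else {
    nodes <- data.frame(id = igraph::V(network)$name %||% character(0),
                        kind = igraph::V(network)$kind %||% character(0),
                        phylum = igraph::V(network)$phylum %||% character(0),
                        stringsAsFactors = FALSE)
    utils::write.table(nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (igraph::ecount(network) > 0) {
      el <- igraph::as_edgelist(network)
      edges <- data.frame(from = el[, 1], to = el[, 2],
                          weight = igraph::E(network)$weight,
                          target_set = igraph::E(network)$target_set,
                          stringsAsFactors = FALSE)
    } else {
      edges <- data.frame(from = character(), to = character(),
                          weight = numeric(), target_set = character())
    }
    utils::write.table(edges, paste0(path, ".edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Virome hub nodes
#'
#' Viral-contig nodes matched by at least `k` spacers, sorted by degree
#' descending (ties by id): the "single contig, several spacers" star
#' components that flag common infection agents.
#'
#' @param network An igraph object from [build_network()].
#' @param k Minimum spacer degree (>= 2).
#' @return Data.frame `target`, `kind`, `degree`.
#' @export
hub_report <- function(network, k = 2L) {
  stopifnot(k >= 2)
  if (igraph::vcount(network) == 0) {
    return(data.frame(target = character(), kind = character(),
                      degree = integer(), stringsAsFactors = FALSE))
  }
  is_virome <- igraph::V(network)$kind != "spacer"
  deg <- igraph::degree(network)
  out <- data.frame(target = igraph::V(network)$name[is_virome],
                    kind = igraph::V(network)$kind[is_virome],
                    degree = as.integer(deg[is_virome]),
                    stringsAsFactors = FALSE)
  out <- out[out$degree >= k, , drop = FALSE]
  out <- out[order(-out$degree, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default virulence/evasion annotation categories
#'
#' Keyword categories for classifying viral gene functional descriptions
#' into virulence- and RM-evasion-related classes (methylases and
#' methyltransferases that evade restriction, chitinases that degrade
#' biofilm, antirestriction and virulence-associated proteins). Patterns
#' are matched case-insensitively as substrings, in priority order; a
#' description is counted once under the first category it matches.
#'
#' @return Data.frame `category`, `pattern`, `priority`.
#' @export
default_virulence_categories <- function() {
  data.frame(
    category = c("Adenine-specific methyltransferase",
                 "Cytosine-specific DNA methylase",
                 "DNA methylase",
                 "Chitinase class I",
                 "Virulence-associated protein E",
                 "Antirestriction ArdA family protein",
                 "Repressor protein",
                 "Type 12 methyltransferase",
                 "Methyltransferase, type 11",
                 "Methyltransferase FkbM family",
                 "Virulence-associated protein"),
    pattern = c("adenine-specific methyltransferase",
                "cytosine-specific dna methylase",
                "dna methylase",
                "chitinase class i",
                "virulence-associated protein e",
                "antirestriction arda",
                "repressor protein",
                "type 12 methyltransferase",
                "methyltransferase, type 11",
                "methyltransferase fkbm",
                "virulence-associated protein"),
    priority = 1:11,
    stringsAsFactors = FALSE
  )
}

#' Categorize viral gene annotations
#'
#' @param descriptions Data.frame with `gene_id` and `description`, or a
#'   character vector of descriptions.
#' @param categories Data.frame from [default_virulence_categories()].
#' @return Data.frame `category`, `n_genes`, sorted by count descending
#'   (ties by priority); genes matching no category are counted under
#'   `"other"`.
#' @export
categorize_annotations <- function(descriptions,
                                   categories = default_virulence_categories()) {
  desc <- if (is.data.frame(descriptions)) descriptions$description else descriptions
  cat_of <- rep(NA_character_, length(desc))
  low <- tolower(desc)
  for (i in order(categories$priority)) {
    hit <- is.na(cat_of) & grepl(categories$pattern[i], low, fixed = TRUE)
    cat_of[hit] <- categories$category[i]
  }
  cat_of[is.na(cat_of)] <- "other"
  counts <- vapply(c(categories$category, "other"),
                   function(cc) sum(cat_of == cc), integer(1))
  out <- data.frame(category = names(counts), n_genes = as.integer(counts),
                    stringsAsFactors = FALSE)
  prio <- c(categories$priority, max(categories$priority) + 1L)
  out <- out[order(-out$n_genes, prio), , drop = FALSE]
  rownames(out) <- NULL
  out
}
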