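CAUSAL_EFFECTS <- c("up", "down", "physical", "unknown")

# Token vocabulary accepted for edge effects, including the arrow glyphs
# used in published causal-network tables.
normalise_effect <- function(tokens) {
  map <- c(
    "up" = "up", "up_regulates" = "up", "up-regulates" = "up",
    "→" = "up", "->" = "up",
    "down" = "down", "down_regulates" = "down", "down-regulates" = "down",
    "―|" = "down", "-|" = "down",
    "physical" = "physical", "physical_interaction" = "physical",
    "―[]" = "physical", "-[]" = "physical",
    "unknown" = "unknown", "―?" = "unknown", "-?" = "unknown", "?" = "unknown"
  )
  out <- unname(map[trimws(tokens)])
  if (anyNA(out)) {
    bad <- unique(trimws(tokens)[is.na(out)])
    stop("unknown effect token(s): ", paste(sQuote(bad), collapse = ", "),
         "; expected up / down / physical / unknown (or the glyphs ",
         "→, ―|, ―[], ―?).", call. = FALSE)
  }
  out
}

#' Construct a signed causal interaction graph
#'
#' A directed graph whose edges carry a regulatory effect: up-regulation,
#' down-regulation, physical interaction (sign-neutral), or unknown.
#' Parallel edges between the same node pair with distinct effects are
#' allowed; exact duplicates are dropped.
#'
#' @param edges A data frame with columns `source`, `effect`, `target`.
#'   Effects may use words (`up`, `down`, `physical`, `unknown`) or the
#'   table glyphs.
#' @return An object of class `causal_graph` with elements `nodes`
#'   (character vector) and `edges` (tibble `source`, `effect`, `target`).
#' @export
causal_graph <- function(edges) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) == 0) {
    return(structure(list(nodes = character(),
                          edges = tibble::tibble(source = character(),
                                                 effect = character(),
                                                 target = character())),
                     class = "causal_graph"))
  }
  if (!all(c("source", "effect", "target") %in% names(edges))) {
    stop("`edges` must have columns `source`, `effect`, `target`.",
         call. = FALSE)
  }
  ed <- tibble::tibble(
    source = as.character(edges$source),
    effect = normalise_effect(edges$effect),
    target = as.character(edges$target)
  )
  ed <- dplyr::distinct(ed)
  structure(
    list(nodes = sort(unique(c(ed$source, ed$target))), edges = ed),
    class = "causal_graph"
  )
}

#' @export
print.causal_graph <- function(x, ...) {
  cat(sprintf("Signed causal graph: %d nodes, %d directed edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a signed edge list (SIF-like TSV)
#'
#' Each non-empty line is `source<TAB>effect<TAB>target`; an optional
#' header row `source effect target` is skipped. Effect tokens follow the
#' vocabulary of [causal_graph()]. Malformed rows are reported with their
#' line numbers.
#'
#' @param path Path to the TSV file.
#' @return A `causal_graph`.
#' @examples
#' edges <- system.file("extdata", "sirt_tubulin_edges.tsv", package = "isobolr")
#' read_edge_list(edges)
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(keep) == 0) return(causal_graph(tibble::tibble()))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- keep[lengths(parts) != 3L]
  if (length(bad) > 0) {
    stop("malformed edge row(s) (need 3 tab-separated fields) at line(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  m <- do.call(rbind, parts)
  ed <- tibble::tibble(source = trimws(m[, 1]), effect = trimws(m[, 2]),
                       target = trimws(m[, 3]))
  if (nrow(ed) > 0 && identical(tolower(unlist(ed[1, ])),
                                c(source = "source", effect = "effect",
                                  target = "target"))) {
    ed <- ed[-1, ]
  }
  causal_graph(ed)
}

#' Net sign of a sequence of regulatory effects
#'
#' Composes edge effects along a path under the product rule: any unknown
#' edge makes the net effect unknown; otherwise the sign is negative when
#' the number of down-regulating edges is odd and positive when even.
#' Physical-interaction edges are sign-neutral — they pass the incoming
#' sign through.
#'
#' @param effects Character vector of edge effects (vocabulary of
#'   [causal_graph()]), in path order; must be non-empty.
#' @return `"positive"`, `"negative"` or `"unknown"`.
#' @examples
#' compose_signs(c("up", "up", "up", "up"))
#' compose_signs(c("down", "physical", "up", "up"))
#' @export
compose_signs <- function(effects) {
  if (length(effects) == 0) stop("`effects` must be non-empty.", call. = FALSE)
  eff <- normalise_effect(effects)
  if (any(eff == "unknown")) return("unknown")
  if (sum(eff == "down") %% 2 == 1) "negative" else "positive"
}

as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges[, c("source", "target", "effect")],
    directed = TRUE,
    vertices = data.frame(name = graph$nodes)
  )
}

check_node <- function(graph, node, arg) {
  if (!node %in% graph$nodes) {
    stop("node ", sQuote(node), " (", arg, ") is not in the graph.",
         call. = FALSE)
  }
}

#' Shortest directed path length
#'
#' Minimum number of directed edges from `from` to `to` (breadth-first
#' search); `0` when the endpoints coincide, `Inf` when no directed path
#' exists.
#'
#' @param graph A `causal_graph`.
#' @param from,to Node identifiers.
#' @return Integer edge count (or `Inf`).
#' @export
shortest_path_length <- function(graph, from, to) {
  stopifnot(inherits(graph, "causal_graph"))
  check_node(graph, from, "from")
  check_node(graph, to, "to")
  if (identical(from, to)) return(0L)
  d <- igraph::distances(as_igraph(graph), v = from, to = to, mode = "out",
                         weights = NA)[1, 1]
  if (is.infinite(d)) Inf else as.integer(d)
}

render_path_string <- function(nodes, effects) {
  glyph <- c(up = " -> ", down = " -| ", physical = " -[] ", unknown = " -? ")
  out <- nodes[1]
  for (i in seq_along(effects)) {
    out <- paste0(out, glyph[[effects[i]]], nodes[i + 1])
  }
  out
}

#' Enumerate simple signed paths between two nodes
#'
#' Depth-first enumeration of all simple directed paths (no repeated node)
#' of at most `max_length` edges, each annotated with its net regulatory
#' sign ([compose_signs()]). Parallel edges with distinct effects yield
#' distinct paths. Results are deterministically ordered by
#' (length, node sequence, effect sequence).
#'
#' @param graph A `causal_graph`.
#' @param from,to Node identifiers.
#' @param max_length Maximum path length in edges (default 8; a hard cap of
#'   12 guards against exponential blow-up — pre-filter the graph for
#'   longer searches).
#' @return A tibble with columns `pathway_string`, `length`,
#'   `final_effect`, plus list-columns `nodes` and `effects`.
#' @examples
#' edges <- system.file("extdata", "sirt_tubulin_edges.tsv", package = "isobolr")
#' g <- read_edge_list(edges)
#' enumerate_paths(g, "SIRT1", "Tubulin", max_length = 4)
#' @export
enumerate_paths <- function(graph, from, to, max_length = 8) {
  stopifnot(inherits(graph, "causal_graph"))
  check_node(graph, from, "from")
  check_node(graph, to, "to")
  if (max_length < 1) stop("`max_length` must be >= 1.", call. = FALSE)
  if (max_length > 12) {
    stop("`max_length` above the hard cap of 12 edges; simple-path counts ",
         "grow exponentially — restrict the graph to the neighbourhood of ",
         "interest before searching deeper.", call. = FALSE)
  }
  out_edges <- split(graph$edges, graph$edges$source)
  paths <- list()
  walk <- function(node, nodes_so_far, effects_so_far) {
    if (length(effects_so_far) > 0 && node == to) {
      paths[[length(paths) + 1]] <<- list(nodes = nodes_so_far,
                                          effects = effects_so_far)
      return(invisible())
    }
    if (length(effects_so_far) >= max_length) return(invisible())
    nxt <- out_edges[[node]]
    if (is.null(nxt)) return(invisible())
    for (i in seq_len(nrow(nxt))) {
      tgt <- nxt$target[i]
      if (tgt %in% nodes_so_far) next
      walk(tgt, c(nodes_so_far, tgt), c(effects_so_far, nxt$effect[i]))
    }
  }
  walk(from, from, character())
  if (length(paths) == 0) {
    return(tibble::tibble(pathway_string = character(), length = integer(),
                          final_effect = character(), nodes = list(),
                          effects = list()))
  }
  tb <- tibble::tibble(
    pathway_string = vapply(paths, function(p)
      render_path_string(p$nodes, p$effects), character(1)),
    length = vapply(paths, function(p) length(p$effects), integer(1)),
    final_effect = vapply(paths, function(p) compose_signs(p$effects),
                          character(1)),
    nodes = lapply(paths, `[[`, "nodes"),
    effects = lapply(paths, `[[`, "effects")
  )
  key_nodes <- vapply(tb$nodes, paste, character(1), collapse = "\r")
  key_eff <- vapply(tb$effects, paste, character(1), collapse = "\r")
  tb[order(tb$length, key_nodes, key_eff), ]
}

#' Write a path report CSV
#'
#' @param paths A tibble from [enumerate_paths()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_path_report <- function(paths, path) {
  readr::write_csv(paths[, c("pathway_string", "length", "final_effect")],
                   path)
  invisible(path)
}
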