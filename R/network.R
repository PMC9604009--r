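#' Build the strain-sharing network
#'
#' Nodes are participants (with family and role metadata); each
#' shared-strain call contributes one edge labelled with its species, so
#' two participants sharing several species are joined by parallel edges.
#'
#' @param calls shared-strain call tibble (see [call_shared()] /
#'   [all_vs_all()]) with `participant_a`, `participant_b`, `taxon` and
#'   `shared` columns; only `shared == TRUE` rows become edges.
#' @param manifest participant tibble: `participant_id`, `family_id`,
#'   `role` (`"mother"`/`"daughter"`), optionally `age`.
#' @return an igraph of class `strain_network` with vertex attributes
#'   `family_id`, `role` and edge attribute `taxon`.
#' @export
build_network <- function(calls, manifest) {
  need <- c("participant_id", "family_id", "role")
  miss <- setdiff(need, names(manifest))
  if (length(miss) > 0) {
    abort(paste0("manifest missing columns: ", paste(miss, collapse = ", ")))
  }
  edges <- dplyr::filter(calls, .data$shared)
  unknown <- setdiff(
    unique(c(edges$participant_a, edges$participant_b)),
    manifest$participant_id
  )
  if (length(unknown) > 0) {
    abort(paste0("calls reference unknown participants: ",
                 paste(unknown, collapse = ", ")))
  }
  if (any(edges$participant_a == edges$participant_b)) {
    abort("self-sharing calls cannot become network edges")
  }
  g <- igraph::graph_from_data_frame(
    d = dplyr::select(edges, "participant_a", "participant_b", "taxon"),
    directed = FALSE,
    vertices = dplyr::rename(manifest, name = "participant_id")
  )
  class(g) <- c("strain_network", class(g))
  g
}

# edge class from the two endpoints' metadata
edge_class_of <- function(fam_a, role_a, fam_b, role_b) {
  same_family <- fam_a == fam_b
  md <- (role_a == "mother" & role_b == "daughter") |
    (role_a == "daughter" & role_b == "mother")
  mm <- role_a == "mother" & role_b == "mother"
  dd <- role_a == "daughter" & role_b == "daughter"
  dplyr::case_when(
    same_family & md ~ "within_family_MD",
    same_family & dd ~ "within_family_DD",
    !same_family & md ~ "between_family_MD",
    !same_family & mm ~ "between_family_MM",
    !same_family & dd ~ "between_family_DD",
    TRUE ~ "other"
  )
}

#' Classify and count strain-sharing edges
#'
#' Labels every edge by the family relationship of its endpoints —
#' within-family mother-daughter, between-family mother-daughter,
#' mother-mother or daughter-daughter (plus a separate within-family
#' daughter-daughter class for sisters) — and counts edges per class.
#' The classes partition the edges, so the counts always sum to the edge
#' total. Also reports the number of *distinct* within-family
#' mother-daughter participant pairs, since one pair can share several
#' species.
#'
#' @param network a [build_network()] result.
#' @return a list: `edges` (tibble with `participant_a`, `participant_b`,
#'   `taxon`, `edge_class`), `counts` (tibble `edge_class`, `n`),
#'   `n_edges`, and `distinct_within_family_pairs`.
#' @export
classify_and_count <- function(network) {
  el <- igraph::as_data_frame(network, what = "edges")
  meta <- igraph::as_data_frame(network, what = "vertices")
  if (nrow(el) == 0) {
    return(list(
      edges = tibble(participant_a = character(0),
                     participant_b = character(0), taxon = character(0),
                     edge_class = character(0)),
      counts = tibble(edge_class = character(0), n = integer(0)),
      n_edges = 0L,
      distinct_within_family_pairs = 0L
    ))
  }
  ia <- match(el$from, meta$name)
  ib <- match(el$to, meta$name)
  edges <- tibble(
    participant_a = el$from,
    participant_b = el$to,
    taxon = el$taxon %||% NA_character_,
    edge_class = edge_class_of(meta$family_id[ia], meta$role[ia],
                               meta$family_id[ib], meta$role[ib])
  )
  counts <- dplyr::count(edges, .data$edge_class, name = "n")
  wf <- dplyr::filter(edges, .data$edge_class == "within_family_MD")
  key <- purrr::map2_chr(wf$participant_a, wf$participant_b,
                         ~ paste(sort(c(.x, .y)), collapse = "|"))
  list(
    edges = edges,
    counts = counts,
    n_edges = nrow(edges),
    distinct_within_family_pairs = length(unique(key))
  )
}

#' Plot a strain-sharing network
#'
#' Fruchterman-Reingold layout with mothers as circles, daughters as
#' squares, and one line per shared strain.
#'
#' @param object a `strain_network`.
#' @param seed layout seed.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot strain_network
#' @export
autoplot.strain_network <- function(object, seed = 1L, ...) {
  xy <- withr::with_seed(as.integer(seed),
                         igraph::layout_with_fr(object))
  meta <- igraph::as_data_frame(object, what = "vertices")
  nodes <- tibble(name = meta$name, family_id = meta$family_id,
                  role = meta$role, x = xy[, 1], y = xy[, 2])
  el <- igraph::as_data_frame(object, what = "edges")
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y))
  if (nrow(el) > 0) {
    seg <- tibble(
      x = nodes$x[match(el$from, nodes$name)],
      y = nodes$y[match(el$from, nodes$name)],
      xend = nodes$x[match(el$to, nodes$name)],
      yend = nodes$y[match(el$to, nodes$name)]
    )
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      colour = "grey60"
    )
  }
  p +
    ggplot2::geom_point(ggplot2::aes(shape = .data$role,
                                     colour = .data$family_id), size = 3) +
    ggplot2::scale_shape_manual(values = c(mother = 16, daughter = 15)) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_void() +
    ggplot2::labs(shape = NULL, title = "Strain-sharing network")
}

#' Write a strain-sharing network to GraphML and node-link JSON
#'
#' @param network a `strain_network`.
#' @param graphml_path,json_path output paths (either may be `NULL` to
#'   skip).
#' @return invisibly, the paths written.
#' @export
write_network <- function(network, graphml_path = NULL, json_path = NULL) {
  if (!is.null(graphml_path)) {
    g <- network
    class(g) <- setdiff(class(g), "strain_network")
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  if (!is.null(json_path)) {
    meta <- igraph::as_data_frame(network, what = "vertices")
    el <- igraph::as_data_frame(network, what = "edges")
    jsonlite::write_json(
      list(nodes = meta, links = el),
      json_path, dataframe = "rows", auto_unbox = TRUE, pretty = TRUE
    )
  }
  invisible(c(graphml_path, json_path))
}
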