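#' Build the complete circle-of-Willis network
#'
#' Wires the 18 canonical segments into the standard topology: each internal
#' carotid terminus joins the ipsilateral A1, MCA and PCoA; the two A1
#' segments meet the ACoA and the A2 efferents at the anterior junctions;
#' the two vertebral arteries share an inlet node and merge into the basilar
#' artery at a confluence node; the basilar terminus splits into the two P1
#' segments, each of which meets the ipsilateral PCoA and P2 efferent at a
#' posterior junction.
#'
#' Sign conventions: the ACoA is oriented left-to-right (positive graph flow
#' = flow towards the right hemisphere) and each PCoA is oriented
#' posterior-to-anterior (positive graph flow = flow feeding the anterior
#' circulation), so graph signs coincide with the usual reporting convention
#' for communicating-artery cross-flow.
#'
#' @param dimensions A dimension tibble with columns \code{id},
#'   \code{length_mm}, \code{diameter_mm} covering all 18 canonical
#'   segments (see [nominal_geometry()], [synthetic_geometry()]).
#'
#' @return An object of class \code{cow_network}: a list with a
#'   \code{segments} tibble (\code{id, from, to, length_mm, diameter_mm,
#'   klass, r_scale}), a \code{nodes} tibble (\code{node, role, territory})
#'   and a \code{flags} character vector.
#' @export
#'
#' @examples
#' net <- build_complete_cow(nominal_geometry())
#' net$segments
build_complete_cow <- function(dimensions = nominal_geometry()) {
  dimensions <- tibble::as_tibble(dimensions)
  req <- c("id", "length_mm", "diameter_mm")
  if (!all(req %in% names(dimensions))) {
    abort("`dimensions` needs columns id, length_mm, diameter_mm.")
  }
  missing <- setdiff(COW_SEGMENT_IDS, dimensions$id)
  if (length(missing) > 0) {
    abort(paste0("Missing dimensions for segment(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(dimensions$length_mm <= 0) || any(dimensions$diameter_mm <= 0)) {
    bad <- dimensions$id[dimensions$length_mm <= 0 | dimensions$diameter_mm <= 0]
    abort(paste0("Non-positive length or diameter for segment(s): ",
                 paste(bad, collapse = ", ")))
  }

  wiring <- tibble::tribble(
    ~id,     ~from,        ~to,          ~klass,
    "RICA",  "RICA_root",  "R_ICA_term", "inlet",
    "LICA",  "LICA_root",  "L_ICA_term", "inlet",
    "RVA",   "VA_root",    "BA_conf",    "inlet",
    "LVA",   "VA_root",    "BA_conf",    "inlet",
    "BA",    "BA_conf",    "BA_top",     "circle",
    "RA1",   "R_ICA_term", "R_ant",      "circle",
    "LA1",   "L_ICA_term", "L_ant",      "circle",
    "ACoA",  "L_ant",      "R_ant",      "circle",
    "RP1",   "BA_top",     "R_post",     "circle",
    "LP1",   "BA_top",     "L_post",     "circle",
    "RPCoA", "R_post",     "R_ICA_term", "circle",
    "LPCoA", "L_post",     "L_ICA_term", "circle",
    "RMCA",  "R_ICA_term", "RMCA_out",   "efferent",
    "LMCA",  "L_ICA_term", "LMCA_out",   "efferent",
    "RA2",   "R_ant",      "RACA_out",   "efferent",
    "LA2",   "L_ant",      "LACA_out",   "efferent",
    "RP2",   "R_post",     "RPCA_out",   "efferent",
    "LP2",   "L_post",     "LPCA_out",   "efferent"
  )

  segments <- wiring |>
    dplyr::left_join(
      dplyr::select(dimensions, "id", "length_mm", "diameter_mm"),
      by = "id"
    ) |>
    dplyr::mutate(r_scale = 1) |>
    dplyr::select("id", "from", "to", "length_mm", "diameter_mm",
                  "klass", "r_scale")

  nodes <- tibble::tribble(
    ~node,        ~role,      ~territory,
    "RICA_root",  "inlet",    NA_character_,
    "LICA_root",  "inlet",    NA_character_,
    "VA_root",    "inlet",    NA_character_,
    "R_ICA_term", "internal", NA_character_,
    "L_ICA_term", "internal", NA_character_,
    "BA_conf",    "internal", NA_character_,
    "BA_top",     "internal", NA_character_,
    "R_ant",      "internal", NA_character_,
    "L_ant",      "internal", NA_character_,
    "R_post",     "internal", NA_character_,
    "L_post",     "internal", NA_character_,
    "RACA_out",   "outlet",   "ACA",
    "LACA_out",   "outlet",   "ACA",
    "RMCA_out",   "outlet",   "MCA",
    "LMCA_out",   "outlet",   "MCA",
    "RPCA_out",   "outlet",   "PCA",
    "LPCA_out",   "outlet",   "PCA"
  )

  new_cow_network(segments, nodes)
}

new_cow_network <- function(segments, nodes, flags = character()) {
  if (anyDuplicated(segments$id) > 0) {
    abort("Duplicate segment identifiers in the network.")
  }
  net <- structure(
    list(segments = tibble::as_tibble(segments),
         nodes = tibble::as_tibble(nodes),
         flags = flags),
    class = "cow_network"
  )
  net$flags <- union(flags, check_connectivity(net))
  net
}

#' @export
print.cow_network <- function(x, ...) {
  n_in <- sum(x$nodes$role == "inlet")
  n_out <- sum(x$nodes$role == "outlet")
  cat(sprintf(
    "Circle-of-Willis network: %d segments, %d nodes (%d inlet, %d outlet)\n",
    nrow(x$segments), nrow(x$nodes), n_in, n_out))
  if (length(x$flags) > 0) {
    cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  }
  invisible(x)
}

# igraph view of the segment graph (undirected, for connectivity questions)
as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$segments[, c("from", "to", "id")],
    directed = FALSE,
    vertices = network$nodes$node
  )
}

# Efferent outlet nodes unreachable from every inlet are flagged, not
# dropped: the solver reports zero flow for them.
check_connectivity <- function(network) {
  g <- as_igraph(network)
  comp <- igraph::components(g)$membership
  inlet_comps <- unique(comp[network$nodes$node[network$nodes$role == "inlet"]])
  outlets <- network$nodes$node[network$nodes$role == "outlet"]
  dead <- outlets[!comp[outlets] %in% inlet_comps]
  if (length(dead) > 0) {
    paste0("efferent(s) disconnected from all inlets: ",
           paste(dead, collapse = ", "))
  } else {
    character()
  }
}

#' Apply an anatomical variant by removing one segment
#'
#' \code{COMPLETE} is the identity; the other five variants each remove one
#' communicating or proximal segment (ACoA, RA1, LA1, RPCoA or LPCoA). If
#' the removal disconnects an efferent from every inlet the network is still
#' returned, with the situation recorded in \code{$flags}.
#'
#' @param network A \code{cow_network}.
#' @param variant One of \code{COW_VARIANTS}.
#'
#' @return The modified \code{cow_network}.
#' @export
#'
#' @examples
#' net <- build_complete_cow() |> apply_variant("LA1_ABSENT")
apply_variant <- function(network, variant = COW_VARIANTS) {
  stopifnot(inherits(network, "cow_network"))
  variant <- match.arg(variant)
  target <- .variant_segment[[variant]]
  if (is.na(target)) {
    return(network)
  }
  if (!target %in% network$segments$id) {
    abort(paste0("Segment `", target, "` not present in the network."))
  }
  segments <- dplyr::filter(network$segments, .data$id != target)
  new_cow_network(segments, network$nodes, network$flags)
}

#' NASCET stenosis degree from diameters
#'
#' \eqn{S = (1 - d_s / d_n) \times 100}, where \eqn{d_s} is the narrowest
#' and \eqn{d_n} the normal lumen diameter.
#'
#' @param narrow_diameter Narrowest diameter \eqn{d_s}, mm; in
#'   \code{[0, normal_diameter]}.
#' @param normal_diameter Normal diameter \eqn{d_n}, mm; > 0.
#'
#' @return Stenosis degree in percent, in \code{[0, 100]}. Vectorised.
#' @export
stenosis_degree <- function(narrow_diameter, normal_diameter) {
  if (any(normal_diameter <= 0)) {
    abort("`normal_diameter` must be positive.")
  }
  if (any(narrow_diameter < 0) || any(narrow_diameter > normal_diameter)) {
    abort("`narrow_diameter` must lie in [0, normal_diameter].")
  }
  (1 - narrow_diameter / normal_diameter) * 100
}

#' Apply a NASCET-graded stenosis to a segment
#'
#' For degrees strictly between 0 and 100 the target segment is split in
#' series into a healthy remainder and a stenotic sub-segment
#' (\code{<id>_sten}) of length \code{stenotic_length} whose diameter is
#' \eqn{d_n (1 - S/100)}. Degree 0 is the identity; degree 100 removes the
#' segment entirely (occlusion), which avoids the ill-conditioned systems a
#' huge-resistance element would produce.
#'
#' @param network A \code{cow_network}.
#' @param degree Stenosis degree in percent, in \code{[0, 100]}.
#' @param target_segment Segment identifier; default \code{"RICA"}.
#' @param stenotic_length Axial extent of the stenosis in mm; must be
#'   shorter than the target segment. Default 10 mm.
#'
#' @return The modified \code{cow_network}.
#' @export
#'
#' @examples
#' build_complete_cow() |> apply_stenosis(75)
apply_stenosis <- function(network, degree, target_segment = "RICA",
                           stenotic_length = 10) {
  stopifnot(inherits(network, "cow_network"))
  if (!is.numeric(degree) || length(degree) != 1 ||
      degree < 0 || degree > 100) {
    abort("`degree` must be a single percentage in [0, 100].")
  }
  seg <- dplyr::filter(network$segments, .data$id == target_segment)
  if (nrow(seg) != 1) {
    abort(paste0("Segment `", target_segment, "` not present in the network."))
  }
  if (paste0(target_segment, "_sten") %in% network$segments$id) {
    abort(paste0("Segment `", target_segment, "` is already stenosed."))
  }
  if (degree == 0) {
    return(network)
  }
  if (degree == 100) {
    segments <- dplyr::filter(network$segments, .data$id != target_segment)
    return(new_cow_network(segments, network$nodes, network$flags))
  }
  if (stenotic_length <= 0 || stenotic_length >= seg$length_mm) {
    abort("`stenotic_length` must be positive and shorter than the segment.")
  }
  mid_node <- paste0(target_segment, "_sten_node")
  healthy <- seg |>
    dplyr::mutate(length_mm = .data$length_mm - stenotic_length,
                  to = mid_node)
  stenotic <- seg |>
    dplyr::mutate(id = paste0(target_segment, "_sten"),
                  length_mm = stenotic_length,
                  diameter_mm = .data$diameter_mm * (1 - degree / 100),
                  from = mid_node)
  segments <- network$segments |>
    dplyr::filter(.data$id != target_segment) |>
    dplyr::bind_rows(healthy, stenotic)
  nodes <- dplyr::bind_rows(
    network$nodes,
    tibble::tibble(node = mid_node, role = "internal",
                   territory = NA_character_)
  )
  new_cow_network(segments, nodes, network$flags)
}
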