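#' Filter interaction records with source-specific rules
#'
#' STRING links are kept only at high confidence (combined score > 0.7);
#' mirTarBase links must be supported by at least two publications and two
#' non-high-throughput methods; KEGG links are kept unconditionally. Counts
#' of kept/dropped records are reported per source.
#'
#' @param records data.table in the interaction-table schema (see
#'   [simulate_interactions()]).
#' @return The filtered records.
#' @export
filter_interactions <- function(records) {
  known <- c("kegg", "string", "mirtarbase")
  if (!all(records$database %in% known)) {
    stop("unknown database tag: ",
         paste(setdiff(unique(records$database), known), collapse = ", "))
  }
  keep <- rep(TRUE, nrow(records))
  is_str <- records$database == "string"
  keep[is_str] <- records$combined_score[is_str] > 0.7
  is_mir <- records$database == "mirtarbase"
  keep[is_mir] <- records$n_publications[is_mir] >= 2 &
    records$n_nonhts_methods[is_mir] >= 2
  for (db in known) {
    i <- records$database == db
    message(sprintf("%s: kept %d / %d records", db, sum(keep[i]), sum(i)))
  }
  records[keep]
}

#' Assemble the aggregated multi-layer network with edge costs
#'
#' KEGG and mirTarBase edges cost 0.1; STRING edges cost
#' `(1 - combined score) + 0.1`. Self-loops are removed and parallel edges
#' collapsed to the minimum cost; type constraints (kegg:
#' metabolite-gene, string: gene-gene, mirtarbase: miRNA-gene) are enforced.
#'
#' @param records Filtered interaction records.
#' @return An undirected `igraph` graph with vertex attribute `type` and
#'   edge attributes `cost` and `provenance`.
#' @export
assign_edge_weights <- function(records) {
  rec <- data.table::copy(records)
  ok_type <- (rec$database == "kegg" & rec$source_type == "metabolite" &
                rec$target_type == "gene") |
    (rec$database == "string" & rec$source_type == "gene" &
       rec$target_type == "gene") |
    (rec$database == "mirtarbase" & rec$source_type == "miRNA" &
       rec$target_type == "gene")
  if (any(!ok_type)) {
    stop(sum(!ok_type), " record(s) with node types incompatible with their",
         " database")
  }
  is_str <- rec$database == "string"
  if (any(is_str & (rec$combined_score <= 0 | rec$combined_score >= 1))) {
    stop("STRING combined score outside (0, 1)")
  }
  rec[, cost := ifelse(database == "string",
                       (1 - combined_score) + 0.1, 0.1)]
  rec <- rec[source_id != target_id]
  rec[, `:=`(a = pmin(source_id, target_id), b = pmax(source_id, target_id))]
  collapsed <- rec[, .(cost = min(cost),
                       provenance = paste(sort(unique(database)),
                                          collapse = "+")),
                   by = .(a, b)]
  types <- unique(data.table::rbindlist(list(
    rec[, .(id = source_id, type = source_type)],
    rec[, .(id = target_id, type = target_type)])))
  g <- igraph::graph_from_data_frame(
    collapsed[, .(from = a, to = b, cost = cost, provenance = provenance)],
    directed = FALSE,
    vertices = types[, .(name = id, type = type)])
  g
}

#' Harmonize omics feature ids onto network nodes
#'
#' mRNA and protein features of the same gene map to the same gene node;
#' metabolite and miRNA features map to their own node ids; features without
#' a network node (e.g. lipids) are listed as unmapped.
#'
#' @param layers Named list of [omics_layer()]s (annotations carry
#'   `node_id`).
#' @param network igraph network from [assign_edge_weights()] (may be empty).
#' @return data.table `feature_id`, `modality`, `node_id` (NA when the node
#'   is absent from the network), plus attribute `unmapped`.
#' @export
harmonize_ids <- function(layers, network) {
  maps <- lapply(names(layers), function(m) {
    ann <- layers[[m]]$annotations
    data.table::data.table(feature_id = ann$feature_id, modality = m,
                           node_id = ann$node_id)
  })
  map <- data.table::rbindlist(maps)
  if (anyDuplicated(map$feature_id)) {
    stop("conflicting mappings: duplicated feature ids across layers")
  }
  present <- igraph::V(network)$name
  map[!(node_id %in% present), node_id := NA_character_]
  data.table::setattr(map, "unmapped", map$feature_id[is.na(map$node_id)])
  map
}

#' Write a network as GraphML and SIF with an edge-attribute table
#'
#' @param g igraph network.
#' @param prefix Output path prefix (writes `<prefix>.graphml`,
#'   `<prefix>.sif`, `<prefix>_edges.tsv`).
#' @return The prefix, invisibly.
#' @export
write_network <- function(g, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  igraph::write_graph(g, paste0(prefix, ".graphml"), format = "graphml")
  ed <- igraph::as_data_frame(g, what = "edges")
  prov <- if ("provenance" %in% names(ed)) ed$provenance else "link"
  sif <- data.table::data.table(source = ed$from, interaction = prov,
                                target = ed$to)
  data.table::fwrite(sif, paste0(prefix, ".sif"), sep = "\t",
                     col.names = FALSE, quote = FALSE)
  write_tsv(data.table::as.data.table(ed), paste0(prefix, "_edges.tsv"))
  invisible(prefix)
}
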