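# Scaffold construction from committed protein models, and merging of
# protein scaffolds that share contigs into super-scaffolds via directed
# precedence graphs. Only "simple" merges are performed: acyclic graph,
# unique topological order, and a consistent orientation assignment;
# anything else is left unmerged and logged.

#' Build a scaffold from a committed protein scaffold model
#'
#' Contigs of the maximal scaffoldable set are ordered by their cluster's
#' protein coordinate; orientation is chosen so each contig's gene model
#' reads the protein N-to-C left to right (a minus-strand gene model flips
#' the contig).
#'
#' @param model One-row committed model (from [greedy_select()]).
#' @param gene_models Gene-model tibble (for strand lookup).
#' @param scaffold_id Id to assign.
#' @return A scaffold tibble: `scaffold_id`, `position`, `contig_id`,
#'   `orientation`, `gene_model_id`, `protein_id`. Gaps between consecutive
#'   components are implicit (fixed placeholder length at output time).
#' @export
scaffold_from_model <- function(model, gene_models, scaffold_id) {
  ms <- model$max_set[[1]]
  cl <- model$clusters[[1]]
  rows <- list()
  for (ci in seq_len(nrow(cl))) {
    mem <- cl$members[[ci]]
    sel <- mem[mem$gene_model_id %in% ms, ]
    if (nrow(sel) == 0) next
    if (nrow(sel) > 1) {
      abort("maximal scaffoldable set contains two members of one cluster")
    }
    rows[[length(rows) + 1L]] <- tibble(
      contig_id = sel$contig_id, orientation = sel$strand,
      gene_model_id = sel$gene_model_id, protein_id = model$protein_id)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  dup <- duplicated(out$contig_id)
  if (any(dup)) {
    warn(sprintf("contig %s appears twice in model %s; keeping first",
                 paste(unique(out$contig_id[dup]), collapse = ","),
                 model$protein_id))
    out <- out[!dup, ]
  }
  out$scaffold_id <- scaffold_id
  out$position <- seq_len(nrow(out))
  out[, c("scaffold_id", "position", "contig_id", "orientation",
          "gene_model_id", "protein_id")]
}

#' Build scaffolds for all committed models
#'
#' @param committed Committed models from [greedy_select()].
#' @param gene_models Gene-model tibble.
#' @param prefix Scaffold id prefix.
#' @return Combined scaffold tibble.
#' @export
scaffolds_from_models <- function(committed, gene_models,
                                  prefix = "scaffold") {
  if (nrow(committed) == 0) {
    return(tibble(scaffold_id = character(), position = integer(),
                  contig_id = character(), orientation = character(),
                  gene_model_id = character(), protein_id = character()))
  }
  dplyr::bind_rows(lapply(seq_len(nrow(committed)), function(i) {
    scaffold_from_model(committed[i, ], gene_models,
                        sprintf("%s_%04d", prefix, i))
  }))
}

flip_scaffold <- function(parts) {
  parts <- parts[rev(seq_len(nrow(parts))), ]
  parts$orientation <- ifelse(parts$orientation == "+", "-", "+")
  parts$position <- seq_len(nrow(parts))
  parts
}

# Unique topological order of an igraph DAG, or NULL when ambiguous: peel a
# unique zero-in-degree vertex at every step.
unique_topo_order <- function(g) {
  order <- character(0)
  while (igraph::vcount(g) > 0) {
    deg <- igraph::degree(g, mode = "in")
    zero <- names(deg)[deg == 0]
    if (length(zero) != 1) return(NULL)
    order <- c(order, zero)
    g <- igraph::delete_vertices(g, zero)
  }
  order
}

#' Merge scaffolds sharing contigs into super-scaffolds
#'
#' Scaffolds are grouped by shared contigs. Within each group, orientations
#' are propagated (a scaffold whose shared contig is oriented oppositely is
#' flipped whole); a directed precedence graph over contigs is built from
#' every scaffold's internal order; if the graph is acyclic with a unique
#' topological order and the orientation assignment is consistent, the group
#' becomes one merged scaffold, otherwise the inputs are kept unmerged and
#' the conflict is recorded.
#'
#' @param scaffolds Scaffold tibble.
#' @return A scaffold tibble; unmergeable groups keep their input scaffolds.
#'   Conflicts are attached as attribute `"conflicts"` (tibble with
#'   `scaffold_ids`, `reason`).
#' @export
merge_scaffolds <- function(scaffolds) {
  conflicts <- list()
  if (nrow(scaffolds) == 0) {
    attr(scaffolds, "conflicts") <- tibble(scaffold_ids = character(),
                                           reason = character())
    return(scaffolds)
  }
  sids <- unique(scaffolds$scaffold_id)
  # scaffold-sharing graph
  by_contig <- split(scaffolds$scaffold_id, scaffolds$contig_id)
  edges <- character(0)
  for (s in by_contig) {
    s <- unique(s)
    if (length(s) > 1) {
      for (i in seq_along(s)[-1]) edges <- c(edges, s[1], s[i])
    }
  }
  sg <- igraph::make_graph(edges = edges, isolates = setdiff(sids, edges),
                           directed = FALSE)
  comp <- igraph::components(sg)
  out <- list()
  merged_n <- 0L
  for (k in seq_len(comp$no)) {
    group <- names(comp$membership)[comp$membership == k]
    parts <- lapply(group, function(s) {
      scaffolds[scaffolds$scaffold_id == s, ][
        order(scaffolds$position[scaffolds$scaffold_id == s]), ]
    })
    names(parts) <- group
    if (length(group) == 1) {
      out[[length(out) + 1L]] <- parts[[1]]
      next
    }
    # orientation propagation over the group (BFS, flipping whole scaffolds)
    flip <- stats::setNames(rep(NA, length(group)), group)
    flip[group[1]] <- FALSE
    queue <- group[1]
    consistent <- TRUE
    while (length(queue) > 0 && consistent) {
      cur <- queue[1]; queue <- queue[-1]
      cur_parts <- if (flip[cur]) flip_scaffold(parts[[cur]]) else parts[[cur]]
      for (other in group) {
        if (other == cur) next
        shared <- intersect(cur_parts$contig_id, parts[[other]]$contig_id)
        if (length(shared) == 0) next
        o_cur <- cur_parts$orientation[match(shared, cur_parts$contig_id)]
        o_oth <- parts[[other]]$orientation[match(shared, parts[[other]]$contig_id)]
        need <- unique(o_cur != o_oth)
        if (length(need) > 1) { consistent <- FALSE; break }
        if (is.na(flip[other])) {
          flip[other] <- need
          queue <- c(queue, other)
        } else if (flip[other] != need) {
          consistent <- FALSE; break
        }
      }
    }
    if (!consistent || anyNA(flip)) {
      conflicts[[length(conflicts) + 1L]] <- tibble(
        scaffold_ids = paste(group, collapse = ","),
        reason = "orientation conflict")
      out <- c(out, parts)
      next
    }
    oriented <- lapply(group, function(s) {
      if (flip[s]) flip_scaffold(parts[[s]]) else parts[[s]]
    })
    # precedence graph over contigs
    pe <- character(0)
    for (p in oriented) {
      cc <- p$contig_id
      if (length(cc) > 1) {
        for (i in seq_along(cc)) for (j in seq_along(cc)) {
          if (i < j) pe <- c(pe, cc[i], cc[j])
        }
      }
    }
    all_contigs <- unique(unlist(lapply(oriented, function(p) p$contig_id)))
    pg <- igraph::make_graph(edges = pe, directed = TRUE,
                             isolates = setdiff(all_contigs,
                                                unique(pe)))
    pg <- igraph::simplify(pg)
    if (!igraph::is_dag(pg)) {
      conflicts[[length(conflicts) + 1L]] <- tibble(
        scaffold_ids = paste(group, collapse = ","),
        reason = "cyclic precedence")
      out <- c(out, parts)
      next
    }
    topo <- unique_topo_order(pg)
    if (is.null(topo)) {
      conflicts[[length(conflicts) + 1L]] <- tibble(
        scaffold_ids = paste(group, collapse = ","),
        reason = "ambiguous order")
      out <- c(out, parts)
      next
    }
    merged_n <- merged_n + 1L
    all_parts <- dplyr::bind_rows(oriented)
    first <- all_parts[!duplicated(all_parts$contig_id), ]
    prov <- vapply(topo, function(cid) {
      paste(sort(unique(all_parts$protein_id[all_parts$contig_id == cid])),
            collapse = ";")
    }, character(1))
    out[[length(out) + 1L]] <- tibble(
      scaffold_id = sprintf("superscaffold_%04d", merged_n),
      position = seq_along(topo), contig_id = topo,
      orientation = first$orientation[match(topo, first$contig_id)],
      gene_model_id = first$gene_model_id[match(topo, first$contig_id)],
      protein_id = prov)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "conflicts") <- if (length(conflicts) == 0) {
    tibble(scaffold_ids = character(), reason = character())
  } else dplyr::bind_rows(conflicts)
  res
}

#' Resolve contigs still shared between scaffolds
#'
#' After merging, a contig can remain in several scaffolds when a merge was
#' refused. Each such contig is kept in the scaffold of highest total
#' provenance power and removed from the others; removal of an interior
#' component splits the remaining scaffold into consecutive runs.
#'
#' @param scaffolds Scaffold tibble.
#' @param model_powers Named numeric vector: power per protein id.
#' @return Scaffold tibble in which every contig appears exactly once.
#' @export
resolve_shared_contigs <- function(scaffolds, model_powers) {
  if (nrow(scaffolds) == 0) return(scaffolds)
  scaffold_power <- function(sid) {
    prots <- unique(unlist(strsplit(
      scaffolds$protein_id[scaffolds$scaffold_id == sid], ";")))
    sum(model_powers[prots], na.rm = TRUE)
  }
  tab <- table(unique(scaffolds[, c("contig_id", "scaffold_id")])$contig_id)
  shared <- names(tab)[tab > 1]
  drop <- rep(FALSE, nrow(scaffolds))
  for (cid in shared) {
    sids <- unique(scaffolds$scaffold_id[scaffolds$contig_id == cid])
    pw <- vapply(sids, scaffold_power, double(1))
    keep_sid <- sids[order(-pw, sids)][1]
    drop <- drop | (scaffolds$contig_id == cid &
                      scaffolds$scaffold_id != keep_sid)
  }
  if (!any(drop)) return(scaffolds)
  res <- scaffolds[!drop, ]
  # split scaffolds with removed interior components into consecutive runs
  out <- list()
  for (sid in unique(res$scaffold_id)) {
    p <- res[res$scaffold_id == sid, ]
    p <- p[order(p$position), ]
    orig <- scaffolds[scaffolds$scaffold_id == sid, ]
    if (nrow(p) == nrow(orig)) {
      out[[length(out) + 1L]] <- p
      next
    }
    run <- cumsum(c(1L, diff(p$position) != 1L))
    for (r in unique(run)) {
      q <- p[run == r, ]
      q$scaffold_id <- if (length(unique(run)) > 1) {
        paste0(sid, ".", r)
      } else sid
      q$position <- seq_len(nrow(q))
      out[[length(out) + 1L]] <- q
    }
  }
  dplyr::bind_rows(out)
}
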