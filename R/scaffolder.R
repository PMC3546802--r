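# The score-optimization core: alpha uncoupling across proteins, clustering
# of contig gene models along each guide protein, exhaustive path enumeration
# with the beta filter, maximal scaffoldable sets and scaffolding power, and
# greedy iterative selection of protein scaffold models.

#' Alpha-uncouple competing contig gene models across proteins
#'
#' For each group of competing gene models of one contig region (single
#' linkage over PExR-set intersection on a contig), models scoring below
#' `alpha` times the best competing score are removed; ties and within-alpha
#' models are all retained. `alpha = 1` keeps only strict maxima; `alpha = 0`
#' removes nothing.
#'
#' @param gene_models Gene-model tibble from [build_gene_models()].
#' @param alpha Ratio threshold in `[0, 1]`.
#' @return The retained subset of `gene_models`.
#' @export
alpha_uncouple <- function(gene_models, alpha = 0.75) {
  if (nrow(gene_models) == 0 || alpha == 0) return(gene_models)
  keep <- rep(TRUE, nrow(gene_models))
  for (cid in unique(gene_models$contig_id)) {
    ii <- which(gene_models$contig_id == cid)
    if (length(ii) < 2) next
    # single-linkage components over PExR-set intersection
    comp <- seq_along(ii)
    for (a in seq_along(ii)) for (b in seq_along(ii)) {
      if (a >= b) next
      if (length(intersect(gene_models$pexr_ids[[ii[a]]],
                           gene_models$pexr_ids[[ii[b]]])) > 0) {
        old <- comp[b]; comp[comp == old] <- comp[a]
      }
    }
    for (cc in unique(comp)) {
      jj <- ii[comp == cc]
      if (length(jj) < 2) next
      best <- max(gene_models$similarity_score[jj])
      keep[jj] <- gene_models$similarity_score[jj] >= alpha * best
    }
  }
  gene_models[keep, ]
}

#' Cluster a protein's contig gene models along the protein
#'
#' Single-linkage clustering of the models' protein intervals at the
#' configured overlap (15 nt = 5 aa by default); within each cluster, models
#' scoring below `alpha` times the cluster best are removed. Clusters are
#' ordered by protein start coordinate.
#'
#' @param protein_id Guide protein id.
#' @param gene_models Gene-model tibble (any proteins; filtered internally).
#' @param config A [scaffolder_config()].
#' @return A tibble with `cluster_id`, `protein_start`, `protein_end` and a
#'   `members` list-column (tibbles with `gene_model_id`, `contig_id`,
#'   `strand`, `score`).
#' @export
cluster_on_protein <- function(protein_id, gene_models,
                               config = scaffolder_config()) {
  gm <- gene_models[gene_models$protein_id == protein_id, ]
  empty <- tibble(cluster_id = integer(), protein_start = integer(),
                  protein_end = integer(), members = list())
  if (nrow(gm) == 0) return(empty)
  overlap_aa <- ceiling(config$cluster_overlap_nt / 3)
  grp <- link_intervals(gm$protein_start, gm$protein_end, overlap_aa)
  rows <- list()
  for (g in unique(grp)) {
    jj <- which(grp == g)
    best <- max(gm$similarity_score[jj])
    jj <- jj[gm$similarity_score[jj] >= config$alpha * best]
    members <- tibble(gene_model_id = gm$gene_model_id[jj],
                      contig_id = gm$contig_id[jj],
                      strand = gm$strand[jj],
                      score = gm$similarity_score[jj])
    rows[[length(rows) + 1L]] <- tibble(
      protein_start = min(gm$protein_start[jj]),
      protein_end = max(gm$protein_end[jj]),
      members = list(members))
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$protein_start, .data$protein_end)
  out$cluster_id <- seq_len(nrow(out))
  out[, c("cluster_id", "protein_start", "protein_end", "members")]
}

#' Enumerate paths through a protein's contig clusters
#'
#' A path picks at most one member per cluster (the empty choice is allowed
#' per cluster); its score is the sum of the members' similarity scores.
#' Paths scoring at least `beta` times the best path are retained. The
#' maximal scaffoldable set is the intersection of the retained non-empty
#' paths' members; by default, retained paths that are strict subsets of a
#' higher-scoring retained path are discarded before intersecting (dominance
#' pruning), which excludes in-paralog alternatives while keeping
#' unambiguous multi-cluster paths intact. `literal = TRUE` intersects all
#' retained non-empty paths as literally stated. The scaffolding power is the
#' summed score of the maximal set's members.
#'
#' When the number of paths would exceed `max_paths`, clusters are trimmed to
#' their top 3 members; if still over the cap, the model is scored by its
#' single best path (best member per cluster) and flagged `approximated`.
#'
#' @param clusters Cluster tibble from [cluster_on_protein()].
#' @param beta Fraction of the best path score in `[0, 1]`.
#' @param max_paths Path-count cap.
#' @param literal Use the literal intersection rule.
#' @return A list with `paths` (tibble `score`, `members` list-column, only
#'   when enumerated), `max_set` (character vector of gene model ids),
#'   `power` (bits), `n_paths`, `approximated`.
#' @export
enumerate_paths <- function(clusters, beta = 0.5, max_paths = 10000L,
                            literal = FALSE) {
  if (nrow(clusters) == 0) {
    return(list(paths = tibble(score = double(), members = list()),
                max_set = character(0), power = 0, n_paths = 0L,
                approximated = FALSE))
  }
  members <- clusters$members
  sizes <- vapply(members, nrow, integer(1))
  approximated <- FALSE
  if (prod(sizes + 1) > max_paths) {
    members <- lapply(members, function(m) {
      m[order(-m$score), ][seq_len(min(3L, nrow(m))), ]
    })
    sizes <- vapply(members, nrow, integer(1))
    approximated <- TRUE
  }
  if (prod(sizes + 1) > max_paths) {
    best <- lapply(members, function(m) m[which.max(m$score), ])
    ids <- vapply(best, function(m) m$gene_model_id, character(1))
    power <- sum(vapply(best, function(m) m$score, double(1)))
    return(list(paths = tibble(score = power, members = list(ids)),
                max_set = ids, power = power,
                n_paths = prod(sizes + 1), approximated = TRUE))
  }
  # choice matrix: one row per path, entry 0 = no member from that cluster
  grid <- as.matrix(expand.grid(lapply(sizes, function(s) 0:s),
                                KEEP.OUT.ATTRS = FALSE))
  k <- ncol(grid)
  scores <- numeric(nrow(grid))
  for (ci in seq_len(k)) {
    scores <- scores + c(0, members[[ci]]$score)[grid[, ci] + 1L]
  }
  best <- max(scores)
  retained <- which(scores >= beta * best & rowSums(grid) > 0)
  paths <- tibble(score = scores, n_members = rowSums(grid > 0))
  if (length(retained) == 0) {
    return(list(paths = paths, max_set = character(0), power = 0,
                n_paths = nrow(grid), approximated = approximated))
  }
  use <- retained
  if (!literal && length(retained) > 1) {
    # p is dominated iff some other retained path agrees with p on every
    # cluster where p chose a member (a strict superset; scores > 0 make
    # any strict superset strictly higher scoring)
    rc <- grid[retained, , drop = FALSE]
    dominated <- logical(length(retained))
    for (i in seq_along(retained)) {
      cand <- rep(TRUE, length(retained))
      for (ci in seq_len(k)) {
        if (rc[i, ci] > 0L) cand <- cand & (rc[, ci] == rc[i, ci])
      }
      dominated[i] <- sum(cand) > 1L
    }
    use <- retained[!dominated]
  }
  # the intersection of the used paths: a member is in every path iff its
  # cluster's choice is unanimous (and non-empty) across them
  uc <- grid[use, , drop = FALSE]
  max_set <- character(0); power <- 0
  for (ci in seq_len(k)) {
    v <- unique(uc[, ci])
    if (length(v) == 1L && v > 0L) {
      max_set <- c(max_set, members[[ci]]$gene_model_id[v])
      power <- power + members[[ci]]$score[v]
    }
  }
  if (length(max_set) == 0) power <- 0
  list(paths = paths, max_set = max_set, power = power,
       n_paths = nrow(grid), approximated = approximated)
}

#' Build one protein scaffold model
#'
#' Clusters the protein's gene models and runs the path enumeration.
#'
#' @param protein_id Guide protein id.
#' @param gene_models Gene-model tibble.
#' @param config A [scaffolder_config()].
#' @return A one-row tibble: `protein_id`, `n_clusters`, `n_paths`, `power`,
#'   `max_set` and `clusters` list-columns, `approximated`.
#' @export
build_protein_model <- function(protein_id, gene_models,
                                config = scaffolder_config()) {
  cl <- cluster_on_protein(protein_id, gene_models, config)
  pe <- enumerate_paths(cl, config$beta, config$max_paths,
                        config$literal_beta_rule)
  tibble(protein_id = protein_id, n_clusters = nrow(cl),
         n_paths = pe$n_paths, power = pe$power,
         max_set = list(pe$max_set), clusters = list(cl),
         approximated = pe$approximated)
}

#' Greedy selection of protein scaffold models
#'
#' Applies the alpha filter, builds a scaffold model per guide protein, then
#' iteratively commits the model with the highest scaffolding power (ties
#' broken lexicographically by protein id). After each pick, every gene
#' model whose PExR set overlaps a committed one is removed from the pool
#' and only the affected proteins' models are recomputed. Selection stops
#' when no model with positive power at or above `min_scaffolding_power`
#' remains.
#'
#' @param gene_models Gene-model tibble from [build_gene_models()].
#' @param config A [scaffolder_config()].
#' @return A tibble of committed models in pick order (`rank`, `protein_id`,
#'   `power`, `max_set`, `clusters`), with the alpha-filtered gene-model pool
#'   attached as attribute `"gene_models"`.
#' @export
greedy_select <- function(gene_models, config = scaffolder_config()) {
  gm <- alpha_uncouple(gene_models, config$alpha)
  pool <- gm
  models <- dplyr::bind_rows(lapply(unique(pool$protein_id), function(p) {
    build_protein_model(p, pool, config)
  }))
  committed <- list()
  floor_power <- max(config$min_scaffolding_power, .Machine$double.eps)
  while (nrow(models) > 0) {
    ok <- models$power >= floor_power & lengths(models$max_set) > 0
    if (!any(ok)) break
    cand <- models[ok, ]
    cand <- cand[order(-cand$power, cand$protein_id), ]
    pick <- cand[1, ]
    pick$rank <- length(committed) + 1L
    committed[[length(committed) + 1L]] <- pick
    used <- pick$max_set[[1]]
    used_px <- unlist(pool$pexr_ids[pool$gene_model_id %in% used])
    used_contigs <- unique(pool$contig_id[pool$gene_model_id %in% used])
    drop <- vapply(seq_len(nrow(pool)), function(i) {
      pool$contig_id[i] %in% used_contigs &&
        length(intersect(pool$pexr_ids[[i]], used_px)) > 0
    }, logical(1))
    affected <- setdiff(unique(pool$protein_id[drop]), pick$protein_id)
    pool <- pool[!drop, ]
    models <- models[models$protein_id != pick$protein_id, ]
    if (length(affected) > 0) {
      models <- models[!models$protein_id %in% affected, ]
      redo <- dplyr::bind_rows(lapply(affected, function(p) {
        build_protein_model(p, pool, config)
      }))
      models <- dplyr::bind_rows(models, redo)
    }
  }
  out <- if (length(committed) == 0) {
    tibble(rank = integer(), protein_id = character(), power = double(),
           max_set = list(), clusters = list(), n_clusters = integer(),
           n_paths = double(), approximated = logical())
  } else dplyr::bind_rows(committed)
  attr(out, "gene_models") <- gm
  out
}
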