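# Independent oracles: deliberately naive implementations used only to
# check the package's optimized code paths.

# PExR oracle: per-base boolean coverage scan.
oracle_pexrs <- function(blocks, contig_len) {
  cov <- logical(contig_len)
  for (i in seq_len(nrow(blocks))) {
    if (blocks$contig_end[i] > blocks$contig_start[i]) {
      cov[(blocks$contig_start[i] + 1):blocks$contig_end[i]] <- TRUE
    }
  }
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

# Path-enumeration oracle: recursive materialization of every choice
# combination; sets represented as sorted comma-joined strings.
oracle_paths <- function(clusters, beta, literal = FALSE) {
  # clusters: list of data.frames with id, score
  paths <- list(list(ids = character(0), score = 0))
  for (cl in clusters) {
    nxt <- list()
    for (p in paths) {
      nxt[[length(nxt) + 1]] <- p
      for (i in seq_len(nrow(cl))) {
        nxt[[length(nxt) + 1]] <- list(ids = c(p$ids, cl$id[i]),
                                       score = p$score + cl$score[i])
      }
    }
    paths <- nxt
  }
  scores <- vapply(paths, function(p) p$score, numeric(1))
  best <- max(scores)
  retained <- paths[scores >= beta * best &
                      vapply(paths, function(p) length(p$ids) > 0, logical(1))]
  if (length(retained) == 0) {
    return(list(max_set = character(0), power = 0, n_paths = length(paths)))
  }
  use <- retained
  if (!literal) {
    dominated <- vapply(seq_along(retained), function(i) {
      any(vapply(seq_along(retained), function(j) {
        i != j &&
          retained[[j]]$score > retained[[i]]$score &&
          length(retained[[i]]$ids) < length(retained[[j]]$ids) &&
          all(retained[[i]]$ids %in% retained[[j]]$ids)
      }, logical(1)))
    }, logical(1))
    use <- retained[!dominated]
  }
  max_set <- Reduce(intersect, lapply(use, function(p) p$ids))
  score_of <- function(id) {
    for (cl in clusters) {
      j <- match(id, cl$id)
      if (!is.na(j)) return(cl$score[j])
    }
    0
  }
  power <- if (length(max_set) == 0) 0 else sum(vapply(max_set, score_of, numeric(1)))
  list(max_set = sort(max_set), power = power, n_paths = length(paths))
}

# Max-weight colinear chain oracle: enumerate all subsets (<= 8 blocks).
oracle_chain_score <- function(blocks, strand) {
  n <- nrow(blocks)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(sel) == 0) next
    b <- blocks[sel, ]
    b <- b[order(b$protein_start), ]
    ok <- TRUE
    if (nrow(b) > 1) {
      for (i in seq_len(nrow(b) - 1)) {
        if (b$protein_start[i + 1] < b$protein_end[i]) { ok <- FALSE; break }
        if (strand == "+" && b$contig_start[i + 1] < b$contig_end[i]) { ok <- FALSE; break }
        if (strand == "-" && b$contig_end[i + 1] > b$contig_start[i]) { ok <- FALSE; break }
      }
    }
    if (ok) best <- max(best, sum(b$raw_score))
  }
  best
}

# All orderings of `contigs` consistent with directed precedence pairs
# (data.frame a, b meaning a before b). Exhaustive permutation search.
oracle_consistent_orders <- function(contigs, prec) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  ok <- list()
  for (p in perms(contigs)) {
    pos <- match(contigs, p)
    names(pos) <- contigs
    good <- all(pos[prec$a] < pos[prec$b])
    if (good) ok[[length(ok) + 1]] <- p
  }
  ok
}

oracle_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  tot <- sum(s)
  acc <- 0
  for (x in s) {
    acc <- acc + x
    if (acc >= tot / 2) return(x)
  }
}
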