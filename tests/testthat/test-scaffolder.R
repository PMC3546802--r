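test_that("alpha uncoupling removes competitors below the ratio threshold", {
  # one contig region mapped by two proteins; scores 70 vs 100 at alpha 0.75
  gm <- dplyr::bind_rows(
    make_gm("c1", "P1", pexr_ids = "c1:0-90", score = 70),
    make_gm("c1", "P2", pexr_ids = "c1:0-90", score = 100))
  out <- alpha_uncouple(gm, 0.75)
  expect_equal(out$protein_id, "P2")  # 70 < 0.75 * 100

  gm2 <- dplyr::bind_rows(
    make_gm("c1", "P1", pexr_ids = "c1:0-90", score = 80),
    make_gm("c1", "P3", pexr_ids = "c1:0-90", score = 100))
  expect_equal(nrow(alpha_uncouple(gm2, 0.75)), 2)  # 80 >= 75: both kept
})

test_that("alpha boundary semantics: 1 keeps only strict maxima, 0 removes nothing", {
  gm <- dplyr::bind_rows(
    make_gm("c1", "P1", pexr_ids = "c1:0-90", score = 99.9),
    make_gm("c1", "P2", pexr_ids = "c1:0-90", score = 100))
  expect_equal(alpha_uncouple(gm, 1)$protein_id, "P2")
  expect_equal(nrow(alpha_uncouple(gm, 0)), 2)
  # exact ties survive alpha = 1
  gm_tie <- dplyr::bind_rows(
    make_gm("c1", "P1", pexr_ids = "c1:0-90", score = 100),
    make_gm("c1", "P2", pexr_ids = "c1:0-90", score = 100))
  expect_equal(nrow(alpha_uncouple(gm_tie, 1)), 2)
})

test_that("contigs cluster on the protein only when intervals overlap enough", {
  cfg <- scaffolder_config()  # 15 nt = 5 aa
  gm <- dplyr::bind_rows(
    make_gm("c1", "P1", p0 = 0, p1 = 100, score = 100),
    make_gm("c2", "P1", p0 = 97, p1 = 200, score = 90))
  cl <- cluster_on_protein("P1", gm, cfg)
  expect_equal(nrow(cl), 2)  # overlap 3 aa < 5 aa
  gm2 <- dplyr::bind_rows(
    make_gm("c1", "P1", p0 = 0, p1 = 100, score = 100),
    make_gm("c2", "P1", p0 = 95, p1 = 200, score = 90))
  expect_equal(nrow(cluster_on_protein("P1", gm2, cfg)), 1)  # overlap 5 aa
})

test_that("within-cluster alpha filtering keeps members within the ratio", {
  cfg <- scaffolder_config(alpha = 0.75)
  gm <- dplyr::bind_rows(
    make_gm("c1", "P1", p0 = 0, p1 = 100, score = 100),
    make_gm("c2", "P1", p0 = 0, p1 = 100, score = 80),
    make_gm("c3", "P1", p0 = 0, p1 = 100, score = 70))
  cl <- cluster_on_protein("P1", gm, cfg)
  expect_equal(nrow(cl), 1)
  expect_setequal(cl$members[[1]]$contig_id, c("c1", "c2"))
  # a single gene model forms one untouched cluster
  cl1 <- cluster_on_protein("P1", gm[1, ], cfg)
  expect_equal(nrow(cl1), 1)
  expect_equal(nrow(cl1$members[[1]]), 1)
})

test_that("path enumeration: in-paralog pair in one cluster is excluded, shared partner kept", {
  cl <- make_clusters(list(data.frame(id = c("A", "B"), score = c(100, 95)),
                           data.frame(id = "C", score = 50)))
  # dominance rule: retained {A,C},{B,C} after pruning; intersection {C}
  pe <- enumerate_paths(cl, beta = 0.5)
  expect_setequal(pe$max_set, "C")
  expect_equal(pe$power, 50)
  expect_equal(pe$n_paths, 6)
  # literal rule: {A},{B},{A,C},{B,C} all retained; intersection empty
  pl <- enumerate_paths(cl, beta = 0.5, literal = TRUE)
  expect_equal(pl$max_set, character(0))
  expect_equal(pl$power, 0)
})

test_that("path enumeration: unambiguous two-cluster model survives dominance pruning", {
  cl <- make_clusters(list(data.frame(id = "A", score = 100),
                           data.frame(id = "C", score = 80)))
  pe <- enumerate_paths(cl, beta = 0.5)
  expect_setequal(pe$max_set, c("A", "C"))
  expect_equal(pe$power, 180)
  # literal rule: {C} = 80 misses beta * 180 = 90, so retained paths are
  # {A} and {A,C}; their intersection keeps A but loses C
  pl <- enumerate_paths(cl, beta = 0.5, literal = TRUE)
  expect_equal(pl$max_set, "A")
  expect_equal(pl$power, 100)
})

test_that("single-cluster model keeps its only member", {
  cl <- make_clusters(list(data.frame(id = "A", score = 100)))
  pe <- enumerate_paths(cl, beta = 0.5)
  expect_equal(pe$max_set, "A")
  expect_equal(pe$power, 100)
})

test_that("path enumeration matches the brute-force oracle on random instances", {
  set.seed(29)
  for (rep in 1:40) {
    k <- sample(1:5, 1)
    member_list <- lapply(seq_len(k), function(i) {
      nm <- sample(1:4, 1)
      data.frame(id = paste0("g", i, "_", seq_len(nm)),
                 score = round(stats::runif(nm, 10, 100), 1))
    })
    cl <- make_clusters(member_list)
    beta <- sample(c(0.3, 0.5, 0.8), 1)
    for (literal in c(FALSE, TRUE)) {
      pe <- enumerate_paths(cl, beta = beta, literal = literal)
      or <- oracle_paths(member_list, beta = beta, literal = literal)
      expect_setequal(pe$max_set, or$max_set)
      expect_equal(pe$power, or$power, tolerance = 1e-9)
      expect_equal(pe$n_paths, or$n_paths)
    }
  }
})

test_that("path cap triggers the documented approximation", {
  member_list <- lapply(1:6, function(i) {
    data.frame(id = paste0("g", i, "_", 1:5), score = c(50, 40, 30, 20, 10))
  })
  cl <- make_clusters(member_list)
  pe <- enumerate_paths(cl, beta = 0.5, max_paths = 100)
  expect_true(pe$approximated)
  expect_equal(length(pe$max_set), 6)  # best member per cluster
  expect_equal(pe$power, 6 * 50)
})

test_that("greedy selection shares contig regions at most once", {
  # P1 and P2 both want c2's gene model region; P1 is stronger
  gm <- dplyr::bind_rows(
    make_gm("c1", "P1", p0 = 0, p1 = 50, score = 100),
    make_gm("c2", "P1", p0 = 60, p1 = 110, score = 100,
            pexr_ids = "c2:0-150"),
    make_gm("c2", "P2", p0 = 0, p1 = 50, score = 90, pexr_ids = "c2:0-150"),
    make_gm("c3", "P2", p0 = 60, p1 = 110, score = 60))
  gm$pexr_ids[[1]] <- "c1:0-150"
  gm$pexr_ids[[4]] <- "c3:0-150"
  cfg <- scaffolder_config(alpha = 0)  # keep the competition for greedy to resolve
  sel <- greedy_select(gm, cfg)
  expect_equal(sel$protein_id[1], "P1")
  expect_equal(sel$power[1], 200)
  # P2 lost c2: recomputed model holds only c3
  p2 <- sel[sel$protein_id == "P2", ]
  expect_equal(p2$max_set[[1]], "c3|P2|+")
  expect_equal(p2$power, 60)
  # no gene model committed twice
  all_models <- unlist(sel$max_set)
  expect_equal(anyDuplicated(all_models), 0L)
})

test_that("selection order does not matter for disjoint proteins", {
  gm <- dplyr::bind_rows(
    make_gm("c1", "P1", p0 = 0, p1 = 50, score = 80, pexr_ids = "c1:0-150"),
    make_gm("c2", "P1", p0 = 60, p1 = 110, score = 70, pexr_ids = "c2:0-150"),
    make_gm("c3", "P2", p0 = 0, p1 = 50, score = 90, pexr_ids = "c3:0-150"),
    make_gm("c4", "P2", p0 = 60, p1 = 110, score = 60, pexr_ids = "c4:0-150"))
  sel <- greedy_select(gm, scaffolder_config())
  expect_setequal(sel$protein_id, c("P1", "P2"))
  expect_setequal(unlist(sel$max_set), gm$gene_model_id)
})

test_that("a minimum power above every model yields an empty selection", {
  gm <- make_gm("c1", "P1", pexr_ids = "c1:0-150", score = 50)
  sel <- greedy_select(gm, scaffolder_config(min_scaffolding_power = 1e6))
  expect_equal(nrow(sel), 0)
})

test_that("raising beta never shrinks a maximal scaffoldable set; raising alpha never enlarges cluster membership", {
  # fewer retained paths at high beta => their intersection can only grow
  set.seed(37)
  for (rep in 1:10) {
    k <- sample(2:4, 1)
    member_list <- lapply(seq_len(k), function(i) {
      nm <- sample(1:3, 1)
      data.frame(id = paste0("g", i, "_", seq_len(nm)),
                 score = round(stats::runif(nm, 10, 100), 1))
    })
    cl <- make_clusters(member_list)
    lo <- enumerate_paths(cl, beta = 0.3)
    hi <- enumerate_paths(cl, beta = 0.8)
    expect_true(all(lo$max_set %in% hi$max_set))
  }
  # alpha monotonicity through the within-cluster filter
  gm <- dplyr::bind_rows(
    make_gm("c1", "P1", p0 = 0, p1 = 100, score = 100),
    make_gm("c2", "P1", p0 = 0, p1 = 100, score = 80))
  lo_cl <- cluster_on_protein("P1", gm, scaffolder_config(alpha = 0.5))
  hi_cl <- cluster_on_protein("P1", gm, scaffolder_config(alpha = 0.9))
  expect_true(all(hi_cl$members[[1]]$gene_model_id %in%
                    lo_cl$members[[1]]$gene_model_id))
})
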