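test_that("the decay law evaluates and clamps per edge kind", {
  p <- decay_parameters()
  # covalent decay is distance-free at the default B = 0
  expect_equal(edge_decay(1.2, "covalent", p), 0.6)
  expect_equal(edge_decay(97, "covalent", p), 0.6)
  expect_equal(log(edge_decay(1.5, "covalent", p)), -0.5108256, tolerance = 1e-6)
  # H-bond exponent vanishes at the reference separation
  expect_equal(edge_decay(2.8, "hbond", p), 0.36)
  # space jump at 3.4 A: q = 0.6 * exp(-1.7 * (3.4 - 1.4))
  expect_equal(edge_decay(3.4, "space", p), 0.6 * exp(-3.4))
  expect_equal(log(edge_decay(3.4, "space", p)), log(0.6) - 3.4)
  # clamp: below the reference distance q never exceeds A
  expect_equal(edge_decay(0.5, "space", p), 0.6)
  expect_equal(edge_decay(1.0, "hbond", p), 0.36)
  expect_error(edge_decay(NaN, "space", p), "non-finite")
})

test_that("decay parameter validation rejects unphysical values", {
  expect_error(decay_parameters(covalent = list(A = 1.2, B = 0, R = 0)),
               "A must be")
  expect_error(decay_parameters(space = list(A = 0.6, B = -1, R = 0)))
})

test_that("a pure covalent chain scores n * ln(A) with the exact path", {
  for (n in c(1L, 4L, 10L)) {
    s <- make_covalent_chain(n)
    gt <- attr(s, "ground_truth")
    p <- best_path(transfer_graph(s), gt$donor, gt$acceptor)
    expect_equal(p$ln_k, n * log(0.6), tolerance = 1e-12)
    expect_equal(p$atom_count, n + 1L)
    expect_equal(p$kind_counts[["covalent"]], n)
    expect_equal(p$ln_k, sum(log(p$edge_decays)), tolerance = 1e-12)
  }
})

test_that("degenerate searches behave: identity and no-path sentinel", {
  g <- transfer_graph(make_covalent_chain(3))
  same <- best_path(g, 2, 2)
  expect_equal(same$ln_k, 0)
  expect_equal(same$atom_count, 1)
  expect_length(same$edge_decays, 0)
  edgeless <- make_random_graph(6, 0, seed = 1)
  lost <- best_path(edgeless, 1, 6)
  expect_false(lost$reachable)
  expect_equal(lost$ln_k, -Inf)
  lost2 <- brute_force_best_path(edgeless, 1, 6)
  expect_equal(lost2$ln_k, -Inf)
})

test_that("Dijkstra agrees with exhaustive enumeration on random graphs", {
  for (seed in 1:60) {
    g <- make_random_graph(10, 0.35, seed = seed)
    a <- best_path(g, 1, 10)
    b <- brute_force_best_path(g, 1, 10)
    expect_identical(a$atoms, b$atoms)
    expect_identical(a$ln_k, b$ln_k)
  }
})

test_that("best_path matches igraph shortest-path weights", {
  skip_if_not_installed("igraph")
  for (seed in c(3, 17, 44)) {
    g <- make_random_graph(12, 0.4, seed = seed)
    p <- best_path(g, 1, 12)
    ig <- igraph::graph_from_edgelist(as.matrix(g$edges[, c("i", "j")]),
                                      directed = FALSE)
    ig <- igraph::add_vertices(ig, max(0, 12 - igraph::vcount(ig)))
    w <- -log(edge_decay(g$edges$r, g$edges$kind, decay_parameters()))
    d <- igraph::distances(ig, v = 1, to = 12, weights = w)[1, 1]
    if (is.finite(d)) expect_equal(-p$ln_k, d, tolerance = 1e-10)
    else expect_false(p$reachable)
  }
})

test_that("path score is symmetric in donor and acceptor", {
  for (seed in c(2, 9, 23)) {
    g <- make_random_graph(9, 0.4, seed = seed)
    fwd <- best_path(g, 1, 9)
    rev <- best_path(g, 9, 1)
    expect_equal(fwd$ln_k, rev$ln_k)
  }
})

test_that("adding an edge never lowers ln(k); stretching one never raises it", {
  g <- make_random_graph(8, 0.35, seed = 5)
  base <- best_path(g, 1, 8)$ln_k
  g_plus <- g
  g_plus$edges <- rbind(g_plus$edges,
                        data.frame(i = 1L, j = 8L, kind = "space", r = 4,
                                   fe_his = FALSE))
  expect_gte(best_path(g_plus, 1, 8)$ln_k, base)
  g_far <- g_plus
  g_far$edges$r[g_far$edges$kind != "covalent"] <-
    g_far$edges$r[g_far$edges$kind != "covalent"] + 2
  expect_lte(best_path(g_far, 1, 8)$ln_k, best_path(g_plus, 1, 8)$ln_k)
})

test_that("residue ranking orders acceptors by hand-computed scores", {
  s <- mini_peroxidase()
  want <- mini_expected()
  r <- rank_residues(s)
  expect_equal(nrow(r), 3)
  expect_equal(r$resno, c(10L, 20L, 30L))     # Tyr10 > Trp20 > Tyr30
  expect_equal(r$acceptor, c("OH", "NE1", "OH"))
  expect_equal(r$ln_k, c(want$tyr10, want$trp20, want$tyr30),
               tolerance = 1e-12)
  expect_equal(r$atom_count, c(3L, 3L, 3L))
  expect_equal(r$uses_fe_his, c(FALSE, FALSE, TRUE))
  expect_true(all(diff(r$ln_k) <= 0))
})

test_that("forbidding the Fe-His link reroutes the proximal-side acceptor", {
  s <- mini_peroxidase()
  allowed <- rank_residues(s)
  blocked <- rank_residues(s, forbid_fe_his = TRUE)
  y30a <- allowed[allowed$resno == 30, ]
  y30b <- blocked[blocked$resno == 30, ]
  expect_true(y30a$uses_fe_his)
  expect_false(y30b$uses_fe_his)
  expect_lt(y30b$ln_k, y30a$ln_k)
})

test_that("residues lacking their acceptor atom are skipped with a warning", {
  s <- mini_peroxidase()
  s$atoms$name[s$atoms$name == "NE1"] <- "CD1"  # Trp ring atom, not NE1
  s2 <- et_structure(s$atoms, s$xyz[, , 1])
  expect_warning(r <- rank_residues(s2), "lacks acceptor atom")
  expect_equal(nrow(r), 2)
  expect_false("TRP" %in% r$resname)
})

test_that("candidate selection applies the ln(k) cutoff in order", {
  s <- mini_peroxidase()
  r <- rank_residues(s)
  mid <- mean(r$ln_k[2:3])
  sel <- select_candidates(r, mid)
  expect_equal(nrow(sel), 2)
  expect_equal(sel$resno, r$resno[1:2])
  expect_equal(nrow(select_candidates(r, min(r$ln_k) - 1)), 3)
  expect_equal(nrow(select_candidates(r, 0)), 0)
  expect_error(select_candidates(r[0, ], -1), "empty")
})

test_that("a structure without heme iron or acceptors errors", {
  s <- make_covalent_chain(3)
  expect_error(rank_residues(s), "no heme iron")
  expect_error(find_heme_fe(s), "no heme iron")
})
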