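nrps_cluster <- function(id, subs, strain = "s") {
  orgs <- paste(vapply(seq_along(subs), function(i) {
    a <- if (is.na(subs[i])) "A" else sprintf("A(%s)", subs[i])
    if (i == 1) paste0(a, "/T") else paste0("C/", a, "/T")
  }, character(1)), collapse = "-")
  bgc_cluster(id, "nrps", list(bgc_orf("o1", parse_domain_string(orgs))))
}

test_that("cluster similarity: identity, type mismatch and substrate swaps", {
  tp <- tp_inventory(); nb <- nbrc_inventory()
  n1a <- bgcrep:::get_cluster(tp, "nrps-1")
  n1b <- bgcrep:::get_cluster(nb, "nrps-1")
  expect_equal(cluster_similarity(n1a, n1a), 1)
  # identical printed domain organizations across the two strains
  expect_equal(cluster_similarity(n1a, n1b), 1)
  expect_equal(cluster_similarity(n1a, bgcrep:::get_cluster(tp, "t2pks-1")), 0)
  # one substrate call swapped out of four modules: (3 + 0.25) / 4
  c1 <- nrps_cluster("a", c("leu", "val", "thr", "gly"))
  c2 <- nrps_cluster("b", c("leu", "val", "thr", "ser"))
  expect_equal(cluster_similarity(c1, c2), 0.8125)
})

test_that("cluster similarity is symmetric and bounded", {
  tp <- tp_inventory(); nb <- nbrc_inventory()
  set.seed(5)
  picks <- expand.grid(i = seq_along(tp$clusters), j = seq_along(nb$clusters))
  for (k in sample(nrow(picks), 30)) {
    a <- tp$clusters[[picks$i[k]]]; b <- nb$clusters[[picks$j[k]]]
    s <- cluster_similarity(a, b)
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(s, cluster_similarity(b, a))
  }
})

test_that("conservation inference recovers the published conserved set", {
  cmap <- infer_conservation(tp_inventory(), nbrc_inventory())
  expect_identical(cmap$cluster_id_A,
                   c("nrps-1", "t1pks-1", "t1pks-2", "t2pks-1", "t3pks-1"))
  expect_identical(cmap$cluster_id_A, cmap$cluster_id_B)
  expect_identical(attr(cmap, "source"), "inferred")
})

test_that("inference edge cases: identical and disjoint inventories", {
  tp <- tp_inventory()
  self <- infer_conservation(tp, tp)
  expect_equal(nrow(self), length(tp$clusters))
  expect_true(all(self$score == 1))
  # all cross-scores below threshold leave the map empty
  a <- bgc_inventory("a", list(nrps_cluster("nrps-1", c("leu", "val"))))
  b <- bgc_inventory("b", list(nrps_cluster("nrps-1", c("pro", "orn", "gly",
                                                        "ser", "arg"))))
  expect_equal(nrow(infer_conservation(a, b, threshold = 0.9)), 0)
})

test_that("assignment matches brute-force permutation search on random instances", {
  set.seed(31)
  for (rep in 1:20) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    S <- matrix(round(runif(n1 * n2), 3), n1, n2)
    thr <- runif(1, 0.2, 0.8)
    Sthr <- S; Sthr[Sthr < thr] <- 0
    got <- bgcrep:::max_weight_matching(Sthr,
                                        sprintf("a%02d", seq_len(n1)),
                                        sprintf("b%02d", seq_len(n2)))
    expect_equal(sum(got$score), brute_force_matching_total(S, thr),
                 tolerance = 1e-9)
    expect_false(anyDuplicated(got$cluster_id_A) > 0)
    expect_false(anyDuplicated(got$cluster_id_B) > 0)
  }
})

test_that("RC arithmetic reproduces the published strain-pair percentages", {
  r <- compute_rc(tp_inventory(), nbrc_inventory(), example_conserved_map())
  expect_equal(c(r$A, r$B, r$Cab), c(9, 13, 5))
  expect_equal(r$RC, 45)
  expect_equal(r$RC_exact, 2 * 5 / 22 * 100)
  expect_equal(c(r$fracSharedA, r$fracSpecificA), c(56, 44))
  expect_equal(c(r$fracSharedB, r$fracSpecificB), c(38, 62))
  expect_setequal(r$sharedA,
                  c("t1pks-1", "t1pks-2", "t2pks-1", "t3pks-1", "nrps-1"))
  expect_setequal(r$specificA,
                  c("t2pks-2", "nrps-2", "pks/nrps-1", "pks/nrps-2"))
  expect_length(r$specificB, 8)
})

test_that("RC is symmetric, bounded, and 100 only for identical repertoires", {
  tp <- tp_inventory(); nb <- nbrc_inventory()
  cmap <- example_conserved_map()
  swapped <- conservation_map(data.frame(cluster_id_A = cmap$cluster_id_B,
                                         cluster_id_B = cmap$cluster_id_A,
                                         score = cmap$score))
  rab <- compute_rc(tp, nb, cmap); rba <- compute_rc(nb, tp, swapped)
  expect_equal(rab$RC_exact, rba$RC_exact)
  expect_equal(rab$sharedA, rba$sharedB)
  expect_equal(rab$specificB, rba$specificA)
  # identical repertoires: RC = 100
  self <- compute_rc(tp, tp, infer_conservation(tp, tp))
  expect_equal(self$RC_exact, 100)
  # empty map: RC = 0
  none <- conservation_map(data.frame(cluster_id_A = character(0),
                                      cluster_id_B = character(0)))
  expect_equal(compute_rc(tp, nb, none)$RC_exact, 0)
})

test_that("adding a conserved pair strictly increases RC", {
  tp <- tp_inventory(); nb <- nbrc_inventory()
  cmap <- example_conserved_map()
  for (k in 1:4) {
    sub <- conservation_map(as.data.frame(cmap)[seq_len(k), ])
    sub1 <- conservation_map(as.data.frame(cmap)[seq_len(k + 1), ])
    expect_lt(compute_rc(tp, nb, sub)$RC_exact,
              compute_rc(tp, nb, sub1)$RC_exact)
  }
})

test_that("maps referencing unknown clusters are rejected", {
  bad <- conservation_map(data.frame(cluster_id_A = "ghost-1",
                                     cluster_id_B = "nrps-1"))
  expect_error(compute_rc(tp_inventory(), nbrc_inventory(), bad),
               class = "bgcrep_unknown_cluster_id")
  expect_error(conservation_map(data.frame(cluster_id_A = c("a", "a"),
                                           cluster_id_B = c("b", "c"))),
               class = "bgcrep_format_error")
})
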