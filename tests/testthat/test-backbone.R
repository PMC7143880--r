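mod <- function(s) parse_domain_string(s)[[1]]

test_that("modules classify by domain content", {
  cases <- c("C/A(val)/T" = "NRPS_EXT",
             "C/A/T/E" = "NRPS_EXT",
             "A(leu)/T" = "NRPS_LOAD",
             "A/MT/T" = "NRPS_LOAD",
             "C/T" = "NRPS_NO_A",
             "KS/AT/DH/ER/KR/ACP" = "PKS_EXT",
             "ACP/KS" = "PKS_EXT",
             "KS" = "PKS_EXT",
             "CoL/T" = "PKS_LOAD",
             "TE" = "TERMINATION_ONLY",
             "TD" = "TERMINATION_ONLY",
             "A" = "FRAGMENT",
             "ACP" = "FRAGMENT",
             "AT/KR/ACP" = "FRAGMENT")
  for (s in names(cases)) expect_equal(classify_module(mod(s)), unname(cases[s]))
})

test_that("clusters classify by type from their domain inventory", {
  tp <- tp_inventory(); nb <- nbrc_inventory()
  for (inv in list(tp, nb)) {
    for (cl in inv$clusters) {
      expect_equal(classify_cluster(cl), cl$ctype, label = cl$cluster_id)
    }
  }
  expect_error(
    classify_cluster(bgc_cluster("frag-1", "t1pks", list(
      bgc_orf("o1", parse_domain_string("AT/KR"))))),
    class = "bgcrep_no_synthase_domains")
})

test_that("assembly-line ordering honours file order, explicit order and the heuristic", {
  tp <- tp_inventory()
  n1 <- bgcrep:::get_cluster(tp, "nrps-1")
  expect_equal(vapply(order_assembly_line(n1, "file_order"), `[[`, "", "locus_tag"),
               c("07_04820", "07_04810", "07_04800", "07_04790"))
  expect_error(order_assembly_line(n1, "explicit"),
               class = "bgcrep_missing_explicit_order")

  p2 <- bgcrep:::get_cluster(tp, "pks/nrps-2")
  expect_equal(vapply(order_assembly_line(p2, "explicit"), `[[`, "", "locus_tag"),
               c("08_01890", "08_01960", "08_01950", "08_01940"))
  # heuristic: loading ORF front, releasing ORF back
  expect_equal(vapply(order_assembly_line(p2, "heuristic"), `[[`, "", "locus_tag"),
               c("08_01890", "08_01960", "08_01950", "08_01940"))
  # singleton cluster is unchanged under every mode
  t3 <- bgcrep:::get_cluster(tp, "t3pks-1")
  for (m in c("file_order", "heuristic", "auto")) {
    expect_equal(vapply(order_assembly_line(t3, m), `[[`, "", "locus_tag"),
                 "03_03810")
  }
})

test_that("dissociated and standalone PKS clusters are rejected by the predictor", {
  tp <- tp_inventory()
  expect_error(predict_backbone(bgcrep:::get_cluster(tp, "t2pks-1")),
               class = "bgcrep_not_an_assembly_line")
  expect_error(predict_backbone(bgcrep:::get_cluster(tp, "t3pks-1")),
               class = "bgcrep_not_an_assembly_line")
})

test_that("type I PKS clusters emit one pk unit per extension module", {
  tp <- tp_inventory()
  expect_identical(format(predict_backbone(bgcrep:::get_cluster(tp, "t1pks-1"))),
                   "pk-pk")
  expect_identical(format(predict_backbone(bgcrep:::get_cluster(tp, "t1pks-2"))),
                   "pk-pk")
})

test_that("epimerization domains never change the emitted residue", {
  a <- format(predict_backbone(bgc_cluster("e0", "nrps", list(
    bgc_orf("o1", parse_domain_string("C/A(leu)/T-C/A(thr)/T-TE"))))))
  b <- format(predict_backbone(bgc_cluster("e1", "nrps", list(
    bgc_orf("o1", parse_domain_string("C/A(leu)/T/E-C/A(thr)/T/E-TE"))))))
  expect_identical(a, b)
})

test_that("residue count equals the number of NRPS modules walked", {
  set.seed(21)
  for (i in 1:25) {
    gp <- generate_pair(generator_config(nA = 3, nB = 3, nShared = 0,
                                         type_weights = c(nrps = 1),
                                         seed = 400 + i))
    for (cl in gp$invA$clusters) {
      classes <- unlist(lapply(cl$orfs, bgcrep:::orf_module_classes))
      n_expect <- sum(classes %in% c("NRPS_EXT", "NRPS_LOAD", "NRPS_NO_A"))
      bp <- predict_backbone(cl)
      expect_equal(length(unlist(bp$chains, recursive = FALSE)), n_expect)
    }
  }
})

test_that("predictions are deterministic across repeated runs", {
  nb <- nbrc_inventory()
  s1 <- vapply(c("nrps-3", "nrps-4", "nrps-5"), function(id)
    format(predict_backbone(bgcrep:::get_cluster(nb, id))), character(1))
  nb2 <- nbrc_inventory()
  s2 <- vapply(c("nrps-3", "nrps-4", "nrps-5"), function(id)
    format(predict_backbone(bgcrep:::get_cluster(nb2, id))), character(1))
  expect_identical(s1, s2)
})

test_that("chain splitting and partial flags follow release and truncation", {
  nb <- nbrc_inventory()
  # two released chains in one cluster
  bp5 <- predict_backbone(bgcrep:::get_cluster(nb, "nrps-5"))
  expect_length(bp5$chains, 2)
  expect_false(any(bp5$chain_partial))
  # open-ended chain: truncated ORF, no TE/TD on the last gene
  bp4 <- predict_backbone(bgcrep:::get_cluster(nb, "nrps-4"))
  expect_length(bp4$chains, 1)
  expect_true(bp4$chain_partial[1])
  # a complete, TE-released line is not partial
  tp <- tp_inventory()
  bp2 <- predict_backbone(bgcrep:::get_cluster(tp, "nrps-2"))
  expect_false(any(bp2$chain_partial))
})
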