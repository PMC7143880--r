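test_that("packaged strain fixtures load with the published structure", {
  tp <- tp_inventory()
  expect_s3_class(tp, "bgc_inventory")
  expect_length(tp$clusters, 9)
  expect_setequal(bgcrep:::cluster_ids(tp),
                  c("t1pks-1", "t1pks-2", "t2pks-1", "t2pks-2", "t3pks-1",
                    "nrps-1", "nrps-2", "pks/nrps-1", "pks/nrps-2"))

  nb <- nbrc_inventory()
  expect_length(nb$clusters, 13)
  g <- bgcrep:::get_cluster(nb, "pks/nrps-3")
  expect_identical(g$known_product, "Guadinomine, partial")
  expect_true(g$partial)

  # lower-bound sizes, thousands separators and scaffold-terminus marks
  s29 <- bgcrep:::get_cluster(nb, "t1pks-3")$orfs[[1]]
  expect_identical(s29$locus_tag, "s29-1")
  expect_true(s29$size_is_lower_bound)
  expect_true(s29$incomplete)
  expect_equal(s29$size_aa, 375L)
  n5 <- bgcrep:::get_cluster(nb, "nrps-5")
  expect_equal(n5$orfs[[3]]$size_aa, 1446L)
})

test_that("inventories round-trip through both file formats", {
  for (inv in list(tp_inventory(), nbrc_inventory())) {
    ftsv <- withr::local_tempfile(fileext = ".tsv")
    fjson <- withr::local_tempfile(fileext = ".json")
    write_inventory(inv, ftsv)
    write_inventory(inv, fjson)
    expect_true(bgcrep:::inventory_equal(inv, read_inventory(ftsv)))
    expect_true(bgcrep:::inventory_equal(inv, read_inventory(fjson)))
  }
})

test_that("canonical serialization uses the A(leu) substrate dialect", {
  inv <- bgc_inventory("s", list(
    bgc_cluster("nrps-1", "nrps", list(
      bgc_orf("orf1", parse_domain_string("C/A_(leu)_/T"), 500)))))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_inventory(inv, f)
  rows <- grep("^#", readLines(f), value = TRUE, invert = TRUE)
  expect_match(rows[2], "C/A\\(leu\\)/T")
  expect_no_match(rows[2], "_\\(")
})

test_that("an empty inventory is valid and round-trips", {
  inv <- bgc_inventory("barestrain")
  expect_length(inv$clusters, 0)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_inventory(inv, f)
  back <- read_inventory(f)
  expect_identical(back$strain_id, "barestrain")
  expect_length(back$clusters, 0)
})

test_that("structural validation rejects malformed inventories", {
  orf <- bgc_orf("o1", parse_domain_string("C/A/T"))
  cl <- bgc_cluster("nrps-1", "nrps", list(orf))
  expect_error(bgc_inventory("s", list(cl, cl)),
               class = "bgcrep_duplicate_cluster_id")
  expect_error(bgc_cluster("x", "nrps", list(orf, orf)),
               class = "bgcrep_format_error")
  expect_error(bgc_cluster("x", "nrps", list(orf), assembly_order = "nope"),
               class = "bgcrep_format_error")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("strain_id\tcluster_id", "s\tx"), f)
  expect_error(read_inventory(f), class = "bgcrep_format_error")
  expect_error(read_inventory("does/not/exist.tsv"),
               class = "bgcrep_io_error")
})

test_that("declared cluster types disagreeing with content warn, not error", {
  orf <- bgc_orf("o1", parse_domain_string("C/A/T-C/A(leu)/T"))
  expect_warning(bgc_inventory("s", list(bgc_cluster("odd-1", "t1pks", list(orf)))),
                 "classifies as nrps")
})
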