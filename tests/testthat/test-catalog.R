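cat_all <- load_catalog()

test_that("catalog counts match the published tallies", {
  gt <- filter_catalog(cat_all, region = c(471, 769), category = "GT-causing")
  expect_identical(nrow(gt), 16L)
  expect_identical(nrow(filter_catalog(cat_all, region = c(471, 769),
                                       category = "GT-causing",
                                       include_index = FALSE)), 15L)
  expect_identical(nrow(filter_catalog(cat_all, category = "HPA")), 2L)
  expect_identical(nrow(filter_catalog(cat_all, category = "database-only")),
                   3L)
})

test_that("expected records are present with their annotations", {
  expect_true(all(c("p.Ala477Pro", "p.Arg551Trp", "p.Arg551Gln",
                    "p.Asp591Ala", "p.Ile596Thr", "p.Gln626His",
                    "p.Cys705Arg", "p.Cys705Leu", "p.Arg755Pro",
                    "p.Arg755Gln") %in% cat_all$variant))
  idx <- cat_all[cat_all$index_case, ]
  expect_identical(idx$variant, "p.Asp591Ala")
  expect_identical(idx$cdna, "c.1772A>C")
  expect_identical(idx$rsid, "rs778608263")
  # database-only genu records carry their rsIDs
  db <- filter_catalog(cat_all, category = "database-only")
  expect_setequal(db$rsid, c("rs1126555", "rs749873100", "rs368974006"))
  # HPA systems
  hpa <- filter_catalog(cat_all, category = "HPA")
  expect_setequal(hpa$hpa_system, c("HPA-24b", "HPA-20b"))
  # the ambiguous printed frequency is stored verbatim, unparsed
  e673 <- cat_all[cat_all$variant == "p.Glu673Lys", ]
  expect_identical(e673$maf_text, "MAF 0.00002/8")
  expect_true(is.na(e673$maf_numeric))
  # the interface record is excluded, not GT-causing
  p772 <- cat_all[cat_all$variant == "p.Pro772Arg", ]
  expect_identical(p772$category, "excluded")
  expect_identical(p772$domain, "calf-1/2 interface")
})

test_that("mechanism filters single out the documented cases", {
  splice <- filter_catalog(cat_all, mechanism = "splicing_mRNA_decay")
  expect_identical(splice$variant, "p.Gln626His")
  ss <- filter_catalog(cat_all, mechanism = "disulfide_loss")
  expect_setequal(ss$variant, c("p.Cys705Arg", "p.Cys705Leu", "p.Cys633Ser"))
  # uncertain pathogenicity flag
  expect_identical(cat_all$variant[cat_all$uncertain], "p.Leu752Val")
  # empty predicate returns everything
  expect_identical(nrow(filter_catalog(cat_all)), nrow(cat_all))
})

test_that("domains are assigned from the boundary table", {
  expect_identical(assign_domain(477), "beta-propeller")
  expect_identical(assign_domain(591), "thigh")
  expect_identical(assign_domain(626), "thigh")
  expect_identical(assign_domain(633), "genu linker")
  expect_identical(assign_domain(639), "genu linker")
  expect_identical(assign_domain(673), "calf-1")
  expect_identical(assign_domain(705), "calf-1")
  expect_identical(assign_domain(772), "calf-1/2 interface")
  expect_true(is.na(assign_domain(1000)))
  # every GT-causing catalog record lands in a named domain
  gt <- filter_catalog(cat_all, category = "GT-causing")
  expect_false(anyNA(gt$domain))
})

test_that("schema violations are rejected on load", {
  bad <- cat_all
  path <- tempfile(fileext = ".tsv")
  bad$mechanisms[1] <- "teleportation"
  utils::write.table(bad[, 1:15], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  expect_error(load_catalog(path), "unknown mechanism")
})
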