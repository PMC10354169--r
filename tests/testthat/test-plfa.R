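test_that("saturation is classified from the double-bond count only", {
  expect_equal(
    classify_saturation(c("16:1w7", "18:2w6,9", "cy17:0", "10Me16:0",
                          "a15:0", "16:0", "19:1w9")),
    c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  expect_error(classify_saturation("notamarker"),
               class = "cuetrace_domain_error")
})

test_that("the packaged marker table is a disjoint exhaustive partition", {
  tab <- plfa_marker_table()
  expect_true(all(tab$primary_group %in% c("fungal", "bacterial", "general")))
  # the printed gram-positive and (cyclopropane) bacterial lists overlap;
  # the partition folds both into "bacterial"
  expect_true(all(tab$primary_group[tab$gram_positive | tab$bacterial] ==
                    "bacterial"))
  expect_setequal(tab$marker[tab$primary_group == "fungal"],
                  c("18:1w9c", "18:2w6,9"))
  expect_true(all(tab$unsaturated[tab$primary_group == "fungal"]))
  expect_false(ct_constants()$internal_standard %in% tab$marker)
})

test_that("internal-standard quantification is a linear single-point scale", {
  areas <- tibble::tibble(marker = c("16:0", "18:1w9c"), area = c(1e5, 5e4))
  q <- quantify_markers(areas, is_area = 1e5, is_amount = 5, dry_soil_g = 1)
  expect_equal(q$c_amount, c(5, 2.5))

  q2 <- quantify_markers(dplyr::mutate(areas, area = 2 * area),
                         1e5, 5, 1)
  expect_equal(q2$c_amount, 2 * q$c_amount)

  expect_error(quantify_markers(areas, 0, 5, 1),
               class = "cuetrace_quantification_error")
  expect_warning(quantify_markers(dplyr::mutate(areas, area = 0), 1e5, 5, 1))
})

test_that("relative abundance is simplex-valued and ignores the standard", {
  prof <- tibble::tibble(marker = c("16:0", "cy17:0", "19:0"),
                         c_amount = c(3, 1, 5))
  ra <- relative_abundance(prof)
  expect_equal(ra$fraction, c(0.75, 0.25))
  expect_equal(sum(ra$fraction), 1, tolerance = 1e-12)

  single <- relative_abundance(tibble::tibble(marker = "16:0", c_amount = 2))
  expect_equal(single$fraction, 1)

  perm <- relative_abundance(prof[c(2, 1, 3), ])
  expect_equal(perm$fraction[perm$marker == "16:0"], 0.75)

  expect_error(relative_abundance(tibble::tibble(marker = "16:0",
                                                 c_amount = 0)),
               class = "cuetrace_domain_error")
})

test_that("quantification-to-abundance composition cancels the standard amount", {
  areas <- tibble::tibble(marker = c("16:0", "cy17:0", "16:1w7"),
                          area = c(4e4, 1e4, 5e4))
  ra1 <- relative_abundance(quantify_markers(areas, 1e5, 5, 1))
  ra2 <- relative_abundance(quantify_markers(areas, 1e5, 50, 2.7))
  expect_equal(ra1$fraction, ra2$fraction, tolerance = 1e-12)
})

test_that("label allocation fractions behave on forced cases", {
  ctrl <- 1.08
  enrich <- function(f) ctrl + f * (10 - ctrl)
  prof <- tibble::tibble(
    marker = c("18:1w9c", "18:2w6,9", "16:0", "cy17:0"),
    c_amount = c(10, 10, 30, 20),
    at_percent = c(enrich(0.2), enrich(0.1), ctrl, ctrl)
  )
  prim <- label_allocation(prof, control_at = ctrl)
  expect_equal(prim$fraction[prim$group == "fungal"], 1)

  # equal label C in one saturated and one unsaturated marker
  prof2 <- tibble::tibble(
    marker = c("16:1w7", "16:0"),
    c_amount = c(10, 20),
    at_percent = c(enrich(0.2), enrich(0.1))
  )
  satu <- label_allocation(prof2, grouping = "saturation", control_at = ctrl)
  expect_equal(satu$fraction, c(0.5, 0.5), tolerance = 1e-12)

  expect_error(label_allocation(
    tibble::tibble(marker = "16:0", c_amount = 1, at_percent = ctrl),
    control_at = ctrl), class = "cuetrace_undefined_allocation")
})

test_that("allocation sums to one under both groupings on random profiles", {
  set.seed(19)
  tab <- plfa_marker_table()
  for (i in 1:10) {
    prof <- tibble::tibble(
      marker = tab$marker,
      c_amount = runif(nrow(tab), 0.5, 50),
      at_percent = 1.08 + runif(nrow(tab), 0, 0.4) * (10 - 1.08)
    )
    prim <- label_allocation(prof, tab, "primary", 1.08)
    satu <- label_allocation(prof, tab, "saturation", 1.08)
    expect_equal(sum(prim$fraction), 1, tolerance = 1e-9)
    expect_equal(sum(satu$fraction), 1, tolerance = 1e-9)
    expect_true(all(prim$fraction >= 0 & prim$fraction <= 1))
    expect_true(all(satu$fraction >= 0 & satu$fraction <= 1))
  }
})

test_that("total PLFA sums biomarkers and excludes the internal standard", {
  prof <- tibble::tibble(marker = c("16:0", "cy17:0", "16:1w7", "19:0"),
                         c_amount = c(10, 20, 30, 99))
  expect_equal(total_plfa(prof), 60)
  with_zero <- dplyr::bind_rows(
    prof, tibble::tibble(marker = "15:0", c_amount = 0))
  expect_equal(total_plfa(with_zero), 60)
})
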