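test_that("the five-instance mandatory-date scenario yields 40% / 2 of 5", {
  sc <- paper_scenarios()$completeness_40
  r <- run_analysis(sc$xml, statistics = FALSE, completeness = TRUE,
                    completeness_mode = "mandatory")
  cp <- r$completeness$mandatory_flag
  nd <- nodes_by_path(cp)
  item <- nd[[sc$expected$item_path]]
  grp <- nd[[sc$expected$group_path]]
  expect_identical(item$expected, 5L)
  expect_identical(item$completed, 2L)
  expect_equal(item$percentage, 40)
  expect_identical(grp$expected, 5L)
  expect_identical(grp$completed, 2L)
  # the recursion reaches the subject level
  expect_identical(cp$total_subjects, 1L)
  expect_identical(cp$completed_subjects, 0L)
})

test_that("instance completeness rules at each level", {
  # group instance with its mandatory item unfilled is incomplete, but a
  # non-mandatory group absent from a form leaves the form complete
  xml <- mini_odm()  # nothing mandatory; value present
  r <- run_analysis(xml, statistics = FALSE, completeness = TRUE)
  cp <- r$completeness$mandatory_flag
  expect_identical(cp$completed_subjects, 1L)
  expect_true(all(vapply(cp$nodes, function(n)
    n$completed == n$expected, TRUE)))

  # an empty-value tag makes its instance incomplete (present but empty)
  r2 <- run_analysis(sub('Value="5"', 'Value=""', mini_odm()),
                     statistics = FALSE, completeness = TRUE)
  cp2 <- r2$completeness$mandatory_flag
  nd <- nodes_by_path(cp2)
  expect_identical(nd[["SE1/F1/IG1/I1"]]$completed, 0L)
  expect_identical(nd[["SE1/F1/IG1/I1"]]$expected, 1L)
  expect_identical(cp2$completed_subjects, 0L)  # (b): present => complete
})

test_that("no-mandatory sparse data: every subject complete; all-mandatory: none", {
  sc <- paper_scenarios()
  r <- run_analysis(sc$no_mandatory_sparse$xml, statistics = FALSE,
                    completeness = TRUE, completeness_mode = "both")
  flag <- r$completeness$mandatory_flag
  expect_identical(flag$completed_subjects, flag$total_subjects)
  allm <- r$completeness$all_mandatory
  expect_identical(allm$completed_subjects, 0L)
  expect_identical(allm$total_subjects, 4L)
})

test_that("expected counts include parents lacking a mandatory child", {
  # subject without the (mandatory) event still contributes to expected
  xml <- sub('StudyEventOID="SE1" Mandatory="No"',
             'StudyEventOID="SE1" Mandatory="Yes"', mini_odm())
  xml <- sub("</SubjectData>\n </ClinicalData>",
             paste0("</SubjectData>\n  <SubjectData SubjectKey=\"S2\">\n",
                    "  </SubjectData>\n </ClinicalData>"), xml)
  r <- run_analysis(xml, statistics = FALSE, completeness = TRUE)
  cp <- r$completeness$mandatory_flag
  nd <- nodes_by_path(cp)
  expect_identical(nd[["SE1"]]$expected, 2L)   # 1 instance + 1 absent
  expect_identical(nd[["SE1"]]$completed, 1L)
  expect_identical(cp$total_subjects, 2L)
  expect_identical(cp$completed_subjects, 1L)
})

test_that("mode monotonicity and compare_modes on randomized fixtures", {
  for (seed in c(31L, 32L, 33L)) {
    fx <- generate_fixture(fixture_spec(seed = seed, subjects = 8L,
                                        missing_rate = 0.25))
    r <- run_analysis(fx$xml, statistics = FALSE, completeness = TRUE,
                      completeness_mode = "both")
    cmp <- compare_modes(r$completeness$mandatory_flag,
                         r$completeness$all_mandatory)
    expect_true(all(cmp$completed_all <= cmp$completed_flag))
    expect_true(all(cmp$expected_all >= cmp$expected_flag))
    # item-level completed counts are mode-independent
    it <- cmp[cmp$level == "item", ]
    expect_identical(it$completed_all, it$completed_flag)
  }
  # fully-filled data: no drops under the stricter mode
  full <- generate_fixture(fixture_spec(seed = 34L, subjects = 5L,
                                        missing_rate = 0,
                                        presence_prob = 1))
  r <- run_analysis(full$xml, statistics = FALSE, completeness = TRUE,
                    completeness_mode = "both")
  cmp <- compare_modes(r$completeness$mandatory_flag,
                       r$completeness$all_mandatory)
  expect_false(any(cmp$drops))
  expect_identical(r$completeness$all_mandatory$completed_subjects,
                   r$completeness$all_mandatory$total_subjects)
})

test_that("completeness equals the generator's independent oracle", {
  for (seed in c(41L, 42L)) {
    fx <- generate_fixture(fixture_spec(seed = seed, subjects = 10L,
                                        missing_rate = 0.2,
                                        repeat_prob = 0.4))
    p <- parse_odm(fx$xml)
    vd <- validate_dataset(p$metadata, p$clinical)
    for (mode in c("mandatory_flag", "all_mandatory")) {
      cp <- compute_completeness(p$metadata, vd$clean, mode)
      or <- fx$manifest$completeness[[mode]]
      expect_identical(cp$completed_subjects, or$completed_subjects)
      nd <- nodes_by_path(cp)
      for (i in seq_len(nrow(or$nodes))) {
        n <- nd[[or$nodes$path[i]]]
        expect_identical(n$expected, or$nodes$expected[i])
        expect_identical(n$completed, or$nodes$completed[i])
      }
    }
  }
})

test_that("never-instantiated branches report undefined percentage", {
  fx <- generate_fixture(fixture_spec(seed = 43L, subjects = 0L))
  r <- run_analysis(fx$xml, statistics = FALSE, completeness = TRUE)
  nd <- r$completeness$mandatory_flag$nodes
  non_mand <- Filter(function(n) !n$mandatory && n$expected == 0L, nd)
  expect_gt(length(non_mand), 0L)
  expect_true(all(vapply(non_mand, function(n) is.na(n$percentage), TRUE)))
})
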