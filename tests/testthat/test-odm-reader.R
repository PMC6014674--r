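test_that("detect_version accepts the supported set and rejects others", {
  expect_identical(detect_version(mini_odm()), "1.3.2")
  expect_identical(detect_version(mini_odm(odm_version = "1.3.0")), "1.3.0")
  v <- detect_version(mini_odm(odm_version = "1.2"))
  expect_true(is.na(v))
  expect_match(attr(v, "error"), "unsupported ODM version")
  no_attr <- sub(' ODMVersion="1.3.2"', "", mini_odm(), fixed = TRUE)
  expect_match(attr(detect_version(no_attr), "error"), "missing ODMVersion")
})

test_that("validate_structure passes conformant files and flags faults", {
  expect_identical(nrow(validate_structure(mini_odm())), 0L)
  fx <- generate_fixture(fixture_spec(seed = 11L, subjects = 4L))
  expect_identical(nrow(validate_structure(fx$xml)), 0L)

  # foreign-namespace extension element
  ext <- sub("<Protocol>",
             '<x:Hack xmlns:x="urn:x">no</x:Hack><Protocol>', mini_odm())
  errs <- validate_structure(ext)
  expect_true(any(grepl("outside the ODM namespace", errs$message)))

  # missing required attribute
  noid <- sub(' OID="I1"', "", mini_odm(), fixed = TRUE)
  errs <- validate_structure(noid)
  expect_true(any(grepl("missing required attribute OID", errs$message)))

  # malformed XML is itself a structural error, never an exception
  errs <- validate_structure("<ODM><unclosed>")
  expect_gt(nrow(errs), 0L)
  expect_true(any(grepl("parse failure", errs$message)))

  # non-UTF-8 encodings are rejected
  latin <- sub('encoding="UTF-8"', 'encoding="ISO-8859-1"', mini_odm())
  expect_true(any(grepl("UTF-8 required",
                        validate_structure(latin)$message)))

  # unknown data type name is a lexical error
  bad_dt <- sub('DataType="integer"', 'DataType="quantum"', mini_odm())
  expect_true(any(grepl("unknown ODM DataType",
                        validate_structure(bad_dt)$message)))

  # out-of-order children violate the schema sequence (Protocol must
  # precede the definition blocks)
  proto <- paste0("   <Protocol>\n",
                  '    <StudyEventRef StudyEventOID="SE1" Mandatory="No"/>\n',
                  "   </Protocol>\n")
  ooo <- sub(proto, "", mini_odm(), fixed = TRUE)
  ooo <- sub("  </MetaDataVersion>", paste0(proto, "  </MetaDataVersion>"),
             ooo, fixed = TRUE)
  expect_true(any(grepl("out of order", validate_structure(ooo)$message)))
})

test_that("parse_odm extracts a minimal file correctly", {
  p <- parse_odm(mini_odm(value = "5"))
  expect_identical(nrow(p$structural_errors), 0L)
  expect_identical(p$version, "1.3.2")
  expect_identical(nrow(p$clinical$items), 1L)
  expect_identical(p$clinical$items$value, "5")
  expect_identical(p$clinical$subject_keys, "S1")
  expect_length(positional_elements(p$metadata), 4L)
})

test_that("multiple Study / MetaDataVersion elements: first wins, warning recorded", {
  p <- parse_odm(mini_odm(n_studies = 2L))
  expect_identical(nrow(p$structural_errors), 0L)
  expect_true(any(grepl("Study elements", p$warnings)))
  expect_identical(p$metadata$study_oid, "ST1")

  p2 <- parse_odm(mini_odm(n_mdv = 2L))
  expect_true(any(grepl("MetaDataVersions", p2$warnings)))
})

test_that("empty and absent item values are recorded as missing, not \"\"", {
  p <- parse_odm(sub('Value="5"', 'Value=""', mini_odm()))
  expect_identical(nrow(p$clinical$items), 1L)
  expect_true(is.na(p$clinical$items$value))
})

test_that("parsing is deterministic", {
  xml <- generate_fixture(fixture_spec(seed = 12L, subjects = 5L))$xml
  p1 <- parse_odm(xml)
  p2 <- parse_odm(xml)
  expect_identical(p1$clinical, p2$clinical)
  expect_identical(lapply(positional_elements(p1$metadata), `[[`, "path"),
                   lapply(positional_elements(p2$metadata), `[[`, "path"))
})

test_that("structural failure aborts: no metadata or clinical data returned", {
  fx <- generate_fixture(fixture_spec(seed = 13L, subjects = 2L,
                                      structural_faults = "missing_oid"))
  p <- parse_odm(fx$xml)
  expect_gt(nrow(p$structural_errors), 0L)
  expect_null(p$metadata)
  expect_null(p$clinical)
  expect_true(all(nzchar(p$structural_errors$xml_path) |
                    !is.na(p$structural_errors$line)))
})
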