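test_that("TSV templates read with synonyms, defaults and validation", {
  p <- write_tsv_lines(c("id\tname\tcounts\tcolor\tnote",
                         "C01\tInfections\t5\t#FFFFFF\tfirst",
                         "C01.100\tSepsis\t\t\tsecond",
                         "C02\tVirus Diseases\t2.5\t\t"))
  t <- read_template(p)
  expect_s3_class(t$rows, "term_records")
  expect_identical(nrow(t$rows), 3L)
  expect_identical(t$rows$code, c("C01", "C01.100", "C02"))
  expect_identical(t$rows$label[2], "Sepsis")
  expect_identical(t$rows$count, c(5, 0, 2.5))        # empty count -> 0
  expect_identical(t$rows$color[1], "#FFFFFF")
  expect_identical(names(t$extra_columns), "note")
  expect_identical(t$extra_columns$note, c("first", "second", ""))

  bad_color <- write_tsv_lines(c("code\tcount\tcolor", "A\t1\t#GGHHII"))
  expect_error(read_template(bad_color), "row", class = "validation_error")
  bad_count <- write_tsv_lines(c("code\tcount", "A\tmany"))
  expect_error(read_template(bad_count), "1", class = "validation_error")
  no_code <- write_tsv_lines(c("label\tcount", "x\t1"))
  expect_error(read_template(no_code), class = "format_error")
  expect_error(read_template(tempfile("nope")), class = "io_error")
})

test_that("templates round-trip through TSV and XLSX identically", {
  t <- mini_template()
  t$rows$color[3] <- "#00FF00"
  t$rows$description[5] <- "an aminopenicillin"
  t$extra_columns <- data.frame(source = paste0("row", seq_len(nrow(t$rows))),
                                stringsAsFactors = FALSE)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  xlsx <- withr::local_tempfile(fileext = ".xlsx")
  write_template(t, tsv, "tsv")
  write_template(t, xlsx, "xlsx")
  from_tsv <- read_template(tsv)
  from_xlsx <- read_template(xlsx, "xlsx")
  expect_equal(from_tsv$rows, t$rows)
  expect_equal(from_tsv$extra_columns, t$extra_columns)
  # the two formats yield identical tables from equivalent content
  expect_equal(from_xlsx$rows, from_tsv$rows)
  expect_equal(from_xlsx$extra_columns, from_tsv$extra_columns)

  empty <- structure(list(rows = make_mini_atc()[0, ], extra_columns = NULL),
                     class = "template_table")
  expect_error(write_template(empty, tsv, "tsv"), class = "validation_error")
})

test_that("non-integer counts survive a write/read cycle numerically", {
  t <- structure(list(rows = term_records(c("A", "B"), count = c(0.125, 1e6)),
                      extra_columns = NULL), class = "template_table")
  for (fmt in c("tsv", "xlsx")) {
    p <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_template(t, p, fmt)
    expect_equal(read_template(p, fmt)$rows$count, c(0.125, 1e6))
  }
})

test_that("OBO is_a graphs unfold into positional records", {
  chain <- obo_text("[Term]", "id: T:1", "name: root", "",
                    "[Term]", "id: T:2", "name: mid", "is_a: T:1", "",
                    "[Term]", "id: T:3", "name: leaf", "is_a: T:2")
  r <- parse_obo(chain)
  expect_identical(nrow(r), 3L)
  expect_identical(oracle_level(r$code), c(1L, 2L, 3L))
  expect_identical(r$label, c("root", "mid", "leaf"))
  expect_true(all(r$count == 0))

  # diamond: D reachable via B and C -> two positional records
  diamond <- obo_text("[Term]", "id: A", "name: a", "",
                      "[Term]", "id: B", "name: b", "is_a: A", "",
                      "[Term]", "id: C", "name: c", "is_a: A", "",
                      "[Term]", "id: D", "name: d", "is_a: B", "is_a: C")
  rd <- parse_obo(diamond)
  expect_identical(sum(rd$description == "D"), 2L)
  expect_identical(nrow(rd), 5L)  # A, B, C, and D twice

  obsolete <- obo_text("[Term]", "id: A", "name: a", "",
                       "[Term]", "id: B", "name: b", "is_a: A",
                       "is_obsolete: true")
  expect_identical(parse_obo(obsolete)$description, "A")

  cyc <- obo_text("[Term]", "id: A", "name: a", "is_a: B", "",
                  "[Term]", "id: B", "name: b", "is_a: A")
  expect_error(parse_obo(cyc), class = "cycle_error")
  expect_error(parse_obo(obo_text("[Term]", "name: nameless")),
               class = "format_error")
})

test_that("OBO output always builds a valid generic forest", {
  set.seed(202)
  for (rep in 1:10) {
    # random DAG: each term picks 0-2 parents among earlier terms
    n <- sample(4:12, 1)
    stanzas <- character(0)
    for (i in seq_len(n)) {
      parents <- if (i == 1) integer(0)
      else sample(seq_len(i - 1), sample(0:min(2, i - 1), 1))
      stanzas <- c(stanzas, "[Term]", sprintf("id: X:%03d", i),
                   sprintf("name: term %d", i),
                   sprintf("is_a: X:%03d", parents), "")
    }
    recs <- parse_obo(obo_text(stanzas))
    f <- build_forest(recs, "generic")
    expect_s3_class(f, "ontology_forest")
    expect_identical(nrow(f), nrow(recs))  # unfolding is ancestor-closed
  }
})

test_that("MeSH descriptor XML yields one record per matching tree number", {
  xml <- paste0(
    "<DescriptorRecordSet>",
    "<DescriptorRecord><DescriptorUI>D001</DescriptorUI>",
    "<DescriptorName><String>Infection A</String></DescriptorName>",
    "<TreeNumberList><TreeNumber>C01.100</TreeNumber>",
    "<TreeNumber>C02.200</TreeNumber>",
    "<TreeNumber>D03.100</TreeNumber></TreeNumberList></DescriptorRecord>",
    "<DescriptorRecord><DescriptorUI>D002</DescriptorUI>",
    "<DescriptorName><String>No Tree</String></DescriptorName>",
    "</DescriptorRecord>",
    "</DescriptorRecordSet>")
  r <- parse_mesh_descriptor_xml(xml, "C")
  expect_identical(nrow(r), 2L)                     # D03.100 filtered out
  expect_identical(r$code, c("C01.100", "C02.200"))
  expect_identical(unique(r$label), "Infection A")  # poly-hierarchy replicates
  expect_identical(unique(r$description), "D001")
  expect_error(parse_mesh_descriptor_xml("<not<well>formed"),
               class = "format_error")
})

test_that("flat ATC tables become records; malformed rows are named", {
  r <- parse_atc_flat_table(data.frame(code = c("N", "N02BE01"),
                                       name = c("NERVOUS SYSTEM", "paracetamol")))
  expect_identical(nrow(r), 2L)
  expect_true(all(r$count == 0))
  expect_error(parse_atc_flat_table(data.frame(code = c("N", "N"),
                                               name = c("a", "b"))),
               class = "duplicate_code")
  expect_error(parse_atc_flat_table(data.frame(code = "N02BE015", name = "x")),
               "row 1", class = "malformed_code")
})
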