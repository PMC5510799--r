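test_that("bulk export writes one file per label and type", {
  g <- hexokinase_demo_graph()
  d <- tempfile()
  man <- write_bulk_csv(g, d)
  files <- man$files
  expect_equal(sum(files$kind == "nodes"), 4L)
  expect_equal(sum(files$kind == "relationships"), 6L)
  # row counts equal graph counts
  for (i in which(files$kind == "nodes"))
    expect_equal(files$rows[i], node_count(g, files$label_or_type[i]))
  for (i in which(files$kind == "relationships"))
    expect_equal(files$rows[i],
                 relationship_count(g, files$label_or_type[i]))
  # determinism: a second export is byte-identical
  d2 <- tempfile()
  write_bulk_csv(g, d2)
  for (f in list.files(d))
    expect_identical(readLines(file.path(d, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE), info = f)
  unlink(c(d, d2), recursive = TRUE)
})

test_that("an empty graph still writes headed node files", {
  d <- tempfile()
  man <- write_bulk_csv(kgraph(), d)
  expect_equal(sum(man$files$rows), 0L)
  expect_equal(sum(man$files$kind == "nodes"), 4L)
  for (f in man$files$file)
    expect_gt(length(readLines(file.path(d, f), warn = FALSE)), 0L)
  unlink(d, recursive = TRUE)
})

test_that("awkward names survive RFC 4180 quoting", {
  g <- kgraph()
  upsert_node(g, "Chemical", chemical_entity(
    "X1", name = 'acid, 2-"keto"', names = c("syn;colon", "plain")))
  d <- tempfile()
  write_bulk_csv(g, d)
  g2 <- read_bulk_csv(d)
  chem <- get_node(g2, "Chemical", "X1")
  expect_equal(chem$name, 'acid, 2-"keto"')
  unlink(d, recursive = TRUE)
})

test_that("write then read is the identity on built fixtures", {
  for (seed in c(1, 2)) {
    src <- tempfile()
    generate_fixture(fixture_spec(seed = seed), src)
    g <- suppressWarnings(build_graph(src))$graph
    d <- tempfile()
    write_bulk_csv(g, d)
    g2 <- read_bulk_csv(d)
    expect_true(graph_equal(g, g2), info = seed)
    unlink(c(src, d), recursive = TRUE)
  }
})

test_that("tampered and extended bulk files are handled", {
  g <- hexokinase_demo_graph()
  d <- tempfile()
  write_bulk_csv(g, d)
  # tamper a START_ID
  f <- file.path(d, "relationships_expresses.csv")
  lines <- readLines(f, warn = FALSE)
  lines[2] <- sub("^[^,]+", "999999", lines[2])
  writeLines(lines, f)
  expect_error(read_bulk_csv(d), class = "kg_validation_error")
  # restore, then add an unknown column
  write_bulk_csv(g, d)
  f <- file.path(d, "organisms.csv")
  lines <- readLines(f, warn = FALSE)
  lines[1] <- paste0(lines[1], ",habitat")
  lines[-1] <- paste0(lines[-1], ",gut")
  writeLines(lines, f)
  warns <- character()
  g2 <- withCallingHandlers(read_bulk_csv(d), warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  expect_true(any(grepl("habitat", warns)))
  expect_equal(get_node(g2, "Organism", "562")$habitat, "gut")
  # a file listed in the manifest must exist
  unlink(file.path(d, "chemicals.csv"))
  expect_error(read_bulk_csv(d), class = "kg_io_error")
  unlink(d, recursive = TRUE)
})

test_that("query results write as CSV and JSON", {
  rows <- data.frame(name = c("apigenin", 'x,"y"'),
                     formula = c("C15H10O5", NA),
                     stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".csv")
  write_results(rows, "csv", f)
  expect_length(readLines(f, warn = FALSE), 3L)   # header + 2 rows
  # csv -> rows -> csv round-trips byte-identically
  back <- read_results_csv(f)
  f2 <- tempfile(fileext = ".csv")
  write_results(back, "csv", f2)
  expect_identical(readLines(f, warn = FALSE), readLines(f2, warn = FALSE))
  j <- tempfile(fileext = ".json")
  write_results(rows[0, ], "json", j)
  expect_equal(readLines(j, warn = FALSE), "[]")
  write_results(rows, "json", j)
  parsed <- jsonlite::read_json(j, simplifyVector = TRUE)
  expect_equal(parsed$name, rows$name)
  expect_error(write_results(rows, "xml", tempfile()),
               class = "kg_validation_error")
})
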