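demo_features <- function(n = 3L) {
  data.frame(family = "glcm",
             name = paste("Feature", seq_len(n)),
             value = as.numeric(seq_len(n)) + 0.5,
             ibsi_code = paste0("local_f", seq_len(n)),
             config_fingerprint = "deadbeef",
             stringsAsFactors = FALSE)
}

test_that("feature names map to IBSI codes with local fallback", {
  tbl <- mapping_table()
  expect_equal(nrow(tbl), 105L)
  expect_identical(tbl$code[tbl$native_name == "firstorder Entropy"], "TLU2")
  expect_identical(tbl$code[tbl$native_name == "glcm Joint Entropy"], "TU9B")
  expect_identical(sum(tbl$source == "ibsi"), 2L)
  m <- suppressMessages(map_features(c("glcm Joint Entropy",
                                       "my_custom_feature")))
  expect_identical(m$code, c("TU9B", "local_my_custom_feature"))
  expect_identical(m$source, c("ibsi", "local"))
})

test_that("user mapping files override and extend the built-in table", {
  p <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(
    native_name = c("firstorder Mean", "exotic thing"),
    ontology_code = c("Q4LE", "X999")), p, row.names = FALSE)
  tbl <- mapping_table(p)
  expect_identical(tbl$code[tbl$native_name == "firstorder Mean"], "Q4LE")
  expect_identical(tbl$code[tbl$native_name == "exotic thing"], "X999")
  expect_equal(nrow(tbl), 106L)
})

test_that("graph shape: one value literal per feature, shared run nodes", {
  spec_dir <- withr::local_tempdir()
  case <- sphere_case(spec_dir)
  vol <- read_series(case$series_dir)
  roi <- read_structset(case$rtstruct_path)$rois[[1]]
  cfg <- extraction_config()
  feats <- extract_all(vol, rasterize(roi, vol), cfg)
  g <- build_graph(feats, "PH-001", "GTV-1", cfg)

  df <- as.data.frame(g)
  has_value <- df$p == "http://www.radiomics.org/RO/hasValue"
  expect_identical(sum(has_value), 105L)
  sw_nodes <- unique(df$o[df$p == "http://www.radiomics.org/RO/computedWith"])
  expect_length(sw_nodes, 1L)
  st_nodes <- unique(df$o[df$p == "http://www.radiomics.org/RO/usedSettings"])
  expect_length(st_nodes, 1L)
  # every feature node reaches the patient node through its VOI
  reach <- query_graph(g, "?f ro:hasValue ?v . ?f ro:ofVOI ?voi . ?voi roo:ofPatient ?p")
  expect_identical(nrow(reach), 105L)
  expect_length(unique(reach$p), 1L)
})

test_that("two VOIs of one patient share the patient node", {
  cfg <- extraction_config()
  g1 <- build_graph(demo_features(), "P9", "GTV-1", cfg)
  g2 <- build_graph(demo_features(), "P9", "GTV-2", cfg)
  g <- graph_union(g1, g2)
  vois <- query_graph(g, "?voi roo:ofPatient ?p")
  expect_identical(nrow(vois), 2L)
  expect_length(unique(vois$p), 1L)
})

test_that("graph construction rejects unlinkable input", {
  expect_error(build_graph(demo_features(), "", "GTV", extraction_config()),
               "patient_id")
  expect_error(build_graph(demo_features()[0, ], "P", "GTV",
                           extraction_config()), "empty")
})

test_that("serialize then parse is the identity on triple sets", {
  cfg <- extraction_config()
  g <- build_graph(demo_features(5L), "P1", "V1", cfg)
  key <- function(x) sort(paste(x$s, x$p, x$o, x$o_type))
  for (fmt in c("ntriples", "turtle")) {
    p <- withr::local_tempfile(
      fileext = if (fmt == "turtle") ".ttl" else ".nt")
    serialize_graph(g, p, fmt)
    expect_identical(key(parse_graph(p)), key(g))
  }
  # empty graph serializes to an empty (or prefix-only) document and back
  p <- withr::local_tempfile(fileext = ".nt")
  serialize_graph(triple_graph(), p, "ntriples")
  expect_identical(nrow(parse_graph(p)), 0L)
})

test_that("decimal literals keep 15 significant digits through round trips", {
  v <- c(1 / 3, pi * 1e6, 2.5e-7)
  f <- demo_features(3L); f$value <- v
  g <- build_graph(f, "P1", "V1", extraction_config())
  p <- withr::local_tempfile(fileext = ".nt")
  serialize_graph(g, p)
  got <- query_graph(parse_graph(p), "?f ro:hasValue ?v")
  expect_setequal(got$v, sprintf("%.15g", v))
})

test_that("query results and CSV rows carry identical values", {
  spec_dir <- withr::local_tempdir()
  case <- sphere_case(spec_dir)
  vol <- read_series(case$series_dir)
  roi <- read_structset(case$rtstruct_path)$rois[[1]]
  cfg <- extraction_config()
  feats <- extract_all(vol, rasterize(roi, vol), cfg)
  g <- build_graph(feats, vol$patient_id, roi$name, cfg)
  p <- withr::local_tempfile(fileext = ".csv")
  features_to_csv(feats, vol$patient_id, roi$name, p)
  csv <- utils::read.csv(p, colClasses = "character")
  expect_identical(nrow(csv), 105L)
  q <- query_graph(g, "?f ro:hasValue ?v . ?f rdfs:label ?name")
  expect_identical(nrow(q), 105L)
  csv_key <- sort(paste(paste(csv$family, csv$name), csv$value))
  q_key <- sort(paste(q$name, q$v))
  expect_identical(q_key, csv_key)
})

test_that("five-variable provenance query separates software in a merged graph", {
  f <- demo_features(2L)
  cfg_a <- extraction_config(software_name = "radsem",
                             software_version = "0.1.0",
                             software_language = "R")
  cfg_b <- extraction_config(software_name = "matlab-radiomics",
                             software_version = "2.1",
                             software_language = "MATLAB")
  g <- graph_union(build_graph(f, "P1", "GTV", cfg_a),
                   build_graph(f, "P2", "GTV", cfg_b))
  res <- query_graph(g, paste(
    "?f ro:ofVOI ?voi . ?voi roo:ofPatient ?p . ?p roo:hasID ?id .",
    "?f rdfs:label ?name . ?f ro:computedWith ?sw .",
    "?sw ro:programmingLanguage ?lang . ?sw ro:softwareVersion ?ver .",
    "?f ro:hasValue ?v"))
  expect_identical(names(res), c("f", "voi", "p", "id", "name", "sw",
                                 "lang", "ver", "v"))
  expect_identical(nrow(res), 4L)  # 2 features x 2 runs
  expect_setequal(unique(res$lang), c("R", "MATLAB"))
  by_pat <- split(res$lang, res$id)
  expect_identical(unique(by_pat$P1), "R")
  expect_identical(unique(by_pat$P2), "MATLAB")
})

test_that("merging graphs is a set union", {
  f <- demo_features(2L)
  cfg <- extraction_config()
  g1 <- build_graph(f, "P1", "GTV", cfg)
  expect_identical(nrow(graph_union(g1, g1)), nrow(g1))
  g2 <- build_graph(f, "P2", "GTV", cfg)
  gu <- graph_union(g1, g2)
  expect_lt(nrow(gu), nrow(g1) + nrow(g2))  # shared software/settings nodes
  expect_identical(nrow(gu), nrow(unique(rbind(as.data.frame(g1),
                                               as.data.frame(g2)))))
})

test_that("query handles empty graphs and degenerate patterns", {
  expect_identical(nrow(query_graph(triple_graph(), "?s ?p ?o")), 0L)
  g <- build_graph(demo_features(1L), "P1", "V", extraction_config())
  expect_error(query_graph(g, "   "), "empty")
  expect_error(query_graph(g, "?a ?b"), "malformed")
  everything <- query_graph(g, "?s ?p ?o")
  expect_identical(nrow(everything), nrow(g))
})

test_that("concordance correlation follows its closed forms", {
  expect_equal(ccc(c(1.5, 2.5, 9), c(1.5, 2.5, 9)), 1)
  # equal means and variances: CCC equals Pearson r
  x <- c(1, 2, 3, 4, 6); y <- c(6, 4, 2, 3, 1)
  expect_equal(ccc(x, y), stats::cor(x, y), tolerance = 1e-12)
  # perfectly anti-correlated with equal moments
  expect_equal(ccc(c(1, 2, 3), c(3, 2, 1)), -1)
  # symmetry and the |r| bound
  set.seed(2)
  for (trial in 1:10) {
    a <- stats::rnorm(20); b <- 2 * a + stats::rnorm(20)
    expect_equal(ccc(a, b), ccc(b, a), tolerance = 1e-12)
    expect_lte(abs(ccc(a, b)), abs(stats::cor(a, b)) + 1e-12)
  }
  # both constant and equal -> 1 by convention
  expect_equal(ccc(c(2, 2), c(2, 2)), 1)
  expect_error(ccc(1, numeric(0)))
})
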