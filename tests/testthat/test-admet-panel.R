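# The 20-endpoint ADMET panel registry, endpoint training and prediction.

test_that("default panel registry satisfies its structural contract", {
  panel <- default_panel()
  expect_equal(nrow(panel), 20L)
  expect_true(all(c("HIA", "Caco-2") %in% panel$name))
  expect_equal(sum(panel$category == "distribution/transporter"), 6L)
  expect_false(anyDuplicated(panel$name) > 0)
  expect_true(all(c("Hepatotoxicity", "Mutagenicity", "OralAcuteToxicity",
                    "Genotoxicity", "Carcinogenicity",
                    "RespiratoryToxicity", "OralBioavailability",
                    "MitochondrialMembranePotential", "OATP1B1-inh",
                    "OATP1B3-inh", "Clearance") %in% panel$name))
})

test_that("panel config round-trips through YAML", {
  cfgfile <- tempfile(fileext = ".yaml")
  eps <- lapply(seq_len(3), function(i) {
    list(name = paste0("E", i), category = "toxicity", min_records = 100)
  })
  yaml::write_yaml(list(endpoints = eps), cfgfile)
  got <- read_panel_config(cfgfile)
  expect_equal(got$name, c("E1", "E2", "E3"))
  expect_equal(got$min_records, rep(100L, 3))
  eps[[2]]$name <- "E1"
  yaml::write_yaml(list(endpoints = eps), cfgfile)
  expect_error(read_panel_config(cfgfile), "unique")
})

test_that("endpoint training separates strong signal and not permuted labels", {
  spec <- default_panel()[1, ]
  dat <- generate_endpoint_dataset(600, effect = 3, seed = 1)
  m <- train_endpoint(spec, dat, seed = 1)
  expect_s3_class(m, "endpoint_model")
  expect_gte(m$metrics$accuracy, 0.9)
  perm <- dat
  set.seed(42)
  perm$label <- sample(dat$label)  # permuted labels
  mp <- suppressWarnings(train_endpoint(spec, perm, seed = 1))
  expect_gte(mp$metrics$accuracy, 0.4)
  expect_lte(mp$metrics$accuracy, 0.6)
})

test_that("min_records gate blocks small endpoint sets unless permissive", {
  spec <- default_panel()[1, ]
  small <- generate_endpoint_dataset(100, effect = 3, seed = 2)
  expect_error(train_endpoint(spec, small, seed = 1), "min_records")
  expect_s3_class(suppressWarnings(
    train_endpoint(spec, small, seed = 1, permissive = TRUE)),
    "endpoint_model")
  onecls <- small; onecls$label <- 1L
  expect_error(train_endpoint(spec, onecls, seed = 1, permissive = TRUE),
               "class")
})

test_that("panel prediction is a deterministic 20-vector of probabilities", {
  panel <- test_panel()
  x <- generate_endpoint_dataset(4, effect = 0, seed = 9)
  v <- predict_panel(panel, as.matrix(x[-1]))
  expect_equal(dim(v), c(4L, 20L))
  expect_equal(colnames(v), default_panel()$name)
  expect_true(all(v >= 0 & v <= 1))
  expect_identical(v, predict_panel(panel, as.matrix(x[-1])))
})

test_that("panel output order follows the registry order (permutation consistency)", {
  panel <- test_panel()
  x <- as.matrix(generate_endpoint_dataset(3, effect = 0, seed = 5)[-1])
  v <- predict_panel(panel, x)
  perm <- rev(seq_along(panel))
  panel_r <- structure(unclass(panel)[perm], class = "admet_panel")
  v_r <- predict_panel(panel_r, x)
  expect_equal(unname(v_r), unname(v[, perm]))
  expect_equal(colnames(v_r), colnames(v)[perm])
})

test_that("a one-sided endpoint pins its probability near 1", {
  spec <- default_panel()[1, ]
  dat <- generate_endpoint_dataset(400, effect = 0, seed = 3)
  dat$label <- c(rep(1L, 398), rep(0L, 2))
  m <- suppressWarnings(train_endpoint(spec, dat, seed = 3,
                                       permissive = TRUE))
  x <- as.matrix(generate_endpoint_dataset(10, effect = 0, seed = 4)[-1])
  p <- predict_prob(m$classifier, apply_descriptor_scaler(x, m$scaler))
  expect_true(all(p >= 0.99))
})

test_that("panel manifest hashes content", {
  panel <- test_panel()
  man <- panel_manifest(panel)
  expect_equal(nrow(man$endpoints), 20L)
  expect_match(man$hash, "^[0-9a-f]{8}$")
})
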