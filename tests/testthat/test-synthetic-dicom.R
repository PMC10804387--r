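test_that("blank quota is exact and the draw is deterministic", {
  cfg <- generator_config(100, blank_fraction = 0.1, seed = 7)
  m1 <- generate_archive(cfg, write_files = FALSE)
  expect_identical(sum(m1$blank), 10L)
  m2 <- generate_archive(cfg, write_files = FALSE)
  expect_identical(m1, m2)
  # manifest file is byte-identical across runs too
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_archive(cfg, out_dir = d1, write_files = FALSE)
  generate_archive(cfg, out_dir = d2, write_files = FALSE)
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
})

test_that("an all-Diffusion archive carries diffusion keywords on every non-blank series", {
  mix <- c(Diffusion = 1)
  cfg <- generator_config(120, class_mix = mix, blank_fraction = 0.1,
                          seed = 5)
  m <- generate_archive(cfg, write_files = FALSE)
  keywords <- c("dw", "dwi", "diff", "adc", "diffusion")
  nb <- which(!m$blank)
  expect_gt(length(nb), 0)
  for (i in nb) {
    texts <- normalize_text(m$series_description[i])
    texts <- paste(texts, normalize_text(m$protocol_name[i]))
    expect_true(any(vapply(keywords, grepl, TRUE, x = texts, fixed = TRUE)),
                label = sprintf("series %d text '%s'", i, texts))
  }
})

test_that("every vendor template maps to its intended label under the default rules", {
  tpl <- describe_templates()
  got <- vapply(tpl$template, label_text, "", USE.NAMES = FALSE)
  expect_identical(got, tpl$label)
  # compound templates exercising precedence are present
  expect_true(any(grepl("T1 FLAIR", tpl$template[tpl$label == "T1"])))
  expect_true(any(grepl("tof|mra|TOF|MRA", tpl$template[tpl$label == "MRA"])))
})

test_that("rule labels reproduce manifest truth exactly on the non-blank partition", {
  ds <- make_dataset(400, seed = 13)
  p <- ds$partition
  expect_identical(ds$decisions$label[p$labeled],
                   ds$manifest$true_label[p$labeled])
  expect_identical(length(p$blank), as.integer(round(0.129 * 400)))
})

test_that("class frequencies and attribute missingness track the configuration", {
  n <- 1000L
  ds <- make_dataset(n, seed = 21)
  mix <- hospital_archive_config(n)$class_mix
  counts <- table(factor(ds$manifest$true_label, levels = names(mix)))
  # counts are allocated by largest remainder: within 1 of expectation
  expect_true(all(abs(as.integer(counts) - mix * n) <= 1))

  rates <- c(scan_options = 0.25, body_part_examined = 0.15,
             imaging_frequency = 0.05, sequence_variant = 0.05)
  for (attr in names(rates)) {
    col <- ds$records[[attr]]
    observed <- if (is.list(col)) {
      mean(vapply(col, is.null, TRUE))
    } else {
      mean(is.na(col))
    }
    p <- rates[[attr]]
    tol <- 3 * sqrt(p * (1 - p) / n)
    expect_lt(abs(observed - p), tol + 1e-12, label = attr)
  }
})

test_that("ambiguity injection adds rule-defeating texts beyond the blank quota", {
  cfg0 <- generator_config(300, blank_fraction = 0.1, seed = 3)
  cfg1 <- generator_config(300, blank_fraction = 0.1, seed = 3,
                           ambiguity_rate = 0.1)
  m0 <- generate_archive(cfg0, write_files = FALSE)
  m1 <- generate_archive(cfg1, write_files = FALSE)
  expect_identical(sum(m0$blank), 30L)
  expect_gt(sum(m1$blank), sum(m0$blank))
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(100, class_mix = c(T1 = 0.6, T2 = 0.6)),
               "sum to 1")
  expect_error(generator_config(100, blank_fraction = 1.2), "blank_fraction")
  expect_error(generator_config(100, class_mix = c(Bogus = 1)), "class_mix")
  expect_error(generator_config(0), "n_series")
})

test_that("manifests round trip through their CSV form", {
  ds <- make_dataset(50, seed = 17)
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(ds$manifest, path)
  back <- read_manifest(path)
  expect_equal(as.data.frame(back), as.data.frame(ds$manifest),
               tolerance = 1e-12)
})
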