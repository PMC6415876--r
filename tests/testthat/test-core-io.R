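test_that("video round-trip through a TIFF stack preserves frames exactly", {
  sc <- gen_motility_video(small_scene(3, seed = 2))
  path <- file.path(withr::local_tempdir(), "scene.tif")
  write_video(sc$video, path)
  back <- read_video(path, fps = sc$video$fps)
  expect_length(back, length(sc$video))
  expect_identical(dim(back$frames[[1]]), dim(sc$video$frames[[1]]))
  expect_equal(back$frames, sc$video$frames, ignore_attr = TRUE)

  truncated <- read_video(path, max_frames = 10)
  expect_length(truncated, 10L)
  expect_equal(truncated$frames[[1]], sc$video$frames[[1]], ignore_attr = TRUE)
})

test_that("unreadable containers and empty inputs raise classed errors", {
  txt <- withr::local_tempfile(fileext = ".tif")
  writeLines("not a tiff", txt)
  expect_error(read_video(txt), class = "spermfx_decode_error")
  expect_error(read_video(file.path(tempdir(), "nope.tif")),
               class = "spermfx_decode_error")
  empty_dir <- withr::local_tempdir()
  expect_error(read_video(empty_dir), class = "spermfx_empty_input_error")
  expect_error(frame_sequence(list(matrix(0, 2, 2))),
               class = "spermfx_empty_input_error")
  expect_error(frame_sequence(list(matrix(0, 2, 2), matrix(0, 3, 2))),
               class = "spermfx_shape_error")
})

test_that("read_image collapses colour to ITU-R 601 luminance on 0-255", {
  d <- withr::local_tempdir()
  black <- file.path(d, "black.png")
  png::writePNG(array(0, dim = c(16, 16)), black)
  img <- read_image(black)
  expect_true(all(img == 0))

  rgb <- array(0, dim = c(8, 8, 3))
  rgb[, , 1] <- 1  # pure red
  redf <- file.path(d, "red.png")
  png::writePNG(rgb, redf)
  expect_true(all(read_image(redf) == round(0.299 * 255)))

  gray <- matrix(0:63, 8, 8)        # exact 8-bit levels
  tf <- file.path(d, "gray.tif")
  tiff::writeTIFF(gray / 255, tf, bits.per.sample = 8L)
  expect_equal(read_image(tf), gray, ignore_attr = TRUE)

  bad <- file.path(d, "trunc.png")
  writeBin(as.raw(c(137, 80, 78, 71)), bad)
  expect_error(read_image(bad), class = "spermfx_decode_error")
})

test_that("measurement tables load from CSV, drop incomplete rows, and flag schema errors", {
  d <- withr::local_tempdir()
  f <- file.path(d, "pairs.csv")
  writeLines(c("sample,phone,manual", "a,70,75", "b,90,85", "c,50,40"), f)
  tab <- read_measurement_table(f, "phone", "manual", sample_col = "sample")
  expect_s3_class(tab, "measurement_table")
  expect_equal(nrow(tab), 3L)
  expect_equal(attr(tab, "n_dropped"), 0L)
  expect_equal(tab$device, c(70, 90, 50))

  writeLines(c("sample,phone,manual", "a,70,75", "b,,85", "c,50,40"), f)
  tab2 <- read_measurement_table(f, "phone", "manual")
  expect_equal(nrow(tab2), 2L)
  expect_equal(attr(tab2, "n_dropped"), 1L)

  expect_error(read_measurement_table(f, "phonee", "manual"),
               class = "spermfx_schema_error")
  writeLines(c("phone,manual", ",", ","), f)
  expect_error(read_measurement_table(f, "phone", "manual"),
               class = "spermfx_empty_input_error")
  expect_error(measurement_table(c("a", "a"), c(1, 2), c(3, 4)),
               class = "spermfx_schema_error")
  expect_error(measurement_table(c("a", "b"), c(1, 200), c(3, 4)),
               class = "spermfx_parameter_error")
})

test_that("measurement tables load from XLSX workbooks with sheet auto-detection", {
  skip_if_not(nzchar(Sys.which("python")), "python not on PATH")
  d <- withr::local_tempdir()
  xf <- file.path(d, "supp.xlsx")
  script <- sprintf(paste0(
    "import openpyxl\n",
    "wb = openpyxl.Workbook()\n",
    "ws0 = wb.active; ws0.title = 'notes'; ws0.append(['irrelevant'])\n",
    "ws = wb.create_sheet('data')\n",
    "ws.append(['Sample', 'Smartphone', 'Manual'])\n",
    "for r in [('a', 70, 75), ('b', 90, 85), ('c', 55.5, 50)]: ws.append(r)\n",
    "wb.save(%s)\n"), shQuote(xf))
  status <- system2("python", "-", input = script, stdout = FALSE, stderr = FALSE)
  skip_if_not(status == 0 && file.exists(xf), "openpyxl unavailable")
  tab <- read_measurement_table(xf, "Smartphone", "Manual", sample_col = "Sample")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$device, c(70, 90, 55.5))
  expect_error(read_measurement_table(xf, "Smartphone", "Typo"),
               class = "spermfx_schema_error")
})

test_that("reports round-trip losslessly through JSON and CSV", {
  rep <- analysis_report(
    "hba",
    parameters = list(threshold = 80, alpha = 0.05),
    results = list(m_ha = 5.123456789012345, m_nc = 20.98765432109876,
                   percent_bound = 75.58761321837485, classification = "positive"),
    inputs = c("va", "vb"))
  d <- withr::local_tempdir()
  jf <- file.path(d, "rep.json")
  write_report(rep, jf)
  back <- read_report(jf)
  expect_equal(back$assay, "hba")
  expect_equal(back$results$percent_bound, rep$results$percent_bound,
               tolerance = 1e-15)
  expect_equal(back$results$m_ha, rep$results$m_ha, tolerance = 1e-15)
  expect_equal(back$parameters$threshold, 80)

  cf <- file.path(d, "rep.csv")
  write_report(rep, cf)
  flat <- read_report(cf)
  val <- as.numeric(flat$value[flat$key == "percent_bound"])
  expect_equal(val, rep$results$percent_bound, tolerance = 1e-15)

  expect_error(write_report(rep, file.path(d, "missing", "rep.json")),
               class = "spermfx_io_error")
  expect_error(analysis_report("hba", results = list(percent_bound = 120)),
               class = "spermfx_parameter_error")
})

test_that("configuration files override defaults and reject unknown keys", {
  d <- withr::local_tempdir()
  f <- file.path(d, "conf.yaml")
  writeLines(c("background_model:", "  alpha: 0.1", "  burn_in: 3",
               "size_gate:", "  min_area_px: 6", "hba_threshold: 70"), f)
  cfg <- load_config(f)
  expect_equal(cfg$bg_params$alpha, 0.1)
  expect_equal(cfg$bg_params$burn_in, 3L)
  expect_equal(cfg$bg_params$K, 3L)           # untouched default
  expect_equal(cfg$gate$min_area_px, 6L)
  expect_equal(cfg$hba_threshold, 70)
  writeLines(c("background_model:", "  alhpa: 0.1"), f)
  expect_error(load_config(f), class = "spermfx_schema_error")
  expect_equal(load_config(NULL)$hba_threshold, 80)
})
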