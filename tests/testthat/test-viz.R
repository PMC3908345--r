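test_that("threshold masks strictly below, keeps the boundary, spares only missing at 0", {
  g <- matrix(c(19.99, 20, 85.5, NA), 2, 2)
  out <- apply_threshold(g, 20)
  expect_true(is.na(out[1, 1]))
  expect_equal(out[2, 1], 20)
  expect_equal(out[1, 2], 85.5)
  expect_true(is.na(out[2, 2]))

  out0 <- apply_threshold(g, 0)
  expect_equal(sum(is.na(out0)), 1)  # only the missing cell
  expect_error(apply_threshold(g, 101), "\\[0, 100\\]")
})

test_that("max_downscale takes block maxima and refuses upscaling", {
  g <- matrix(1:16, 4, 4, byrow = TRUE)
  out <- max_downscale(g, 2, 2)
  expect_equal(out, matrix(c(6, 14, 8, 16), 2, 2))

  same <- max_downscale(g, 4, 4)
  expect_equal(same, matrix(as.numeric(g), 4, 4))

  expect_error(max_downscale(g, 5, 4), "upscale")

  all_na <- matrix(NA_real_, 4, 4)
  expect_true(all(is.na(max_downscale(all_na, 2, 2))))
})

test_that("max_downscale agrees with the assignment-based oracle on random grids", {
  withr::local_seed(77)
  for (k in 1:40) {
    nr <- sample(2:35, 1)
    nc <- sample(2:35, 1)
    g <- random_masked_grid(nr, nc, missing_frac = stats::runif(1, 0, 0.9))
    or <- sample(1:nr, 1)
    oc <- sample(1:nc, 1)
    expect_equal(max_downscale(g, or, oc), block_max_oracle(g, or, oc))
  }
})

test_that("no downscaled cell falls below the threshold applied before scaling", {
  withr::local_seed(88)
  for (k in 1:10) {
    g <- random_masked_grid(30, 40, 0.3)
    t <- stats::runif(1, 0, 100)
    out <- max_downscale(apply_threshold(g, t), sample(1:30, 1), sample(1:40, 1))
    vals <- out[!is.na(out)]
    expect_true(all(vals >= t))
  }
})

test_that("anchor colours are exact and interpolation is per-channel linear", {
  sc <- color_scale()
  expect_equal(unname(pid_to_color(100, sc)[1, ]), c(255, 0, 0))    # red
  expect_equal(unname(pid_to_color(70, sc)[1, ]), c(0, 0, 255))     # blue
  expect_equal(unname(pid_to_color(20, sc)[1, ]),
               unname(t(grDevices::col2rgb("#9ACD32"))[1, ]))        # yellow-green
  # midpoint of the 70 and 100 anchors, channel by channel
  expect_equal(unname(pid_to_color(85, sc)[1, ]), c(128, 0, 128))
  # masked cells take the background colour
  expect_equal(unname(pid_to_color(NA, sc)[1, ]), c(255, 255, 255))
  expect_error(pid_to_color(101, sc), "\\[0, 100\\]")
  # purity: identical calls give identical bytes
  expect_identical(pid_to_color(c(0, 13.7, 55, 99.99), sc),
                   pid_to_color(c(0, 13.7, 55, 99.99), sc))
})

test_that("sort_rows orders ascending by mean identity with accession tie-break", {
  cells <- rbind(c(90, 90), c(50, 50), c(70, 70))
  m <- identity_matrix(
    cells,
    row_meta = tibble::tibble(replicon_accession = c("A1", "B1", "C1"),
                              organism_name = "", replicon_kind = "unknown"),
    col_meta = tibble::tibble(protein_id = c("p1", "p2"), locus_tag = "",
                              product = "")
  )
  expect_equal(sort_rows(m), c(2L, 3L, 1L))

  # missing counts as zero in single-column sorts
  cells2 <- rbind(c(NA, 95), c(10, 95))
  m2 <- identity_matrix(cells2, m$row_meta[1:2, ], m$col_meta)
  expect_equal(sort_rows(m2, columns = 1), c(1L, 2L))
  # hits-only averaging instead ranks the missing row by its present cells
  expect_equal(sort_rows(m2, missing_as_zero = FALSE), c(2L, 1L))
  expect_equal(sort_rows(m2), c(1L, 2L))

  # full tie preserves accession order
  cells3 <- rbind(c(50, 50), c(50, 50), c(50, 50))
  m3 <- identity_matrix(cells3, m$row_meta, m$col_meta)
  expect_equal(sort_rows(m3), 1:3)

  expect_error(sort_rows(m, columns = integer()), "non-empty")
})

test_that("sort_rows is a permutation and sorting twice is idempotent", {
  withr::local_seed(55)
  for (k in 1:10) {
    m <- random_identity_matrix(sample(2:12, 1), sample(2:8, 1), stats::runif(1, 0, 0.5))
    p <- sort_rows(m)
    expect_setequal(p, seq_len(nrow(m$cells)))
    sorted <- identity_matrix(m$cells[p, , drop = FALSE], m$row_meta[p, ], m$col_meta)
    expect_equal(sort_rows(sorted), seq_len(nrow(m$cells)))
  }
})

test_that("locate_matrix finds rows and columns by substring, case-insensitive", {
  m <- random_identity_matrix(3, 3, 0)
  m$col_meta$product[2] <- "GMP reductase GuaC"
  m <- identity_matrix(m$cells, m$row_meta, m$col_meta)

  by_acc <- locate_matrix(m, "ACC002")
  expect_equal(by_acc$kind, "row")
  expect_equal(by_acc$index, 2L)

  by_prod <- locate_matrix(m, "guac")
  expect_true(any(by_prod$kind == "column" & by_prod$index == 2L))

  expect_equal(nrow(locate_matrix(m, "no such thing anywhere")), 0)
})

test_that("rendering writes a pixel-exact PNG and an HTML companion", {
  cells <- rbind(c(100, 70), c(20, NA))
  m <- identity_matrix(
    cells,
    row_meta = tibble::tibble(replicon_accession = c("R1", "R2"),
                              organism_name = c("o1", "o2"),
                              replicon_kind = "chromosome"),
    col_meta = tibble::tibble(protein_id = c("p1", "p2"), locus_tag = "",
                              product = "")
  )
  png_path <- withr::local_tempfile(fileext = ".png")
  html_path <- withr::local_tempfile(fileext = ".html")
  render_heatmap(m, png_path, render_spec(out_rows = 2, out_cols = 2),
                 html_path = html_path)
  img <- png::readPNG(png_path)
  expect_equal(dim(img)[1:2], c(2L, 2L))
  expected <- pid_to_color(as.vector(cells)) / 255
  expect_equal(as.vector(img[, , 1]), expected[, "r"])
  expect_equal(as.vector(img[, , 2]), expected[, "g"])
  expect_equal(as.vector(img[, , 3]), expected[, "b"])
  expect_true(any(grepl("<table>", readLines(html_path))))

  # threshold 100 with no 100-cells -> uniform background
  m2 <- identity_matrix(matrix(c(99, 50, 10, NA), 2, 2), m$row_meta, m$col_meta)
  render_heatmap(m2, png_path, render_spec(pid_threshold = 100))
  img2 <- png::readPNG(png_path)
  expect_true(all(img2 == 1))

  # oversized requests clamp to the matrix dimensions
  render_heatmap(m, png_path, render_spec(out_rows = 50, out_cols = 50))
  expect_equal(dim(png::readPNG(png_path))[1:2], c(2L, 2L))
})

test_that("autoplot returns a ggplot raster of the matrix", {
  m <- random_identity_matrix(4, 5, 0.2)
  p <- ggplot2::autoplot(m, pid_threshold = 10)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_equal(nrow(built$data[[1]]), 20)
})

test_that("a horizontally transferred block reads as a high-identity stripe in a faint row", {
  # recipient seed carries a 3-protein block copied from an otherwise
  # unrelated donor: the donor row must be >=90% exactly at those columns and
  # faint or missing everywhere else
  donor <- random_proteome(8, c(150L, 250L), 61, accession = "STRDONOR",
                           organism = "Faraway donor")
  recipient <- random_proteome(8, c(150L, 250L), 62, accession = "STRRECIP",
                               organism = "Recipient")
  for (ord in 2:4) {
    recipient$sequence[ord + 1] <- evolve_protein(donor$sequence[ord + 1], 0.01,
                                                  700 + ord)
  }
  db <- build_database(list(donor, recipient))
  m <- build_matrix(recipient, db)
  donor_row <- m$cells["STRDONOR", ]
  stripe <- unname(which(!is.na(donor_row) & donor_row >= 90))
  expect_equal(stripe, 3:5)
  background <- donor_row[-(3:5)]
  expect_true(all(is.na(background) | background < 40))
})
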