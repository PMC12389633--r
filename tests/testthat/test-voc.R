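make_ann <- function() {
  voc_annotation("plant_001.png", 640, 480, 3,
                 data.frame(name = c("Acanthus mollis", "Gentiana lutea"),
                            xmin = c(10, 200), ymin = c(20, 100),
                            xmax = c(110, 340), ymax = c(220, 260)))
}

test_that("VOC XML round-trips losslessly", {
  ann <- make_ann()
  p1 <- tempfile(fileext = ".xml")
  p2 <- tempfile(fileext = ".xml")
  write_voc_xml(ann, p1)
  back <- read_voc_xml(p1)
  expect_identical(back$filename, ann$filename)
  expect_identical(back$width, ann$width)
  expect_identical(back$height, ann$height)
  expect_equal(back$objects, ann$objects)
  # write(read(f)) == read(f)
  write_voc_xml(back, p2)
  expect_equal(read_voc_xml(p2), back)
  unlink(c(p1, p2))
})

test_that("parsed fields match the authored fixture exactly", {
  ann <- voc_annotation("a.png", 400, 300, 3,
                        data.frame(name = "Acanthus mollis", xmin = 10,
                                   ymin = 20, xmax = 110, ymax = 220))
  p <- tempfile(fileext = ".xml")
  write_voc_xml(ann, p)
  got <- read_voc_xml(p)
  expect_identical(got$objects$name, "Acanthus mollis")
  expect_equal(unlist(got$objects[1, 2:5]),
               c(xmin = 10, ymin = 20, xmax = 110, ymax = 220))
  # 0-based half-open conversion happens at this one boundary
  expect_equal(as.vector(plantrcnn:::ann_boxes(got)), c(9, 19, 110, 220))
  unlink(p)
})

test_that("malformed annotations are rejected by element name", {
  p <- tempfile(fileext = ".xml")
  writeLines("<annotation><filename>x.png</filename></annotation>", p)
  expect_error(read_voc_xml(p), "<size>")
  writeLines(paste0("<annotation><size><width>10</width>",
                    "<height>10</height></size>",
                    "<object><name>x</name></object></annotation>"), p)
  expect_error(read_voc_xml(p), "bndbox")
  unlink(p)
  expect_error(voc_annotation("f", 100, 100, 3,
                              data.frame(name = "a", xmin = 50, ymin = 1,
                                         xmax = 20, ymax = 10)),
               "degenerate")
  expect_error(voc_annotation("f", 100, 100, 3,
                              data.frame(name = "a", xmin = 1, ymin = 1,
                                         xmax = 200, ymax = 10)),
               "bounds")
})

test_that("stratified splitting is exact, disjoint and deterministic", {
  # exact division: 100 records per class at 0.8/0.1/0.1
  labels <- rep(c("a", "b"), each = 100)
  sp <- stratified_split(labels, c(0.8, 0.1, 0.1), seed = 1)
  for (cl in c("a", "b")) {
    expect_identical(sum(labels[sp$train] == cl), 80L)
    expect_identical(sum(labels[sp$val] == cl), 10L)
    expect_identical(sum(labels[sp$test] == cl), 10L)
  }

  # determinism
  expect_identical(stratified_split(labels, seed = 7),
                   stratified_split(labels, seed = 7))

  # the five-class composition with per-class totals 110/95/103/99/124
  counts <- c(110, 95, 103, 99, 124)
  labels5 <- rep(paste0("c", 1:5), times = counts)
  sp5 <- stratified_split(labels5, c(0.8, 0.1, 0.1), seed = 2)
  idx <- unlist(sp5)
  expect_identical(length(idx), 531L)           # partition is exhaustive
  expect_identical(anyDuplicated(idx), 0L)      # and disjoint
  for (i in 1:5) {
    n <- counts[i]
    cl <- paste0("c", i)
    expect_lte(abs(sum(labels5[sp5$train] == cl) - 0.8 * n), 1)
    expect_lte(abs(sum(labels5[sp5$val] == cl) - 0.1 * n), 1)
    expect_lte(abs(sum(labels5[sp5$test] == cl) - 0.1 * n), 1)
  }

  # degenerate stratum goes to train with a warning
  expect_warning(spd <- stratified_split(c("a", "a", rep("b", 30)),
                                         seed = 3),
                 "fewer records")
  expect_identical(sum(c("a", "a", rep("b", 30))[spd$train] == "a"), 2L)

  expect_error(stratified_split(labels, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("brightness statistics use the standard luminance", {
  cst <- array(128, c(4, 4, 3))
  blk <- array(0, c(4, 4, 3))
  bs <- brightness_stats(list(cst, blk))
  expect_equal(unname(bs$mean), c(128, 0))

  # 2x1 gray image with pixels 100 and 120
  two <- array(c(100, 120), c(2, 1, 3))
  expect_equal(unname(brightness_stats(list(two))$mean), 110)

  # channel weights 0.299/0.587/0.114
  red <- array(0, c(2, 2, 3)); red[, , 1] <- 200
  expect_equal(unname(brightness_stats(list(red))$mean), 0.299 * 200)
  expect_error(brightness_stats(list()), "empty")
})

test_that("resolution tables count exact multisets", {
  anns <- list(voc_annotation("a", 640, 480),
               voc_annotation("b", 640, 480),
               voc_annotation("c", 640, 480))
  rt <- resolution_table(anns)
  expect_identical(nrow(rt), 1L)
  expect_identical(rt$count, 3L)
  expect_identical(rt$width, 640L)

  expect_identical(nrow(resolution_table(list())), 0L)

  mixed <- c(anns, list(voc_annotation("d", 512, 512),
                        voc_annotation("e", 512, 512),
                        voc_annotation("f", 500, 375)))
  rt2 <- resolution_table(mixed)
  expect_identical(nrow(rt2), 3L)
  tallied <- setNames(rt2$count, paste(rt2$width, rt2$height))
  expect_identical(tallied[["640 480"]], 3L)
  expect_identical(tallied[["512 512"]], 2L)
  expect_identical(tallied[["500 375"]], 1L)
})
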