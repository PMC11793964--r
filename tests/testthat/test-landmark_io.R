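test_that("long and wide CSV dialects parse and round-trip losslessly", {
  set.seed(101)
  configs <- lapply(1:5, function(i)
    landmark_config(paste0("sp", i), rand_config(7), paste0("lm", 1:7)))
  ds <- landmark_dataset(configs)

  for (schema in c("long", "wide")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_landmarks_csv(ds, path, schema)
    back <- read_landmarks_csv(path, schema)
    expect_equal(back$specimen_id, ds$specimen_id)
    expect_lt(max(abs(back$coords - ds$coords)), 1e-12)
  }

  # long file with 2 specimens x 4 landmarks parses directly
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("specimen_id,landmark,x,y,z",
               paste0("a,L", 1:4, ",", 1:4, ",0,0"),
               paste0("b,L", 1:4, ",", 5:8, ",1,1")), p)
  frag <- read_landmarks_csv(p, "long")
  expect_equal(dim(frag$coords), c(4L, 3L, 2L))
  expect_equal(frag$coords[3, 1, "b"], 7)
})

test_that("CSV validation names the offending specimen and landmark", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("specimen_id,landmark,x,y,z",
               paste0("a,L", 1:4, ",0,0,0"),
               paste0("b,L", 1:3, ",0,0,0")), p)   # b misses landmark 4
  expect_error(read_landmarks_csv(p, "long"), "b.*landmark 4")

  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("specimen_id,landmark,x,y,z",
               paste0("a,L", 1:4, ",0,0,0"),
               "b,L1,0,0,0", "b,L2,0,oops,0", "b,L3,0,0,0", "b,L4,0,0,0"), p2)
  expect_error(read_landmarks_csv(p2, "long"), "non-numeric.*'b'")

  # wide file whose second row omits a z coordinate
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(paste0("id,", paste(paste0(c("x", "y", "z"), rep(1:4, each = 3)),
                                   collapse = ",")),
               paste("a", paste(rep("1", 12), collapse = ","), sep = ","),
               paste("b", paste(c(rep("1", 11), ""), collapse = ","), sep = ",")),
             p3)
  expect_error(read_landmarks_csv(p3, "wide"), "'b'.*landmark 4")

  expect_error(landmark_config("bad", matrix(c(NaN, rep(0, 11)), 4, 3)),
               "non-finite.*'bad'.*landmark 1")
})

test_that("TPS records parse with ID and SCALE semantics and round-trip", {
  p <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM3=4", "0 0 0", "1 0 0", "0 1 0", "0 0 1", "ID=a",
               "LM3=4", "0 0 0", "1 0 0", "0 1 0", "0 0 1",
               "SCALE=2.0", "ID=b"), p)
  ds <- read_tps(p)
  expect_equal(ds$specimen_id, c("a", "b"))
  expect_equal(ds$coords[, , "b"], 2 * ds$coords[, , "a"],
               ignore_attr = TRUE)

  # count mismatch names the record
  p2 <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM3=4", "0 0 0", "1 0 0", "0 1 0", "ID=a"), p2)
  expect_error(read_tps(p2), "record 1")

  # generated 135-record file has n = 135, and round-trips
  set.seed(77)
  configs <- lapply(1:135, function(i)
    landmark_config(paste0("sp", i), rand_config(5)))
  big <- landmark_dataset(configs)
  p3 <- withr::local_tempfile(fileext = ".tps")
  write_tps(big, p3)
  back <- read_tps(p3)
  expect_equal(dim(back$coords)[3], 135L)
  expect_lt(max(abs(back$coords - big$coords)), 1e-12)
})

test_that("pts files parse headers and quoted names and round-trip", {
  p <- withr::local_tempfile(fileext = ".pts")
  writeLines(c("5", "prosthion 0.5 1.25 -3", '"nasal tip" 1 2 3',
               "bregma 0 0 1", "lambda 1 1 1", "basion -1 0 2"), p)
  cfg <- read_pts(p, "spec1")
  expect_equal(nrow(cfg$coords), 5L)
  expect_equal(cfg$landmark_names[2], "nasal tip")
  expect_equal(unname(cfg$coords[1, ]), c(0.5, 1.25, -3))

  p2 <- withr::local_tempfile(fileext = ".pts")
  write_pts(cfg, p2)
  back <- read_pts(p2, "spec1")
  expect_identical(back$landmark_names, cfg$landmark_names)
  expect_lt(max(abs(back$coords - cfg$coords)), 1e-12)

  p3 <- withr::local_tempfile(fileext = ".pts")
  writeLines(c("a 0 0 0", "b 1 1 1", "c 2 2 2"), p3)
  expect_error(read_pts(p3), "fewer than 4")
})

test_that("assemble_dataset joins by id, reports design counts, is order-stable", {
  set.seed(55)
  n <- c(DE_h = 28, DE_m = 20, DL_h = 23, DL_m = 16, w_h = 33, w_m = 15)
  ids <- paste0("s", seq_len(sum(n)))
  configs <- lapply(ids, function(id) landmark_config(id, rand_config(6)))
  frag <- landmark_dataset(configs)
  md <- data.frame(specimen_id = ids,
                   lineage = rep(c("DE", "DE", "DL", "DL", "wild", "wild"), n),
                   period = rep(rep(c("historic", "modern"), 3), n))
  sym <- symmetry_map(cbind(1:2, 3:4), midline = 5:6)

  ds <- assemble_dataset(frag, md, sym)
  expect_equal(as.vector(table(ds$lineage, ds$period)),
               c(28, 23, 33, 20, 16, 15))

  # metadata row order never matters
  ds2 <- assemble_dataset(frag, md[rev(seq_len(nrow(md))), ], sym)
  expect_identical(ds$coords, ds2$coords)
  expect_identical(ds$lineage, ds2$lineage)

  # dataset is sized by the coordinates; metadata superset ignored
  md_plus <- rbind(md, data.frame(specimen_id = "ghost", lineage = "DE",
                                  period = "modern"))
  expect_equal(dim(assemble_dataset(frag, md_plus, sym)$coords)[3], sum(n))

  # specimens without metadata dropped with a warning
  expect_warning(ds3 <- assemble_dataset(frag, md[-1, ], sym), "dropping 1")
  expect_equal(dim(ds3$coords)[3], sum(n) - 1L)

  expect_error(assemble_dataset(frag,
                                data.frame(specimen_id = "none",
                                           lineage = "DE", period = "modern")),
               "no specimen ids shared")
  md_bad <- md; md_bad$lineage[1] <- "landrace"
  expect_error(assemble_dataset(frag, md_bad, sym), "unknown lineage")
  expect_error(assemble_dataset(frag, md, symmetry_map(cbind(1:2, 3:4),
                                                       midline = c(5, 7))),
               "out of range")
})

test_that("symmetry maps must partition 1..k and reject re-used indices", {
  expect_error(symmetry_map(cbind(1:2, 2:3)), "re-uses")
  expect_error(validate_symmetry_map(symmetry_map(cbind(1, 2)), 4),
               "does not partition")
  expect_silent(validate_symmetry_map(symmetry_map(cbind(1, 2), midline = 3:4), 4))

  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("left,right", "1,2", "3,", "5,6"), p)
  map <- read_symmetry_csv(p, 6)
  expect_equal(nrow(map$pairs), 2L)
  expect_equal(map$midline, c(3L, 4L))  # explicit + implicit midline
})
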