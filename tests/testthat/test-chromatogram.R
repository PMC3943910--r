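test_that("chromatogram CSV round-trips at full precision and rejects bad input", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("scan,response", "0,1.0", "1,2.0", "2,1.5"), p)
  ch <- read_chromatogram(p, "breath", "A")
  expect_equal(ch$response, c(1.0, 2.0, 1.5))
  expect_equal(ch$scan_rate, 3013)

  # round-trip of awkward doubles
  set.seed(7)
  orig <- chromatogram(rnorm(50) * pi, "air", "B", scan_rate = 100)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_chromatogram(orig, p2)
  back <- read_chromatogram(p2, "air", "B", scan_rate = 100)
  expect_identical(back$response, orig$response)

  writeLines(c("scan,response", "0,1.0", "1,NaN"), p)
  expect_error(read_chromatogram(p, "breath"), "row 2")
  writeLines(c("scan,response", "0,1.0", "0,2.0"), p)
  expect_error(read_chromatogram(p, "breath"), "increasing")
  writeLines(c("foo,bar", "0,1.0"), p)
  expect_error(read_chromatogram(p, "breath"), "header")
  expect_error(read_chromatogram(file.path(tempdir(), "no-such.csv"), "breath"),
               "not found")
  expect_error(chromatogram(numeric(0), "breath"), "at least one")
  expect_error(chromatogram(c(1, Inf), "breath"), "non-finite")
})

test_that("subject records enforce matched breath/air pairs", {
  b <- chromatogram(1:10, "breath", "A")
  a <- chromatogram(10:1, "air", "A")
  rec <- subject_record("A", "disease", b, a)
  expect_s3_class(rec, "subject_record")
  expect_error(subject_record("A", "disease", b, chromatogram(1:9, "air")),
               "scan count")
  expect_error(subject_record("A", "disease", b,
                              chromatogram(10:1, "air", scan_rate = 99)),
               "scan_rate")
  expect_error(subject_record("A", "disease", a, b), "breath chromatogram")
})

test_that("cohort manifests are validated and resolved relative to their directory", {
  dir <- withr::local_tempdir()
  for (s in c("A", "B")) {
    write_chromatogram(chromatogram(1:5, "breath", s),
                       file.path(dir, paste0(s, "_b.csv")))
    write_chromatogram(chromatogram(5:1, "air", s),
                       file.path(dir, paste0(s, "_a.csv")))
  }
  man <- file.path(dir, "manifest.csv")
  writeLines(c("subject_id,label,breath_path,air_path",
               "A,disease,A_b.csv,A_a.csv",
               "B,control,B_b.csv,B_a.csv"), man)
  coh <- read_cohort(man)
  expect_length(coh, 2L)
  expect_equal(vapply(coh, `[[`, character(1), "label"),
               c("disease", "control"))

  writeLines(c("subject_id,label,breath_path,air_path",
               "A,maybe,A_b.csv,A_a.csv"), man)
  expect_error(read_cohort(man), "unknown group label 'maybe'")
  writeLines(c("subject_id,label,breath_path,air_path",
               "A,disease,ghost.csv,A_a.csv"), man)
  expect_error(read_cohort(man), "ghost.csv")
  writeLines(c("subject_id,label,breath_path,air_path",
               "A,disease,A_b.csv,A_a.csv",
               "A,control,B_b.csv,B_a.csv"), man)
  expect_error(read_cohort(man), "duplicate")
})

test_that("segment schemes tile the scan axis disjointly", {
  sch <- segment_scheme(3013, 100)
  expect_equal(sch$n_segments, 31L)
  expect_equal(unname(sch$bounds[31, "end"] - sch$bounds[31, "start"]), 13L)
  expect_equal(segment_scheme(50, 50)$n_segments, 1L)
  expect_equal(segment_scheme(50, 500)$n_segments, 1L)  # width > n is fine
  expect_equal(segment_scheme(50, 1)$n_segments, 50L)
  expect_error(segment_scheme(50, 0), "width_scans")
  expect_error(segment_scheme(0, 10), "n_scans")

  # tiling property: widths sum to n_scans, segments disjoint and ordered
  set.seed(3)
  for (i in 1:25) {
    n <- sample(1:500, 1); w <- sample(1:60, 1)
    s <- segment_scheme(n, w)
    widths <- s$bounds[, "end"] - s$bounds[, "start"]
    expect_equal(sum(widths), n)
    expect_true(all(s$bounds[-1, "start"] == s$bounds[-s$n_segments, "end"]))
    expect_equal(scan_to_segment(s$bounds[, "start"], s), seq_len(s$n_segments))
  }
  expect_error(scan_to_segment(3013, sch), "outside")
})

test_that("alveolar gradients are breath minus air per segment", {
  sch <- segment_scheme(6, 3)
  rec <- make_record("A", "disease", c(1, 2, 3, 4, 5, 6), c(0, 0, 0, 1, 1, 1))
  expect_equal(alveolar_gradients(rec, sch, "sum")$gradients, c(6, 12))

  same <- make_record("B", "control", 1:6, 1:6)
  expect_identical(alveolar_gradients(same, sch)$gradients, c(0, 0))

  shifted <- make_record("C", "control", 1:6 + 2.5, as.numeric(1:6))
  expect_equal(alveolar_gradients(shifted, sch, "mean")$gradients, c(2.5, 2.5))

  # antisymmetry: swapping breath and air negates every gradient exactly
  set.seed(11)
  for (i in 1:10) {
    b <- rnorm(30); a <- rnorm(30)
    s <- segment_scheme(30, sample(1:10, 1))
    fwd <- alveolar_gradients(make_record("X", "disease", b, a), s)$gradients
    rev <- alveolar_gradients(make_record("X", "disease", a, b), s)$gradients
    expect_identical(fwd, -rev)
  }

  expect_error(alveolar_gradients(rec, segment_scheme(7, 3)), "built for 7")
})

test_that("kovats index interpolates between bracketing n-alkanes", {
  ladder <- alkane_ladder(6:22, retention_times = (6:22)^1.3 / 10)
  rt10 <- ladder$retention_times[ladder$carbon_numbers == 10]
  rt11 <- ladder$retention_times[ladder$carbon_numbers == 11]
  expect_equal(kovats_index(rt10, ladder), 1000)
  expect_equal(kovats_index((rt10 + rt11) / 2, ladder), 1050)
  expect_error(kovats_index(min(ladder$retention_times) - 0.01, ladder),
               "outside")
  expect_error(kovats_index(max(ladder$retention_times) + 0.01, ladder),
               "outside")

  # strictly increasing in rt within the ladder range
  rts <- seq(min(ladder$retention_times), max(ladder$retention_times),
             length.out = 200)
  expect_true(all(diff(kovats_index(rts, ladder)) > 0))

  # gapped ladder uses the actual carbon numbers of the bracketing alkanes
  gap <- alkane_ladder(c(10, 12), c(1, 2))
  expect_equal(kovats_index(1.5, gap), 1100)

  # CSV reader
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("carbon_number,rt_min", "6,0.5", "7,0.9"), p)
  expect_equal(kovats_index(0.7, read_alkane_ladder(p)), 650)
  expect_error(alkane_ladder(c(7, 6), c(1, 2)), "strictly increasing")
})
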